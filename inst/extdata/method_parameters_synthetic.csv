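analyte,slope,intercept,recovery,matrix_effect
Sulfapyridine,1174.07,0,0.9300,-0.0575
Sulfathiazole,633.811,0,0.4420,0.0187
Sulfamethazine,2324.3,0,0.6983,-0.0345
Sulfadimethoxine,2670.56,0,0.4937,-0.0175
Sulfamethoxazole,1626.52,0,0.4357,-0.0195
Sulfamethoxypyridazine,2057.08,0,0.7047,0.0305
Sulfamerazine,1345.72,0,0.8203,-0.0035
Trimethoprim,1588.92,0,0.9057,0.0317
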