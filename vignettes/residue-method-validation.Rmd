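---
title: "Targeted LC-HRMS residue quantification and method validation with residuescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted LC-HRMS residue quantification and method validation with residuescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(residuescreen)
```

## The problem

Sulfonamide antimicrobials and trimethoprim are used (and misused) in fish
farming; regulators cap their residues in fin-fish muscle at a maximum residue
limit (MRL) of 100 ng·g⁻¹ for individual sulfonamides or their combined total,
and 50 ng·g⁻¹ for trimethoprim. A surveillance laboratory therefore needs
(i) identity confirmation of each candidate peak by accurate mass, retention
time and identification points; (ii) quantification against matrix-matched
calibration; (iii) a documented method validation — linearity, sensitivity,
matrix effect, recovery, precision, decision limit CCα, detection capability
CCβ, LOD and LOQ; and (iv) a compliance decision per sample, including the
summed-sulfonamide rule.

`residuescreen` implements that computational chain for the eight monitored
compounds (seven sulfonamides and trimethoprim, bundled as a target list with
formulas, retention times, fragment ions, groups and MRLs), and pairs it with
a synthetic-data generator that emulates a full validation campaign so every
stage can be exercised and tested end to end with known ground truth.

## Models and statistics

**Mass arithmetic.** Formulas are parsed from Hill notation; monoisotopic
masses are count-weighted sums over a curated table (C = 12 exact,
H = 1.00782503, N = 14.00307401, O = 15.99491462, S = 31.97207069 Da, …).
The protonated molecular ion is computed as M + 1.00727646 Da (proton mass) by
default. Instrument reports sometimes reference M + H with the *neutral*
hydrogen mass instead; the published ppm errors for these compounds are
consistent with that convention for 7 of 8 analytes, so `adduct_mz()` exposes
`reference = "proton"|"hydrogen"` rather than forcing agreement. Mass errors
are signed ppm, `1e6·(obs − theo)/theo`.

**Identity confirmation.** A peak matches a target when |ppm error| ≤ 5 ppm
and |ΔRT| ≤ 0.1 min (defaults; the source method states no tolerances, these
are conventional Q-TOF screening values and are arguments everywhere).
Identification points follow the high-resolution rule: 2.0 for the precursor,
2.5 per fragment; the default confirmation threshold is 4.0 points for
prohibited (group A) and 3.0 for authorized (group B) substances, so precursor
plus one fragment (4.5) confirms. Fragment matching reuses the precursor ppm
tolerance (one knob); each target fragment can be claimed by one observed
fragment, assigned greedily by |ppm| so the score is order-invariant. When
several peaks match, the smallest |ppm| wins, then the smallest |ΔRT|.

**Calibration and quantification.** `fit_curve()` is unweighted ordinary
least squares of level-mean area on nominal concentration (≥ 3 distinct
levels), with the linearity gate R² ≥ 0.99. Quantification inverts the line
and applies the injection dilution factor and a tissue factor (g-equivalent
tissue per mL extract; default 1.0, the value implied by 2.5 g extracted into
10 mL with a 2 mL aliquot reconstituted in 0.5 mL, which makes extract
ng·mL⁻¹ numerically equal to tissue ng·g⁻¹ — the two unit systems are treated
as interchangeable throughout). Negative back-calculations are clamped to 0
and flagged for reporting, but all validation statistics (recovery means,
CVs, decision-limit SDs) use the signed values: truncating at zero would bias
every replicate average computed near the bottom of the curve.

**Validation statistics.** CV% is 100·SD/mean with the n−1 SD. The matrix
effect is 100·(extract − solvent)/solvent, negative for suppression — the
orientation forced by the published tables — with |ME| > 20% flagged as
relevant. Recovery is measured/nominal in percent, with the measured
concentration read against the *post-extraction fortified-extract* curve so
that the ratio isolates preparation losses from ionization effects.
Repeatability is the within-day CV (5 replicates); intermediate precision
pools all days at a level (3 × 5 = 15 results), which is why the interday
rows of a validation report coincide with the accuracy CVs at n = 15. The
decision limit is CCα = MRL + 1.64·SD of 20 blanks fortified at the MRL, and
CCβ = CCα + 1.64·SD of 20 blanks fortified at CCα, with the literal constant
1.64. LOD is the smallest level with S/N ≥ 3 (S/N = window max minus baseline
median, over baseline SD); LOQ is the smallest calibration level with
replicate CV ≤ 20%, both inclusive at the boundary.

**Compliance.** An analyte is nonconforming only when its identity is
confirmed *and* its concentration reaches CCα — a concentration between LOQ
and CCα never triggers nonconformity (that is the 5% false-positive
protection), and an unconfirmed identity is reported as conforming with an
explicit "identity not confirmed" rationale, never acted on quantitatively.
The group rule sums confirmed, quantifiable (≥ LOQ) sulfonamide
concentrations and compares the total to the group MRL of 100 ng·g⁻¹; no
group-level CCα exists, a limitation recorded in the decision rationale.

## The synthetic world

`simulate_validation_campaign()` generates integrated peak areas under

    area = intercept + slope · (1 + ME) · recovery · (conc / dilution) · ε

where ε is mean-one lognormal noise with CV `noise_cv` (areas are positive
and published precision CVs are scale-free, so multiplicative noise is the
natural choice). Solvent standards omit both factors, post-extraction
fortified extracts omit recovery only, and full-procedure (matrix-matched)
samples carry both — matching the mechanistic attribution of slope
differences to ionization effects versus preparation losses. Observed m/z
values are jittered by 1 ppm (SD), retention times by 0.01 min.

Defaults restate the study design: calibration at 5.0–250.0 ng·g⁻¹ in
duplicate in all three modes; spikes at 10/20/40 ng·g⁻¹, 5 replicates × 3
days; 20 fortified blanks at the MRL and 20 at the true CCα (the generator
knows the truth MRL·(1 + 1.64·noise_cv), which the real experiment
approximates iteratively); incurred-like samples at 1062.9 ng·g⁻¹ measured
in 10 replicates after 10-fold dilution. Per-analyte slopes and the recovery
and matrix-effect fractions are the bundled synthetic parameter set derived
from the published validation summary (level-mean recovery/100, level-mean
matrix effect/100); `noise_cv` defaults to 0.10, the magnitude of the
published CVs. There is no between-day variance by default (the published
interday CVs barely exceed the intraday ones); a `between_day_cv` knob
exists. Everything is scoped to a mandatory seed and regenerates
bit-identically.

What the generator does *not* emulate: raw spectra and peak integration,
isotope envelopes, baseline drift, carryover, day-to-day RT drift, and any
correlation between analytes within a sample. A green test therefore
establishes the correctness of the statistical chain from integrated areas
onward, not of peak picking.

The LOD/LOQ scenario (`simulate_lod_loq_scenario()`) deserves its own note.
The S/N estimator takes the *maximum* of the peak window, which carries a
positive noise-floor bias equal to the expected maximum order statistic of
the window (≈ 2σ for a 41-point window). A level at half the LOD can
therefore not be held below S/N 3 with a proportional response; the sub-LOD
demonstration level is 0.1 ng·g⁻¹, where the true amplitude (0.4 baseline
SDs) is negligible against that floor, and S/N is averaged over 10 replicate
chromatograms (the same replication used to validate the LOQ). The LOQ
replicate sets are drawn stochastically and rescaled to exact sample CVs
(25%, 18%, 5% at 2.5, 5.0, 12.5 ng·g⁻¹), so the 20% crossing at 5.0 ng·g⁻¹
is deterministic for any seed.

## Numerical and design choices

* **R² of a perfect or flat fit**: computed directly from sums of squares;
  a zero total sum of squares yields R² 1 for an exact fit and 0 otherwise.
* **Reported masses** round half-even to 4 decimals (R's `round()`).
* **Unweighted OLS** is the stated fitting method, and it has a real
  consequence this package surfaces rather than hides: with 10%
  multiplicative noise, the top calibration level (250 ng·g⁻¹) dominates the
  fit, the estimated intercept carries ≈ 3.3 ng·g⁻¹ of concentration-scale
  noise, and quantification of 10 ng·g⁻¹ spikes inherits it. Validation
  statistics therefore use unclamped values (above), and occasional interday
  CV-gate failures at the lowest spike level are an honest property of this
  world, reported by `run_validate()` rather than suppressed. Weighted
  fitting would mitigate this but is deliberately not the default.
* **Monte-Carlo acceptance bands** for parameter-recovery checks are
  3 Monte-Carlo standard errors *plus the analytic finite-sample expectation
  offset of the estimator*, fixed a priori from design constants: the
  relative variance of the OLS slope under multiplicative noise
  (v_b = cv²·Σ(c−c̄)²c²/(m·S_cc²) ≈ 0.0045 for the default design) biases
  quantities divided by the estimated slope upward by ≈ 0.45%, and the n = 20
  sample SD inside CCα has expectation c₄(20)·σ ≈ 0.987·σ. Without these
  allowances an exact 3·SE test at 200 seeds would reject a correct
  implementation with ≈ 10–20% probability.
* **Infeasible linearity quantifier**: the acceptance clause "every
  matrix-matched curve reaches R² ≥ 0.99" cannot hold under the stated noise:
  E[R²] ≈ 0.995 but P(R² < 0.99) ≈ 0.10 per curve (the published R² range
  0.9914–0.9994 sits inside this distribution), so over 1600 simulated
  curves the minimum falls below the gate with probability ≈ 1. The
  corresponding test is implemented faithfully and left failing, with the
  observed distribution in its failure message.
* **S/N oracle expectations** account for the max-statistic bias: for a
  strong peak (amplitude 10 SD) the bias is small and the estimate lands in
  10 ± 2; near the detection limit (amplitude 3 SD) the estimate sits 1–2.5
  units above the amplitude ratio, and tests assert that band rather than an
  idealized 3.0 ± 0.5.

## Known limitations

Only `[M+H]+` and `[M+Na]+` adducts and a small curated element table are
provided (extensible by passing a custom table). No measurement-uncertainty
budget, ruggedness or stability testing. The group-sum rule is MRL-based
only. Chromatographic simulation is a single Gaussian per trace — sufficient
for the S/N rule it feeds, nothing more.
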