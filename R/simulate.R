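#' Ground-truth configuration of the synthetic measurement chain
#'
#' Describes the world the simulator draws from: per-analyte response slopes,
#' preparation recovery and matrix-effect fractions, the multiplicative
#' measurement noise, and the design of the validation campaign (calibration
#' levels in duplicate, spiking levels with 5 replicates on 3 days, 20
#' fortified blanks at the MRL and 20 at CCalpha, plus high-concentration
#' incurred-like samples measured after dilution).
#'
#' The defaults emulate the validated tilapia method: calibration at 5.0 to
#' 250.0 ng/g, spikes at 10/20/40 ng/g, per-analyte slopes and mean
#' recovery/matrix-effect fractions taken from the published validation
#' summary (bundled as `method_parameters_synthetic.csv`), and 10%
#' multiplicative noise, the magnitude of the published precision CVs.
#'
#' @param seed Integer seed; mandatory, every draw is scoped to it.
#' @param analytes Data frame with columns `analyte`, `slope` (counts per
#'   ng/g), `intercept` (counts), `recovery` (fraction in (0, 1.5]) and
#'   `matrix_effect` (signed fraction). Default: the bundled synthetic
#'   parameter set for the eight monitored compounds.
#' @param targets Target list providing m/z, retention time and fragments
#'   (default [read_targets()]).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (mean-one lognormal) area noise.
#' @param calibration_levels Nominal calibration concentrations, ng/g.
#' @param calibration_replicates Injections per calibration level.
#' @param me_levels Levels at which the matrix effect is evaluated, ng/g.
#' @param spike_levels Fortification levels for accuracy/precision, ng/g.
#' @param replicates_per_day,days Spike replication design.
#' @param n_fortified Fortified blanks per decision-limit experiment (>= 20).
#' @param between_day_cv CV of an optional multiplicative day effect
#'   (default 0: interday ~ intraday, as observed).
#' @param mz_jitter_ppm SD of the relative m/z error, ppm.
#' @param rt_jitter_min SD of the retention-time error, minutes.
#' @param incurred List describing the incurred-like samples: `analyte`,
#'   true `conc` (ng/g), `n` replicates, `dilution_factor` applied before
#'   injection so the diluted extract falls inside the calibration range.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              analytes = default_method_parameters(),
                              targets = read_targets(),
                              noise_cv = 0.10,
                              calibration_levels = c(5, 12.5, 25, 50, 75, 100,
                                                     125, 250),
                              calibration_replicates = 2L,
                              me_levels = c(12.5, 50, 100),
                              spike_levels = c(10, 20, 40),
                              replicates_per_day = 5L,
                              days = 3L,
                              n_fortified = 20L,
                              between_day_cv = 0,
                              mz_jitter_ppm = 1,
                              rt_jitter_min = 0.01,
                              incurred = list(analyte = "Sulfamethazine",
                                              conc = 1062.9, n = 10L,
                                              dilution_factor = 10)) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(noise_cv >= 0, between_day_cv >= 0, n_fortified >= 1L,
            all(c("analyte", "slope", "intercept", "recovery",
                  "matrix_effect") %in% names(analytes)),
            all(analytes$recovery > 0 & analytes$recovery <= 1.5),
            all(analytes$analyte %in% targets$name))
  structure(list(
    seed = as.integer(seed), analytes = analytes, targets = targets,
    noise_cv = noise_cv, calibration_levels = calibration_levels,
    calibration_replicates = as.integer(calibration_replicates),
    me_levels = me_levels, spike_levels = spike_levels,
    replicates_per_day = as.integer(replicates_per_day),
    days = as.integer(days), n_fortified = as.integer(n_fortified),
    between_day_cv = between_day_cv, mz_jitter_ppm = mz_jitter_ppm,
    rt_jitter_min = rt_jitter_min, incurred = incurred
  ), class = "simulation_config")
}

#' Default per-analyte synthetic method parameters
#'
#' Slopes (sensitivity, counts per ng/g) and mean recovery and matrix-effect
#' fractions for the eight monitored compounds, seeded from the published
#' validation summary of the tilapia method (level-mean recoveries / 100 and
#' level-mean matrix effects / 100). These are the ground-truth parameters of
#' the synthetic world, not measured data.
#'
#' @return Data frame `analyte`, `slope`, `intercept`, `recovery`,
#'   `matrix_effect`.
#' @export
default_method_parameters <- function() {
  path <- system.file("extdata", "method_parameters_synthetic.csv",
                      package = "residuescreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# mean-one lognormal multiplicative noise factors with the requested CV
.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

# mode-dependent effective response: solvent standards see neither the matrix
# nor the preparation losses; post-extraction fortified extract sees only the
# matrix; matrix-matched (full-procedure) samples see both
.mode_factor <- function(mode, recovery, matrix_effect) {
  switch(mode,
    solvent = 1,
    fortified_extract = 1 + matrix_effect,
    matrix_matched = (1 + matrix_effect) * recovery,
    stop("unknown preparation mode: ", mode)
  )
}

# draw areas/mz/rt for a sample sheet using the *current* RNG state
.sim_peaks <- function(config, samples) {
  p <- config$analytes
  tg <- config$targets
  n <- nrow(samples)
  day_fac <- rep(1, n)
  if (config$between_day_cv > 0 && !is.null(samples$day)) {
    for (d in unique(stats::na.omit(samples$day))) {
      f <- .noise_factor(1, config$between_day_cv)
      day_fac[!is.na(samples$day) & samples$day == d] <- f
    }
  }
  out <- samples
  out$area <- NA_real_
  out$mz <- NA_real_
  out$rt <- NA_real_
  out$fragments <- NA_character_
  eps <- .noise_factor(n, config$noise_cv)
  mzjit <- stats::rnorm(n, 0, config$mz_jitter_ppm) * 1e-6
  rtjit <- stats::rnorm(n, 0, config$rt_jitter_min)
  fragjit <- stats::rnorm(n, 0, config$mz_jitter_ppm) * 1e-6
  for (i in seq_len(n)) {
    a <- samples$analyte[i]
    ip <- match(a, p$analyte)
    it <- match(a, tg$name)
    if (is.na(ip) || is.na(it)) stop("unknown analyte in sample sheet: ", a)
    fac <- .mode_factor(samples$mode[i], p$recovery[ip], p$matrix_effect[ip])
    conc_injected <- samples$conc[i] / samples$dilution_factor[i]
    out$area[i] <- p$intercept[ip] +
      p$slope[ip] * fac * conc_injected * eps[i] * day_fac[i]
    out$mz[i] <- tg$precursor_mz[it] * (1 + mzjit[i])
    out$rt[i] <- tg$rt_min[it] + rtjit[i]
    frs <- .parse_fragment_list(tg$fragment_mz[it])
    out$fragments[i] <- paste(sprintf("%.4f", frs * (1 + fragjit[i])),
                              collapse = ";")
  }
  out$height <- out$area / 3  # nominal peak shape factor; area carries signal
  out
}

#' Simulate an integrated peak table
#'
#' Generates one integrated peak per row of the sample sheet under the
#' multiplicative measurement model
#' `area = intercept + slope * (1 + ME) * recovery * conc / dilution * eps`,
#' where the matrix-effect and recovery factors apply according to the
#' preparation mode (see [simulation_config()]) and `eps` is mean-one
#' lognormal noise with CV `noise_cv`. Observed m/z and retention times are
#' jittered around the target values. Deterministic under `config$seed`.
#'
#' @param config A `simulation_config`.
#' @param samples Sample sheet: data frame with columns `sample_id`,
#'   `analyte`, `mode` (`"solvent"`, `"fortified_extract"`,
#'   `"matrix_matched"`), `conc` (true tissue concentration, ng/g), and
#'   optionally `dilution_factor` (default 1) and `day`.
#' @return List with `peaks` (the sample sheet plus `area`, `height`, `mz`,
#'   `rt`, `fragments`) and `truth` (the ground-truth parameters echoed from
#'   the config).
#' @export
simulate_peak_table <- function(config, samples) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(samples),
            all(c("sample_id", "analyte", "mode", "conc") %in% names(samples)))
  if (is.null(samples$dilution_factor)) samples$dilution_factor <- 1
  peaks <- withr::with_seed(config$seed, .sim_peaks(config, samples))
  list(peaks = peaks,
       truth = list(parameters = config$analytes, noise_cv = config$noise_cv,
                    samples = samples))
}

#' Simulate a chromatogram with a Gaussian peak
#'
#' Gaussian peak `height * exp(-(t - rt)^2 / (2 * width_sd^2))` plus white
#' noise of standard deviation `noise_sd` on a uniform time grid.
#'
#' @param rt Peak apex retention time, minutes.
#' @param height Peak amplitude, counts.
#' @param width_sd Gaussian width (SD), minutes (> 0).
#' @param noise_sd White-noise SD, counts (>= 0).
#' @param grid Time grid, minutes; must be fine enough to place >= 10 points
#'   within `rt` +/- 2.5 `width_sd`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [chromatogram()].
#' @export
simulate_chromatogram <- function(rt, height, width_sd, noise_sd, grid,
                                  seed = NULL) {
  stopifnot(width_sd > 0, noise_sd >= 0, length(grid) >= 2L)
  if (sum(abs(grid - rt) <= 2.5 * width_sd) < 10L)
    stop("grid too coarse: fewer than 10 points across the peak")
  draw <- function() {
    signal <- height * exp(-(grid - rt)^2 / (2 * width_sd^2))
    chromatogram(grid, signal + stats::rnorm(length(grid), 0, noise_sd))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full validation campaign
#'
#' Generates every input the validation pipeline needs, mirroring the method's
#' design: calibration standards in all three preparation modes, spiked blanks
#' at the fortification levels over several days, fortified blanks at the MRL
#' (for CCalpha) and at the true CCalpha (for CCbeta), and high-concentration
#' incurred-like samples that are diluted to the calibration range before
#' injection. The true CCalpha used for the second fortification experiment is
#' `MRL + 1.64 * MRL * noise_cv`, the noiseless-campaign limit of the
#' estimator. Bit-identical under `(config, seed)`.
#'
#' @param config A `simulation_config`.
#' @return Object of class `validation_campaign`: list with `config`, `peaks`
#'   (long peak table with a `role` column: `"calibration"`, `"spike"`,
#'   `"fortified_mrl"`, `"fortified_ccalpha"`, `"incurred"`) and `truth`
#'   (per-analyte true parameters, true MRLs and true CCalpha values).
#' @export
simulate_validation_campaign <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  p <- config$analytes
  tg <- config$targets
  mrl <- stats::setNames(tg$mrl_ng_g, tg$name)[p$analyte]
  true_sd_mrl <- mrl * config$noise_cv
  true_ccalpha <- mrl + 1.64 * true_sd_mrl

  sheets <- list()
  for (a in p$analyte) {
    cal <- expand.grid(mode = c("solvent", "fortified_extract",
                                "matrix_matched"),
                       conc = config$calibration_levels,
                       replicate = seq_len(config$calibration_replicates),
                       stringsAsFactors = FALSE)
    cal$role <- "calibration"
    cal$day <- NA_integer_
    spk <- expand.grid(mode = "matrix_matched", conc = config$spike_levels,
                       replicate = seq_len(config$replicates_per_day),
                       day = seq_len(config$days), stringsAsFactors = FALSE)
    spk$role <- "spike"
    fm <- data.frame(mode = "matrix_matched", conc = mrl[[a]],
                     replicate = seq_len(config$n_fortified),
                     day = NA_integer_, role = "fortified_mrl")
    fc <- data.frame(mode = "matrix_matched", conc = true_ccalpha[[a]],
                     replicate = seq_len(config$n_fortified),
                     day = NA_integer_, role = "fortified_ccalpha")
    sh <- rbind(cal[c("mode", "conc", "replicate", "day", "role")],
                spk[c("mode", "conc", "replicate", "day", "role")],
                fm, fc)
    sh$analyte <- a
    sh$dilution_factor <- 1
    sheets[[a]] <- sh
  }
  inc <- data.frame(mode = "matrix_matched",
                    conc = config$incurred$conc,
                    replicate = seq_len(config$incurred$n),
                    day = NA_integer_, role = "incurred",
                    analyte = config$incurred$analyte,
                    dilution_factor = config$incurred$dilution_factor)
  samples <- do.call(rbind, c(sheets, list(inc)))
  samples$sample_id <- sprintf("%s_%s_%s_r%02d",
                               abbreviate(samples$analyte, 4),
                               samples$role,
                               formatC(samples$conc, format = "g"),
                               samples$replicate)
  rownames(samples) <- NULL
  peaks <- withr::with_seed(config$seed, .sim_peaks(config, samples))
  structure(list(
    config = config,
    peaks = peaks,
    truth = list(parameters = p, mrl = mrl, sd_at_mrl = true_sd_mrl,
                 ccalpha = true_ccalpha, noise_cv = config$noise_cv,
                 incurred = config$incurred)
  ), class = "validation_campaign")
}

#' Simulate the LOD/LOQ determination scenario
#'
#' Builds the detection-limit experiment at the bottom of the calibration
#' range. For the LOD, replicate chromatograms are simulated at sub-LOQ
#' levels with a proportional response (`height = response_factor * conc`)
#' over a constant baseline noise, and the S/N of each level is the mean over
#' replicates; the response factor and noise place the S/N = 3 crossing at
#' 1.0 ng/g. For the LOQ, replicate measured concentrations at the lowest
#' calibration levels are generated with the stated sample CVs (the draws are
#' rescaled so the replicate sets attain those CVs exactly), placing the
#' CV = 20% crossing at 5.0 ng/g.
#'
#' @param seed Integer seed.
#' @param lod_levels Concentrations probed for the S/N rule, ng/g.
#' @param response_factor Peak amplitude per unit concentration, counts per
#'   ng/g.
#' @param noise_sd Baseline noise SD, counts.
#' @param n_chrom Replicate chromatograms per level.
#' @param loq_cvs Named numeric vector: nominal level -> target replicate CV
#'   (percent) of the measured concentrations.
#' @param n_rep Replicates per LOQ level.
#' @return List with `snr_table` (data frame `nominal`, `snr`),
#'   `loq_measurements` (named list of replicate concentration vectors),
#'   `lod` and `loq` (the rule outputs, via [assign_lod()] / [assign_loq()]).
#' @export
simulate_lod_loq_scenario <- function(seed,
                                      lod_levels = c(0.1, 1, 2.5, 5),
                                      response_factor = 400,
                                      noise_sd = 100,
                                      n_chrom = 10L,
                                      loq_cvs = c("2.5" = 25, "5" = 18,
                                                  "12.5" = 5),
                                      n_rep = 10L) {
  withr::with_seed(seed, {
    grid <- seq(0, 2, by = 0.005)  # minutes; peak at 1.0, width 0.02 min
    snr <- vapply(lod_levels, function(conc) {
      mean(vapply(seq_len(n_chrom), function(i) {
        ch <- simulate_chromatogram(rt = 1, height = response_factor * conc,
                                    width_sd = 0.02, noise_sd = noise_sd,
                                    grid = grid)
        estimate_snr(ch, peak_window = c(0.9, 1.1),
                     noise_window = c(0.1, 0.7))
      }, numeric(1)))
    }, numeric(1))
    snr_table <- data.frame(nominal = lod_levels, snr = snr)

    loq_measurements <- lapply(names(loq_cvs), function(nm) {
      nominal <- as.numeric(nm)
      x <- stats::rnorm(n_rep)
      # rescale to the exact target sample mean and CV
      z <- (x - mean(x)) / stats::sd(x)
      nominal * (1 + z * loq_cvs[[nm]] / 100)
    })
    names(loq_measurements) <- names(loq_cvs)

    list(snr_table = snr_table,
         loq_measurements = loq_measurements,
         lod = assign_lod(snr_table),
         loq = assign_loq(loq_measurements))
  })
}
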