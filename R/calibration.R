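#' Fit a least-squares calibration curve
#'
#' Ordinary (unweighted) least squares of mean peak area against nominal
#' concentration, one point per calibration level. Linearity is gated on the
#' coefficient of determination, R^2 >= `linearity_min` (default 0.99, the
#' acceptance criterion of the validation guides this package follows).
#'
#' @param levels A data frame with columns `nominal` (ng/g) and `area`
#'   (counts); replicate rows per level are averaged before fitting.
#' @param mode Preparation mode of the standards: `"solvent"`,
#'   `"fortified_extract"` (blank extract spiked after extraction) or
#'   `"matrix_matched"` (spiked blank tissue carried through the full
#'   procedure).
#' @param linearity_min Minimum acceptable R^2.
#' @return Object of class `calibration_curve` with components `mode`, `slope`
#'   (counts per ng/g), `intercept` (counts), `r_squared`, `linearity_pass`,
#'   `levels` (the level-mean table) and `n_levels`.
#' @examples
#' cal <- data.frame(nominal = c(5, 50, 250), area = c(5000, 50000, 250000))
#' fit_curve(cal)$slope  # 1000
#' @export
fit_curve <- function(levels,
                      mode = c("matrix_matched", "fortified_extract", "solvent"),
                      linearity_min = 0.99) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(levels), all(c("nominal", "area") %in% names(levels)))
  if (anyNA(levels$nominal) || anyNA(levels$area))
    stop("calibration levels contain missing values")
  means <- stats::aggregate(area ~ nominal, data = levels, FUN = mean)
  if (nrow(means) < 3L)
    stop("calibration requires at least 3 distinct nominal levels, got ",
         nrow(means))
  if (stats::var(means$nominal) == 0)
    stop("all nominal concentrations identical: singular calibration design")
  fit <- stats::lm(area ~ nominal, data = means)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((means$area - mean(means$area))^2)
  # flat response: define R^2 as 1 for an exact fit, 0 otherwise
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  structure(list(
    mode = mode,
    slope = unname(stats::coef(fit)[["nominal"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    r_squared = r2,
    linearity_pass = r2 >= linearity_min,
    levels = means,
    n_levels = nrow(means)
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: area = %.4g + %.4g * conc, R2 = %.4f (%s), %d levels\n",
              x$mode, x$intercept, x$slope, x$r_squared,
              if (x$linearity_pass) "pass" else "FAIL", x$n_levels))
  invisible(x)
}

#' Back-calculate concentration from peak area
#'
#' Inverts the calibration line and applies the extract dilution factor and
#' the tissue factor (gram-equivalents of tissue per mL of final extract).
#' With the default tissue factor of 1 g-equiv/mL (2.5 g extracted into 10 mL,
#' a 2 mL aliquot evaporated and reconstituted in 0.5 mL), extract ng/mL and
#' tissue ng/g coincide numerically. Negative back-calculated values are
#' clamped to 0 and flagged; validation statistics that average over
#' replicates should set `clamp = FALSE` to avoid truncation bias.
#'
#' @param area Peak area(s), counts (>= 0).
#' @param curve A `calibration_curve` with nonzero slope.
#' @param dilution_factor Dilution applied to the extract before injection
#'   (>= 1).
#' @param tissue_factor Gram-equivalents of tissue per mL of extract (> 0).
#' @param clamp Clamp negative back-calculations to 0 (default `TRUE`).
#' @return Numeric vector of concentrations (ng/g) with attribute
#'   `below_curve`: logical, `TRUE` where the raw back-calculation was
#'   negative (and, when `clamp = TRUE`, the value was set to 0).
#' @examples
#' cv <- fit_curve(data.frame(nominal = c(5, 50, 250),
#'                            area = c(5000, 50000, 250000)))
#' quantify(50000, cv)                       # 50
#' quantify(50000, cv, dilution_factor = 10) # 500
#' @export
quantify <- function(area, curve, dilution_factor = 1, tissue_factor = 1,
                     clamp = TRUE) {
  stopifnot(inherits(curve, "calibration_curve"),
            all(area >= 0), all(dilution_factor >= 1), tissue_factor > 0)
  if (curve$slope == 0) stop("calibration slope is zero; cannot quantify")
  conc <- (area - curve$intercept) / curve$slope * dilution_factor / tissue_factor
  below <- conc < 0
  if (clamp) conc[below] <- 0
  attr(conc, "below_curve") <- below
  conc
}

#' Construct a chromatogram
#'
#' @param times Strictly increasing time grid, minutes.
#' @param intensities Intensities (counts), same length as `times`.
#' @return Object of class `chromatogram` (a list with `times`,
#'   `intensities`).
#' @export
chromatogram <- function(times, intensities) {
  stopifnot(length(times) == length(intensities), length(times) >= 2L,
            all(diff(times) > 0))
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities)),
            class = "chromatogram")
}

#' Signal-to-noise ratio of a chromatographic peak
#'
#' S/N = (maximum intensity in the peak window minus the median of the
#' analyte-free noise window) divided by the standard deviation of the noise
#' window. Adding a constant to the whole trace leaves the estimate unchanged.
#'
#' @param chrom A `chromatogram`.
#' @param peak_window Length-2 numeric, minutes: window containing the peak.
#' @param noise_window Length-2 numeric, minutes: analyte-free baseline
#'   window; must be disjoint from `peak_window`. Each window must contain at
#'   least 5 points.
#' @return S/N ratio (numeric scalar).
#' @export
estimate_snr <- function(chrom, peak_window, noise_window) {
  stopifnot(inherits(chrom, "chromatogram"),
            length(peak_window) == 2L, length(noise_window) == 2L)
  peak_window <- sort(peak_window); noise_window <- sort(noise_window)
  if (max(min(peak_window), min(noise_window)) <
      min(max(peak_window), max(noise_window)))
    stop("peak and noise windows must be disjoint")
  in_peak <- chrom$times >= peak_window[1] & chrom$times <= peak_window[2]
  in_noise <- chrom$times >= noise_window[1] & chrom$times <= noise_window[2]
  if (sum(in_peak) < 5L || sum(in_noise) < 5L)
    stop("each window must contain at least 5 points")
  noise <- chrom$intensities[in_noise]
  s <- stats::sd(noise)
  if (s == 0) stop("zero noise variance in baseline window")
  (max(chrom$intensities[in_peak]) - stats::median(noise)) / s
}

#' Assign the limit of detection by the S/N rule
#'
#' LOD is the lowest concentration whose signal-to-noise ratio reaches the
#' threshold (3 by convention).
#'
#' @param levels_with_snr Data frame with columns `nominal` (ng/g, distinct)
#'   and `snr`.
#' @param snr_min Qualifying S/N threshold (inclusive).
#' @return Smallest qualifying nominal concentration, or `NA_real_` (with a
#'   warning) when no level qualifies.
#' @examples
#' assign_lod(data.frame(nominal = c(0.5, 1, 5), snr = c(1.2, 3.4, 17)))  # 1
#' @export
assign_lod <- function(levels_with_snr, snr_min = 3) {
  stopifnot(is.data.frame(levels_with_snr),
            all(c("nominal", "snr") %in% names(levels_with_snr)),
            nrow(levels_with_snr) >= 1L)
  if (anyDuplicated(levels_with_snr$nominal))
    stop("nominal concentrations must be distinct")
  ok <- levels_with_snr$snr >= snr_min
  if (!any(ok)) {
    warning("no level reaches S/N >= ", snr_min, "; LOD undefined")
    return(NA_real_)
  }
  min(levels_with_snr$nominal[ok])
}

#' Assign the limit of quantification by the precision rule
#'
#' LOQ is the lowest level whose replicate coefficient of variation does not
#' exceed `cv_max` percent (20% by convention, boundary inclusive).
#'
#' @param level_measurements Named list: nominal concentration (coercible to
#'   numeric names) -> numeric vector of replicate measured concentrations
#'   (>= 2 replicates each).
#' @param cv_max Maximum acceptable CV, percent.
#' @return Smallest qualifying nominal concentration, or `NA_real_` (with a
#'   warning) when none qualifies.
#' @examples
#' assign_loq(list("2.5" = c(2, 3, 2.6), "5" = c(4.9, 5.2, 5.0)))
#' @export
assign_loq <- function(level_measurements, cv_max = 20) {
  stopifnot(is.list(level_measurements), length(level_measurements) >= 1L)
  nominal <- as.numeric(names(level_measurements))
  if (anyNA(nominal)) stop("list names must be the nominal concentrations")
  cvs <- vapply(level_measurements, cv_percent, numeric(1))
  ok <- cvs <= cv_max
  if (!any(ok)) {
    warning("no level achieves CV <= ", cv_max, "%; LOQ undefined")
    return(NA_real_)
  }
  min(nominal[ok])
}
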