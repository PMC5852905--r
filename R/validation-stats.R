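#' Coefficient of variation, percent
#'
#' 100 * sample standard deviation (n-1 denominator) / mean.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @examples
#' cv_percent(c(8, 12))  # 28.28
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Matrix effect, signed percent
#'
#' Signed percentage change of the analyte signal in post-extraction fortified
#' blank extract relative to pure solvent at the same concentration:
#' `100 * (area_extract - area_solvent) / area_solvent`. Negative values mean
#' ionization suppression, positive values enhancement. The result carries a
#' `relevant` attribute, `TRUE` when |ME| exceeds `relevance_max` percent
#' (20%, the acceptance ceiling of the validation guides).
#'
#' @param area_solvent Mean area in solvent (> 0).
#' @param area_extract Mean area in fortified extract.
#' @param relevance_max Relevance threshold, percent.
#' @return Signed matrix effect in percent, with attribute `relevant`.
#' @examples
#' matrix_effect(100, 81.02)  # -18.98, not relevant
#' @export
matrix_effect <- function(area_solvent, area_extract, relevance_max = 20) {
  if (any(area_solvent <= 0)) stop("solvent area must be positive")
  me <- 100 * (area_extract - area_solvent) / area_solvent
  attr(me, "relevant") <- abs(me) > relevance_max
  me
}

#' Recovery, percent
#'
#' 100 * measured / nominal for a spiked blank, reflecting losses during
#' sample preparation when the measured concentration is read against a
#' post-extraction fortified-extract curve.
#'
#' @param measured Measured concentration, ng/g (>= 0).
#' @param nominal Fortification level, ng/g (> 0).
#' @return Recovery in percent.
#' @export
recovery_percent <- function(measured, nominal) {
  if (any(nominal <= 0)) stop("nominal concentration must be positive")
  if (any(measured < 0)) stop("measured concentration must be non-negative")
  100 * measured / nominal
}

#' Intraday and interday precision summary
#'
#' Repeatability (intraday) is the CV of the replicates within one day at one
#' level; intermediate precision (interday) is the CV of all results pooled
#' across days at that level (e.g. 3 days x 5 replicates = n 15). Each CV
#' carries a pass flag at `cv_max` percent.
#'
#' @param sets Data frame with columns `level` (ng/g), `day` (index) and
#'   `value` (measured concentration, ng/g); >= 2 replicates per (level, day)
#'   and >= 2 days per level for the interday CV.
#' @param cv_max Acceptance ceiling, percent.
#' @return List with data frames `intraday` (`level`, `day`, `cv`, `pass`)
#'   and `interday` (`level`, `cv`, `n`, `pass`).
#' @export
precision_summary <- function(sets, cv_max = 20) {
  stopifnot(is.data.frame(sets), all(c("level", "day", "value") %in% names(sets)))
  cnt <- stats::aggregate(value ~ level + day, data = sets, FUN = length)
  if (any(cnt$value < 2L))
    stop("each (level, day) cell needs at least 2 replicates")
  intraday <- stats::aggregate(value ~ level + day, data = sets,
                               FUN = cv_percent)
  names(intraday)[names(intraday) == "value"] <- "cv"
  intraday <- intraday[order(intraday$level, intraday$day), ]
  intraday$pass <- intraday$cv <= cv_max
  days_per_level <- stats::aggregate(day ~ level, data = sets,
                                     FUN = function(d) length(unique(d)))
  if (any(days_per_level$day < 2L))
    stop("interday precision needs at least 2 days per level")
  interday <- do.call(rbind, lapply(split(sets, sets$level), function(d) {
    data.frame(level = d$level[1], cv = cv_percent(d$value), n = nrow(d))
  }))
  interday <- interday[order(interday$level), ]
  interday$pass <- interday$cv <= cv_max
  rownames(intraday) <- rownames(interday) <- NULL
  list(intraday = intraday, interday = interday)
}

#' Decision limit CCalpha
#'
#' For an MRL substance: the MRL plus `k` times the standard deviation of
#' measured concentrations in blanks fortified at the MRL (n >= 20 in the
#' underlying design), with k = 1.64 for alpha = 5%.
#'
#' @param mrl Maximum residue limit, ng/g (> 0).
#' @param sd_at_mrl Standard deviation of measured concentrations at the MRL,
#'   ng/g (>= 0).
#' @param k One-sided factor (default 1.64).
#' @return CCalpha, ng/g.
#' @examples
#' cc_alpha(50, 12.195)  # 70.0
#' @export
cc_alpha <- function(mrl, sd_at_mrl, k = 1.64) {
  stopifnot(mrl > 0)
  if (any(sd_at_mrl < 0)) stop("standard deviation must be non-negative")
  mrl + k * sd_at_mrl
}

#' Detection capability CCbeta
#'
#' CCalpha plus `k` times the standard deviation of measured concentrations
#' in blanks fortified at CCalpha, with k = 1.64 for beta = 5%.
#'
#' @param cc_alpha_val Decision limit CCalpha, ng/g.
#' @param sd_at_ccalpha Standard deviation of measured concentrations at
#'   CCalpha, ng/g (>= 0).
#' @param k One-sided factor (default 1.64).
#' @return CCbeta, ng/g.
#' @examples
#' cc_beta(70, 12.134)  # 89.9
#' @export
cc_beta <- function(cc_alpha_val, sd_at_ccalpha, k = 1.64) {
  if (any(sd_at_ccalpha < 0)) stop("standard deviation must be non-negative")
  cc_alpha_val + k * sd_at_ccalpha
}
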