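#' Construct a monitored analyte target
#'
#' One row of the monitored-compound list: name, elemental formula, expected
#' retention time, diagnostic fragment ions, regulatory group and MRL. The
#' theoretical precursor m/z is computed from the formula on construction.
#'
#' @param name Compound name.
#' @param formula Formula string or `elemental_formula`.
#' @param rt_expected Expected retention time, minutes (> 0).
#' @param fragment_mz Numeric vector of diagnostic fragment m/z values (may be
#'   empty).
#' @param group Regulatory group: `"A"` (prohibited substance) or `"B"`
#'   (authorized, MRL-bearing).
#' @param mrl Maximum residue limit, ng/g.
#' @param adduct Monitored adduct (default protonated molecular ion).
#' @param reference Mass reference convention passed to [adduct_mz()].
#' @return Object of class `analyte_target`.
#' @export
analyte_target <- function(name, formula, rt_expected, fragment_mz = numeric(0),
                           group = c("B", "A"), mrl = NA_real_,
                           adduct = "[M+H]+",
                           reference = c("proton", "hydrogen")) {
  group <- match.arg(group)
  reference <- match.arg(reference)
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(is.numeric(rt_expected), length(rt_expected) == 1L, rt_expected > 0)
  structure(list(
    name = name,
    formula = formula,
    rt_expected = rt_expected,
    precursor_mz = adduct_mz(formula, adduct = adduct, reference = reference),
    fragment_mz = as.numeric(fragment_mz),
    group = group,
    mrl = mrl
  ), class = "analyte_target")
}

#' @export
print.analyte_target <- function(x, ...) {
  cat(sprintf("<analyte_target> %s (%s) [M+H]+ %.4f, RT %.2f min, group %s, MRL %s ng/g\n",
              x$name, format_formula(x$formula), x$precursor_mz, x$rt_expected,
              x$group, format(x$mrl)))
  invisible(x)
}

#' Construct an integrated peak observation
#'
#' Carrier for one integrated chromatographic peak as exported by peak
#' integration software: observed m/z and retention time of the apex, area and
#' height, plus any co-acquired fragment-ion m/z values.
#'
#' @param sample_id Sample identifier.
#' @param mz_observed Observed precursor m/z (Da).
#' @param rt_observed Observed retention time, minutes (>= 0).
#' @param area Integrated area (counts, >= 0).
#' @param height Apex height (counts, >= 0).
#' @param fragments_observed Numeric vector of observed fragment m/z (Da).
#' @return Object of class `peak_observation`.
#' @export
peak_observation <- function(sample_id, mz_observed, rt_observed,
                             area = 0, height = 0,
                             fragments_observed = numeric(0)) {
  stopifnot(area >= 0, height >= 0, rt_observed >= 0)
  structure(list(
    sample_id = sample_id,
    mz_observed = mz_observed,
    rt_observed = rt_observed,
    area = area,
    height = height,
    fragments_observed = as.numeric(fragments_observed)
  ), class = "peak_observation")
}

.identity_result <- function(matched, ppm, rt_delta, ip_score = NA_real_,
                             confirmed = FALSE, reasons = character(0)) {
  structure(list(matched = matched, ppm = ppm, rt_delta = rt_delta,
                 ip_score = ip_score, confirmed = confirmed,
                 reasons = reasons), class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("<identity_result> matched=%s confirmed=%s ppm=%.2f dRT=%.3f IP=%s%s\n",
              x$matched, x$confirmed, x$ppm, x$rt_delta, format(x$ip_score),
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Match a peak against a target by accurate mass and retention time
#'
#' A peak matches when its precursor mass error is within `ppm_tol` and its
#' retention time is within `rt_tol` of the expected value. Returns a partial
#' identity result (no identification-point scoring); see [confirm_identity()]
#' for the full confirmation decision.
#'
#' @param target An `analyte_target`.
#' @param peak A `peak_observation`.
#' @param ppm_tol Mass tolerance, ppm (> 0). Default 5 ppm, conventional for
#'   Q-TOF screening.
#' @param rt_tol Retention-time tolerance, minutes (> 0). Default 0.1 min.
#' @return An `identity_result` with `ip_score = NA` and `confirmed = FALSE`;
#'   `reasons` lists each failed criterion.
#' @export
match_feature <- function(target, peak, ppm_tol = 5, rt_tol = 0.1) {
  stopifnot(ppm_tol > 0, rt_tol > 0)
  ppm <- ppm_error(peak$mz_observed, target$precursor_mz)
  rt_delta <- peak$rt_observed - target$rt_expected
  reasons <- character(0)
  if (!is.finite(ppm) || abs(ppm) > ppm_tol)
    reasons <- c(reasons, "mass tolerance")
  if (!is.finite(rt_delta) || abs(rt_delta) > rt_tol)
    reasons <- c(reasons, "retention time")
  .identity_result(matched = length(reasons) == 0L, ppm = ppm,
                   rt_delta = rt_delta, reasons = reasons)
}

#' Identification-point score for high-resolution MS
#'
#' Additive confirmation score: a high-resolution precursor ion earns 2 points
#' and each high-resolution transition/fragment ion earns 2.5 points.
#'
#' @param n_precursor_hr Number of matched high-resolution precursor ions (0/1
#'   in practice).
#' @param n_fragment_hr Number of matched high-resolution fragment ions.
#' @return Points (multiple of 0.5).
#' @examples
#' identification_points(1, 1)  # 4.5
#' @export
identification_points <- function(n_precursor_hr, n_fragment_hr) {
  if (n_precursor_hr < 0 || n_fragment_hr < 0)
    stop("ion counts must be non-negative")
  2.0 * n_precursor_hr + 2.5 * n_fragment_hr
}

#' Default identification-point threshold by regulatory group
#'
#' Prohibited (group A) substances require 4 points; authorized MRL-bearing
#' (group B) substances require 3.
#'
#' @param group `"A"` or `"B"`.
#' @return Minimum identification points.
#' @export
default_ip_threshold <- function(group) {
  switch(match.arg(group, c("A", "B")), A = 4.0, B = 3.0)
}

#' Confirm analyte identity in a peak
#'
#' Full confirmation decision: the precursor must match in mass and retention
#' time ([match_feature()]), and the identification-point score — 2 for the
#' matched precursor plus 2.5 for each observed fragment lying within
#' `ppm_tol` of a distinct target fragment — must reach `ip_threshold`.
#'
#' @inheritParams match_feature
#' @param ip_threshold Minimum identification points; defaults to the value
#'   for the target's regulatory group ([default_ip_threshold()]).
#' @return An `identity_result`; `reasons` enumerates every failed criterion.
#' @export
confirm_identity <- function(target, peak, ppm_tol = 5, rt_tol = 0.1,
                             ip_threshold = default_ip_threshold(target$group)) {
  stopifnot(ip_threshold >= 0)
  res <- match_feature(target, peak, ppm_tol = ppm_tol, rt_tol = rt_tol)
  n_prec <- as.integer(is.finite(res$ppm) && abs(res$ppm) <= ppm_tol)
  n_frag <- .count_fragment_matches(peak$fragments_observed,
                                    target$fragment_mz, ppm_tol)
  res$ip_score <- identification_points(n_prec, n_frag)
  reasons <- res$reasons
  if (res$ip_score < ip_threshold)
    reasons <- c(reasons, "identification points")
  res$confirmed <- res$matched && res$ip_score >= ip_threshold
  res$reasons <- reasons
  res
}

# each target fragment may be claimed by at most one observed fragment;
# greedy assignment in increasing |ppm| keeps the count order-invariant
.count_fragment_matches <- function(observed, targets, ppm_tol) {
  if (!length(observed) || !length(targets)) return(0L)
  pairs <- expand.grid(obs = seq_along(observed), tgt = seq_along(targets))
  pairs$ppm <- abs(ppm_error(observed[pairs$obs], targets[pairs$tgt]))
  pairs <- pairs[pairs$ppm <= ppm_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$ppm), , drop = FALSE]
  n <- 0L
  used_obs <- logical(length(observed))
  used_tgt <- logical(length(targets))
  for (i in seq_len(nrow(pairs))) {
    o <- pairs$obs[i]; t <- pairs$tgt[i]
    if (!used_obs[o] && !used_tgt[t]) {
      used_obs[o] <- used_tgt[t] <- TRUE
      n <- n + 1L
    }
  }
  n
}

#' Select the best candidate peak for a target
#'
#' When several peaks in one sample match a target, keeps the one with the
#' smallest absolute mass error, breaking ties by smallest absolute
#' retention-time deviation.
#'
#' @param target An `analyte_target`.
#' @param peaks List of `peak_observation`s.
#' @inheritParams match_feature
#' @return Index of the selected peak in `peaks`, or `NA_integer_` when none
#'   matches.
#' @export
select_best_peak <- function(target, peaks, ppm_tol = 5, rt_tol = 0.1) {
  if (!length(peaks)) return(NA_integer_)
  res <- lapply(peaks, match_feature, target = target,
                ppm_tol = ppm_tol, rt_tol = rt_tol)
  ok <- vapply(res, `[[`, logical(1), "matched")
  if (!any(ok)) return(NA_integer_)
  idx <- which(ok)
  appm <- vapply(res[idx], function(r) abs(r$ppm), numeric(1))
  art <- vapply(res[idx], function(r) abs(r$rt_delta), numeric(1))
  idx[order(appm, art)][1L]
}
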