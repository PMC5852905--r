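#' Analyse a validation campaign
#'
#' Runs the full validation computation on a (simulated or imported) campaign
#' peak table: least-squares calibration in the three preparation modes with
#' the R^2 >= 0.99 linearity gate, matrix effect at the comparison levels,
#' recovery of the spiked blanks read against the fortified-extract curve
#' (so that losses reflect sample preparation only), intraday and interday
#' precision of the matrix-matched results, and CCalpha/CCbeta from the
#' fortified-blank experiments.
#'
#' @param campaign A `validation_campaign` (see
#'   [simulate_validation_campaign()]), or any list with `config` and a
#'   `peaks` data frame in the same layout.
#' @param cv_max Precision acceptance ceiling, percent.
#' @param linearity_min Linearity gate on R^2.
#' @return Object of class `validation_result`: list with `records` (one
#'   `validation_record` per analyte), `curves` (analyte -> mode ->
#'   `calibration_curve`) and `gates` (data frame of named acceptance gates
#'   with pass flags).
#' @export
analyze_campaign <- function(campaign, cv_max = 20, linearity_min = 0.99) {
  peaks <- campaign$peaks
  config <- campaign$config
  analytes <- unique(config$analytes$analyte)
  mrl <- stats::setNames(config$targets$mrl_ng_g, config$targets$name)

  records <- list()
  curves <- list()
  gates <- list()
  for (a in analytes) {
    pk <- peaks[peaks$analyte == a, , drop = FALSE]
    cal <- pk[pk$role == "calibration", , drop = FALSE]
    crv <- lapply(c(solvent = "solvent", fortified_extract = "fortified_extract",
                    matrix_matched = "matrix_matched"), function(m) {
      d <- cal[cal$mode == m, , drop = FALSE]
      fit_curve(data.frame(nominal = d$conc, area = d$area), mode = m,
                linearity_min = linearity_min)
    })
    curves[[a]] <- crv

    # matrix effect: mean areas solvent vs post-extraction fortified extract
    me <- vapply(config$me_levels, function(lv) {
      sol <- mean(cal$area[cal$mode == "solvent" & cal$conc == lv])
      ext <- mean(cal$area[cal$mode == "fortified_extract" & cal$conc == lv])
      as.numeric(matrix_effect(sol, ext))
    }, numeric(1))
    me_df <- data.frame(level = config$me_levels, matrix_effect_pct = me,
                        relevant = abs(me) > 20)

    # recovery against the fortified-extract curve
    spk <- pk[pk$role == "spike", , drop = FALSE]
    spk$measured_ext <- as.numeric(quantify(spk$area, crv$fortified_extract,
                                            clamp = FALSE))
    # signed recovery: negative back-calculations keep their sign here so
    # replicate means stay unbiased (recovery_percent() itself rejects them)
    spk$recovery <- 100 * spk$measured_ext / spk$conc
    rec_df <- do.call(rbind, lapply(split(spk, spk$conc), function(d) {
      data.frame(level = d$conc[1], mean_recovery_pct = mean(d$recovery),
                 cv_pct = cv_percent(d$recovery), n = nrow(d))
    }))
    rownames(rec_df) <- NULL

    # precision on the method's own (matrix-matched) quantitation
    spk$measured <- as.numeric(quantify(spk$area, crv$matrix_matched,
                                        clamp = FALSE))
    prec <- precision_summary(data.frame(level = spk$conc, day = spk$day,
                                         value = spk$measured),
                              cv_max = cv_max)

    fm <- pk[pk$role == "fortified_mrl", , drop = FALSE]
    conc_mrl <- as.numeric(quantify(fm$area, crv$matrix_matched, clamp = FALSE))
    cca <- cc_alpha(mrl[[a]], stats::sd(conc_mrl))
    fc <- pk[pk$role == "fortified_ccalpha", , drop = FALSE]
    conc_cca <- as.numeric(quantify(fc$area, crv$matrix_matched, clamp = FALSE))
    ccb <- cc_beta(cca, stats::sd(conc_cca))

    records[[a]] <- structure(list(
      analyte = a,
      working_range = range(config$calibration_levels),
      r_squared = vapply(crv, `[[`, numeric(1), "r_squared"),
      sensitivity = crv$matrix_matched$slope,
      matrix_effect = me_df,
      recovery = rec_df,
      intraday = prec$intraday,
      interday = prec$interday,
      cc_alpha = cca,
      cc_beta = ccb,
      mrl = mrl[[a]],
      lod = NA_real_,
      loq = NA_real_
    ), class = "validation_record")

    gates[[a]] <- data.frame(
      analyte = a,
      gate = c("R2>=0.99 (matrix-matched)", "CV<=20 (interday)",
               "|ME|<=20"),
      pass = c(crv$matrix_matched$linearity_pass,
               all(prec$interday$pass),
               all(!me_df$relevant)))
  }
  structure(list(records = records, curves = curves,
                 gates = do.call(rbind, c(gates, list(make.row.names = FALSE)))),
            class = "validation_result")
}

#' @export
print.validation_record <- function(x, ...) {
  cat(sprintf("<validation_record> %s\n", x$analyte))
  cat(sprintf("  working range %.1f-%.1f ng/g, R2(mm) %.4f, sensitivity %.2f\n",
              x$working_range[1], x$working_range[2],
              x$r_squared[["matrix_matched"]], x$sensitivity))
  cat(sprintf("  CCalpha %.1f, CCbeta %.1f ng/g (MRL %.0f); LOD %s, LOQ %s ng/g\n",
              x$cc_alpha, x$cc_beta, x$mrl, format(x$lod), format(x$loq)))
  invisible(x)
}

#' Run the validation workflow
#'
#' Simulates (or accepts) a validation campaign, analyses it, attaches the
#' LOD/LOQ determination, and writes the three report tables: validation
#' parameters (range, linearity, sensitivity, matrix effect, recovery,
#' LOD/LOQ), precision (intraday/interday CV grids) and decision limits
#' (CCalpha/CCbeta).
#'
#' @param config A `simulation_config`, or an already simulated
#'   `validation_campaign`.
#' @param out_dir Output directory for the report CSVs; `NULL` suppresses
#'   writing.
#' @param lod_loq_seed Seed for the LOD/LOQ scenario (defaults to the
#'   campaign seed + 1).
#' @return A `validation_result` with an added `lod_loq` element, per-record
#'   `lod`/`loq` filled in, and `all_pass` (logical: every acceptance gate
#'   green). Report paths are attached as attribute `paths`.
#' @export
run_validate <- function(config, out_dir = NULL, lod_loq_seed = NULL) {
  campaign <- if (inherits(config, "validation_campaign")) config
              else simulate_validation_campaign(config)
  res <- analyze_campaign(campaign)
  if (is.null(lod_loq_seed)) lod_loq_seed <- campaign$config$seed + 1L
  ll <- simulate_lod_loq_scenario(lod_loq_seed)
  for (a in names(res$records)) {
    res$records[[a]]$lod <- ll$lod
    res$records[[a]]$loq <- ll$loq
  }
  res$lod_loq <- ll
  res$all_pass <- all(res$gates$pass)
  if (!res$all_pass) {
    failed <- res$gates[!res$gates$pass, ]
    warning("failed validation gate(s): ",
            paste(sprintf("%s [%s]", failed$gate, failed$analyte),
                  collapse = "; "))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      parameters = file.path(out_dir, "validation_parameters.csv"),
      precision = file.path(out_dir, "precision.csv"),
      decision_limits = file.path(out_dir, "decision_limits.csv"),
      gates = file.path(out_dir, "gates.csv"))
    utils::write.csv(validation_parameters_table(res), paths[["parameters"]],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(precision_table(res), paths[["precision"]],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(decision_limits_table(res), paths[["decision_limits"]],
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(res$gates, paths[["gates"]], row.names = FALSE,
                     quote = FALSE)
    attr(res, "paths") <- paths
  }
  res
}

#' Validation-parameters report table
#'
#' One row per analyte: working range, linearity, sensitivity, matrix effect
#' by level, mean recovery (CV) by level, LOD and LOQ.
#'
#' @param res A `validation_result`.
#' @return Data frame.
#' @export
validation_parameters_table <- function(res) {
  do.call(rbind, lapply(res$records, function(r) {
    row <- data.frame(
      analyte = r$analyte,
      working_range = sprintf("%g-%g", r$working_range[1], r$working_range[2]),
      r_squared = round(r$r_squared[["matrix_matched"]], 4),
      sensitivity = round(r$sensitivity, 2))
    for (i in seq_len(nrow(r$matrix_effect)))
      row[[sprintf("me_pct_%g", r$matrix_effect$level[i])]] <-
        round(r$matrix_effect$matrix_effect_pct[i], 2)
    for (i in seq_len(nrow(r$recovery)))
      row[[sprintf("recovery_pct_%g", r$recovery$level[i])]] <-
        sprintf("%.1f (%.1f)", r$recovery$mean_recovery_pct[i],
                r$recovery$cv_pct[i])
    row$lod_ng_g <- r$lod
    row$loq_ng_g <- r$loq
    row
  }))
}

#' Precision report table
#'
#' Intraday and interday CV grid, one row per (analyte, type, level).
#'
#' @param res A `validation_result`.
#' @return Data frame `analyte`, `type`, `level`, `cv_pct`, `pass`.
#' @export
precision_table <- function(res) {
  do.call(rbind, lapply(res$records, function(r) {
    intr <- stats::aggregate(cv ~ level, data = r$intraday, FUN = mean)
    rbind(
      data.frame(analyte = r$analyte, type = "intraday", level = intr$level,
                 cv_pct = round(intr$cv, 1),
                 pass = intr$level %in% r$intraday$level[r$intraday$pass]),
      data.frame(analyte = r$analyte, type = "interday",
                 level = r$interday$level, cv_pct = round(r$interday$cv, 1),
                 pass = r$interday$pass))
  }))
}

#' Decision-limit report table
#'
#' @param res A `validation_result`.
#' @return Data frame `analyte`, `mrl_ng_g`, `cc_alpha_ng_g`, `cc_beta_ng_g`.
#' @export
decision_limits_table <- function(res) {
  do.call(rbind, lapply(res$records, function(r) {
    data.frame(analyte = r$analyte, mrl_ng_g = r$mrl,
               cc_alpha_ng_g = round(r$cc_alpha, 1),
               cc_beta_ng_g = round(r$cc_beta, 1))
  }))
}

#' Screen samples for MRL compliance
#'
#' For each sample in a peak table: select the best matching peak per target,
#' confirm identity (accurate mass, retention time, identification points),
#' quantify against the analyte's matrix-matched curve applying the peak's
#' dilution factor, and issue the per-analyte and summed-sulfonamide
#' compliance decision.
#'
#' @param peaks Peak table (columns of [read_peaks()]; `analyte_hint` or
#'   `analyte` names the target each peak is attributed to).
#' @param targets Target list ([read_targets()]).
#' @param curves Named list: analyte -> `calibration_curve` (matrix-matched)
#'   or a mode-keyed list containing one.
#' @param ccalphas,loqs Named numeric vectors per analyte.
#' @param registry An [mrl_registry()].
#' @param ppm_tol,rt_tol Identification tolerances.
#' @param out_path Optional CSV path for the machine-readable decisions.
#' @return List of `compliance_decision`, one per sample; the flat decision
#'   table is attached as attribute `table`.
#' @export
run_screen <- function(peaks, targets, curves, ccalphas, loqs,
                       registry = mrl_registry(), ppm_tol = 5, rt_tol = 0.1,
                       out_path = NULL) {
  if (is.null(peaks$analyte_hint) && !is.null(peaks$analyte))
    peaks$analyte_hint <- peaks$analyte
  if (is.null(peaks$dilution_factor)) peaks$dilution_factor <- 1
  unknown <- setdiff(unique(peaks$analyte_hint), targets$name)
  if (length(unknown))
    stop("peak table names unknown analyte(s): ",
         paste(unknown, collapse = ", "))
  no_curve <- setdiff(unique(peaks$analyte_hint), names(curves))
  if (length(no_curve))
    stop("no calibration curve for analyte(s): ",
         paste(no_curve, collapse = ", "))

  curve_of <- function(a) {
    cv <- curves[[a]]
    if (inherits(cv, "calibration_curve")) cv else cv$matrix_matched
  }

  decisions <- lapply(split(peaks, peaks$sample_id), function(sp) {
    concs <- stats::setNames(rep(0, nrow(targets)), targets$name)
    identities <- list()
    for (a in unique(sp$analyte_hint)) {
      rows <- sp[sp$analyte_hint == a, , drop = FALSE]
      tgt <- as_analyte_target(targets, a)
      pobs <- lapply(seq_len(nrow(rows)), function(i)
        peak_observation(rows$sample_id[i], rows$mz[i], rows$rt[i],
                         rows$area[i],
                         if (!is.null(rows$height)) rows$height[i] else 0,
                         .parse_fragment_list(rows$fragments[i])))
      best <- select_best_peak(tgt, pobs, ppm_tol = ppm_tol, rt_tol = rt_tol)
      if (is.na(best)) next
      identities[[a]] <- confirm_identity(tgt, pobs[[best]],
                                          ppm_tol = ppm_tol, rt_tol = rt_tol)
      concs[[a]] <- as.numeric(quantify(rows$area[best], curve_of(a),
                                        dilution_factor =
                                          rows$dilution_factor[best]))
    }
    screen_sample(concs, identities, registry, ccalphas, loqs,
                  sample_id = sp$sample_id[1])
  })

  tab <- do.call(rbind, lapply(decisions, function(d) {
    pa <- d$per_analyte
    pa$sample_id <- d$sample_id
    pa$sum_sulfonamides <- d$sum_sulfonamides
    pa$group_status <- d$group_status
    pa[, c("sample_id", "analyte", "conc", "status", "sum_sulfonamides",
           "group_status")]
  }))
  rownames(tab) <- NULL
  if (!is.null(out_path))
    utils::write.csv(tab, out_path, row.names = FALSE, quote = FALSE)
  attr(decisions, "table") <- tab
  decisions
}
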