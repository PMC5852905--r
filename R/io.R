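#' Read a monitored-analyte target list
#'
#' Reads a comma-separated target list with columns `name`, `formula`,
#' `rt_min`, `fragment_mz` (semicolon-separated list, may be empty), `group`
#' ("A"/"B") and `mrl_ng_g`. Formulas are parsed and theoretical precursor
#' m/z values computed on load. The bundled default reproduces the eight
#' monitored sulfonamides and trimethoprim.
#'
#' @param path Path to the CSV; default the bundled target list.
#' @param reference Mass reference convention for the precursor m/z
#'   (see [adduct_mz()]).
#' @param dec Decimal mark of the file (`"."` default; `","` accepted for
#'   European exports).
#' @return Data frame of class `analyte_targets` with an added
#'   `precursor_mz` column.
#' @examples
#' tg <- read_targets()
#' nrow(tg)  # 8
#' @export
read_targets <- function(path = NULL, reference = c("proton", "hydrogen"),
                         dec = ".") {
  reference <- match.arg(reference)
  if (is.null(path))
    path <- system.file("extdata", "tilapia_targets.csv",
                        package = "residuescreen", mustWork = TRUE)
  tg <- utils::read.csv(path, stringsAsFactors = FALSE, dec = dec)
  required <- c("name", "formula", "rt_min", "fragment_mz", "group",
                "mrl_ng_g")
  missing <- setdiff(required, names(tg))
  if (length(missing))
    stop("target list '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(tg) == 0L) stop("target list '", path, "' contains no records")
  tg$precursor_mz <- vapply(seq_len(nrow(tg)), function(i) {
    tryCatch(adduct_mz(parse_formula(tg$formula[i]), reference = reference),
             error = function(e) stop("line ", i + 1L, " of '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  class(tg) <- c("analyte_targets", "data.frame")
  tg
}

#' Write a target list
#'
#' @param targets Data frame as returned by [read_targets()] (the computed
#'   `precursor_mz` column is dropped on write).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(targets, path) {
  keep <- c("name", "formula", "rt_min", "fragment_mz", "group", "mrl_ng_g")
  utils::write.csv(as.data.frame(targets)[keep], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Convert a target-list row to an [analyte_target()]
#'
#' @param targets An `analyte_targets` data frame.
#' @param name Analyte name to extract.
#' @return An `analyte_target`.
#' @export
as_analyte_target <- function(targets, name) {
  i <- match(name, targets$name)
  if (is.na(i)) stop("unknown analyte '", name, "' in target list")
  analyte_target(name = targets$name[i], formula = targets$formula[i],
                 rt_expected = targets$rt_min[i],
                 fragment_mz = .parse_fragment_list(targets$fragment_mz[i]),
                 group = targets$group[i], mrl = targets$mrl_ng_g[i])
}

.parse_fragment_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(as.character(x), ";", fixed = TRUE)[[1]])
}

#' Read an integrated peak table
#'
#' Comma-separated with header `sample_id`, `analyte_hint`, `mz`, `rt`,
#' `area`, `height`, `fragments` (semicolon-separated m/z list) and optional
#' `dilution_factor` (default 1).
#'
#' @param path CSV path.
#' @param dec Decimal mark (`"."` default, `","` accepted).
#' @return Data frame of peaks.
#' @export
read_peaks <- function(path, dec = ".") {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE, dec = dec,
                        colClasses = c(fragments = "character"))
  required <- c("sample_id", "analyte_hint", "mz", "rt", "area", "height",
                "fragments")
  missing <- setdiff(required, names(pk))
  if (length(missing))
    stop("peak table '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(pk$dilution_factor)) pk$dilution_factor <- 1
  pk
}

#' Write an integrated peak table
#'
#' @param peaks Data frame with the columns of [read_peaks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  keep <- intersect(c("sample_id", "analyte_hint", "mz", "rt", "area",
                      "height", "fragments", "dilution_factor"),
                    names(peaks))
  utils::write.csv(peaks[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist fitted calibration curves
#'
#' @param curves Named list (analyte -> list of `calibration_curve` by mode)
#'   or a flat named list of curves.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- list()
  for (a in names(curves)) {
    entry <- curves[[a]]
    if (inherits(entry, "calibration_curve")) entry <- list(entry)
    for (cv in entry) {
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, mode = cv$mode, slope = cv$slope,
        intercept = cv$intercept, r_squared = cv$r_squared,
        levels = paste(cv$levels$nominal, collapse = ";"))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read persisted calibration curves
#'
#' @param path CSV written by [write_curves()].
#' @return Data frame with one row per (analyte, mode).
#' @export
read_curves <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
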