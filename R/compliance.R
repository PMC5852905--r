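#' Maximum-residue-limit registry
#'
#' Per-analyte MRLs and regulatory grouping, plus the group MRL applied to the
#' combined total residues of all sulfonamides (100 ng/g in fin fish muscle;
#' trimethoprim carries its own MRL of 50 ng/g and is excluded from the sum).
#'
#' @param per_analyte Data frame with columns `analyte`, `mrl` (ng/g),
#'   `group` ("A"/"B") and `sulfonamide` (logical: counted in the group sum).
#'   Defaults to the registry for the eight monitored compounds, built from
#'   the bundled target list.
#' @param group_mrl_sulfonamides Group MRL for summed sulfonamides, ng/g.
#' @return Object of class `mrl_registry`.
#' @export
mrl_registry <- function(per_analyte = NULL, group_mrl_sulfonamides = 100) {
  if (is.null(per_analyte)) {
    tg <- read_targets()
    per_analyte <- data.frame(
      analyte = tg$name,
      mrl = tg$mrl_ng_g,
      group = tg$group,
      sulfonamide = grepl("^sulfa", tg$name, ignore.case = TRUE)
    )
  }
  stopifnot(all(c("analyte", "mrl", "group", "sulfonamide") %in%
                  names(per_analyte)))
  structure(list(per_analyte = per_analyte,
                 group_mrl_sulfonamides = group_mrl_sulfonamides),
            class = "mrl_registry")
}

#' Screen one sample against MRLs using CCalpha
#'
#' Per-analyte decision: `not_detected` (no quantifiable signal),
#' `below_loq` (signal below the limit of quantification), `conforming`
#' (quantified below CCalpha, or not actionable because identity was not
#' confirmed), or `nonconforming` (identity confirmed and concentration at or
#' above CCalpha, the 5% false-positive decision limit). The combined
#' sulfonamide total sums the confirmed, quantifiable (>= LOQ) sulfonamide
#' concentrations and is nonconforming at or above the group MRL.
#'
#' @param concs Named numeric vector: analyte -> measured concentration, ng/g
#'   (`NA` or 0 = not detected).
#' @param identities Named list: analyte -> `identity_result` (or logical
#'   `confirmed` flag). Analytes absent from the list are treated as not
#'   confirmed.
#' @param registry An `mrl_registry`.
#' @param ccalphas Named numeric vector: analyte -> CCalpha, ng/g. Required
#'   for every analyte in `concs`.
#' @param loqs Named numeric vector: analyte -> LOQ, ng/g. Required for every
#'   analyte in `concs`.
#' @param sample_id Sample identifier carried into the decision.
#' @return Object of class `compliance_decision`: list with `sample_id`,
#'   `per_analyte` (data frame `analyte`, `conc`, `status`), `sum_sulfonamides`
#'   (ng/g), `group_status` and `rationale` (character vector naming each
#'   governing rule applied).
#' @export
screen_sample <- function(concs, identities, registry, ccalphas, loqs,
                          sample_id = "sample") {
  stopifnot(inherits(registry, "mrl_registry"))
  analytes <- names(concs)
  if (is.null(analytes)) stop("concs must be named by analyte")
  missing_cc <- setdiff(analytes, names(ccalphas))
  if (length(missing_cc))
    stop("missing CCalpha for: ", paste(missing_cc, collapse = ", "))
  missing_loq <- setdiff(analytes, names(loqs))
  if (length(missing_loq))
    stop("missing LOQ for: ", paste(missing_loq, collapse = ", "))

  confirmed_of <- function(a) {
    id <- identities[[a]]
    if (is.null(id)) return(FALSE)
    if (is.logical(id)) return(isTRUE(id))
    isTRUE(id$confirmed)
  }

  rationale <- character(0)
  status <- character(length(analytes))
  names(status) <- analytes
  for (a in analytes) {
    conc <- concs[[a]]
    if (is.na(conc) || conc <= 0) {
      status[a] <- "not_detected"
    } else if (conc < loqs[[a]]) {
      status[a] <- "below_loq"
    } else if (conc >= ccalphas[[a]]) {
      if (confirmed_of(a)) {
        status[a] <- "nonconforming"
        rationale <- c(rationale, sprintf(
          "%s: %.1f ng/g >= CCalpha %.1f ng/g with confirmed identity (alpha = 5%% rule)",
          a, conc, ccalphas[[a]]))
      } else {
        status[a] <- "conforming"
        rationale <- c(rationale, sprintf(
          "%s: identity not confirmed; %.1f ng/g not actionable", a, conc))
      }
    } else {
      status[a] <- "conforming"
    }
  }

  reg <- registry$per_analyte
  is_sulfa <- analytes %in% reg$analyte[reg$sulfonamide]
  quantifiable <- !is.na(concs) & concs >= loqs[analytes] &
    vapply(analytes, confirmed_of, logical(1))
  sum_sulfa <- sum(concs[is_sulfa & quantifiable])
  group_status <- if (sum_sulfa >= registry$group_mrl_sulfonamides) {
    rationale <- c(rationale, sprintf(
      "sum of sulfonamides %.1f ng/g >= group MRL %.1f ng/g",
      sum_sulfa, registry$group_mrl_sulfonamides))
    "nonconforming"
  } else "conforming"

  structure(list(
    sample_id = sample_id,
    per_analyte = data.frame(analyte = analytes, conc = unname(concs),
                             status = unname(status)),
    sum_sulfonamides = sum_sulfa,
    group_status = group_status,
    rationale = rationale
  ), class = "compliance_decision")
}

#' @export
print.compliance_decision <- function(x, ...) {
  cat(sprintf("<compliance_decision> %s: group %s (sum sulfonamides %.1f ng/g)\n",
              x$sample_id, x$group_status, x$sum_sulfonamides))
  print(x$per_analyte, row.names = FALSE)
  for (r in x$rationale) cat(" - ", r, "\n", sep = "")
  invisible(x)
}

#' Check achieved LOQs against a regulatory policy
#'
#' Pass when the achieved LOQ does not exceed the class ceiling (inclusive),
#' e.g. 10 ng/g for individual sulfonamides and 20 ng/g for trimethoprim
#' under the strictest multiresidue policies.
#'
#' @param loqs Named numeric vector: analyte -> achieved LOQ, ng/g.
#' @param policy Named numeric vector: class -> maximum acceptable LOQ, ng/g.
#' @param classes Named character vector: analyte -> class; defaults to
#'   `"sulfonamide"` for names starting with "sulfa" and `"trimethoprim"`
#'   otherwise.
#' @return Data frame `analyte`, `loq`, `class`, `limit`, `pass`.
#' @export
loq_policy_check <- function(loqs,
                             policy = c(sulfonamide = 10, trimethoprim = 20),
                             classes = NULL) {
  analytes <- names(loqs)
  if (is.null(analytes)) stop("loqs must be named by analyte")
  if (is.null(classes)) {
    classes <- ifelse(grepl("^sulfa", analytes, ignore.case = TRUE),
                      "sulfonamide", "trimethoprim")
    names(classes) <- analytes
  }
  unmapped <- setdiff(unique(classes[analytes]), names(policy))
  if (length(unmapped))
    stop("no policy limit for class(es): ", paste(unmapped, collapse = ", "))
  limit <- policy[classes[analytes]]
  data.frame(analyte = analytes, loq = unname(loqs),
             class = unname(classes[analytes]), limit = unname(limit),
             pass = unname(loqs <= limit))
}
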