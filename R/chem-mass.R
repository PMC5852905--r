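#' Monoisotopic atomic mass table
#'
#' Returns the curated table of monoisotopic atomic masses (Da) used throughout
#' the package, together with the proton and electron masses. Carbon-12 is
#' exact by definition; the remaining values are the CODATA/IUPAC monoisotopic
#' masses of the principal isotopes, sufficient to reproduce the reference
#' masses of all monitored sulfonamides and trimethoprim at 4 decimal places.
#'
#' @return A list with components `masses` (named numeric vector, Da per atom),
#'   `proton_mass` (Da) and `electron_mass` (Da).
#' @examples
#' atomic_mass_table()$masses[["C"]]  # 12, exact
#' @export
atomic_mass_table <- function() {
  list(
    masses = c(
      C  = 12.0,
      H  = 1.00782503,
      N  = 14.00307401,
      O  = 15.99491462,
      S  = 31.97207069,
      P  = 30.97376200,
      F  = 18.99840322,
      Cl = 34.96885268,
      Br = 78.91833710,
      I  = 126.90447300,
      Na = 22.98976928,
      K  = 38.96370649
    ),
    proton_mass   = 1.00727646,
    electron_mass = 0.00054858
  )
}

#' Parse an elemental formula
#'
#' Parses a Hill-style molecular formula string (e.g. `"C14H18N4O3"`) into a
#' named count vector. An element symbol with no following digits has count 1;
#' repeated symbols accumulate.
#'
#' @param text Formula string: alternating element symbols (capital letter,
#'   optional lowercase letter) and optional integer counts.
#' @param table Atomic mass table (see [atomic_mass_table()]); symbols absent
#'   from it are rejected.
#' @return An object of class `elemental_formula`: a named integer vector of
#'   element counts. The empty string is not permitted, but a formula may be
#'   empty via `elemental_formula(character())` if ever needed programmatically.
#' @examples
#' parse_formula("C14H18N4O3")   # trimethoprim
#' parse_formula("C9H9N3O2S2")   # sulfathiazole
#' parse_formula("S")            # implicit count 1
#' @export
parse_formula <- function(text, table = atomic_mass_table()) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop(sprintf("malformed formula '%s': unexpected character '%s' at position %d",
                   text, substr(text, pos, pos), pos))
    sym <- m[2]
    if (!sym %in% names(table$masses))
      stop(sprintf("unknown element '%s' in formula '%s' at position %d",
                   sym, text, pos))
    cnt <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (cnt < 1L)
      stop(sprintf("element '%s' has count %d in '%s'; counts must be >= 1",
                   sym, cnt, text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + cnt
    pos <- pos + nchar(m[1])
  }
  elemental_formula(counts)
}

#' Construct an elemental formula from counts
#'
#' @param counts Named integer vector, element symbol -> count (>= 1). An empty
#'   vector is permitted and has mass 0.
#' @return Object of class `elemental_formula`.
#' @export
elemental_formula <- function(counts = integer(0)) {
  counts <- unlist(counts)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts))))
      stop("counts must be named by element symbol")
    if (any(counts < 1) || any(counts != round(counts)))
      stop("element counts must be positive integers")
    storage.mode(counts) <- "integer"
  } else {
    counts <- integer(0)
  }
  structure(counts, class = "elemental_formula")
}

#' Format an elemental formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (the convention of the compound tables this package mirrors); count 1 is
#' omitted.
#'
#' @param f An `elemental_formula` (or named count vector).
#' @return A single formula string.
#' @export
format_formula <- function(f) {
  f <- unclass(f)
  if (!length(f)) return("")
  syms <- names(f)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s) {
    paste0(s, if (f[[s]] > 1L) f[[s]] else "")
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' Sum of count-weighted monoisotopic atomic masses. Rounded to 4 decimal
#' places this reproduces the reference masses of the monitored analytes
#' (e.g. trimethoprim C14H18N4O3 -> 290.1379 Da).
#'
#' @param f An `elemental_formula`, or a formula string (parsed on the fly).
#' @param table Atomic mass table.
#' @return Monoisotopic mass in Da (numeric scalar, full precision).
#' @examples
#' monoisotopic_mass("C14H18N4O3")  # 290.1379 at 4 dp
#' @export
monoisotopic_mass <- function(f, table = atomic_mass_table()) {
  if (is.character(f)) f <- parse_formula(f, table)
  f <- unclass(f)
  if (!length(f)) return(0)
  missing <- setdiff(names(f), names(table$masses))
  if (length(missing))
    stop("element(s) missing from atomic mass table: ",
         paste(missing, collapse = ", "))
  sum(table$masses[names(f)] * as.numeric(f))
}

# registry of supported adducts: ionic mass shift under each reference
# convention, and charge. "proton" is the physically correct charged-adduct
# mass; "hydrogen" adds a neutral H atom, the convention that reproduces the
# printed ppm errors of the reference compound table.
.adduct_registry <- function(table, reference) {
  h_shift <- switch(reference,
    proton   = table$proton_mass,
    hydrogen = table$masses[["H"]],
    stop("unknown mass reference convention: ", reference)
  )
  list(
    "[M+H]+"  = list(shift = h_shift, charge = 1L),
    "[M+Na]+" = list(shift = table$masses[["Na"]] - table$electron_mass,
                     charge = 1L)
  )
}

#' Theoretical adduct m/z
#'
#' m/z of an ionic adduct of the neutral molecule; for `"[M+H]+"` this is the
#' monoisotopic mass plus the proton mass (default convention) at charge 1.
#' The `reference` argument selects the mass added for protonation: `"proton"`
#' (1.00727646 Da, physically correct for a charged species) or `"hydrogen"`
#' (neutral H, 1.00782503 Da, the convention some instrument reports use).
#'
#' @param f `elemental_formula` or formula string.
#' @param adduct Adduct name; `"[M+H]+"` and `"[M+Na]+"` are supported.
#' @param table Atomic mass table.
#' @param reference `"proton"` (default) or `"hydrogen"`.
#' @return Theoretical m/z in Da.
#' @examples
#' adduct_mz("C14H18N4O3")                         # 291.1452
#' adduct_mz("C14H18N4O3", reference = "hydrogen") # 291.1457
#' @export
adduct_mz <- function(f, adduct = "[M+H]+", table = atomic_mass_table(),
                      reference = c("proton", "hydrogen")) {
  reference <- match.arg(reference)
  reg <- .adduct_registry(table, reference)
  if (!adduct %in% names(reg))
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(names(reg), collapse = ", "))
  a <- reg[[adduct]]
  (monoisotopic_mass(f, table) + a$shift) / a$charge
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da), must be > 0.
#' @return Signed ppm error, `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(291.1460, 291.1452)  # +2.7 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0))
    stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}
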