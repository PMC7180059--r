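# Monoisotopic mass arithmetic underlying all annotation rules.

# Monoisotopic atomic masses (Da), CODATA/IUPAC values.
.atomic_masses <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  Na = 22.98976928
)

.electron_mass <- 0.00054857990907

#' Monoisotopic mass of an elemental formula
#'
#' Computes the neutral monoisotopic mass of a molecular formula over the
#' elements C, H, N, O, S and Na.
#'
#' @param formula Character vector of formulas, e.g. `"C23H34O4"`.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass("C2H2O")   # acetyl shift, 42.0106
#' monoisotopic_mass("C23H34O4") # digitoxigenin, 374.2457
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, .monoisotopic_mass1, numeric(1), USE.NAMES = FALSE)
}

.monoisotopic_mass1 <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a non-empty character string", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  total <- 0
  for (tok in tokens) {
    elem <- gsub("[0-9]", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!elem %in% names(.atomic_masses)) {
      stop("unknown element '", elem, "' in formula ", formula, call. = FALSE)
    }
    total <- total + n * .atomic_masses[[elem]]
  }
  total
}

#' Adduct mass constants
#'
#' Charge-carrier masses used in all adduct arithmetic.  The proton mass is
#' mass(H) - mass(electron); the electron is included even though it is far
#' below instrument tolerance.
#'
#' @return Named list with `proton` (Da), `sodium_ion` (Da), and
#'   `na_h_spacing`, the m/z gap between the \[M+Na\]+ and \[M+H\]+ adducts
#'   of one molecule (21.9819 Da).
#' @export
adduct_masses <- function() {
  proton <- .atomic_masses[["H"]] - .electron_mass
  sodium <- .atomic_masses[["Na"]] - .electron_mass
  list(proton = proton, sodium_ion = sodium, na_h_spacing = sodium - proton)
}

# m/z of common adducts of a neutral mass
mz_mh_pos <- function(m) m + adduct_masses()$proton
mz_mna_pos <- function(m) m + adduct_masses()$sodium_ion
mz_mh_neg <- function(m) m - adduct_masses()$proton

.water_mass <- function() 2 * .atomic_masses[["H"]] + .atomic_masses[["O"]]
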