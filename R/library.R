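# Compound library: the annotation rule base.

#' Read a compound library from structured text
#'
#' A compound library lists cardenolide genins, glycoside neutral losses
#' (anhydro sugar masses), the acetyl shift, target glucosinolates, and the
#' negative-mode diagnostic fragment m/z values used to flag unknown
#' glucosinolate candidates.  Masses are recomputed from elemental formulas;
#' when a file also states a mass it must agree with its formula to within
#' 0.0005 Da.
#'
#' @param path Path to a JSON library file.
#' @return An object of class `compound_library`: a list with data frames
#'   `genins` (name, formula, mass), `sugars` (name, formula, loss_mass),
#'   `glucosinolates` (name, formula, class, mass), and scalars
#'   `acetyl_mass`, `diagnostic_fragments_neg`.
#' @export
read_compound_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_compound_library(raw)
}

#' Default compound library
#'
#' The library shipped with the package: nine cardenolide genins, four sugar
#' losses (digitoxose, deoxyhexose, xylose, hexose), the acetyl shift, ten
#' named glucosinolates spanning the major side-chain classes, and five
#' negative-mode diagnostic fragments.
#'
#' @return A `compound_library` object.
#' @export
default_compound_library <- function() {
  read_compound_library(system.file("extdata", "compound_library.json",
                                    package = "chemophylo", mustWork = TRUE))
}

as_compound_library <- function(raw) {
  check_block <- function(df, mass_field = "mass") {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df$computed_mass <- monoisotopic_mass(df$formula)
    if (mass_field %in% names(df)) {
      bad <- abs(df[[mass_field]] - df$computed_mass) >= 5e-4
      if (any(bad, na.rm = TRUE)) {
        stop("library mass inconsistent with formula for: ",
             paste(df$name[which(bad)], collapse = ", "), call. = FALSE)
      }
    }
    df
  }
  genins <- check_block(raw$genins)
  genins$mass <- genins$computed_mass
  if (anyDuplicated(genins$name)) stop("genin names must be unique", call. = FALSE)
  sugars <- check_block(raw$sugars)
  sugars$loss_mass <- sugars$computed_mass
  gsl <- check_block(raw$glucosinolate_targets)
  gsl$mass <- gsl$computed_mass
  lib <- list(
    genins = genins[, c("name", "formula", "mass")],
    sugars = sugars[, c("name", "formula", "loss_mass")],
    acetyl_mass = monoisotopic_mass(raw$acetyl_formula),
    glucosinolates = gsl[, c("name", "formula", "class", "mass")],
    diagnostic_fragments_neg = as.numeric(raw$diagnostic_fragments_neg)
  )
  stopifnot(all(lib$genins$mass > 0), all(lib$sugars$loss_mass > 0),
            lib$acetyl_mass > 0)
  structure(lib, class = "compound_library")
}

#' @export
print.compound_library <- function(x, ...) {
  cat("Compound library:", nrow(x$genins), "genins,",
      nrow(x$sugars), "sugar losses,",
      nrow(x$glucosinolates), "glucosinolate targets\n")
  cat("Acetyl shift:", round(x$acetyl_mass, 4), "Da;",
      length(x$diagnostic_fragments_neg), "diagnostic fragments (neg mode)\n")
  invisible(x)
}
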