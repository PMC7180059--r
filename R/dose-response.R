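# Mixed-effects 4-parameter logistic calibration of Na+/K+-ATPase
# inhibition assays and conversion to ouabain equivalents.
#
# Orientation: sample wells are indexed by x = log10(dilution factor), so
# inhibitor concentration DECREASES with x and absorbance rises to the
# uninhibited asymptote A as x -> +Inf:
#   Abs = A + (B - A) / (1 + exp((x - x_mid) / scal)),  scal > 0.
# Calibration wells are indexed by x = log10(molar ouabain), where
# concentration INCREASES with x, using the complementary orientation.

.fourpl_sample <- function(x, A, B, x_mid, scal) {
  A + (B - A) / (1 + exp((x - x_mid) / scal))
}

.fourpl_conc <- function(x, A, B, x_mid, scal) {
  A + (B - A) / (1 + exp((x_mid - x) / scal))
}

#' Background-correct a plate
#'
#' Subtracts each well's paired background absorbance.  Negative corrected
#' values are retained (and flagged), not clamped.
#'
#' @param plate Data frame with `absorbance` and `background` columns.
#' @return `plate` with an added `corrected` column; attribute
#'   `n_negative` counts negative corrected values.
#' @export
correct_background <- function(plate) {
  if (!all(c("absorbance", "background") %in% names(plate))) {
    stop("plate needs 'absorbance' and 'background' columns", call. = FALSE)
  }
  if (anyNA(plate$background)) {
    stop("every reaction well needs a paired background value",
         call. = FALSE)
  }
  plate$corrected <- plate$absorbance - plate$background
  attr(plate, "n_negative") <- sum(plate$corrected < 0)
  plate
}

#' Default scal grid
#'
#' 21 shape values log-spaced over \[0.05, 5\], the grid searched when the
#' shared 4PL shape parameter is profiled by AIC.
#'
#' @return Numeric vector.
#' @export
default_scal_grid <- function() {
  exp(seq(log(0.05), log(5), length.out = 21))
}

#' Fit the mixed-effects 4PL inhibition model
#'
#' Fits absorbance against log10 dilution with shared asymptotes A
#' (uninhibited) and B (fully inhibited), a per-extract midpoint `x_mid`
#' treated as a random effect around a fixed mean, and a shape parameter
#' `scal` held fixed within each fit and profiled over a grid by AIC (four
#' observations per extract cannot identify four free parameters).  The
#' mixed model is fitted with \pkg{nlme}; when it cannot converge (e.g. on
#' noise-free plates) the fit falls back to profiled least squares with
#' per-extract fixed midpoints.
#'
#' @param plate Plate data frame (`extract_id`, `role`, `x`, `absorbance`,
#'   `background`); only `role == "sample"` rows are fitted, after
#'   background correction.
#' @param scal_grid Candidate shape values (default
#'   [default_scal_grid()]).
#' @return Object of class `fourpl_fit`: `A`, `B`, `scal`, `x_mid` (named
#'   per extract), `x_mid_fixed`, `sd_ranef`, `sigma`, `AIC`, `engine`,
#'   `aic_table`, `x_range`.
#' @export
fit_4pl_mixed <- function(plate, scal_grid = default_scal_grid()) {
  if (!length(scal_grid)) stop("empty scal grid", call. = FALSE)
  d <- plate[plate$role == "sample", , drop = FALSE]
  if (!"corrected" %in% names(d)) d <- correct_background(d)
  d$extract_id <- as.character(d$extract_id)
  extracts <- sort(unique(d$extract_id))
  fits <- lapply(scal_grid, function(s) .fit_4pl_at_scal(d, s, extracts))
  aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$AIC,
                 numeric(1))
  if (all(!is.finite(aics))) {
    stop("4PL fit failed to converge for every scal value", call. = FALSE)
  }
  best <- fits[[which.min(aics)]]
  best$aic_table <- data.frame(scal = scal_grid, AIC = aics)
  best$x_range <- range(d$x)
  structure(best, class = "fourpl_fit")
}

.start_values <- function(d, extracts) {
  A0 <- max(d$corrected); B0 <- min(d$corrected)
  mid <- (A0 + B0) / 2
  xm <- vapply(extracts, function(e) {
    de <- d[d$extract_id == e, ]
    de$x[which.min(abs(de$corrected - mid))]
  }, numeric(1))
  list(A = A0, B = B0, xm = xm)
}

.fit_4pl_at_scal <- function(d, scal, extracts) {
  st <- .start_values(d, extracts)
  mixed <- if (length(extracts) >= 2) tryCatch({
    m <- nlme::nlme(
      corrected ~ A + (B - A) / (1 + exp((x - xmid) / s)),
      fixed = A + B + xmid ~ 1,
      random = xmid ~ 1 | extract_id,
      data = cbind(d, s = scal),
      start = c(A = st$A, B = st$B, xmid = mean(st$xm)),
      control = nlme::nlmeControl(maxIter = 200, returnObject = FALSE))
    fe <- nlme::fixef(m)
    re <- nlme::ranef(m)
    xm <- setNames(fe[["xmid"]] + re[extracts, 1], extracts)
    list(A = fe[["A"]], B = fe[["B"]], scal = scal, x_mid = xm,
         x_mid_fixed = fe[["xmid"]],
         sd_ranef = as.numeric(nlme::VarCorr(m)[1, 2]),
         sigma = m$sigma, AIC = stats::AIC(m), engine = "nlme")
  }, error = function(e) NULL) else NULL
  if (!is.null(mixed)) return(mixed)
  .fit_4pl_ls(d, scal, extracts, st)
}

# profiled least squares: per-extract fixed midpoints, A and B linear
.fit_4pl_ls <- function(d, scal, extracts, st) {
  idx <- match(d$extract_id, extracts)
  rss_fun <- function(xm) {
    g <- 1 / (1 + exp((d$x - xm[idx]) / scal))  # weight toward B
    X <- cbind(1 - g, g)
    fit <- lm.fit(X, d$corrected)
    sum(fit$residuals^2)
  }
  opt <- optim(st$xm, rss_fun, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  xm <- setNames(opt$par, extracts)
  g <- 1 / (1 + exp((d$x - xm[idx]) / scal))
  ab <- lm.fit(cbind(1 - g, g), d$corrected)$coefficients
  n <- nrow(d)
  rss <- opt$value
  k <- 2 + length(extracts) + 1  # A, B, midpoints, sigma
  aic <- n * log(max(rss, 1e-300) / n) + n * (1 + log(2 * pi)) + 2 * k
  list(A = unname(ab[1]), B = unname(ab[2]), scal = scal, x_mid = xm,
       x_mid_fixed = mean(xm), sd_ranef = sd(xm),
       sigma = sqrt(rss / max(1, n - (k - 1))), AIC = aic,
       engine = "profiled-ls")
}

# profiled least squares for a single 4PL series: A and B solved linearly
# at each (xmid, log scal); returns list(A, B, xmid, scal) or NULL
.fit_1series_4pl <- function(x, y, orientation = c("conc", "sample")) {
  orientation <- match.arg(orientation)
  sgn <- if (orientation == "conc") -1 else 1
  ab_rss <- function(par) {
    g <- 1 / (1 + exp(sgn * (x - par[1]) / exp(par[2])))
    fit <- lm.fit(cbind(1 - g, g), y)
    list(ab = fit$coefficients, rss = sum(fit$residuals^2))
  }
  starts <- expand.grid(xmid = quantile(x, c(0.25, 0.5, 0.75)),
                        lscal = log(c(0.1, 0.5, 2)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(as.numeric(starts[i, ]), function(p) ab_rss(p)$rss,
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) return(NULL)
  best <- tryCatch(
    optim(best$par, function(p) ab_rss(p)$rss, method = "BFGS",
          control = list(maxit = 1000, reltol = 1e-15)),
    error = function(e) best)
  sol <- ab_rss(best$par)
  list(A = unname(sol$ab[1]), B = unname(sol$ab[2]),
       xmid = best$par[1], scal = exp(best$par[2]))
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat("Mixed-effects 4PL fit (", x$engine, ")\n", sep = "")
  cat(sprintf("  A = %.4g, B = %.4g, scal = %.4g\n", x$A, x$B, x$scal))
  cat(sprintf("  x_mid: fixed %.4g, SD across %d extracts %.4g\n",
              x$x_mid_fixed, length(x$x_mid), x$sd_ranef))
  cat("  AIC =", round(x$AIC, 2), "\n")
  invisible(x)
}

#' Fit the ouabain calibration curve
#'
#' Single-series 4PL over log10 molar ouabain concentration; the midpoint
#' is the concentration producing 50% inhibition.
#'
#' @param calibration_wells Data frame with `x` (log10 molarity),
#'   `absorbance`, `background` (rows with `role` column are filtered to
#'   `role == "calibration"`).
#' @return Object of class `calibration_fit`: `A`, `B`, `scal`,
#'   `log10_ic50`, `ic50` (molar).
#' @export
calibrate_ouabain <- function(calibration_wells) {
  d <- calibration_wells
  if ("role" %in% names(d)) d <- d[d$role == "calibration", , drop = FALSE]
  if (!"corrected" %in% names(d)) d <- correct_background(d)
  if (length(unique(d$x)) < 4) {
    stop("calibration needs >= 4 distinct concentrations", call. = FALSE)
  }
  if (sd(d$corrected) < 1e-12) {
    stop("calibration absorbances carry no signal", call. = FALSE)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      corrected ~ A + (B - A) / (1 + exp((xmid - x) / scal)), data = d,
      start = list(A = max(d$corrected), B = min(d$corrected),
                   xmid = median(d$x), scal = diff(range(d$x)) / 6),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  cf <- if (!is.null(fit)) as.list(coef(fit)) else
    .fit_1series_4pl(d$x, d$corrected, orientation = "conc")
  if (is.null(cf)) {
    stop("calibration fit did not converge", call. = FALSE)
  }
  structure(list(A = cf[["A"]], B = cf[["B"]], scal = cf[["scal"]],
                 log10_ic50 = cf[["xmid"]], ic50 = 10^cf[["xmid"]],
                 fit = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "Ouabain calibration: IC50 = %.4g M (A = %.3g, B = %.3g, scal = %.3g)\n",
    x$ic50, x$A, x$B, x$scal))
  invisible(x)
}

#' Extract preparation constants
#'
#' The unit chain from dry leaf tissue to the assay well, every factor
#' explicit and overridable.
#'
#' @param tissue_mg_per_ml mg dry tissue extracted per mL of stock solvent.
#' @param well_dilution Extra dilution of the stock inside the well before
#'   the plotted dilution series.
#' @param ouabain_molar_mass g/mol.
#' @return Named list.
#' @export
prep_config <- function(tissue_mg_per_ml = 10, well_dilution = 1,
                        ouabain_molar_mass = 584.65) {
  stopifnot(tissue_mg_per_ml > 0, well_dilution > 0)
  list(tissue_mg_per_ml = tissue_mg_per_ml, well_dilution = well_dilution,
       ouabain_molar_mass = ouabain_molar_mass)
}

#' Ouabain equivalents of plant extracts
#'
#' At an extract's fitted midpoint the well contains inhibitor equivalent
#' to the calibration IC50, so the undiluted stock holds
#' `IC50_ouabain * 10^x_mid * well_dilution` molar ouabain equivalents;
#' the molar mass and tissue loading convert this to micrograms of ouabain
#' per mg dry tissue.
#'
#' @param sample_fit A `fourpl_fit`.
#' @param calib_fit A `calibration_fit`.
#' @param prep A [prep_config()] list.
#' @return Data frame per extract: `extract_id`, `x_mid`,
#'   `stock_molar` (ouabain-equivalent molarity of the undiluted stock),
#'   `ug_per_mg` (micrograms ouabain equivalents per mg dry tissue),
#'   `extrapolated` (x_mid outside the tested dilution range).
#' @export
ouabain_equivalents <- function(sample_fit, calib_fit, prep = prep_config()) {
  stopifnot(inherits(sample_fit, "fourpl_fit"),
            inherits(calib_fit, "calibration_fit"))
  xm <- sample_fit$x_mid
  stock <- calib_fit$ic50 * 10^xm * prep$well_dilution
  ug_per_ml <- stock * prep$ouabain_molar_mass * 1000  # g/L -> ug/mL
  out <- data.frame(extract_id = names(xm), x_mid = unname(xm),
                    stock_molar = unname(stock),
                    ug_per_mg = unname(ug_per_ml / prep$tissue_mg_per_ml),
                    extrapolated = unname(xm < sample_fit$x_range[1] |
                                            xm > sample_fit$x_range[2]),
                    stringsAsFactors = FALSE)
  if (any(out$extrapolated)) {
    warning("x_mid outside the tested dilution range for: ",
            paste(out$extract_id[out$extrapolated], collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Simulate a 96-well inhibition plate
#'
#' Generates background-offset absorbances for a dilution series of each
#' extract from the sample-orientation 4PL, plus an ouabain calibration
#' series from the concentration-orientation 4PL with the same asymptotes
#' and shape.
#'
#' @param true_ic50s Named vector of stock ouabain-equivalent molarities
#'   (> 0), one per extract.
#' @param plate_params List: `A`, `B`, `scal`, `noise_sd`, `background`,
#'   `calib_ic50` (M), `dilutions_log10`, `calib_log10_conc`.
#' @param seed Integer seed.
#' @return List with `plate` (long data frame: `extract_id`, `role`, `x`,
#'   `absorbance`, `background`) and `truth` (`x_mid` per extract,
#'   `calib_log10_ic50`, plate parameters).
#' @export
simulate_plate <- function(true_ic50s,
                           plate_params = list(), seed = 1) {
  pp <- modifyList(list(A = 1, B = 0, scal = 0.5, noise_sd = 0,
                        background = 0.05, calib_ic50 = 1e-7,
                        dilutions_log10 = log10(c(1, 5, 50, 500)),
                        calib_log10_conc = seq(-8, -3)), plate_params)
  if (any(true_ic50s <= 0)) stop("IC50s must be > 0", call. = FALSE)
  if (is.null(names(true_ic50s))) {
    names(true_ic50s) <- paste0("extract", seq_along(true_ic50s))
  }
  x_mid <- log10(true_ic50s / pp$calib_ic50)
  with_seed(seed, {
    rows <- lapply(names(true_ic50s), function(e) {
      x <- pp$dilutions_log10
      mu <- .fourpl_sample(x, pp$A, pp$B, x_mid[[e]], pp$scal)
      data.frame(extract_id = e, role = "sample", x = x,
                 absorbance = mu + pp$background +
                   rnorm(length(x), sd = pp$noise_sd),
                 background = pp$background, stringsAsFactors = FALSE)
    })
    xc <- pp$calib_log10_conc
    muc <- .fourpl_conc(xc, pp$A, pp$B, log10(pp$calib_ic50), pp$scal)
    rows[[length(rows) + 1L]] <- data.frame(
      extract_id = "ouabain", role = "calibration", x = xc,
      absorbance = muc + pp$background + rnorm(length(xc), sd = pp$noise_sd),
      background = pp$background, stringsAsFactors = FALSE)
    plate <- do.call(rbind, rows)
    rownames(plate) <- NULL
    list(plate = plate,
         truth = list(x_mid = x_mid,
                      calib_log10_ic50 = log10(pp$calib_ic50), params = pp))
  })
}
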