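# Cross-experiment assembly of species chemical profiles: standardization,
# log transform, the combining linear mixed model, and derived summaries.

#' Standardize raw ion counts
#'
#' Divides raw intensities by dry sample mass and dilution and multiplies by
#' an internal-standard correction.  Pooled samples are standardized by the
#' mean dry mass of the contributing plants.
#'
#' @param samples Data frame with columns `sample_id`, `intensity`, and any
#'   identifier columns (species, compound, experiment, treatment) carried
#'   through.
#' @param metadata Data frame with `sample_id`, `dry_mass` (mg; for pooled
#'   samples a list-column or comma-separated string of contributor masses),
#'   and optional `dilution` (default 1) and `internal_std` correction
#'   factor (default 1).
#' @return `samples` with an added `std_intensity` column.
#' @export
standardize <- function(samples, metadata) {
  i <- match(samples$sample_id, metadata$sample_id)
  if (anyNA(i)) {
    stop("samples without metadata: ",
         paste(unique(samples$sample_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  mass <- vapply(metadata$dry_mass, function(m) {
    if (is.character(m)) m <- as.numeric(strsplit(m, ",")[[1]])
    mean(as.numeric(m))
  }, numeric(1))
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("dry mass must be > 0 for every sample", call. = FALSE)
  }
  dil <- if ("dilution" %in% names(metadata)) metadata$dilution else 1
  istd <- if ("internal_std" %in% names(metadata)) metadata$internal_std else 1
  dil <- ifelse(is.na(dil), 1, dil)
  istd <- ifelse(is.na(istd), 1, istd)
  if (any(dil <= 0) || any(istd <= 0)) {
    stop("standardization factors must be > 0", call. = FALSE)
  }
  fac <- istd / (mass * dil)
  samples$std_intensity <- samples$intensity * fac[i]
  samples
}

#' Log(+0.1) transform
#'
#' Natural log of `x + 0.1`, the transform applied to standardized ion
#' counts before modelling (zero maps to `log(0.1)`).
#'
#' @param x Non-negative numeric vector.
#' @return `log(x + 0.1)`, elementwise.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("'x' must be >= 0", call. = FALSE)
  log(x + 0.1)
}

#' Fit the experiment-combining mixed model
#'
#' Models log-transformed ion counts with experiment as a fixed effect, a
#' species-by-compound identifier as the main random effect, and (when
#' replicate observations per species-compound-experiment cell exist) a
#' nested species-by-compound-by-experiment random effect.  Compound enters
#' as a fixed effect so that the species-by-compound BLUPs are deviations
#' from per-compound means.  Fitted by REML via \pkg{lme4}; degenerate data
#' (a single experiment, or an exactly noise-free balanced table) fall back
#' to closed-form cell means with variance components flagged
#' unidentifiable.
#'
#' @param long_table Data frame with `species`, `compound`, `experiment`,
#'   `log_intensity` (replicates allowed as repeated rows).
#' @return Object of class `combining_fit`: list with `mu` (per-compound
#'   means at the reference experiment), `beta` (experiment effects,
#'   reference = 0), `u_sc` (species x compound BLUP matrix),
#'   `species_means` (mu_c + u_sc), `varcomp`, `method`.
#' @export
fit_combining_model <- function(long_table) {
  d <- long_table
  req <- c("species", "compound", "experiment", "log_intensity")
  if (!all(req %in% names(d))) {
    stop("long_table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d$species <- as.character(d$species)
  d$compound <- as.character(d$compound)
  d$experiment <- as.character(d$experiment)
  species <- sort(unique(d$species))
  compounds <- sort(unique(d$compound))
  experiments <- sort(unique(d$experiment))
  cellkey <- interaction(d$species, d$compound, d$experiment, drop = TRUE)
  has_reps <- any(table(cellkey) > 1)

  exact <- .combining_exact(d, species, compounds, experiments)
  single_exp <- length(experiments) < 2
  if (single_exp || exact$noiseless) {
    fit <- exact
    fit$method <- if (single_exp) "cell-means (single experiment)" else
      "cell-means (noise-free data)"
    fit$varcomp <- c(sigma2_u = NA_real_, sigma2_w = NA_real_,
                     sigma2_eps = NA_real_)
    fit$identifiable <- FALSE
  } else {
    form <- if (has_reps) {
      log_intensity ~ 0 + compound + experiment +
        (1 | species:compound) + (1 | species:compound:experiment)
    } else {
      log_intensity ~ 0 + compound + experiment + (1 | species:compound)
    }
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = d, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    fe <- lme4::fixef(m)
    mu <- fe[paste0("compound", compounds)]
    names(mu) <- compounds
    beta <- setNames(numeric(length(experiments)), experiments)
    bn <- paste0("experiment", experiments[-1])
    beta[experiments[-1]] <- fe[bn]
    re <- lme4::ranef(m)[["species:compound"]]
    u <- matrix(0, length(species), length(compounds),
                dimnames = list(species, compounds))
    parts <- strsplit(rownames(re), ":", fixed = TRUE)
    for (k in seq_along(parts)) {
      u[parts[[k]][1], parts[[k]][2]] <- re[k, 1]
    }
    vc <- as.data.frame(lme4::VarCorr(m))
    getv <- function(g) {
      v <- vc$vcov[vc$grp == g]
      if (length(v)) v else NA_real_
    }
    fit <- list(
      mu = mu, beta = beta, u_sc = u,
      species_means = matrix(mu, length(species), length(compounds),
                             byrow = TRUE,
                             dimnames = list(species, compounds)) + u,
      varcomp = c(sigma2_u = getv("species:compound"),
                  sigma2_w = getv("species:compound:experiment"),
                  sigma2_eps = vc$vcov[vc$grp == "Residual"]),
      method = "REML (lme4)", identifiable = TRUE, model = m)
  }
  structure(fit, class = "combining_fit")
}

# Closed-form balanced path: experiment effects from experiment means,
# cell means from experiment-adjusted averages.  Also detects whether the
# table is exactly noise-free.
.combining_exact <- function(d, species, compounds, experiments) {
  cell <- tapply(d$log_intensity,
                 list(d$species, d$compound, d$experiment), mean)
  ref <- experiments[1]
  beta <- setNames(numeric(length(experiments)), experiments)
  for (e in experiments) {
    beta[e] <- mean(cell[, , e] - cell[, , ref], na.rm = TRUE)
  }
  adj <- cell
  for (e in experiments) adj[, , e] <- cell[, , e] - beta[e]
  sc <- apply(adj, c(1, 2), mean, na.rm = TRUE)
  resid_max <- if (length(experiments) > 1) {
    max(abs(sweep(adj, c(1, 2), sc)), na.rm = TRUE)
  } else 0
  mu <- colMeans(sc)
  u <- sweep(sc, 2, mu)
  list(mu = mu, beta = beta, u_sc = u[species, compounds, drop = FALSE],
       species_means = sc[species, compounds, drop = FALSE],
       noiseless = resid_max < 1e-8)
}

#' @export
print.combining_fit <- function(x, ...) {
  cat("Experiment-combining mixed model (", x$method, ")\n", sep = "")
  cat(" ", length(x$mu), "compounds x", nrow(x$u_sc), "species;",
      length(x$beta), "experiments\n")
  if (isTRUE(x$identifiable)) {
    cat("  variance components: sigma2_u =",
        signif(x$varcomp["sigma2_u"], 4), ", sigma2_eps =",
        signif(x$varcomp["sigma2_eps"], 4), "\n")
  } else {
    cat("  variance components not identifiable\n")
  }
  invisible(x)
}

#' @export
summary.combining_fit <- function(object, ...) {
  cat("Experiment fixed effects (reference = 0):\n")
  print(round(object$beta, 4))
  cat("\nVariance components:\n")
  print(object$varcomp)
  invisible(object)
}

#' @export
coef.combining_fit <- function(object, ...) {
  list(mu = object$mu, beta = object$beta)
}

#' Extract species chemical profiles from a combining fit
#'
#' Species x compound profile matrix: `max(0, mu_c + u_sc)` on the log
#' scale (negative values correspond to intensities below the reliable
#' detection limit and are floored at zero), with per-species totals on the
#' intensity scale and nonzero compound counts.
#'
#' @param fit A `combining_fit`.
#' @return Object of class `species_profiles`: the floored matrix with
#'   attributes `totals` (intensity-scale row totals, inverse of the
#'   log(+0.1) transform applied to nonzero entries) and `n_compounds`
#'   (per-species nonzero counts).
#' @export
extract_species_means <- function(fit) {
  stopifnot(inherits(fit, "combining_fit"))
  m <- pmax(fit$species_means, 0)
  totals <- rowSums(ifelse(m > 0, exp(m) - 0.1, 0))
  counts <- rowSums(m > 0)
  structure(m, class = c("species_profiles", class(m)),
            totals = totals, n_compounds = counts)
}

#' Defense inducibility from paired treatment profiles
#'
#' Per-species difference in intensity-scale totals between induced (e.g.
#' jasmonic-acid treated) and control profiles, with the grand mean and its
#' t-based 95% confidence interval.  A CI excluding zero indicates a
#' significant induction effect.
#'
#' @param control_profiles,induced_profiles `species_profiles` matrices (or
#'   plain matrices of log-scale profiles) sharing species rows.
#' @return List with `delta` (named per-species differences), `mean`,
#'   `ci` (length 2), `significant`, `n`.
#' @export
compute_inducibility <- function(control_profiles, induced_profiles) {
  tot <- function(m) {
    a <- attr(m, "totals")
    if (!is.null(a)) return(a)
    rowSums(ifelse(m > 0, exp(m) - 0.1, 0))
  }
  tc <- tot(control_profiles); ti <- tot(induced_profiles)
  shared <- intersect(names(tc), names(ti))
  if (!length(shared)) stop("no shared species between treatments",
                            call. = FALSE)
  delta <- ti[shared] - tc[shared]
  n <- length(delta)
  m <- mean(delta)
  if (n < 2) {
    return(list(delta = delta, mean = m, ci = c(NA_real_, NA_real_),
                significant = NA, n = n))
  }
  se <- sd(delta) / sqrt(n)
  ci <- m + c(-1, 1) * qt(0.975, n - 1) * se
  list(delta = delta, mean = m, ci = ci,
       significant = ci[1] > 0 || ci[2] < 0, n = n)
}

#' Classify species chemotypes by dominant compound class
#'
#' Sums profile intensity by compound class and labels each species with
#' the class carrying the largest share.  Ties are broken deterministically
#' by the order of `rules$priority` and flagged.
#'
#' @param profile_matrix Species x compound matrix.
#' @param rules List with `class_map` (named character vector
#'   compound -> class) and optional `priority` (class order for
#'   tie-breaks; defaults to sorted class names).
#' @return Character vector of labels named by species, with attribute
#'   `tied` marking tie-broken species.
#' @export
classify_chemotype <- function(profile_matrix, rules) {
  cmap <- rules$class_map
  missing <- setdiff(colnames(profile_matrix), names(cmap))
  if (length(missing)) {
    stop("compounds missing from class map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  classes <- cmap[colnames(profile_matrix)]
  priority <- if (!is.null(rules$priority)) rules$priority else
    sort(unique(unname(classes)))
  labels <- character(nrow(profile_matrix))
  tied <- logical(nrow(profile_matrix))
  for (i in seq_len(nrow(profile_matrix))) {
    sums <- tapply(profile_matrix[i, ], classes, sum)
    best <- names(sums)[sums == max(sums)]
    tied[i] <- length(best) > 1
    labels[i] <- priority[min(match(best, priority))]
  }
  names(labels) <- rownames(profile_matrix)
  attr(labels, "tied") <- setNames(tied, rownames(profile_matrix))
  labels
}
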