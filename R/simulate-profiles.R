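# Synthetic species x compound intensity profiles with experiment structure.

#' Simulation configuration
#'
#' Bundles the controls of the synthetic-data generator.  Defaults define the
#' study conditions the pipeline is tested under: 48 species, 30 compounds,
#' 3 experiments with modest fixed offsets, species-by-compound effects of
#' unit scale, and log-scale noise well below the between-species signal.
#'
#' @param n_tips Number of species (tree tips), >= 2.
#' @param birth_rate Speciation rate of the simulated Yule tree.
#' @param sigma2 Brownian rate used when traits or profile effects are
#'   phylogenetically structured.
#' @param n_compounds Number of compounds per species profile.
#' @param n_experiments Number of independent experiments.
#' @param experiment_effects Log-scale fixed offsets per experiment
#'   (reference experiment 0).
#' @param sd_interaction SD of the species-by-compound random effect u_sc.
#' @param noise_sd_cell SD of the species-by-compound-by-experiment effect.
#' @param noise_sd_rep Residual (replicate) SD.
#' @param phylo_structure If `TRUE`, u_sc is Brownian on the tree per
#'   compound instead of iid normal.
#' @param mu Overall log-scale compound mean(s); recycled to `n_compounds`.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tips = 48, birth_rate = 1, sigma2 = 1,
                       n_compounds = 30, n_experiments = 3,
                       experiment_effects = NULL,
                       sd_interaction = 1, noise_sd_cell = 0.3,
                       noise_sd_rep = 0.2, phylo_structure = TRUE,
                       mu = 2, seed = 1) {
  if (n_tips < 2) stop("'n_tips' must be >= 2", call. = FALSE)
  if (n_experiments < 1) stop("'n_experiments' must be >= 1", call. = FALSE)
  if (is.null(experiment_effects)) {
    experiment_effects <- if (n_experiments == 1) 0 else
      c(0, seq(0.5, by = -1, length.out = n_experiments - 1))
  }
  if (length(experiment_effects) != n_experiments) {
    stop("'experiment_effects' must have length n_experiments", call. = FALSE)
  }
  vals <- c(birth_rate = birth_rate, sigma2 = sigma2,
            sd_interaction = sd_interaction, noise_sd_cell = noise_sd_cell,
            noise_sd_rep = noise_sd_rep)
  if (any(vals < 0) || birth_rate <= 0 || sigma2 <= 0) {
    stop("rates must be > 0 and SDs >= 0", call. = FALSE)
  }
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 sigma2 = sigma2, n_compounds = as.integer(n_compounds),
                 n_experiments = as.integer(n_experiments),
                 experiment_effects = experiment_effects,
                 sd_interaction = sd_interaction,
                 noise_sd_cell = noise_sd_cell, noise_sd_rep = noise_sd_rep,
                 phylo_structure = isTRUE(phylo_structure),
                 mu = rep_len(mu, n_compounds), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate species chemical profiles across experiments
#'
#' Generates per-experiment species x compound log-intensity matrices under
#' the model
#' \deqn{y_{sce} = \mu_c + \beta_e + u_{sc} + w_{sce} + \epsilon_{sce}}
#' with `u_sc` either iid normal or Brownian on the tree per compound,
#' `w_sce` a species-by-compound-by-experiment effect and `eps` residual
#' noise.  This is the data-generating model the combining mixed model of
#' [fit_combining_model()] assumes.
#'
#' @param tree A `phylo` with as many tips as `config$n_tips`.
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list with `experiments` (list of species x compound matrices,
#'   one per experiment) and `truth` (list with `mu`, `beta`, `u_sc` matrix,
#'   and `species_means` = mu_c + u_sc).
#' @export
simulate_profiles <- function(tree, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (ape::Ntip(tree) != config$n_tips) {
    stop("tree has ", ape::Ntip(tree), " tips but config expects ",
         config$n_tips, call. = FALSE)
  }
  n_s <- config$n_tips; n_c <- config$n_compounds; n_e <- config$n_experiments
  species <- tree$tip.label
  compounds <- paste0("cmp", seq_len(n_c))
  with_seed(seed, {
    u_sc <- if (config$phylo_structure) {
      V <- brownian_cov(tree)$V
      L <- t(chol(V / mean(diag(V))))  # unit marginal variance
      config$sd_interaction * (L %*% matrix(rnorm(n_s * n_c), n_s, n_c))
    } else {
      matrix(rnorm(n_s * n_c, sd = config$sd_interaction), n_s, n_c)
    }
    dimnames(u_sc) <- list(species, compounds)
    mu_mat <- matrix(config$mu, n_s, n_c, byrow = TRUE,
                     dimnames = dimnames(u_sc))
    species_means <- mu_mat + u_sc
    experiments <- vector("list", n_e)
    for (e in seq_len(n_e)) {
      w <- matrix(rnorm(n_s * n_c, sd = config$noise_sd_cell), n_s, n_c)
      eps <- matrix(rnorm(n_s * n_c, sd = config$noise_sd_rep), n_s, n_c)
      y <- species_means + config$experiment_effects[e] + w + eps
      dimnames(y) <- dimnames(u_sc)
      experiments[[e]] <- y
    }
    names(experiments) <- paste0("exp", seq_len(n_e))
    list(experiments = experiments,
         truth = list(mu = setNames(config$mu, compounds),
                      beta = setNames(config$experiment_effects,
                                      names(experiments)),
                      u_sc = u_sc, species_means = species_means))
  })
}

#' Convert per-experiment profile matrices to a long table
#'
#' The long format consumed by [fit_combining_model()].
#'
#' @param experiments List of species x compound matrices (one per
#'   experiment), as produced by [simulate_profiles()].
#' @return Data frame with columns `species`, `compound`, `experiment`,
#'   `log_intensity`.
#' @export
profiles_to_long <- function(experiments) {
  out <- do.call(rbind, lapply(names(experiments), function(e) {
    m <- experiments[[e]]
    data.frame(species = rep(rownames(m), ncol(m)),
               compound = rep(colnames(m), each = nrow(m)),
               experiment = e,
               log_intensity = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
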