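# Configuration and the end-to-end pipeline driver.

#' Pipeline configuration
#'
#' Defaults follow the study design the package targets: 1000 Mantel
#' permutations, 10,000 signal-test simulations, and 10,000 multiscale
#' bootstrap iterations (distributed over the resampling scales).
#'
#' @param tree A `phylo` object or path to a Newick file.
#' @param feature_tables Named list (one element per experiment) of feature
#'   tables or CSV paths.
#' @param sample_species Optional named vector mapping `sample_id` to
#'   species; by default sample ids are taken as species names.
#' @param plate Optional plate data frame or CSV path for the inhibition
#'   assay stage.
#' @param library A `compound_library` (default the shipped one).
#' @param out_dir Output directory.
#' @param mz_tol,rt_tol Annotation tolerances.
#' @param n_perm Mantel permutations.
#' @param n_sim Signal-test simulations.
#' @param n_boot Total multiscale bootstrap iterations.
#' @param seed Integer seed recorded in every output header.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tree, feature_tables, sample_species = NULL,
                            plate = NULL, library = NULL,
                            out_dir = tempfile("chemophylo_run_"),
                            mz_tol = 0.005, rt_tol = 0.05,
                            n_perm = 1000, n_sim = 10000, n_boot = 10000,
                            seed = 1) {
  stopifnot(n_perm >= 1, n_sim >= 1, n_boot >= 1)
  structure(list(tree = tree, feature_tables = feature_tables,
                 sample_species = sample_species, plate = plate,
                 library = library, out_dir = out_dir, mz_tol = mz_tol,
                 rt_tol = rt_tol, n_perm = as.integer(n_perm),
                 n_sim = as.integer(n_sim), n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes annotation, profile assembly, chemodiversity statistics, and
#' phylogenetic statistics (plus the dose-response stage when a plate is
#' supplied), writing all tables with seed/tolerance headers plus a run
#' manifest and log to the configured output directory.
#'
#' @param config A [pipeline_config()].
#' @return List of in-memory results (`annotations`, `profiles`, `fit`,
#'   `bray`, `chemogram`, `pcoa`, `mantel`, `signal`, `tip_rates`, `trc`,
#'   optionally `dose_response`), invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logfile, append = TRUE)
    message(msg)
  }
  hdr <- c(seed = config$seed, mz_tol = config$mz_tol,
           rt_tol = config$rt_tol)
  lib <- if (is.null(config$library)) default_compound_library() else
    config$library
  tree <- .stage("load-tree", {
    if (inherits(config$tree, "phylo")) config$tree else
      read_newick(config$tree)
  })
  params <- annotation_params(mz_tol = config$mz_tol,
                              rt_tol = config$rt_tol)

  logmsg("annotate: ", length(config$feature_tables), " experiment(s)")
  ann_res <- .stage("annotate", {
    lapply(config$feature_tables, function(ft) {
      if (is.character(ft)) ft <- read_csv_header(ft)
      card <- annotate_cardenolides(ft, lib, params)
      gsl <- screen_glucosinolates(ft, lib, params)
      quant <- quantify_compounds(ft, list(card, gsl))
      list(cardenolides = card, glucosinolates = gsl, quant = quant)
    })
  })

  logmsg("assemble: combining mixed model")
  long <- .stage("assemble-long", {
    do.call(rbind, lapply(names(ann_res), function(e) {
      q <- ann_res[[e]]$quant
      if (ncol(q) == 0) return(NULL)
      sp <- rownames(q)
      if (!is.null(config$sample_species)) {
        sp <- unname(config$sample_species[sp])
      }
      data.frame(species = rep(sp, ncol(q)),
                 compound = rep(colnames(q), each = nrow(q)),
                 experiment = e,
                 log_intensity = log_transform(as.vector(q)),
                 stringsAsFactors = FALSE)
    }))
  })
  fit <- .stage("assemble-fit", fit_combining_model(long))
  profiles <- extract_species_means(fit)
  write_csv_header(unclass(profiles), file.path(config$out_dir,
                                                "species_profiles.csv"),
                   header = hdr)

  logmsg("chemodiversity: distances, chemogram, ordination")
  keep <- intersect(rownames(profiles), tree$tip.label)
  prof <- profiles[keep, , drop = FALSE]
  tree_k <- ape::keep.tip(tree, keep)
  chem <- .stage("chemodiversity", {
    bray <- bray_curtis(prof)
    n_scales <- length(seq(0.5, 1.4, by = 0.1))
    boot <- multiscale_bootstrap_support(
      prof, n_boot = max(1L, config$n_boot %/% n_scales),
      seed = config$seed + 1L)
    ord <- pcoa(bray)
    coph <- cophenetic(tree_k)
    mant <- mantel_test(bray, coph, n_perm = config$n_perm,
                        seed = config$seed + 2L)
    list(bray = bray, boot = boot, pcoa = ord, mantel = mant)
  })
  write_csv_header(chem$bray, file.path(config$out_dir, "bray_curtis.csv"),
                   header = hdr)
  write_csv_header(chem$pcoa$coordinates,
                   file.path(config$out_dir, "pcoa_coordinates.csv"),
                   header = hdr)
  write_csv_header(chem$boot$support,
                   file.path(config$out_dir, "chemogram_support.csv"),
                   header = hdr)

  logmsg("phylogenetics: signal and tip-rate statistics")
  phylo <- .stage("phylo", {
    traits <- list(total = attr(profiles, "totals")[keep],
                   n_compounds = attr(profiles, "n_compounds")[keep],
                   pco1 = chem$pcoa$coordinates[, 1],
                   pco2 = if (ncol(chem$pcoa$coordinates) > 1)
                     chem$pcoa$coordinates[, 2] else NULL)
    traits <- Filter(Negate(is.null), traits)
    sig <- lapply(seq_along(traits), function(i)
      phylo_signal_test(tree_k, traits[[i]], n_sim = config$n_sim,
                        seed = config$seed + 10L + i))
    names(sig) <- names(traits)
    tr <- tip_rates(tree_k)
    trc <- list()
    for (tn in names(traits)) {
      for (m in c("nd", "es")) {
        rts <- if (m == "nd") tr$nd else tr$rate_es
        names(rts) <- tr$tip
        for (meth in c("pgls", "sim")) {
          res <- trc_test(tree_k, rts, traits[[tn]], method = meth,
                          n_sim = config$n_sim,
                          seed = config$seed + 20L)
          trc[[length(trc) + 1L]] <- data.frame(
            trait = tn, rate = m, method = meth,
            statistic = res$statistic, p = res$p,
            stringsAsFactors = FALSE)
        }
      }
    }
    list(signal = sig, tip_rates = tr, trc = do.call(rbind, trc))
  })
  sigtab <- data.frame(
    trait = names(phylo$signal),
    K = vapply(phylo$signal, `[[`, numeric(1), "K"),
    p = vapply(phylo$signal, `[[`, numeric(1), "p"))
  write_csv_header(sigtab, file.path(config$out_dir, "phylo_signal.csv"),
                   header = hdr)
  write_csv_header(phylo$trc, file.path(config$out_dir, "trc_tests.csv"),
                   header = hdr)
  write_csv_header(phylo$tip_rates,
                   file.path(config$out_dir, "tip_rates.csv"), header = hdr)

  dose <- NULL
  if (!is.null(config$plate)) {
    logmsg("dose-response: 4PL calibration")
    dose <- .stage("dose-response", {
      plate <- if (is.character(config$plate))
        read_csv_header(config$plate) else config$plate
      sfit <- fit_4pl_mixed(plate)
      cfit <- calibrate_ouabain(plate)
      list(sample_fit = sfit, calib_fit = cfit,
           equivalents = ouabain_equivalents(sfit, cfit))
    })
    write_csv_header(dose$equivalents,
                     file.path(config$out_dir, "ouabain_equivalents.csv"),
                     header = hdr)
  }

  manifest <- list(seed = config$seed, mz_tol = config$mz_tol,
                   rt_tol = config$rt_tol, n_perm = config$n_perm,
                   n_sim = config$n_sim, n_boot = config$n_boot,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("chemophylo")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logmsg("done")
  invisible(list(annotations = ann_res, profiles = profiles, fit = fit,
                 bray = chem$bray, chemogram = chem$boot, pcoa = chem$pcoa,
                 mantel = chem$mantel, signal = phylo$signal,
                 tip_rates = phylo$tip_rates, trc = phylo$trc,
                 dose_response = dose))
}
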