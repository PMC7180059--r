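# Synthetic LC-MS feature tables with known compound ground truth.

#' MS simulation parameters
#'
#' Controls for [simulate_feature_table()].  The retention-time domain
#' (0-15 min) matches a typical cardenolide gradient and the m/z domain
#' (50-1200) the instrument scan range the pipeline assumes.
#'
#' @param mz_jitter_sd SD of m/z measurement error (Da).
#' @param rt_jitter_sd SD of retention-time error (min).
#' @param n_noise Number of uniform noise peaks per sample.
#' @param noise_intensity Mean intensity of noise peaks.
#' @param genin_fraction,genin_h2o_fraction,loss_fraction,diag_fraction
#'   Fragment intensities as fractions of the compound abundance.
#' @param n_diag Number of diagnostic fragments emitted per glucosinolate.
#' @param min_abundance Abundance below which a compound emits no features.
#' @param mz_domain,rt_domain Ranges for noise peaks.
#' @return List of class `ms_params`.
#' @export
ms_params <- function(mz_jitter_sd = 0, rt_jitter_sd = 0, n_noise = 0,
                      noise_intensity = 500,
                      genin_fraction = 0.3, genin_h2o_fraction = 0.15,
                      loss_fraction = 0.25, diag_fraction = 0.1, n_diag = 3,
                      min_abundance = 0,
                      mz_domain = c(50, 1200), rt_domain = c(0, 15)) {
  structure(as.list(environment()), class = "ms_params")
}

#' Simulate a ground-truth compound set
#'
#' Draws a set of cardenolides (genin + 0-2 sugars, optional acetyl on the
#' inner sugar) and glucosinolates from a compound library, assigns each a
#' distinct retention time, and optionally duplicates cardenolide
#' compositions at other retention times to create isomers.
#'
#' @param library A [default_compound_library()]-style `compound_library`.
#' @param n_cardenolides,n_glucosinolates Compound counts.
#' @param p_acetyl Probability a glycoside is acetylated.
#' @param n_isomers Number of cardenolides duplicated as RT-separated
#'   isomers.
#' @param rt_range Retention-time window over which compounds are spread.
#' @param seed Integer seed.
#' @return Data frame with one row per compound: `compound_id`, `class`,
#'   `genin`, `sugar_inner`, `sugar_outer`, `acetyl`, `neutral_mass`, `rt`,
#'   `isomer_index`, `na_ratio`.
#' @export
simulate_compound_set <- function(library, n_cardenolides = 15,
                                  n_glucosinolates = 6, p_acetyl = 0.25,
                                  n_isomers = 2, rt_range = c(1, 14),
                                  seed = 1) {
  stopifnot(inherits(library, "compound_library"))
  if (n_glucosinolates > nrow(library$glucosinolates)) {
    stop("at most ", nrow(library$glucosinolates),
         " glucosinolates available in the library", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    seen <- character(0)
    tries <- 0
    while (length(rows) < n_cardenolides && tries < 1000) {
      tries <- tries + 1
      genin <- library$genins[sample.int(nrow(library$genins), 1), ]
      n_sug <- sample(0:2, 1, prob = c(0.25, 0.4, 0.35))
      sugars <- if (n_sug > 0)
        library$sugars$name[sample.int(nrow(library$sugars), n_sug,
                                       replace = TRUE)] else character(0)
      acetyl <- n_sug > 0 && runif(1) < p_acetyl
      key <- paste(genin$name, paste(sugars, collapse = "+"), acetyl)
      if (key %in% seen) next
      seen <- c(seen, key)
      mass <- genin$mass +
        sum(library$sugars$loss_mass[match(sugars, library$sugars$name)]) +
        if (acetyl) library$acetyl_mass else 0
      rows[[length(rows) + 1L]] <- data.frame(
        class = "cardenolide", genin = genin$name,
        sugar_inner = if (n_sug >= 1) sugars[1] else NA_character_,
        sugar_outer = if (n_sug == 2) sugars[2] else NA_character_,
        acetyl = acetyl, neutral_mass = mass, stringsAsFactors = FALSE)
    }
    empty <- data.frame(class = character(), genin = character(),
                        sugar_inner = character(), sugar_outer = character(),
                        acetyl = logical(), neutral_mass = numeric(),
                        gsl_name = character(), stringsAsFactors = FALSE)
    card <- if (length(rows)) do.call(rbind, rows) else NULL
    # duplicate some compositions as isomers at other retention times
    if (!is.null(card)) {
      n_isomers <- min(n_isomers, nrow(card))
      if (n_isomers > 0) {
        card <- rbind(card, card[sample.int(nrow(card), n_isomers), ])
      }
      card$gsl_name <- NA_character_
    } else {
      card <- empty
    }
    gsl <- if (n_glucosinolates > 0) {
      gsl_rows <- library$glucosinolates[
        sample.int(nrow(library$glucosinolates), n_glucosinolates), ]
      data.frame(class = "glucosinolate", genin = NA_character_,
                 sugar_inner = NA_character_, sugar_outer = NA_character_,
                 acetyl = FALSE, neutral_mass = gsl_rows$mass,
                 gsl_name = gsl_rows$name, stringsAsFactors = FALSE)
    } else {
      empty
    }
    out <- rbind(card, gsl)
    if (nrow(out) == 0) stop("empty compound set requested", call. = FALSE)
    # distinct, well-separated retention times for every compound
    slots <- seq(rt_range[1], rt_range[2], length.out = nrow(out))
    out$rt <- sample(slots)
    out$na_ratio <- runif(nrow(out), 0.4, 2.5)
    # isomer index: ascending RT within (class, neutral mass)
    out$isomer_index <- 1L
    key <- paste(out$class, round(out$neutral_mass, 3))
    for (k in unique(key)) {
      i <- which(key == k)
      out$isomer_index[i[order(out$rt[i])]] <- seq_along(i)
    }
    out$compound_id <- ifelse(
      out$class == "cardenolide",
      paste0(out$genin, "_", round(out$neutral_mass, 4), "_iso",
             out$isomer_index),
      paste0(out$gsl_name, "_iso", out$isomer_index))
    rownames(out) <- NULL
    out[, c("compound_id", "class", "genin", "gsl_name", "sugar_inner",
            "sugar_outer", "acetyl", "neutral_mass", "rt", "isomer_index",
            "na_ratio")]
  })
}

#' Simulate an LC-MS feature table from species profiles
#'
#' For every species-compound with abundance above threshold, emits the ion
#' signals the annotation rules expect: for cardenolides a parental
#' \[M+H\]+/\[M+Na\]+ adduct pair, genin fragments (protonated genin and its
#' one-water loss), and for di-glycosides the outer-sugar neutral-loss
#' fragment; for glucosinolates the \[M-H\]- parent and co-eluting
#' diagnostic fragments.  All ions of a compound share its retention time.
#' Uniform noise peaks are added over the m/z x RT domain.
#'
#' @param library A `compound_library`; every profiled genin must be in it.
#' @param species_profiles Species x compound abundance matrix (intensity
#'   scale, >= 0); column names must match `compound_set$compound_id`.
#' @param compound_set Ground-truth compounds from
#'   [simulate_compound_set()].
#' @param params An [ms_params()] list.
#' @param seed Integer seed.
#' @return List with `features` (data frame: `feature_id`, `mz`, `rt`,
#'   `intensity`, `sample_id`, `mode`, plus ground-truth columns
#'   `true_compound` and `ion`) and `compounds` (the compound set).
#' @export
simulate_feature_table <- function(library, species_profiles, compound_set,
                                   params = ms_params(), seed = 1) {
  stopifnot(inherits(library, "compound_library"))
  cs <- compound_set
  missing_genin <- setdiff(na.omit(unique(cs$genin)), library$genins$name)
  if (length(missing_genin)) {
    stop("compound genin(s) absent from library: ",
         paste(missing_genin, collapse = ", "), call. = FALSE)
  }
  if (!all(colnames(species_profiles) %in% cs$compound_id)) {
    stop("profile columns must match compound_set$compound_id", call. = FALSE)
  }
  am <- adduct_masses()
  water <- .water_mass()
  sugar_mass <- function(s) {
    ifelse(is.na(s), 0, library$sugars$loss_mass[match(s, library$sugars$name)])
  }
  with_seed(seed, {
    rows <- list()
    emit <- function(sample, mz, rt, intensity, mode, compound, ion) {
      rows[[length(rows) + 1L]] <<- data.frame(
        mz = mz, rt = rt, intensity = intensity, sample_id = sample,
        mode = mode, true_compound = compound, ion = ion,
        stringsAsFactors = FALSE)
    }
    for (s in rownames(species_profiles)) {
      for (cid in colnames(species_profiles)) {
        ab <- species_profiles[s, cid]
        if (ab <= params$min_abundance) next
        cmp <- cs[cs$compound_id == cid, ]
        if (cmp$class == "cardenolide") {
          genin_m <- library$genins$mass[match(cmp$genin, library$genins$name)]
          emit(s, cmp$neutral_mass + am$proton, cmp$rt, ab, "positive", cid, "M+H")
          emit(s, cmp$neutral_mass + am$sodium_ion, cmp$rt, ab * cmp$na_ratio,
               "positive", cid, "M+Na")
          emit(s, genin_m + am$proton, cmp$rt, ab * params$genin_fraction,
               "positive", cid, "genin+H")
          emit(s, genin_m + am$proton - water, cmp$rt,
               ab * params$genin_h2o_fraction, "positive", cid, "genin+H-H2O")
          if (!is.na(cmp$sugar_outer)) {
            emit(s, cmp$neutral_mass - sugar_mass(cmp$sugar_outer) + am$proton,
                 cmp$rt, ab * params$loss_fraction, "positive", cid,
                 "M+H-outer")
          }
        } else {
          emit(s, cmp$neutral_mass - am$proton, cmp$rt, ab, "negative", cid,
               "M-H")
          diag <- head(library$diagnostic_fragments_neg, params$n_diag)
          for (d in diag) {
            emit(s, d, cmp$rt, ab * params$diag_fraction, "negative", cid,
                 "diagnostic")
          }
        }
      }
      if (params$n_noise > 0) {
        for (k in seq_len(params$n_noise)) {
          emit(s, runif(1, params$mz_domain[1], params$mz_domain[2]),
               runif(1, params$rt_domain[1], params$rt_domain[2]),
               params$noise_intensity * exp(rnorm(1, sd = 0.5)),
               sample(c("positive", "negative"), 1), NA_character_, "noise")
        }
      }
    }
    feats <- do.call(rbind, rows)
    if (is.null(feats)) {
      feats <- data.frame(mz = numeric(), rt = numeric(),
                          intensity = numeric(), sample_id = character(),
                          mode = character(), true_compound = character(),
                          ion = character(), stringsAsFactors = FALSE)
    } else {
      if (params$mz_jitter_sd > 0) {
        feats$mz <- feats$mz + rnorm(nrow(feats), sd = params$mz_jitter_sd)
      }
      if (params$rt_jitter_sd > 0) {
        feats$rt <- feats$rt + rnorm(nrow(feats), sd = params$rt_jitter_sd)
      }
      # merge coincident ions within a sample (e.g. [M+H]+ of a free genin
      # and its own genin fragment are one physical peak)
      key <- paste(feats$sample_id, feats$mode, round(feats$mz, 5),
                   round(feats$rt, 4))
      if (anyDuplicated(key)) {
        first <- !duplicated(key)
        inten <- tapply(feats$intensity, key, sum)
        feats <- feats[first, ]
        feats$intensity <- as.numeric(inten[paste(
          feats$sample_id, feats$mode, round(feats$mz, 5),
          round(feats$rt, 4))])
      }
    }
    feats$feature_id <- seq_len(nrow(feats))
    feats <- feats[, c("feature_id", "mz", "rt", "intensity", "sample_id",
                       "mode", "true_compound", "ion")]
    list(features = feats, compounds = cs)
  })
}
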