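# Rule-based annotation of cardenolides and glucosinolates from LC-MS
# feature tables: adduct pairing, genin-guided fragment matching, glycoside
# chain inference, isomer indexing, and adduct-based quantification.

#' Annotation parameters
#'
#' @param mz_tol m/z matching tolerance (Da).  0.005 is appropriate for
#'   QTOF-accuracy data.
#' @param rt_tol Co-elution window (min).
#' @param require_pair Require a full \[M+H\]+/\[M+Na\]+ adduct pair to
#'   establish a cardenolide parent mass.
#' @param min_diag Minimum number of co-eluting diagnostic fragments needed
#'   to flag an unknown glucosinolate candidate.
#' @return List of class `annotation_params`.
#' @export
annotation_params <- function(mz_tol = 0.005, rt_tol = 0.05,
                              require_pair = TRUE, min_diag = 2) {
  stopifnot(mz_tol > 0, rt_tol > 0, min_diag >= 1)
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol,
                 require_pair = require_pair, min_diag = min_diag),
            class = "annotation_params")
}

annotation_failure <- function(msg) {
  stop(structure(class = c("annotation_failure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Merge features observed in several samples into consensus features by
# (mode, m/z, RT) proximity.  Returns one row per consensus feature with
# intensity summed over samples and the contributing raw feature ids.
aggregate_features <- function(features, mz_tol = 0.005, rt_tol = 0.05) {
  if (nrow(features) == 0) {
    return(data.frame(agg_id = integer(), mz = numeric(), rt = numeric(),
                      intensity = numeric(), mode = character(),
                      members = I(list())))
  }
  out <- list()
  for (mode in unique(features$mode)) {
    f <- features[features$mode == mode, ]
    f <- f[order(f$mz, f$rt), ]
    grp <- cumsum(c(1, diff(f$mz) > mz_tol))
    for (g in unique(grp)) {
      fg <- f[grp == g, ]
      fg <- fg[order(fg$rt), ]
      rtg <- cumsum(c(1, diff(fg$rt) > rt_tol))
      for (h in unique(rtg)) {
        fh <- fg[rtg == h, ]
        out[[length(out) + 1L]] <- data.frame(
          mz = sum(fh$mz * fh$intensity) / sum(fh$intensity),
          rt = sum(fh$rt * fh$intensity) / sum(fh$intensity),
          intensity = sum(fh$intensity), mode = mode,
          members = I(list(fh$feature_id)), stringsAsFactors = FALSE)
      }
    }
  }
  agg <- do.call(rbind, out)
  agg <- agg[order(agg$mz, agg$rt), ]
  agg$agg_id <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg[, c("agg_id", "mz", "rt", "intensity", "mode", "members")]
}

# Split features into co-elution groups by RT gaps larger than rt_tol
rt_group_ids <- function(rt, rt_tol) {
  o <- order(rt)
  grp <- integer(length(rt))
  grp[o] <- cumsum(c(1, diff(rt[o]) > rt_tol))
  grp
}

#' Find \[M+H\]+ / \[M+Na\]+ adduct pairs
#'
#' Pairs co-eluting positive-mode features whose m/z spacing matches the
#' Na-H ion mass difference (21.9819 Da).  Each feature joins at most one
#' pair; conflicts are resolved greedily by descending combined intensity,
#' ties by lower feature id.
#'
#' @param features Data frame with `feature_id`, `mz`, `rt`, `intensity`,
#'   and (optionally) `mode`; all rows must be positive mode.
#' @param mz_tol,rt_tol Matching tolerances (Da, min).
#' @return Data frame with one row per pair: `h_feature`, `na_feature`,
#'   `neutral_mass`, `rt`, `intensity` (pair total).
#' @export
find_adduct_pairs <- function(features, mz_tol = 0.005, rt_tol = 0.05) {
  if ("mode" %in% names(features) && any(features$mode != "positive")) {
    stop("adduct pairing requires positive-mode features only", call. = FALSE)
  }
  am <- adduct_masses()
  n <- nrow(features)
  cand <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dmz <- features$mz[j] - features$mz[i]
        lo <- if (dmz > 0) i else j
        hi <- if (dmz > 0) j else i
        if (abs(abs(dmz) - am$na_h_spacing) <= mz_tol &&
            abs(features$rt[i] - features$rt[j]) <= rt_tol) {
          cand[[length(cand) + 1L]] <- data.frame(
            h = features$feature_id[lo], na = features$feature_id[hi],
            inten = features$intensity[lo] + features$intensity[hi],
            mz_h = features$mz[lo],
            rt = (features$rt[lo] + features$rt[hi]) / 2)
        }
      }
    }
  }
  empty <- data.frame(h_feature = integer(), na_feature = integer(),
                      neutral_mass = numeric(), rt = numeric(),
                      intensity = numeric())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$inten, pmin(cand$h, cand$na)), ]
  used <- integer(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!(cand$h[k] %in% used) && !(cand$na[k] %in% used)) {
      keep[k] <- TRUE
      used <- c(used, cand$h[k], cand$na[k])
    }
  }
  cand <- cand[keep, ]
  data.frame(h_feature = cand$h, na_feature = cand$na,
             neutral_mass = cand$mz_h - am$proton, rt = cand$rt,
             intensity = cand$inten)
}

#' Detect genin fragments in a co-eluting feature group
#'
#' A genin is a candidate for a chromatographic peak when the group contains
#' a feature matching its protonated ion \[genin+H\]+ or a water-loss ion
#' \[genin+H-kH2O\]+ (k = 1, 2), the fragmentation signature of the
#' steroidal core.
#'
#' @param feature_group Data frame of co-eluting positive-mode features.
#' @param library A `compound_library`.
#' @param mz_tol Matching tolerance (Da).
#' @return Data frame `genin`, `genin_mass`, `n_matched`, sorted by
#'   descending match count then descending genin mass.
#' @export
detect_genin_fragments <- function(feature_group, library, mz_tol = 0.005) {
  am <- adduct_masses()
  water <- .water_mass()
  res <- lapply(seq_len(nrow(library$genins)), function(i) {
    g <- library$genins[i, ]
    targets <- g$mass + am$proton - (0:2) * water
    nm <- sum(vapply(targets, function(t)
      any(abs(feature_group$mz - t) <= mz_tol), logical(1)))
    data.frame(genin = g$name, genin_mass = g$mass, n_matched = nm)
  })
  res <- do.call(rbind, res)
  res <- res[res$n_matched > 0, , drop = FALSE]
  res <- res[order(-res$n_matched, -res$genin_mass), ]
  rownames(res) <- NULL
  res
}

# All sugar/acetyl residue combinations up to 2 sugars, as a data frame
.residue_combos <- function(library) {
  sug <- library$sugars
  combos <- list(data.frame(s1 = NA_character_, s2 = NA_character_,
                            acetyl = FALSE, dm = 0))
  for (i in seq_len(nrow(sug))) {
    combos[[length(combos) + 1L]] <- data.frame(
      s1 = sug$name[i], s2 = NA_character_, acetyl = FALSE,
      dm = sug$loss_mass[i])
    combos[[length(combos) + 1L]] <- data.frame(
      s1 = sug$name[i], s2 = NA_character_, acetyl = TRUE,
      dm = sug$loss_mass[i] + library$acetyl_mass)
    for (j in seq_len(nrow(sug))) {
      combos[[length(combos) + 1L]] <- data.frame(
        s1 = sug$name[i], s2 = sug$name[j], acetyl = FALSE,
        dm = sug$loss_mass[i] + sug$loss_mass[j])
      combos[[length(combos) + 1L]] <- data.frame(
        s1 = sug$name[i], s2 = sug$name[j], acetyl = TRUE,
        dm = sug$loss_mass[i] + sug$loss_mass[j] + library$acetyl_mass)
    }
  }
  do.call(rbind, combos)
}

#' Infer the glycoside chain of a cardenolide
#'
#' Finds the sugar chain (0-2 residues, inner to outer) and acetylation
#' state whose summed neutral-loss masses explain the gap between the
#' parent neutral mass and the genin.  For di-glycosides the residue order
#' is fixed by an observed outer-sugar loss fragment
#' (\[M+H - outer\]+); without such a fragment the chain is reported with
#' `order_resolved = FALSE` under a deterministic priority (fewest sugars,
#' non-acetylated, alphabetical).
#'
#' @param neutral_mass Parent neutral mass (Da).
#' @param genin Genin name (must be in the library).
#' @param feature_group Co-eluting features (used for loss fragments).
#' @param library A `compound_library`.
#' @param mz_tol Tolerance (Da).
#' @return List with `sugars` (character, inner to outer), `acetyl`,
#'   `order_resolved`.  Throws an `annotation_failure` condition when no
#'   residue combination matches.
#' @export
infer_glycoside_chain <- function(neutral_mass, genin, feature_group, library,
                                  mz_tol = 0.005) {
  gm <- library$genins$mass[match(genin, library$genins$name)]
  if (is.na(gm)) stop("unknown genin: ", genin, call. = FALSE)
  delta <- neutral_mass - gm
  if (delta < -mz_tol) {
    annotation_failure(sprintf(
      "parent mass %.4f below genin %s (%.4f)", neutral_mass, genin, gm))
  }
  am <- adduct_masses()
  combos <- .residue_combos(library)
  hit <- combos[abs(combos$dm - delta) <= mz_tol, , drop = FALSE]
  if (nrow(hit) == 0) {
    annotation_failure(sprintf(
      "no residue combination matches delta %.4f for genin %s", delta, genin))
  }
  # score di-glycoside candidates by observed outer-loss fragments
  hit$order_resolved <- TRUE
  hit$frag_support <- 0
  two <- which(!is.na(hit$s2))
  resolved <- list()
  for (k in two) {
    pair <- c(hit$s1[k], hit$s2[k])
    losses <- library$sugars$loss_mass[match(pair, library$sugars$name)]
    ord_ok <- logical(2)
    for (ord in 1:2) {
      outer <- if (ord == 1) losses[2] else losses[1]
      frag_mz <- neutral_mass - outer + am$proton
      ord_ok[ord] <- any(abs(feature_group$mz - frag_mz) <= mz_tol)
    }
    if (ord_ok[1]) {
      resolved[[length(resolved) + 1L]] <- data.frame(
        s1 = pair[1], s2 = pair[2], acetyl = hit$acetyl[k], dm = hit$dm[k],
        order_resolved = TRUE, frag_support = 1)
    }
    if (ord_ok[2] && !(pair[1] == pair[2] && ord_ok[1])) {
      resolved[[length(resolved) + 1L]] <- data.frame(
        s1 = pair[2], s2 = pair[1], acetyl = hit$acetyl[k], dm = hit$dm[k],
        order_resolved = TRUE, frag_support = 1)
    }
    if (!any(ord_ok)) {
      hit$order_resolved[k] <- FALSE
    }
  }
  if (length(resolved)) {
    cand <- do.call(rbind, resolved)
  } else {
    cand <- hit
  }
  n_sug <- (!is.na(cand$s1)) + (!is.na(cand$s2))
  ord <- order(-cand$frag_support, n_sug, cand$acetyl,
               ifelse(is.na(cand$s1), "", cand$s1),
               ifelse(is.na(cand$s2), "", cand$s2))
  best <- cand[ord[1], ]
  sugars <- c(best$s1, best$s2)
  sugars <- sugars[!is.na(sugars)]
  list(sugars = sugars, acetyl = best$acetyl,
       order_resolved = isTRUE(best$order_resolved) || length(sugars) < 2)
}

#' Annotate cardenolides in a positive-mode feature table
#'
#' Full rule-based procedure: features are merged across samples and
#' grouped by co-elution; parental masses come from \[M+H\]+/\[M+Na\]+
#' adduct pairs; genins are detected from characteristic fragments; the
#' glycoside chain is inferred from residue arithmetic and neutral-loss
#' fragments.  Compounds sharing a neutral mass but separated in retention
#' time are indexed as isomers in ascending RT order.
#'
#' @param features Feature table (positive mode rows are used; negative
#'   mode rows cause an error if `strict_mode = TRUE`).
#' @param library A `compound_library`.
#' @param params An [annotation_params()] list.
#' @return Data frame of class `annotated_compounds`, ordered by (genin,
#'   neutral mass, RT), with attribute `adduct_members`: per-compound raw
#'   feature ids of the H and Na adducts.
#' @export
annotate_cardenolides <- function(features, library,
                                  params = annotation_params()) {
  features <- features[features$mode == "positive", , drop = FALSE]
  empty <- data.frame(compound_id = character(), class = character(),
                      genin = character(), sugar_inner = character(),
                      sugar_outer = character(), acetyl = logical(),
                      order_resolved = logical(), neutral_mass = numeric(),
                      rt = numeric(), isomer_index = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(features) == 0) {
    return(structure(empty, class = c("annotated_compounds", "data.frame"),
                     adduct_members = list(), skipped = character()))
  }
  agg <- aggregate_features(features, params$mz_tol, params$rt_tol)
  grp <- rt_group_ids(agg$rt, params$rt_tol)
  ann <- list()
  members <- list()
  skipped <- character(0)
  for (g in unique(grp)) {
    fg <- agg[grp == g, ]
    fg$feature_id <- fg$agg_id
    pairs <- find_adduct_pairs(fg, params$mz_tol, params$rt_tol)
    if (nrow(pairs) == 0) next
    genins <- detect_genin_fragments(fg, library, params$mz_tol)
    if (nrow(genins) == 0) next
    for (p in seq_len(nrow(pairs))) {
      chain <- NULL
      used_genin <- NULL
      for (gi in seq_len(nrow(genins))) {
        chain <- tryCatch(
          infer_glycoside_chain(pairs$neutral_mass[p], genins$genin[gi], fg,
                                library, params$mz_tol),
          annotation_failure = function(e) NULL)
        if (!is.null(chain)) { used_genin <- genins$genin[gi]; break }
      }
      if (is.null(chain)) {
        skipped <- c(skipped, sprintf("parent %.4f @ rt %.2f: no genin/chain",
                                      pairs$neutral_mass[p], pairs$rt[p]))
        next
      }
      hrow <- fg[fg$agg_id == pairs$h_feature[p], ]
      narow <- fg[fg$agg_id == pairs$na_feature[p], ]
      ann[[length(ann) + 1L]] <- data.frame(
        class = "cardenolide", genin = used_genin,
        sugar_inner = if (length(chain$sugars) >= 1) chain$sugars[1] else NA_character_,
        sugar_outer = if (length(chain$sugars) == 2) chain$sugars[2] else NA_character_,
        acetyl = chain$acetyl, order_resolved = chain$order_resolved,
        neutral_mass = pairs$neutral_mass[p], rt = pairs$rt[p],
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <-
        list(h = hrow$members[[1]], na = narow$members[[1]],
             h_intensity = hrow$intensity, na_intensity = narow$intensity)
    }
  }
  if (!length(ann)) {
    return(structure(empty, class = c("annotated_compounds", "data.frame"),
                     adduct_members = list(), skipped = skipped))
  }
  out <- do.call(rbind, ann)
  out$isomer_index <- .isomer_index(out$neutral_mass, out$rt, params$mz_tol)
  out$compound_id <- paste0(out$genin, "_", round(out$neutral_mass, 4),
                            "_iso", out$isomer_index)
  o <- order(out$genin, out$neutral_mass, out$rt)
  out <- out[o, c("compound_id", "class", "genin", "sugar_inner",
                  "sugar_outer", "acetyl", "order_resolved", "neutral_mass",
                  "rt", "isomer_index")]
  rownames(out) <- NULL
  members <- members[o]
  names(members) <- out$compound_id
  structure(out, class = c("annotated_compounds", "data.frame"),
            adduct_members = members, skipped = skipped)
}

# isomer index: ascending RT within clusters of near-identical neutral mass
.isomer_index <- function(neutral_mass, rt, mz_tol) {
  idx <- integer(length(neutral_mass))
  o <- order(neutral_mass)
  cluster <- cumsum(c(1, diff(neutral_mass[o]) > mz_tol))
  for (cl in unique(cluster)) {
    i <- o[cluster == cl]
    idx[i[order(rt[i])]] <- seq_along(i)
  }
  idx
}

#' Screen a negative-mode feature table for glucosinolates
#'
#' Library glucosinolates are matched by the exact \[M-H\]- mass; features
#' with no library match that co-elute with at least `params$min_diag`
#' characteristic glucosinolate fragments are flagged as unknown
#' candidates.
#'
#' @param features Feature table (negative mode).
#' @param library A `compound_library`.
#' @param params An [annotation_params()] list.
#' @return Data frame of class `annotated_compounds` with attribute
#'   `adduct_members` (raw feature ids of the \[M-H\]- ion per compound).
#' @export
screen_glucosinolates <- function(features, library,
                                  params = annotation_params()) {
  features <- features[features$mode == "negative", , drop = FALSE]
  empty <- data.frame(compound_id = character(), class = character(),
                      name = character(), gsl_class = character(),
                      known = logical(), neutral_mass = numeric(),
                      rt = numeric(), isomer_index = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(features) == 0) {
    return(structure(empty, class = c("annotated_compounds", "data.frame"),
                     adduct_members = list()))
  }
  agg <- aggregate_features(features, params$mz_tol, params$rt_tol)
  am <- adduct_masses()
  targets <- library$glucosinolates
  target_mz <- targets$mass - am$proton
  is_diag <- vapply(agg$mz, function(m)
    any(abs(m - library$diagnostic_fragments_neg) <= params$mz_tol),
    logical(1))
  ann <- list(); members <- list()
  matched <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    hit <- which(abs(agg$mz[i] - target_mz) <= params$mz_tol)
    if (length(hit)) {
      hit <- hit[which.min(abs(agg$mz[i] - target_mz[hit]))]
      matched[i] <- TRUE
      ann[[length(ann) + 1L]] <- data.frame(
        class = "glucosinolate", name = targets$name[hit],
        gsl_class = targets$class[hit], known = TRUE,
        neutral_mass = agg$mz[i] + am$proton, rt = agg$rt[i],
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <-
        list(mh = agg$members[[i]], intensity = agg$intensity[i])
    }
  }
  # unknown candidates: unmatched, non-diagnostic parents with co-eluting
  # diagnostic fragments
  for (i in which(!matched & !is_diag)) {
    n_co <- sum(is_diag & abs(agg$rt - agg$rt[i]) <= params$rt_tol)
    if (n_co >= params$min_diag) {
      ann[[length(ann) + 1L]] <- data.frame(
        class = "glucosinolate", name = "unknown", gsl_class = "unknown",
        known = FALSE, neutral_mass = agg$mz[i] + am$proton, rt = agg$rt[i],
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <-
        list(mh = agg$members[[i]], intensity = agg$intensity[i])
    }
  }
  if (!length(ann)) {
    return(structure(empty, class = c("annotated_compounds", "data.frame"),
                     adduct_members = list()))
  }
  out <- do.call(rbind, ann)
  out$isomer_index <- .isomer_index(out$neutral_mass, out$rt, params$mz_tol)
  out$compound_id <- paste0(out$name, "_iso", out$isomer_index)
  o <- order(out$name, out$neutral_mass, out$rt)
  out <- out[o, c("compound_id", "class", "name", "gsl_class", "known",
                  "neutral_mass", "rt", "isomer_index")]
  rownames(out) <- NULL
  members <- members[o]
  names(members) <- out$compound_id
  structure(out, class = c("annotated_compounds", "data.frame"),
            adduct_members = members)
}

#' Quantify annotated compounds per sample
#'
#' Cardenolides are quantified from the \[M+H\]+ or \[M+Na\]+ adduct,
#' whichever has the larger total intensity across all samples for that
#' compound; glucosinolates always from the \[M-H\]- adduct.  Absences are
#' reported as 0.
#'
#' @param features The raw feature table the annotations were derived from.
#' @param annotations One `annotated_compounds` object or a list of them.
#' @return Numeric matrix, samples in rows, compounds in columns.
#' @export
quantify_compounds <- function(features, annotations) {
  if (inherits(annotations, "annotated_compounds")) {
    annotations <- list(annotations)
  }
  samples <- sort(unique(features$sample_id))
  cols <- list()
  for (ann in annotations) {
    members <- attr(ann, "adduct_members")
    for (cid in names(members)) {
      m <- members[[cid]]
      ids <- if (!is.null(m$mh)) m$mh else {
        use_na <- !is.null(m$na_intensity) && m$na_intensity > m$h_intensity
        if (use_na) m$na else m$h
      }
      if (!all(ids %in% features$feature_id)) {
        stop("annotation references feature ids absent from the table",
             call. = FALSE)
      }
      f <- features[features$feature_id %in% ids, ]
      v <- setNames(numeric(length(samples)), samples)
      agg <- tapply(f$intensity, f$sample_id, sum)
      v[names(agg)] <- agg
      cols[[cid]] <- v
    }
  }
  mat <- do.call(cbind, cols)
  if (is.null(mat)) mat <- matrix(numeric(0), nrow = length(samples), ncol = 0,
                                  dimnames = list(samples, NULL))
  mat
}
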