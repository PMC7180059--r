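# Chemical dissimilarity, clustering with multiscale-bootstrap support,
# ordination, and matrix correlation over species profiles.

#' Bray-Curtis dissimilarity from species profiles
#'
#' Converts each species row to proportions (compounds summing to 1) and
#' computes pairwise Bray-Curtis dissimilarities
#' \eqn{d(x, y) = \sum |x_i - y_i| / \sum (x_i + y_i)}.
#'
#' @param profile_matrix Non-negative species x compound matrix (any row
#'   already summing to 1 is left as is).
#' @return Square symmetric matrix with zero diagonal, entries in \[0, 1\],
#'   labelled by species.
#' @export
bray_curtis <- function(profile_matrix) {
  m <- as.matrix(profile_matrix)
  if (any(m < 0)) stop("profiles must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    stop("all-zero profile row(s): ",
         paste(rownames(m)[rs == 0], collapse = ", "), call. = FALSE)
  }
  p <- m / rs
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <-
          sum(abs(p[i, ] - p[j, ])) / sum(p[i, ] + p[j, ])
      }
    }
  }
  d
}

#' Ward clustering of a dissimilarity matrix
#'
#' Agglomerative Ward linkage on the dissimilarities as provided (the
#' "ward.D" convention, not squared); set `squared = TRUE` for the
#' "ward.D2" variant.  Ties are resolved by `stats::hclust`'s deterministic
#' lowest-index rule.
#'
#' @param dist Square symmetric dissimilarity matrix or `dist` object.
#' @param squared Use squared dissimilarities (ward.D2)?
#' @return An `hclust` object.
#' @export
ward_dendrogram <- function(dist, squared = FALSE) {
  d <- as.dist(dist)
  if (attr(d, "Size") < 2) stop("need at least 2 objects", call. = FALSE)
  hclust(d, method = if (squared) "ward.D2" else "ward.D")
}

# tip-label sets of every internal merge of an hclust tree
hclust_clusters <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) hc$labels[-k] else sets[[k]]
    sets[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
  }
  sets
}

#' Multiscale bootstrap support for a chemogram
#'
#' Clusters the full profile matrix (proportions, Bray-Curtis, Ward), then
#' resamples compound columns at a range of relative sizes r, recording for
#' every cluster of the full-data dendrogram its bootstrap probability
#' BP(r).  The approximately unbiased (AU) probability is obtained by
#' weighted least-squares fit of
#' \eqn{\Phi^{-1}(1 - BP(r)) = d\sqrt{r} + c/\sqrt{r}} and
#' \eqn{AU = 1 - \Phi(d - c)}.
#'
#' @param profile_matrix Species x compound matrix.
#' @param scales Relative resample sizes around 1.
#' @param n_boot Bootstrap replicates per scale (>= 100 advised).
#' @param seed Integer seed.
#' @return List of class `supported_dendrogram`: `hclust` (full-data tree),
#'   `support` (data frame: cluster id, members, `au`, `bp`, `flagged`),
#'   `scales`, `n_boot`.
#' @export
multiscale_bootstrap_support <- function(profile_matrix,
                                         scales = seq(0.5, 1.4, by = 0.1),
                                         n_boot = 1000, seed = 1) {
  stopifnot(length(scales) >= 2, n_boot >= 1)
  m <- as.matrix(profile_matrix)
  hc <- ward_dendrogram(bray_curtis(m))
  clusters <- hclust_clusters(hc)
  keys <- vapply(clusters, paste, character(1), collapse = "|")
  n_cl <- length(clusters)
  counts <- matrix(0, n_cl, length(scales))
  valid <- integer(length(scales))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      msize <- max(2L, round(scales[si] * ncol(m)))
      for (b in seq_len(n_boot)) {
        cols <- sample.int(ncol(m), msize, replace = TRUE)
        bm <- m[, cols, drop = FALSE]
        bhc <- tryCatch(ward_dendrogram(bray_curtis(bm)),
                        error = function(e) NULL)
        if (is.null(bhc)) next
        valid[si] <- valid[si] + 1L
        bkeys <- vapply(hclust_clusters(bhc), paste, character(1),
                        collapse = "|")
        counts[match(intersect(keys, bkeys), keys), si] <-
          counts[match(intersect(keys, bkeys), keys), si] + 1
      }
    }
  })
  bp <- sweep(counts, 2, pmax(valid, 1), "/")
  sup <- lapply(seq_len(n_cl), function(i) {
    au_from_bp(bp[i, ], scales, n_boot)
  })
  support <- data.frame(
    cluster = seq_len(n_cl),
    members = vapply(clusters, paste, character(1), collapse = ","),
    au = vapply(sup, `[[`, numeric(1), "au"),
    bp = bp[, which.min(abs(scales - 1))],
    flagged = vapply(sup, `[[`, logical(1), "flagged"),
    stringsAsFactors = FALSE)
  structure(list(hclust = hc, support = support, scales = scales,
                 n_boot = n_boot, bp_by_scale = bp),
            class = "supported_dendrogram")
}

#' AU probability from per-scale bootstrap probabilities
#'
#' The weighted least-squares z-transform step of the multiscale bootstrap,
#' exposed for direct use.  With BP = 0.5 at every scale, AU = 0.5; BP
#' identically 0 or 1 is clamped to that bound and flagged.
#'
#' @param bp Bootstrap probabilities per scale.
#' @param scales Relative resample sizes.
#' @param n_boot Replicates per scale (sets binomial weights).
#' @return List with `au`, `d`, `c`, `flagged`.
#' @export
au_from_bp <- function(bp, scales, n_boot) {
  if (all(bp <= 0)) return(list(au = 0, d = NA, c = NA, flagged = TRUE))
  if (all(bp >= 1)) return(list(au = 1, d = NA, c = NA, flagged = TRUE))
  eps <- 0.5 / n_boot
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- qnorm(1 - bpc)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- n_boot * dnorm(qnorm(bpc))^2 / (bpc * (1 - bpc))
  fit <- lm.wfit(X, z, w)
  d <- fit$coefficients[1]; cc <- fit$coefficients[2]
  list(au = 1 - pnorm(d - cc), d = unname(d), c = unname(cc),
       flagged = FALSE)
}

#' @export
print.supported_dendrogram <- function(x, ...) {
  cat("Chemogram with multiscale bootstrap support:",
      length(x$hclust$labels), "species,", x$n_boot,
      "replicates x", length(x$scales), "scales\n")
  cat("AU range:", paste(round(range(x$support$au), 3), collapse = " - "),
      "\n")
  invisible(x)
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers \eqn{-D^2/2}, eigendecomposes, and returns coordinates
#' scaled by the square roots of the positive eigenvalues.  Axis signs are
#' fixed by making each axis's largest-magnitude loading positive.
#' Negative eigenvalues are reported, not corrected.
#'
#' @param dist Square symmetric dissimilarity matrix.
#' @return List of class `pcoa_result`: `coordinates` (objects x axes),
#'   `eigenvalues` (all), `percent` (share of the positive-eigenvalue sum
#'   per retained axis).
#' @export
pcoa <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  for (k in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, k])), k] < 0) {
      coords[, k] <- -coords[, k]
    }
  }
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 percent = 100 * e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", nrow(x$coordinates), "objects,", ncol(x$coordinates),
      "positive axes\n")
  cat("Variance explained (%):",
      paste(round(head(x$percent, 4), 1), collapse = ", "), "...\n")
  invisible(x)
}

.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal upper triangles, with a
#' two-sided permutation p-value under simultaneous row/column permutation
#' of the second matrix (add-one rule, so p is never 0).  When the full
#' permutation group is no larger than `n_perm` the test enumerates it
#' exhaustively instead of sampling; the identity permutation then plays
#' the add-one role.
#'
#' @param d1,d2 Square symmetric matrices with matching labels (if both
#'   carry dimnames, `d2` is aligned to `d1`).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 99)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2))) {
      stop("matrix labels do not match", call. = FALSE)
    }
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  if (nrow(d1) != nrow(d2)) stop("matrix sizes differ", call. = FALSE)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (sd(v1) == 0 || sd(d2[ut]) == 0) {
    stop("constant off-diagonal entries: correlation undefined",
         call. = FALSE)
  }
  r_obs <- cor(v1, d2[ut])
  n <- nrow(d1)
  if (n <= 170 && factorial(n) <= n_perm) {
    perms <- .all_permutations(n)
    hits <- sum(vapply(perms, function(p)
      abs(cor(v1, d2[p, p][ut])) >= abs(r_obs) - 1e-12, logical(1)))
    return(list(r = r_obs, p = hits / length(perms),
                n_perm = length(perms), exhaustive = TRUE))
  }
  with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      rp <- cor(v1, d2[p, p][ut])
      if (abs(rp) >= abs(r_obs) - 1e-12) hits <- hits + 1L
    }
    list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm,
         exhaustive = FALSE)
  })
}
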