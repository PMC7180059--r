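# Synthetic phylogenies and traits.

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Simulates a Yule tree and (by default) rescales it to unit root depth.
#' Only relative branch lengths matter for the downstream statistics
#' (Blomberg's K, PGLS, node density, equal splits), so depth is a free
#' scale.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Speciation rate (events per unit time), > 0.
#' @param seed Integer seed fixing all randomness.
#' @param rescale_depth Target root-to-tip depth, or `NULL` to keep the
#'   simulated depth. Default 1.
#' @return An object of class `phylo` (rooted, binary, ultrametric), tips
#'   labelled `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = 1, rescale_depth = 1) {
  if (!is.numeric(n_tips) || n_tips < 2) {
    stop("'n_tips' must be >= 2", call. = FALSE)
  }
  if (birth_rate <= 0) stop("'birth_rate' must be > 0", call. = FALSE)
  tr <- with_seed(seed, ape::rphylo(n = as.integer(n_tips), birth = birth_rate,
                                    death = 0))
  if (!is.null(rescale_depth)) {
    depth <- max(node_depths(tr))
    tr$edge.length <- tr$edge.length * (rescale_depth / depth)
  }
  tr
}

# Run expr with a local RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Root-to-node path lengths for every node (tips first, then internals)
node_depths <- function(tree) {
  ntot <- ape::Ntip(tree) + tree$Nnode
  depth <- numeric(ntot)
  root <- ape::Ntip(tree) + 1L
  # edges in cladewise order: parent always visited before child
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + tr$edge.length[k]
  }
  depth
}

#' Simulate continuous traits on a phylogeny
#'
#' Under `model = "bm"`, tip values are multivariate normal with covariance
#' `sigma2 * V(tree)` where `V` is the Brownian (shared path length)
#' covariance matrix.  Under `model = "white"`, values are iid normal across
#' tips with variance `sigma2` (no phylogenetic signal), the generator used
#' for random-trait calibration.
#'
#' @param tree A `phylo` object.
#' @param model `"bm"` or `"white"`.
#' @param sigma2 Trait variance rate (> 0): Brownian rate for `"bm"`,
#'   marginal variance for `"white"`.
#' @param n_traits Number of independent traits to simulate.
#' @param seed Integer seed.
#' @return Numeric matrix, tips in rows (named by tip label), traits in
#'   columns.
#' @export
simulate_traits <- function(tree, model = c("bm", "white"), sigma2 = 1,
                            n_traits = 1, seed = 1) {
  model <- match.arg(model)
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("'sigma2' must be > 0", call. = FALSE)
  }
  n <- ape::Ntip(tree)
  with_seed(seed, {
    z <- matrix(rnorm(n * n_traits), n, n_traits)
    x <- if (model == "white") {
      sqrt(sigma2) * z
    } else {
      V <- brownian_cov(tree)$V
      # chol gives upper-triangular U with U'U = V
      t(chol(sigma2 * V)) %*% z
    }
    rownames(x) <- tree$tip.label
    colnames(x) <- paste0("trait", seq_len(n_traits))
    x
  })
}
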