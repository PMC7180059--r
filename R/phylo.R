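# Phylogenetic comparative statistics: Brownian covariance, Blomberg's K,
# PGLS, ancestral states, tip speciation rates, and tip-rate correlation
# tests with false-positive calibration.

#' Brownian covariance matrix of a phylogeny
#'
#' `V[i, j]` is the root-to-MRCA path length shared by tips i and j (the
#' diagonal holds root-to-tip depths); under Brownian motion at rate
#' sigma2, tip trait covariance is `sigma2 * V`.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @return List of class `brownian_cov` with `V` (tips in `tree$tip.label`
#'   order) and `tips`.
#' @export
brownian_cov <- function(tree) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree needs branch lengths",
                                      call. = FALSE)
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  mr <- ape::mrca(tree)
  V <- matrix(depth[mr], n, n)
  diag(V) <- depth[seq_len(n)]
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  structure(list(V = V, tips = tree$tip.label), class = "brownian_cov")
}

# align a named trait vector to tip order; unnamed vectors must already be
# in tip order
.align_trait <- function(tree, trait) {
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), tree$tip.label)) {
      stop("trait names do not match tip labels", call. = FALSE)
    }
    trait <- trait[tree$tip.label]
  } else if (length(trait) != ape::Ntip(tree)) {
    stop("trait length does not match number of tips", call. = FALSE)
  }
  as.numeric(trait)
}

# core K statistics given V and its inverse
.k_stats <- function(V, Vinv, x) {
  n <- length(x)
  one <- rep(1, n)
  w <- Vinv %*% one
  a_hat <- sum(w * x) / sum(w)
  r <- x - a_hat
  MSE0 <- sum(r^2) / (n - 1)
  MSE <- drop(crossprod(r, Vinv %*% r)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(w)) / (n - 1)
  list(K = (MSE0 / MSE) / expected, MSE0 = MSE0, MSE = MSE,
       expected = expected, a_hat = a_hat)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetically corrected mean to the GLS mean squared error, scaled by
#' its Brownian expectation.  K is near 1 when trait similarity matches
#' Brownian motion on the tree and near 0 for traits lacking phylogenetic
#' signal; K is identically 1 on two-tip trees.
#'
#' @param tree Rooted `phylo`.
#' @param trait Numeric vector, named by tip label or in tip order.
#' @return The K statistic (numeric scalar).
#' @export
blomberg_k <- function(tree, trait) {
  x <- .align_trait(tree, trait)
  if (sd(x) == 0) stop("trait is constant: K undefined", call. = FALSE)
  V <- brownian_cov(tree)$V
  .k_stats(V, solve(V), x)$K
}

#' Permutation test of phylogenetic signal
#'
#' Computes Blomberg's K and a p-value from shuffling trait values across
#' tips: smaller GLS mean squared error than under permutation indicates
#' signal.  `method = "bm"` instead simulates Brownian traits on the tree
#' as the reference distribution.
#'
#' @param tree Rooted `phylo`.
#' @param trait Trait vector (named or in tip order).
#' @param n_sim Number of permutations/simulations (>= 100).
#' @param seed Integer seed.
#' @param method `"permutation"` (default) or `"bm"`.
#' @return Object of class `k_result`: `K`, `MSE0`, `MSE`,
#'   `expected_ratio`, `p`, `n_sim`, `method`.
#' @export
phylo_signal_test <- function(tree, trait, n_sim = 999, seed = 1,
                              method = c("permutation", "bm")) {
  method <- match.arg(method)
  stopifnot(n_sim >= 99)
  x <- .align_trait(tree, trait)
  if (sd(x) == 0) stop("trait is constant: K undefined", call. = FALSE)
  V <- brownian_cov(tree)$V
  Vinv <- solve(V)
  obs <- .k_stats(V, Vinv, x)
  with_seed(seed, {
    n <- length(x)
    ref <- if (method == "permutation") {
      vapply(seq_len(n_sim), function(k)
        .k_stats(V, Vinv, x[sample.int(n)])$MSE, numeric(1))
    } else {
      L <- t(chol(V))
      vapply(seq_len(n_sim), function(k)
        .k_stats(V, Vinv, drop(L %*% rnorm(n)))$MSE, numeric(1))
    }
    p <- (1 + sum(ref <= obs$MSE + 1e-12)) / (1 + n_sim)
    structure(list(K = obs$K, MSE0 = obs$MSE0, MSE = obs$MSE,
                   expected_ratio = obs$expected, p = p, n_sim = n_sim,
                   method = method), class = "k_result")
  })
}

#' @export
print.k_result <- function(x, ...) {
  cat("Blomberg's K =", signif(x$K, 4), "; p =", signif(x$p, 3),
      sprintf("(%d %ss)\n", x$n_sim,
              if (x$method == "permutation") "permutation" else "simulation"))
  invisible(x)
}

#' Phylogenetic generalized least squares
#'
#' GLS regression with residual covariance proportional to the Brownian
#' covariance of the tree: \eqn{\hat\beta = (X'V^{-1}X)^{-1}X'V^{-1}y}.
#' The overall F statistic tests all non-intercept terms; for a single
#' predictor the degrees of freedom are (1, n - 2).
#'
#' @param tree Rooted `phylo`.
#' @param y Response, named by tip or in tip order.
#' @param X Predictor vector or matrix (an intercept is added).
#' @return Object of class `pgls_fit`: `coefficients`, `F`, `df`, `p`,
#'   `sigma2`, `residuals`.
#' @export
pgls_fit <- function(tree, y, X) {
  y <- .align_trait(tree, y)
  if (is.null(dim(X))) {
    nm <- names(X)
    X <- matrix(.align_trait(tree, X), ncol = 1,
                dimnames = list(NULL, "x"))
  } else {
    X <- as.matrix(X)
    if (!is.null(rownames(X))) X <- X[tree$tip.label, , drop = FALSE]
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  n <- length(y)
  Xd <- cbind(`(Intercept)` = 1, X)
  p_par <- ncol(Xd)
  V <- brownian_cov(tree)$V
  Vinv <- solve(V)
  XtVi <- crossprod(Xd, Vinv)
  M <- XtVi %*% Xd
  if (rcond(M) < 1e-12) stop("singular design matrix", call. = FALSE)
  beta <- solve(M, XtVi %*% y)
  r <- y - Xd %*% beta
  RSS <- drop(crossprod(r, Vinv %*% r))
  one <- Xd[, 1, drop = FALSE]
  b0 <- solve(crossprod(one, Vinv %*% one), crossprod(one, Vinv %*% y))
  r0 <- y - one %*% b0
  RSS0 <- drop(crossprod(r0, Vinv %*% r0))
  q <- p_par - 1
  Fstat <- ((RSS0 - RSS) / q) / (RSS / (n - p_par))
  structure(list(coefficients = setNames(drop(beta), colnames(Xd)),
                 F = Fstat, df = c(q, n - p_par),
                 p = pf(Fstat, q, n - p_par, lower.tail = FALSE),
                 sigma2 = RSS / (n - p_par), residuals = drop(r)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS (Brownian correlation)\n")
  print(round(x$coefficients, 5))
  cat(sprintf("F_%d,%d = %.4g, p = %.4g\n", x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Internal-node state estimates that maximize the Brownian likelihood;
#' equivalently the solution of branch-length-weighted squared-change
#' minimization, so each node estimate is the GLS phylogenetic mean of the
#' tree re-rooted at that node.  The root estimate equals the GLS mean used
#' by Blomberg's K.
#'
#' @param tree Rooted `phylo`.
#' @param trait Trait vector (named or in tip order).
#' @return Named numeric vector of internal-node estimates (names are the
#'   `phylo` node numbers).
#' @export
ancestral_states_bm <- function(tree, trait) {
  x <- .align_trait(tree, trait)
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  # weighted graph Laplacian over the tree; internal states solve the
  # boundary-value problem with tip values fixed
  w <- 1 / tree$edge.length
  A <- matrix(0, m, m)
  b <- numeric(m)
  for (k in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[k, 1] - n
    ch <- tree$edge[k, 2]
    A[pa, pa] <- A[pa, pa] + w[k]
    if (ch <= n) {
      b[pa] <- b[pa] + w[k] * x[ch]
    } else {
      ci <- ch - n
      A[ci, ci] <- A[ci, ci] + w[k]
      A[pa, ci] <- A[pa, ci] - w[k]
      A[ci, pa] <- A[ci, pa] - w[k]
    }
  }
  states <- solve(A, b)
  names(states) <- as.character(n + seq_len(m))
  states
}

#' Tip-specific speciation-rate statistics
#'
#' Node density (ND): the number of internal nodes along the root-to-tip
#' path (root included) divided by the path length, capturing splitting
#' over a lineage's entire history.  Equal splits (ES): the sum of edge
#' lengths along the path from the tip rootward, halving the weight at
#' each split; its inverse is a speciation-rate proxy weighted toward
#' recent branching.
#'
#' @param tree Rooted `phylo` with positive branch lengths.
#' @return Data frame with `tip`, `nd`, `es`, `rate_es` (= 1/es).
#' @export
tip_rates <- function(tree) {
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("tree needs non-negative branch lengths", call. = FALSE)
  }
  n <- ape::Ntip(tree)
  depth <- node_depths(tree)
  if (any(depth[seq_len(n)] <= 0)) {
    stop("zero-length root-to-tip path", call. = FALSE)
  }
  ntot <- n + tree$Nnode
  # internal-node count from root down to each node
  anc <- integer(ntot)
  anc[n + 1L] <- 1L
  tr <- ape::reorder.phylo(tree, "cladewise")
  parent_of <- integer(ntot)
  elen <- numeric(ntot)
  for (k in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    parent_of[ch] <- pa
    elen[ch] <- tr$edge.length[k]
    if (ch > n) anc[ch] <- anc[pa] + 1L
  }
  nd <- es <- numeric(n)
  root <- n + 1L
  for (i in seq_len(n)) {
    nd[i] <- anc[parent_of[i]] / depth[i]
    node <- i; j <- 0L; s <- 0
    while (node != root) {
      j <- j + 1L
      s <- s + elen[node] * 0.5^(j - 1)
      node <- parent_of[node]
    }
    es[i] <- s
  }
  data.frame(tip = tree$tip.label, nd = nd, es = es, rate_es = 1 / es,
             stringsAsFactors = FALSE)
}

#' Tip-rate correlation test
#'
#' Tests whether tip speciation rates covary with a trait, either by PGLS
#' of the rates on the trait or by the simulation-based method: the
#' observed Pearson correlation is compared against correlations between
#' the rates and Brownian traits simulated on the tree (two-sided, add-one
#' p).
#'
#' @param tree Rooted `phylo`.
#' @param rates Tip rates, named by tip or in tip order.
#' @param trait Trait vector.
#' @param method `"pgls"` or `"sim"`.
#' @param n_sim Simulations for `"sim"` (>= 100).
#' @param seed Integer seed.
#' @return List with `statistic` (F or Pearson r), `p`, `method`.
#' @export
trc_test <- function(tree, rates, trait, method = c("pgls", "sim"),
                     n_sim = 999, seed = 1) {
  method <- match.arg(method)
  rates <- .align_trait(tree, rates)
  trait <- .align_trait(tree, trait)
  if (sd(rates) == 0 || sd(trait) == 0) {
    stop("constant rates or trait: correlation undefined", call. = FALSE)
  }
  if (method == "pgls") {
    f <- pgls_fit(tree, rates, trait)
    return(list(statistic = f$F, p = f$p, method = "pgls", fit = f))
  }
  stopifnot(n_sim >= 99)
  r_obs <- cor(rates, trait)
  V <- brownian_cov(tree)$V
  L <- t(chol(V))
  with_seed(seed, {
    sims <- L %*% matrix(rnorm(length(rates) * n_sim), length(rates), n_sim)
    r_null <- drop(cor(rates, sims))
    p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (1 + n_sim)
    list(statistic = r_obs, p = p, method = "sim", n_sim = n_sim)
  })
}

#' False-positive calibration of the tip-rate correlation tests
#'
#' Generates random traits, runs the four tests (ND and ES rates, each by
#' PGLS and by simulation) at level `alpha` on each, and counts the traits
#' with more than one significant test -- the multiple-testing safeguard
#' used to judge whether repeated significance could arise by chance.
#'
#' @param tree Rooted `phylo`.
#' @param n_traits Number of random traits (>= 100 advised).
#' @param alpha Significance level per test.
#' @param trait_model `"white"` (iid normal) or `"bm"`.
#' @param n_sim Simulations per `"sim"` test.
#' @param seed Integer seed.
#' @return List with `count` (traits with >= 2 significant tests),
#'   `rejection_rates` (per test), `significant` (traits x tests logical
#'   matrix).
#' @export
fpr_calibration <- function(tree, n_traits = 1000, alpha = 0.05,
                            trait_model = c("white", "bm"), n_sim = 199,
                            seed = 1) {
  trait_model <- match.arg(trait_model)
  tr <- tip_rates(tree)
  rates <- list(nd = tr$nd, es = tr$rate_es)
  traits <- simulate_traits(tree, model = trait_model, sigma2 = 1,
                            n_traits = n_traits, seed = seed)
  sig <- matrix(FALSE, n_traits, 4,
                dimnames = list(NULL, c("nd_pgls", "nd_sim", "es_pgls",
                                        "es_sim")))
  if (alpha > 0) {
    V <- brownian_cov(tree)$V
    Vinv <- solve(V)
    L <- t(chol(V))
    n <- nrow(traits)
    with_seed(seed + 1L, {
      for (t in seq_len(n_traits)) {
        x <- traits[, t]
        for (m in c("nd", "es")) {
          f <- .pgls_quick(Vinv, rates[[m]], x)
          sig[t, paste0(m, "_pgls")] <- f < alpha
        }
        sims <- L %*% matrix(rnorm(n * n_sim), n, n_sim)
        for (m in c("nd", "es")) {
          r_obs <- cor(rates[[m]], x)
          r_null <- drop(cor(rates[[m]], sims))
          p <- (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (1 + n_sim)
          sig[t, paste0(m, "_sim")] <- p < alpha
        }
      }
    })
  }
  list(count = sum(rowSums(sig) >= 2), rejection_rates = colMeans(sig),
       significant = sig)
}

# F-test p-value of a single-predictor GLS with precomputed V inverse
.pgls_quick <- function(Vinv, y, x) {
  n <- length(y)
  Xd <- cbind(1, x)
  XtVi <- crossprod(Xd, Vinv)
  beta <- solve(XtVi %*% Xd, XtVi %*% y)
  r <- y - Xd %*% beta
  RSS <- drop(crossprod(r, Vinv %*% r))
  one <- Xd[, 1, drop = FALSE]
  b0 <- solve(crossprod(one, Vinv %*% one), crossprod(one, Vinv %*% y))
  r0 <- y - one %*% b0
  RSS0 <- drop(crossprod(r0, Vinv %*% r0))
  Fstat <- (RSS0 - RSS) / (RSS / (n - 2))
  pf(Fstat, 1, n - 2, lower.tail = FALSE)
}
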