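# Phylogenetic comparative statistics: Brownian covariance, Blomberg's K,
# PGLS, ancestral states, tip rates, and the tip-rate correlation tests.

test_that("brownian_cov matches ape::vcv", {
  tr <- simulate_tree(15, seed = 61)
  V <- brownian_cov(tr)$V
  ref <- ape::vcv(tr)
  expect_equal(V[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
  expect_error(brownian_cov(ape::unroot(simulate_tree(5, seed = 1))),
               "root")
})

test_that("blomberg_k is exactly 1 on two-tip trees", {
  tr <- ape::read.tree(text = "(A:1.5,B:0.7);")
  expect_equal(blomberg_k(tr, c(A = 3.2, B = -1)), 1, tolerance = 1e-10)
  expect_equal(blomberg_k(tr, c(A = 100, B = 2)), 1, tolerance = 1e-10)
  expect_error(blomberg_k(tr, c(A = 1, B = 1)), "constant")
})

test_that("blomberg_k matches picante::Kcalc", {
  tr <- simulate_tree(20, seed = 62)
  x <- simulate_traits(tr, model = "bm", seed = 3)[, 1]
  expect_equal(blomberg_k(tr, x),
               drop(as.matrix(picante::Kcalc(x[tr$tip.label], tr))),
               tolerance = 1e-8, ignore_attr = TRUE)
  w <- simulate_traits(tr, model = "white", seed = 4)[, 1]
  expect_equal(blomberg_k(tr, w),
               drop(as.matrix(picante::Kcalc(w[tr$tip.label], tr))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("blomberg_k is invariant to affine trait transforms", {
  tr <- simulate_tree(12, seed = 63)
  x <- simulate_traits(tr, model = "bm", seed = 5)[, 1]
  expect_equal(blomberg_k(tr, 10 + 3 * x), blomberg_k(tr, x),
               tolerance = 1e-10)
  expect_equal(blomberg_k(tr, -x), blomberg_k(tr, x), tolerance = 1e-10)
})

test_that("phylo_signal_test bounds, determinism, and both methods", {
  tr <- simulate_tree(14, seed = 64)
  x <- simulate_traits(tr, model = "bm", seed = 6)[, 1]
  res <- phylo_signal_test(tr, x, n_sim = 199, seed = 1)
  expect_s3_class(res, "k_result")
  expect_gte(res$p, 1 / 200)
  expect_lte(res$p, 1)
  expect_equal(res$K, blomberg_k(tr, x), tolerance = 1e-12)
  expect_identical(res$p,
                   phylo_signal_test(tr, x, n_sim = 199, seed = 1)$p)
  resb <- phylo_signal_test(tr, x, n_sim = 199, seed = 1, method = "bm")
  expect_identical(resb$method, "bm")
  expect_gte(resb$p, 1 / 200)
  # strong BM signal on a bigger tree is detected by permutation
  tr2 <- simulate_tree(40, seed = 65)
  x2 <- simulate_traits(tr2, model = "bm", seed = 7)[, 1]
  expect_lt(phylo_signal_test(tr2, x2, n_sim = 999, seed = 2)$p, 0.05)
})

test_that("pgls_fit equals OLS on a star phylogeny", {
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  # resolve the basal polytomy with zero-length edges: V stays diagonal
  star <- ape::multi2di(star)
  star$edge.length[is.na(star$edge.length)] <- 0
  set.seed(66)
  x <- rnorm(10)
  y <- 2 + 3 * x + rnorm(10, sd = 0.3)
  names(x) <- names(y) <- star$tip.label
  fit <- pgls_fit(star, y, x)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  expect_equal(fit$F, unname(summary(ols)$fstatistic[1]), tolerance = 1e-8)
  expect_equal(fit$df, unname(summary(ols)$fstatistic[2:3]))
})

test_that("pgls_fit matches nlme::gls with Brownian correlation", {
  tr <- simulate_tree(18, seed = 67)
  x <- simulate_traits(tr, model = "bm", seed = 8)[, 1]
  y <- 1 + 0.5 * x + simulate_traits(tr, model = "bm", seed = 9)[, 1]
  fit <- pgls_fit(tr, y, x)
  d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                  sp = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(phy = tr, form = ~sp))
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  # exact recovery of a noiseless linear relationship
  fit2 <- pgls_fit(tr, 4 - 2 * x, x)
  expect_equal(unname(fit2$coefficients), c(4, -2), tolerance = 1e-8)
  expect_error(pgls_fit(tr, y, cbind(x, 2 * x)), "singular")
})

test_that("ancestral_states_bm solves the boundary problem", {
  # star tree: single internal state is the plain mean (equal branches)
  star <- ape::stree(6, type = "star")
  star$edge.length <- rep(2, nrow(star$edge))
  x <- setNames(c(1, 2, 3, 4, 5, 9), star$tip.label)
  expect_equal(unname(ancestral_states_bm(star, x)), mean(x),
               tolerance = 1e-10)
  # 3-tip oracle, solved by hand: ((A:1,B:1):1,C:2);
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  xa <- c(A = 0, B = 2, C = 6)
  # node 5 (A,B ancestor): minimizes (s-0)^2/1+(s-2)^2/1+(s-r)^2/1
  # root r: (r-s)^2/1 + (r-6)^2/2; solving: s = (2 + r)/3? jointly:
  # d/ds: 2s-2+ (s-r) = 0 -> 3s - r = 2 ; d/dr: (r-s) + (r-6)/2 = 0
  # -> 3r - 2s = 6 ; => r = 22/7, s = 8/7... recompute: from 3s - r = 2,
  # r = 3s - 2; 3(3s-2) - 2s = 6 -> 7s = 12 -> s = 12/7, r = 22/7
  st <- ancestral_states_bm(tr, xa)
  expect_equal(unname(st), c(22 / 7, 12 / 7), tolerance = 1e-10)
  # constant trait: every ancestor takes the same value
  expect_equal(unname(ancestral_states_bm(tr, c(A = 5, B = 5, C = 5))),
               c(5, 5), tolerance = 1e-12)
})

test_that("ancestral_states_bm matches phytools::fastAnc", {
  tr <- simulate_tree(16, seed = 68)
  x <- simulate_traits(tr, model = "bm", seed = 10)[, 1]
  mine <- ancestral_states_bm(tr, x)
  ref <- phytools::fastAnc(tr, x[tr$tip.label])
  expect_equal(unname(mine[names(ref)]), unname(as.numeric(ref)),
               tolerance = 1e-6)
})

test_that("tip_rates reproduces hand-computed ND and ES", {
  # balanced: ((A:1,B:1):1,(C:1,D:1):1); depth 2
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  res <- tip_rates(tr)
  # each tip: parent cherry node is the 2nd node on the path (root + 1)
  expect_equal(res$nd, rep(2 / 2, 4))
  # ES: pendant edge weight 1, parent edge weight 1/2
  expect_equal(res$es, rep(1 * 1 + 1 * 0.5, 4))
  expect_equal(res$rate_es, rep(1 / 1.5, 4))
  # ladder: (((A:1,B:1):1,C:2):1,D:3); cherry tips pass more nodes
  lad <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  r2 <- tip_rates(lad)
  rownames(r2) <- r2$tip
  expect_equal(r2["A", "nd"], 3 / 3)
  expect_equal(r2["C", "nd"], 2 / 3)
  expect_equal(r2["D", "nd"], 1 / 3)
  expect_equal(r2["A", "es"], 1 + 1 / 2 + 1 / 4)
  expect_equal(r2["C", "es"], 2 + 1 / 2)
  expect_equal(r2["D", "es"], 3)
  # ES rates rank recently-splitting tips fastest
  expect_gt(r2["A", "rate_es"], r2["D", "rate_es"])
  expect_error(tip_rates(ape::read.tree(text = "(A,B);")), "branch")
})

test_that("trc_test reports both methods coherently", {
  tr <- simulate_tree(20, seed = 69)
  rts <- setNames(tip_rates(tr)$rate_es, tr$tip.label)
  # trait identical to the rates: maximal correlation, minimal sim p
  res <- trc_test(tr, rts, rts + rnorm(20, sd = 1e-8), method = "sim",
                  n_sim = 199, seed = 3)
  expect_equal(res$statistic, 1, tolerance = 1e-4)
  expect_equal(res$p, 1 / 200, tolerance = 0.05)
  resp <- trc_test(tr, rts, rts, method = "pgls")
  expect_lt(resp$p, 1e-6)
  x <- simulate_traits(tr, model = "white", seed = 11)[, 1]
  r2 <- trc_test(tr, rts, x, method = "sim", n_sim = 199, seed = 4)
  expect_true(r2$p >= 1 / 200 && r2$p <= 1)
  expect_identical(r2$p,
                   trc_test(tr, rts, x, method = "sim", n_sim = 199,
                            seed = 4)$p)
  expect_error(trc_test(tr, rep(1, 20), x), "constant")
})

test_that("fpr_calibration counts repeated significance honestly", {
  tr <- simulate_tree(20, seed = 70)
  # alpha = 0: nothing can ever be significant
  z <- fpr_calibration(tr, n_traits = 20, alpha = 0, n_sim = 99, seed = 5)
  expect_equal(z$count, 0)
  expect_equal(unname(z$rejection_rates), rep(0, 4))
  res <- fpr_calibration(tr, n_traits = 60, alpha = 0.05, n_sim = 99,
                         seed = 6)
  expect_equal(dim(res$significant), c(60, 4))
  # white-noise traits: per-test rejection near alpha, far below 0.5
  expect_true(all(res$rejection_rates < 0.25))
  expect_lte(res$count, 60)
  expect_identical(res$count,
                   fpr_calibration(tr, n_traits = 60, alpha = 0.05,
                                   n_sim = 99, seed = 6)$count)
})
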