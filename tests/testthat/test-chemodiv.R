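# Bray-Curtis distances, chemograms with AU support, PCoA, Mantel,
# and the tanglegram.

test_that("bray_curtis has the textbook values on hand cases", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 0))
  d <- bray_curtis(m)
  expect_equal(unname(d["a", "b"]), 1)          # disjoint profiles
  expect_equal(unname(d["a", "c"]), 0)          # identical profiles
  expect_equal(diag(d), setNames(rep(0, 3), rownames(m)))
  expect_equal(d, t(d))
  # proportions: scaling a row must not change anything
  m2 <- m
  m2["a", ] <- m["a", ] * 7
  expect_equal(bray_curtis(m2), d, tolerance = 1e-12)
  # hand case: p1 = (0.5, 0.5), p2 = (0.25, 0.75) -> BC = 0.25
  h <- bray_curtis(rbind(x = c(1, 1), y = c(1, 3)))
  expect_equal(unname(h["x", "y"]), 0.25, tolerance = 1e-12)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "zero")
})

test_that("bray_curtis agrees with the vegan reference", {
  set.seed(41)
  m <- matrix(runif(60), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("c", 1:10)))
  d <- bray_curtis(m)
  ref <- as.matrix(vegan::vegdist(m / rowSums(m), method = "bray"))
  expect_equal(d, ref[rownames(d), colnames(d)], tolerance = 1e-12)
})

test_that("ward_dendrogram recovers planted cluster structure", {
  set.seed(42)
  m <- rbind(cbind(matrix(10, 4, 3), matrix(0, 4, 3)),
             cbind(matrix(0, 4, 3), matrix(10, 4, 3))) +
    matrix(runif(48), 8, 6)
  rownames(m) <- paste0("s", 1:8)
  hc <- ward_dendrogram(bray_curtis(m))
  expect_s3_class(hc, "hclust")
  expect_identical(hc$method, "ward.D")
  ct <- cutree(hc, 2)
  expect_equal(length(unique(ct[1:4])), 1)
  expect_equal(length(unique(ct[5:8])), 1)
  expect_false(ct[1] == ct[5])
})

test_that("au_from_bp maps boundary and central bp correctly", {
  scales <- seq(0.5, 1.4, by = 0.1)
  expect_equal(au_from_bp(rep(1, 10), scales, 100)$au, 1)
  expect_true(au_from_bp(rep(1, 10), scales, 100)$flagged)
  expect_equal(au_from_bp(rep(0, 10), scales, 100)$au, 0)
  # bp identically 0.5 at every scale: d and c both 0, AU = 0.5
  res <- au_from_bp(rep(0.5, 10), scales, 1000)
  expect_equal(unname(res$au), 0.5, tolerance = 1e-8)
})

test_that("multiscale bootstrap gives high support to clean clusters", {
  set.seed(43)
  m <- rbind(cbind(matrix(40, 5, 6), matrix(0, 5, 6)),
             cbind(matrix(0, 5, 6), matrix(40, 5, 6))) +
    matrix(runif(120), 10, 12)
  rownames(m) <- paste0("s", 1:10)
  boot <- multiscale_bootstrap_support(m, n_boot = 400, seed = 7)
  expect_s3_class(boot, "supported_dendrogram")
  expect_true(all(boot$support$au >= 0 & boot$support$au <= 1))
  # the planted 5/5 split must be present and strongly supported
  members <- strsplit(boot$support$members, ",")
  planted <- vapply(members, function(mm)
    setequal(mm, paste0("s", 1:5)) || setequal(mm, paste0("s", 6:10)),
    logical(1))
  expect_gte(sum(planted), 1)
  # AU is conservative when bp sits at the ceiling on every scale (the
  # curvature of the z-fit is then underdetermined), so assert strong
  # rather than near-certain support
  expect_true(all(boot$support$au[planted] > 0.8))
  expect_true(all(boot$support$bp[planted] > 0.9))
  expect_identical(boot$support,
                   multiscale_bootstrap_support(m, n_boot = 400,
                                                seed = 7)$support)
})

test_that("pcoa embeds euclidean configurations exactly", {
  set.seed(44)
  X <- matrix(rnorm(5 * 3), 5, 3)
  rownames(X) <- paste0("p", 1:5)
  D <- as.matrix(dist(X))
  res <- pcoa(D)
  expect_s3_class(res, "pcoa_result")
  # inter-point distances in the embedding reproduce D
  expect_equal(as.matrix(dist(res$coordinates)), D, tolerance = 1e-8)
  # sign convention: largest-magnitude loading on each axis is positive
  for (j in seq_len(ncol(res$coordinates))) {
    v <- res$coordinates[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_true(all(diff(res$percent) <= 1e-12))
})

test_that("pcoa matches the ape reference implementation", {
  set.seed(45)
  m <- matrix(runif(48), 6, 8, dimnames = list(paste0("s", 1:6), NULL))
  D <- bray_curtis(m)
  mine <- pcoa(D)
  ref <- ape::pcoa(as.dist(D))
  k <- min(ncol(mine$coordinates), ncol(ref$vectors))
  for (j in seq_len(k)) {
    expect_equal(abs(cor(mine$coordinates[, j], ref$vectors[, j])), 1,
                 tolerance = 1e-6)
    expect_equal(sd(mine$coordinates[, j]), sd(ref$vectors[, j]),
                 tolerance = 1e-6)
  }
})

test_that("mantel_test returns r = 1 for identical matrices", {
  set.seed(46)
  D <- as.matrix(dist(runif(8)))
  dimnames(D) <- list(paste0("s", 1:8), paste0("s", 1:8))
  res <- mantel_test(D, D, n_perm = 199, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 0.05)
})

test_that("mantel_test matches vegan's statistic and handles labels", {
  set.seed(47)
  D1 <- as.matrix(dist(runif(7)))
  D2 <- as.matrix(dist(runif(7)))
  nm <- paste0("s", 1:7)
  dimnames(D1) <- dimnames(D2) <- list(nm, nm)
  res <- mantel_test(D1, D2, n_perm = 199, seed = 2)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 99)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)
  # shuffled labels are realigned before correlating
  perm <- sample(nm)
  res2 <- mantel_test(D1, D2[perm, perm], n_perm = 199, seed = 2)
  expect_equal(res2$r, res$r, tolerance = 1e-12)
  dimnames(D2) <- list(paste0("x", 1:7), paste0("x", 1:7))
  expect_error(mantel_test(D1, D2), "labels")
  expect_error(mantel_test(D1, matrix(1, 7, 7)), "constant")
})

test_that("mantel_test enumerates exhaustively for tiny matrices", {
  set.seed(48)
  D1 <- as.matrix(dist(runif(4)))
  D2 <- as.matrix(dist(runif(4)))
  res <- mantel_test(D1, D2, n_perm = 999)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 24)
  # independent oracle: enumerate permutations via filtered expand.grid
  eg <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  eg <- eg[apply(eg, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
  ut <- upper.tri(D1)
  r_obs <- cor(D1[ut], D2[ut])
  rs <- apply(eg, 1, function(p) cor(D1[ut], D2[p, p][ut]))
  expect_equal(res$p, mean(abs(rs) >= abs(r_obs) - 1e-12))
  # exhaustive p is independent of the seed
  expect_equal(mantel_test(D1, D2, n_perm = 999, seed = 5)$p, res$p)
})

test_that("tanglegram is zero for matching topologies and optimizes links", {
  tr <- simulate_tree(12, seed = 49)
  hc <- hclust(as.dist(cophenetic(tr)), method = "average")
  tg <- tanglegram(tr, hc)
  expect_equal(tg$link_length, 0)
  expect_identical(tg$order1, tg$order2)
  # mismatched tip sets abort
  tr2 <- simulate_tree(12, seed = 50)
  tr2$tip.label <- paste0("z", 1:12)
  expect_error(tanglegram(tr2, hc))
  # permutation p-value for structure present
  m <- bray_curtis(matrix(runif(120), 12, 10,
                          dimnames = list(tr$tip.label, NULL)))
  tgp <- tanglegram(tr, ward_dendrogram(m), n_perm = 99, seed = 3)
  expect_true(tgp$p > 0 && tgp$p <= 1)
  expect_identical(tgp$p, tanglegram(tr, ward_dendrogram(m), n_perm = 99,
                                     seed = 3)$p)
})
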