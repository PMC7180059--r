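# Rule-based annotation: adduct pairing, fragment matching, chain
# inference, the glucosinolate screen, and quantification.

lib <- default_compound_library()
am <- adduct_masses()

test_that("find_adduct_pairs pairs H/Na adducts and resolves conflicts", {
  M <- 374.2457
  f <- data.frame(feature_id = 1:3,
                  mz = c(mz_mh_pos(M), mz_mna_pos(M), 500),
                  rt = c(5, 5.01, 5), intensity = c(100, 40, 10),
                  mode = "positive")
  p <- find_adduct_pairs(f)
  expect_equal(nrow(p), 1)
  expect_equal(p$h_feature, 1)
  expect_equal(p$na_feature, 2)
  expect_equal(p$neutral_mass, M, tolerance = 1e-6)

  # conflict: two candidate Na partners; greedy keeps the more intense pair
  f2 <- data.frame(feature_id = 1:3,
                   mz = c(mz_mh_pos(M), mz_mna_pos(M), mz_mna_pos(M)),
                   rt = c(5, 5, 5.02), intensity = c(100, 40, 90),
                   mode = "positive")
  p2 <- find_adduct_pairs(f2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$na_feature, 3)

  # equal intensities: tie broken by lower feature id
  f3 <- f2
  f3$intensity <- c(100, 50, 50)
  p3 <- find_adduct_pairs(f3)
  expect_equal(p3$na_feature, 2)

  # RT separation beyond tolerance kills the pair
  f4 <- f
  f4$rt[2] <- 5.2
  expect_equal(nrow(find_adduct_pairs(f4)), 0)
  expect_error(find_adduct_pairs(transform(f, mode = "negative")),
               "positive")
})

test_that("detect_genin_fragments counts water-loss ions", {
  gm <- lib$genins$mass[lib$genins$name == "digitoxigenin"]
  w <- monoisotopic_mass("H2O")
  grp <- data.frame(feature_id = 1:3,
                    mz = c(gm + am$proton, gm - w + am$proton,
                           gm - 2 * w + am$proton),
                    rt = 5, intensity = 10)
  res <- detect_genin_fragments(grp, lib)
  top <- res[1, ]
  expect_equal(top$genin, "digitoxigenin")
  expect_equal(top$n_matched, 3)
  # absent genin: no match rows with n_matched > 0 for that mass region
  grp2 <- data.frame(feature_id = 1, mz = 1000, rt = 5, intensity = 10)
  res2 <- detect_genin_fragments(grp2, lib)
  expect_true(nrow(res2) == 0 || all(res2$n_matched == 0))
})

test_that("infer_glycoside_chain does residue arithmetic", {
  gm <- lib$genins$mass[lib$genins$name == "digitoxigenin"]
  hex <- lib$sugars$loss_mass[lib$sugars$name == "hexose"]
  empty <- data.frame(feature_id = integer(), mz = numeric(),
                      rt = numeric(), intensity = numeric())
  # bare genin
  ch0 <- infer_glycoside_chain(gm, "digitoxigenin", empty, lib)
  expect_length(ch0$sugars, 0)
  expect_false(ch0$acetyl)
  # digitoxigenin mono-hexoside, neutral mass 536.2985
  ch1 <- infer_glycoside_chain(gm + hex, "digitoxigenin", empty, lib)
  expect_equal(ch1$sugars, "hexose")
  expect_equal(gm + hex, 536.2985, tolerance = 5e-4)
  # acetylated mono-hexoside
  ch1a <- infer_glycoside_chain(gm + hex + lib$acetyl_mass,
                                "digitoxigenin", empty, lib)
  expect_equal(ch1a$sugars, "hexose")
  expect_true(ch1a$acetyl)
  # no combination -> classed condition
  expect_error(infer_glycoside_chain(gm + 77.7, "digitoxigenin", empty, lib),
               class = "annotation_failure")
  expect_error(infer_glycoside_chain(gm, "nosuchgenin", empty, lib),
               "unknown genin")
})

test_that("isobaric di-glycosides are resolved by outer-loss fragments", {
  gm <- lib$genins$mass[lib$genins$name == "digitoxigenin"]
  res <- setNames(lib$sugars$loss_mass, lib$sugars$name)
  # hexose+digitoxose collides with deoxyhexose+deoxyhexose
  M <- gm + res["hexose"] + res["digitoxose"]
  expect_equal(unname(M), unname(gm + 2 * res["deoxyhexose"]),
               tolerance = 1e-3)
  # outer digitoxose loss fragment picks hexose(inner)-digitoxose(outer)
  grp <- data.frame(feature_id = 1,
                    mz = M - res["digitoxose"] + am$proton,
                    rt = 5, intensity = 10)
  ch <- infer_glycoside_chain(unname(M), "digitoxigenin", grp, lib)
  expect_equal(ch$sugars, c("hexose", "digitoxose"))
  expect_true(ch$order_resolved)
  # outer deoxyhexose loss instead picks the deoxyhexose disaccharide
  grp2 <- data.frame(feature_id = 1,
                     mz = M - res["deoxyhexose"] + am$proton,
                     rt = 5, intensity = 10)
  ch2 <- infer_glycoside_chain(unname(M), "digitoxigenin", grp2, lib)
  expect_equal(ch2$sugars, c("deoxyhexose", "deoxyhexose"))
  # no fragments at all: falls back deterministically and flags it
  empty <- data.frame(feature_id = integer(), mz = numeric(),
                      rt = numeric(), intensity = numeric())
  ch3 <- infer_glycoside_chain(unname(M), "digitoxigenin", empty, lib)
  expect_false(ch3$order_resolved)
  expect_identical(ch3,
                   infer_glycoside_chain(unname(M), "digitoxigenin",
                                         empty, lib))
})

test_that("annotate_cardenolides recovers simulated compounds", {
  cs <- simulate_compound_set(lib, n_cardenolides = 8,
                              n_glucosinolates = 0, seed = 21)
  prof <- matrix(100, 2, nrow(cs),
                 dimnames = list(c("a", "b"), cs$compound_id))
  ft <- simulate_feature_table(lib, prof, cs, ms_params(), seed = 21)
  ann <- annotate_cardenolides(ft$features, lib, annotation_params())
  expect_equal(nrow(ann), nrow(cs))
  for (i in seq_len(nrow(cs))) {
    j <- which.min(abs(ann$rt - cs$rt[i]))
    expect_lt(abs(ann$rt[j] - cs$rt[i]), 0.05)
    expect_equal(ann$genin[j], cs$genin[i])
    expect_equal(ann$acetyl[j], cs$acetyl[i])
    expect_equal(ann$isomer_index[j], cs$isomer_index[i])
  }
})

test_that("annotation is monotone in the m/z tolerance", {
  cs <- simulate_compound_set(lib, n_cardenolides = 8,
                              n_glucosinolates = 0, seed = 22)
  prof <- matrix(100, 1, nrow(cs),
                 dimnames = list("a", cs$compound_id))
  ft <- simulate_feature_table(lib, prof, cs, ms_params(), seed = 22)
  wide <- annotate_cardenolides(ft$features, lib,
                                annotation_params(mz_tol = 0.005))
  narrow <- annotate_cardenolides(ft$features, lib,
                                  annotation_params(mz_tol = 1e-7))
  expect_lte(nrow(narrow), nrow(wide))
  # exact synthetic masses: even a tiny tolerance finds everything
  expect_equal(nrow(narrow), nrow(cs))
})

test_that("screen_glucosinolates matches the library and flags unknowns", {
  cs <- simulate_compound_set(lib, n_cardenolides = 0,
                              n_glucosinolates = 5, seed = 23)
  prof <- matrix(100, 1, nrow(cs), dimnames = list("a", cs$compound_id))
  ft <- simulate_feature_table(lib, prof, cs, ms_params(), seed = 23)
  gsl <- screen_glucosinolates(ft$features, lib, annotation_params())
  known <- gsl[gsl$known, ]
  expect_setequal(known$name, cs$gsl_name)
  # an unknown [M-H]- with co-eluting diagnostic fragments is flagged
  extra <- data.frame(
    feature_id = max(ft$features$feature_id) + (1:3),
    mz = c(500.0000, lib$diagnostic_fragments_neg[1:2]),
    rt = 7.77, intensity = c(50, 5, 5), sample_id = "a",
    mode = "negative", true_compound = NA, ion = NA)
  gsl2 <- screen_glucosinolates(rbind(ft$features, extra), lib,
                                annotation_params())
  unk <- gsl2[!gsl2$known, ]
  expect_gte(nrow(unk), 1)
  expect_true(any(abs(unk$neutral_mass - (500 + am$proton)) < 0.01))
  # raising min_diag above what co-elutes suppresses the unknown
  gsl3 <- screen_glucosinolates(rbind(ft$features, extra), lib,
                                annotation_params(min_diag = 3))
  expect_false(any(!gsl3$known & abs(gsl3$neutral_mass -
                                       (500 + am$proton)) < 0.01))
})

test_that("quantify_compounds uses the globally dominant adduct", {
  cs <- simulate_compound_set(lib, n_cardenolides = 4,
                              n_glucosinolates = 2, seed = 24)
  set.seed(24)
  prof <- matrix(runif(3 * nrow(cs), 50, 150), 3, nrow(cs),
                 dimnames = list(paste0("s", 1:3), cs$compound_id))
  ft <- simulate_feature_table(lib, prof, cs, ms_params(), seed = 24)
  ann <- annotate_cardenolides(ft$features, lib, annotation_params())
  gsl <- screen_glucosinolates(ft$features, lib, annotation_params())
  q <- quantify_compounds(ft$features, list(ann, gsl))
  expect_equal(dim(q), c(3, nrow(cs)))
  expect_true(all(q >= 0))
  # every quantified cardenolide intensity equals the generating H or Na
  # ion intensity for that sample
  for (i in which(cs$class == "cardenolide")) {
    cid <- cs$compound_id[i]
    sub <- ft$features[ft$features$true_compound == cid &
                         ft$features$ion %in% c("M+H", "M+Na"), ]
    j <- which.min(abs(ann$rt - cs$rt[i]))
    for (s in rownames(q)) {
      expect_true(q[s, ann$compound_id[j]] %in%
                    c(sub$intensity[sub$sample_id == s], 0))
    }
  }
})

test_that("aggregate_features merges repeated observations", {
  f <- data.frame(feature_id = 1:4,
                  mz = c(400.0000, 400.0002, 400.0001, 410),
                  rt = c(5, 5.001, 5.002, 5), intensity = c(10, 20, 30, 5),
                  sample_id = c("a", "b", "c", "a"), mode = "positive")
  agg <- chemophylo:::aggregate_features(f)
  expect_equal(nrow(agg), 2)
  merged <- agg[which.min(abs(agg$mz - 400)), ]
  expect_equal(merged$intensity, 60)
  expect_setequal(merged$members[[1]], 1:3)
})
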