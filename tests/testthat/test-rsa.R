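mk_labels <- function(n = 12) sprintf("s%02d", seq_len(n))

test_that("model RDMs are categorical block matrices", {
  lab4 <- rep(c("happiness", "affection", "sadness", "anger"), each = 12)
  m <- model_rdm(lab4, labels = mk_labels(48))
  expect_s3_class(m, "rdm")
  expect_equal(sum(m$matrix), 48^2 - 4 * 12^2)   # 1728 dissimilar entries
  expect_true(all(m$matrix[1:12, 1:12] == 0))
  expect_true(all(diag(m$matrix) == 0))

  allsame <- model_rdm(rep("anger", 6), labels = mk_labels(6))
  expect_true(all(allsame$matrix == 0))
  expect_error(model_rdm(c("a", NA, "b")), "labelled")
})

test_that("feature RDMs are absolute differences, affine-covariant", {
  f <- feature_rdm(c(1, 2, 4), labels = c("a", "b", "c"))
  expect_equal(f$matrix[upper.tri(f$matrix)], c(1, 3, 2))
  set.seed(51)
  v <- rnorm(10)
  f1 <- feature_rdm(v, labels = mk_labels(10))
  f2 <- feature_rdm(3 * v + 5, labels = mk_labels(10))
  expect_equal(f2$matrix, 3 * f1$matrix, tolerance = 1e-12)
  ref <- feature_rdm(rnorm(10), labels = mk_labels(10))
  expect_equal(tau_a(f1, ref), tau_a(f2, ref), tolerance = 1e-12)
  expect_warning(feature_rdm(rep(1, 5), labels = mk_labels(5)), "constant")
})

test_that("behavioural RDMs from ratings", {
  df <- expand.grid(rater = 1:2, scene_id = c("s1", "s2", "s3"),
                    stringsAsFactors = FALSE)
  df$emotion_true <- "happiness"
  df$response <- c("happiness", "happiness", "happiness", "anger",
                   "happiness", "anger")
  df$valence <- c(-5L, -5L, 0L, 0L, 5L, 5L)
  b <- behavioural_rdms(df)
  ## rater 1 rated everything identically -> zero emotion RDM
  expect_true(all(b$emotion[["1"]]$matrix == 0))
  ## valence {-5, 0, 5} -> off-diagonals {5, 10, 5}
  expect_equal(b$valence[["1"]]$matrix[upper.tri(diag(3))], c(5, 10, 5))
  ## rater 2: happiness, anger, anger
  expect_equal(b$emotion[["2"]]$matrix["s1", "s2"], 1)
  expect_equal(b$emotion[["2"]]$matrix["s2", "s3"], 0)
  ## group mean emotion RDM averages the binary entries
  expect_equal(b$group_emotion$matrix["s1", "s2"], 0.5)
  expect_error(behavioural_rdms(df[-1, ]), "incomplete")
})

test_that("tau_a matches brute-force pair enumeration, with and without ties", {
  set.seed(52)
  expect_equal(tau_a(1:10, 1:10), 1)
  expect_equal(tau_a(1:10, 10:1), -1)
  x5 <- c(1, 2, 2, 3, 5); y5 <- c(2, 1, 4, 4, 6)
  expect_equal(tau_a(x5, y5), oracle_tau_a(x5, y5), tolerance = 1e-12)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    x <- sample(1:8, n, TRUE)            # many ties -> grouped fast path
    y <- rnorm(n)
    expect_equal(tau_a(x, y), oracle_tau_a(x, y), tolerance = 1e-12)
    expect_equal(tau_a(y, x), oracle_tau_a(y, x), tolerance = 1e-12)
    xc <- rnorm(n); yc <- rnorm(n)       # continuous -> tau-b conversion path
    expect_equal(tau_a(xc, yc), oracle_tau_a(xc, yc), tolerance = 1e-12)
  }
  ## invariance under strictly monotone transforms
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(tau_a(exp(x), y), tau_a(x, y), tolerance = 1e-12)
  expect_warning(t0 <- tau_a(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(t0))
})

test_that("model-feature relation: aligned features, permutation p, MDS", {
  set.seed(53)
  n <- 12
  v <- rnorm(n)
  base <- feature_rdm(v, labels = mk_labels(n), name = "base")
  mono <- rdm(base$matrix^2, mk_labels(n), "feature", "mono")  # monotone
  noise <- feature_rdm(rnorm(n), labels = mk_labels(n), name = "noise")
  res <- relate_models_to_features(list(base = base),
                                   list(mono = mono, noise = noise),
                                   n_perm = 200, seed = 9)
  expect_equal(res$tau["base", "mono"], 1, tolerance = 1e-12)
  cmp <- res$comparisons
  expect_lt(cmp$p[cmp$feature == "mono"], 0.02)
  expect_gt(cmp$p[cmp$feature == "noise"], 0.05)
  expect_equal(cmp$p_bonferroni, pmin(1, 2 * cmp$p), tolerance = 1e-12)
  ## MDS: aligned pair nearly coincident, noise distant
  d <- as.matrix(dist(res$mds))
  expect_lt(d["base", "mono"], d["base", "noise"] / 5)
})

test_that("noise ceilings and feature-behaviour relation", {
  set.seed(54)
  n <- 10
  v <- rnorm(n)
  fr <- feature_rdm(v, labels = mk_labels(n), name = "driver")
  other <- feature_rdm(rnorm(n), labels = mk_labels(n), name = "other")
  subj_same <- lapply(1:6, function(i) {
    rdm(fr$matrix, mk_labels(n), "behav_valence", sprintf("s%d", i))
  })
  res <- relate_features_to_behaviour(list(driver = fr, other = other),
                                      subj_same, statistic = "tau_a")
  expect_equal(res$table$mean_cor[res$table$feature == "driver"], 1,
               tolerance = 1e-12)
  expect_equal(res$ceiling$upper, 1, tolerance = 1e-12)
  expect_equal(res$ceiling$lower, 1, tolerance = 1e-12)
  expect_equal(res$table$feature[1], "driver")

  ## noisy subjects: lower <= upper; subject order irrelevant
  subj_noisy <- lapply(1:8, function(i) {
    w <- v + rnorm(n, 0, 0.8)
    rdm(abs(outer(w, w, "-")), mk_labels(n), "behav_valence",
        sprintf("n%d", i))
  })
  nc <- noise_ceiling(subj_noisy, "pearson")
  expect_lte(nc$lower, nc$upper)
  nc2 <- noise_ceiling(rev(subj_noisy), "pearson")
  expect_equal(nc2$lower, nc$lower, tolerance = 1e-12)
  expect_equal(nc2$upper, nc$upper, tolerance = 1e-12)
})

test_that("pairwise signed-rank feature tests", {
  set.seed(55)
  per_subject <- rbind(A = runif(31, 0.2, 0.4), B = runif(31, 0.2, 0.4))
  per_subject <- rbind(per_subject, C = per_subject["B", ])  # exact copy
  per_subject["A", ] <- per_subject["B", ] + runif(31, 0.01, 0.1)  # A wins all
  res <- pairwise_feature_tests(per_subject)
  expect_true(is.na(res$p["A", "A"]))
  expect_equal(res$p, t(res$p))
  expect_equal(res$p["B", "C"], 1)
  ## 31 one-signed differences: minimal exact two-sided signed-rank p
  expect_equal(res$p["A", "B"], 2 / 2^31, tolerance = 1e-15)
  expect_error(pairwise_feature_tests(per_subject[, 1:4]), "6 subjects")
})

test_that("combination RDMs: self-combination, levels, exclusion", {
  set.seed(56)
  v <- rnorm(9)
  f <- feature_rdm(v, labels = mk_labels(9))
  combo <- combine_rdms(list(f, f))
  expect_equal(tau_a(combo, f), 1, tolerance = 1e-12)

  ## two "orthogonal" binary RDMs -> three levels {0, 1/2, 1}
  b1 <- model_rdm(rep(c("x", "y"), each = 4), labels = mk_labels(8))
  b2 <- model_rdm(rep(c("x", "y"), times = 4), labels = mk_labels(8))
  cb <- combine_rdms(list(b1, b2))
  expect_setequal(unique(as.vector(cb$matrix)), c(0, 0.5, 1))

  expect_warning(
    c2 <- combine_rdms(list(f, rdm(matrix(0, 9, 9), mk_labels(9)))),
    "constant")
  expect_equal(tau_a(c2, f), 1, tolerance = 1e-12)

  ## invariant guards on construction
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(rdm(bad, c("a", "b")), "symmetric")
  expect_error(rdm(matrix(c(0.5, 1, 1, 0), 2, 2), c("a", "b")), "diagonal")
})
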