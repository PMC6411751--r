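test_that("feature weights match the Laplacian-corrected closed form", {
  expect_equal(feature_weight(2, 2, 0.5), log(1.5))
  expect_equal(feature_weight(0, 2, 0.5), log(0.5))
  # a feature at the base rate carries no evidence
  for (t in c(2, 5, 10, 20)) {
    for (p in c(0.2, 0.25, 0.5, 0.7)) {
      a <- t * p
      if (a == round(a)) expect_equal(feature_weight(a, t, p), 0)
    }
  }
  expect_error(feature_weight(3, 2, 0.5), "a_i")
  expect_error(feature_weight(1, 0, 0.5), "t_i")
})

test_that("weights are monotone in the counts", {
  w <- feature_weight(0:10, 10, 0.4)
  expect_true(all(diff(w) > 0))
  w_t <- vapply(5:20, function(t) feature_weight(5, t, 0.4), 0)
  expect_true(all(diff(w_t) < 0))
})

test_that("the toy 4-molecule set trains with the expected structure", {
  fd <- toy_dataset()
  m <- train_bayes(fd)
  expect_equal(m$p_good, 0.5)
  w <- setNames(m$weights, m$feature_ids)
  expect_gt(w[["1"]], 0)  # feature 1 only in actives
  expect_lt(w[["2"]], 0)  # feature 2 only in inactives
  expect_equal(w[["3"]], 0)  # features 3/4 at base rate
  expect_equal(w[["4"]], 0)
  # an active's own features score positive
  sc <- score_features(m, toy_features()$a1)
  expect_gt(sc$raw, 0)
  loo <- loo_scores(fd)
  expect_length(loo, 4)
  expect_gt(mean(loo[1:2]), mean(loo[3:4]))
  expect_equal(loo_roc(fd)$auc, 1.0)
})

test_that("scores are additive and empty feature sets score zero", {
  m <- train_bayes(toy_dataset())
  expect_equal(score_features(m, integer(0))$raw, 0)
  f <- c(1L, 3L); g <- c(2L, 4L)
  expect_equal(score_features(m, c(f, g))$raw,
               score_features(m, f)$raw + score_features(m, g)$raw)
  # unseen features contribute nothing
  expect_equal(score_features(m, c(f, 999L))$raw, score_features(m, f)$raw)
})

test_that("training rejects degenerate inputs", {
  fd_one_class <- feature_dataset(toy_features(), rep("active", 4))
  expect_error(train_bayes(fd_one_class), "both classes")
  fd_na <- feature_dataset(toy_features(), c("active", NA, "inactive", "inactive"))
  expect_error(train_bayes(fd_na), "label")
})

test_that("train/score/LOO agree with the brute-force oracle", {
  for (seed in 1:25) {
    dat <- random_feature_data(n_mol = sample(6:12, 1), n_feat = 8, seed = seed)
    fd <- feature_dataset(dat$features, dat$labels)
    m <- train_bayes(fd)
    # full-data scores
    for (i in seq_along(dat$features)) {
      got <- score_features(m, dat$features[[i]])
      want <- brute_score(dat$features, dat$labels, dat$features[[i]])
      expect_equal(got$raw, want[["raw"]], tolerance = 1e-12)
      expect_equal(got$s, want[["s"]], tolerance = 1e-12)
    }
    # decrement-based LOO equals naive retrain-per-record
    expect_equal(loo_scores(fd), brute_loo(dat$features, dat$labels),
                 tolerance = 1e-12)
  }
})

test_that("EstPGood matches the dual-Gaussian expression and its identities", {
  m <- structure(list(mu_active = 2, sigma_active = 1,
                      mu_inactive = -2, sigma_inactive = 1),
                 class = "orco_nb")
  expect_equal(est_p_good(m, 0), 0.5)
  expect_equal(est_p_good(m, 1), 1 / (1 + exp(-4)))
  # monotone when sigmas are equal, limits resolve in log space
  s <- seq(-50, 50, length.out = 201)
  p <- est_p_good(m, s)
  expect_true(all(diff(p) >= 0))
  expect_false(anyNA(est_p_good(m, c(-1e6, 1e6))))
  expect_equal(est_p_good(m, 1e6), 1)
  expect_equal(est_p_good(m, -1e6), 0)
})

test_that("prediction combines score, probability and binary call", {
  fd <- toy_dataset()
  m <- train_bayes(fd)
  pr <- predict(m, toy_features())
  expect_equal(pr$call, c("active", "active", "inactive", "inactive"))
  expect_true(all(pr$est_p_good[1:2] > 0.5))
  expect_true(all(pr$est_p_good[3:4] < 0.5))
  # a record with no trained features sits at normalized score zero
  pr0 <- predict(m, list(x = c(900L, 901L)))
  expect_equal(pr0$s, 0)
  expect_equal(pr0$est_p_good, est_p_good(m, 0))
})

test_that("model-B construction gates actives on strict potency", {
  ms <- molecule_set(
    paste0("m", 1:6),
    c("CCO", "CCC", "CCCC", "CCCCC", "CC", "CCCCCC"),
    label = c("active", "active", "active", "active", "inactive", "inactive"),
    ic50_um = c(499, 500, 501, 48, NA, NA))
  b <- select_model_b_set(ms)
  expect_setequal(b$id[b$label == "active"], c("m1", "m4"))
  expect_equal(sum(b$label == "inactive"), 2)
})

test_that("models serialize to JSON and round-trip losslessly", {
  fd <- fixture_training_features()
  m <- train_bayes(fd)
  f <- withr::local_tempfile(fileext = ".json")
  write_bayes_model(m, f)
  m2 <- read_bayes_model(f)
  expect_equal(m2$p_good, m$p_good)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$threshold, m$threshold)
  probe <- fd$features[1:5]
  expect_equal(predict(m2, probe), predict(m, probe))
})
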