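test_that("percent-of-control normalization follows the stated order", {
  # candidate response equal to control, clean sham -> no inhibition
  r <- percent_response(100, 100, 100, sham_percent = 100)
  expect_equal(r$normalized_percent, 100)
  expect_equal(r$inhibition_percent, 0)
  # complete block
  expect_equal(percent_response(80, 120, 0)$inhibition_percent, 100)
  # raw 45% against a 90% sham -> normalized 50%, inhibition 50%
  r <- percent_response(100, 100, 45, sham_percent = 90)
  expect_equal(r$raw_percent, 45)
  expect_equal(r$normalized_percent, 50)
  expect_equal(r$inhibition_percent, 50)
  expect_error(percent_response(0, 0, 10), "positive")
})

test_that("normalized percent is invariant to current rescaling", {
  for (k in c(0.1, 2, 37)) {
    a <- percent_response(90, 110, 55, 95)
    b <- percent_response(90 * k, 110 * k, 55 * k, 95)
    expect_equal(a$normalized_percent, b$normalized_percent)
  }
})

test_that("the 20%-at-3-mM activity call sits exactly on its boundary", {
  expect_equal(classify_antagonist(20.0), "inactive")
  expect_equal(classify_antagonist(20.1), "active")
  expect_equal(classify_antagonist(95), "active")
  expect_equal(classify_antagonist(c(0, 19.99, 20, 20.01, 100)),
               c("inactive", "inactive", "inactive", "active", "active"))
})

test_that("the Hill fit recovers noiseless parameters almost exactly", {
  x <- 10^seq(0, 4, length.out = 8)
  y <- 100 / (1 + (x / 48)^1)
  f <- fit_concentration_inhibition(x, y)
  expect_true(f$converged)
  expect_equal(f$ic50, 48, tolerance = 1e-3)
  expect_equal(f$hill_n, 1, tolerance = 1e-3)
  expect_equal(f$i_max, 100, tolerance = 1e-3)
  # at X = IC50 the fitted curve predicts half of Imax
  pred <- f$i_max / (1 + (f$ic50 / f$ic50)^f$hill_n)
  expect_equal(pred, f$i_max / 2)
  expect_true(f$ic50_in_range)
})

test_that("degenerate concentration-inhibition inputs are flagged, not hidden", {
  x <- 10^seq(0, 4, length.out = 8)
  rising <- seq(10, 100, length.out = 8)  # no inhibition at all
  f <- fit_concentration_inhibition(x, rising)
  expect_true(!isTRUE(f$converged) || !isTRUE(f$ic50_in_range))
  expect_error(fit_concentration_inhibition(x[1:3], rising[1:3]), "4 concentration")
  expect_error(fit_concentration_inhibition(rep(10, 8), rising), "log unit")
})

test_that("the potency gate for model-B actives is strict", {
  fits <- data.frame(compound_id = c("a", "b", "c"),
                     ic50_um = c(499, 500, 501))
  expect_equal(select_model_b_actives(fits), "a")
  expect_equal(select_model_b_actives(fits, cutoff = 502), c("a", "b", "c"))
})

test_that("the Response Index obeys its arithmetic identities", {
  expect_equal(response_index(50, 0), 1)
  expect_equal(response_index(0, 50), -1)
  expect_equal(response_index(25, 25), 0)
  expect_equal(response_index(44, 6), 0.76)
  for (s in c(1, 10, 30)) for (c_ in c(0, 5, 20)) {
    expect_equal(response_index(s, c_), -response_index(c_, s))
  }
  expect_error(response_index(0, 0), "undefined")
  expect_error(response_index(-1, 5), "non-negative")
})

test_that("dose-response tables fit per compound from raw currents", {
  tab <- rbind(
    generate_dose_response(dose_response_spec(true_ic50 = 48, seed = 3),
                           compound_id = "bmp"),
    generate_dose_response(dose_response_spec(true_ic50 = 251, seed = 4),
                           compound_id = "lf"))
  fits <- fit_dose_response_table(tab)
  expect_equal(sort(fits$compound_id), c("bmp", "lf"))
  expect_true(all(fits$converged))
  expect_equal(fits$ic50_um[fits$compound_id == "bmp"], 48, tolerance = 0.25)
  expect_equal(fits$ic50_um[fits$compound_id == "lf"], 251, tolerance = 0.25)
})
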