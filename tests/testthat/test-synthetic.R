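test_that("the training generator reproduces the study panel layout", {
  tr <- fixture_training()
  expect_equal(sum(tr$label == "active"), 58)
  expect_equal(sum(tr$label == "inactive"), 25)
  expect_true(all(tr$standardized))
  expect_true(all(!is.na(tr$ic50_um[tr$label == "active"])))
  expect_true(all(is.na(tr$ic50_um[tr$label == "inactive"])))
  # structures are already standard: re-standardizing changes nothing
  expect_identical(standardize_molecules(tr)$smiles, tr$smiles)
  # potency gate yields a non-empty strict subset (the model-B situation)
  potent <- tr$ic50_um[tr$label == "active"] < 500
  expect_gt(sum(potent), 0)
  expect_lt(sum(potent), 58)
})

test_that("every generated active carries a motif and inactives do not", {
  tr <- fixture_training()
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    setNames(tr$smiles, paste0("q", seq_len(nrow(tr))))))
  hits <- rep(FALSE, nrow(tr))
  for (pat in c("[OX2H]c1ccccc1", "O=C(O[#6])C=Cc1ccccc1")) {
    hits <- hits | ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE) > 0
  }
  expect_true(all(hits[tr$label == "active"]))
  expect_false(any(hits[tr$label == "inactive"]))
})

test_that("generators are byte-identical under a fixed seed", {
  s <- library_spec(n_actives = 10, n_inactives = 6, n_library = 40, seed = 3)
  expect_identical(generate_training_set(s), generate_training_set(s))
  expect_identical(generate_library(s), generate_library(s))
  expect_false(identical(
    generate_training_set(s),
    generate_training_set(library_spec(n_actives = 10, n_inactives = 6,
                                       n_library = 40, seed = 4))))
})

test_that("the library generator hits its motif fraction and spikes training ids", {
  spec <- library_spec(n_actives = 10, n_inactives = 6, n_library = 200,
                       active_fraction_library = 0.1, seed = 13)
  tr <- generate_training_set(spec)
  lib <- generate_library(spec, training = tr, spike_training = TRUE,
                          n_spike_active = 4, n_spike_inactive = 2)
  expect_equal(nrow(lib$molecules), 200)
  expect_equal(sum(lib$truth$is_training), 6)
  expect_true(all(lib$truth$id[lib$truth$is_training] %in% tr$id))
  # without spiking, the motif count is exactly round(n * fraction)
  plain <- generate_library(spec)
  expect_equal(sum(plain$truth$is_motif), 20)
  expect_false(any(plain$truth$is_training))
})

test_that("dose-response rows invert the Hill curve exactly at zero noise", {
  spec <- dose_response_spec(true_ic50 = 48, noise_cv = 0, seed = 1)
  tab <- generate_dose_response(spec)
  resp <- percent_response(tab$i_pre1, tab$i_pre2, tab$i_test,
                           tab$sham_percent)$normalized_percent
  hill <- 100 / (1 + tab$concentration_um / 48)
  expect_equal(resp, hill, tolerance = 1e-10)
  expect_equal(resp[which.min(abs(tab$concentration_um - 48))],
               50, tolerance = 7)
  # same curve, different noise under different seeds
  a <- generate_dose_response(dose_response_spec(seed = 1))
  b <- generate_dose_response(dose_response_spec(seed = 2))
  expect_false(identical(a$i_test, b$i_test))
})

test_that("behavior trials follow the two-choice binomial model", {
  t1 <- generate_behavior_trial(p_stim = 1, p_excluded = 0, seed = 1)
  expect_equal(t1$ri, 1)
  expect_equal(t1$s_count + t1$c_count, 50)
  big <- generate_behavior_trial(n_larvae = 1e4, p_stim = 0.5,
                                 p_excluded = 0.1, seed = 2)
  expect_lt(abs(big$ri), 0.05)
  expect_equal(formals(generate_behavior_trial)$n_larvae, 50)
})

test_that("label noise degrades separability monotonically", {
  aucs <- vapply(c(0, 0.2, 0.4), function(noise) {
    spec <- library_spec(n_actives = 20, n_inactives = 14,
                         label_noise = noise, seed = 31)
    loo_roc(featurize_dataset(generate_training_set(spec)))$auc
  }, 0)
  expect_true(all(diff(aucs) < 0))
  expect_gte(aucs[1], 0.95)
})
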