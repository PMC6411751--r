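# small dual-model screen shared across this file
.screen_fixture <- function() {
  fixture("screen_small", function() {
    spec <- library_spec(n_actives = 14, n_inactives = 10, n_library = 60,
                         active_fraction_library = 0.2, seed = 21)
    tr <- generate_training_set(spec)
    lib <- generate_library(spec, training = tr, spike_training = TRUE,
                            n_spike_active = 3, n_spike_inactive = 2)
    mA <- train_bayes(tr)
    mB <- train_bayes(tr, actives_max_ic50 = 1500)
    scr <- gate_candidates(screen_library(mA, mB, lib$molecules))
    list(tr = tr, lib = lib, mA = mA, mB = mB, scr = scr)
  })
}

test_that("screening flags training members and ranks deterministically", {
  fx <- .screen_fixture()
  scr <- fx$scr
  expect_equal(nrow(scr), 60)
  expect_equal(sum(scr$is_training), 5)
  expect_true(all(scr$id[scr$is_training] %in% fx$tr$id))
  comb <- scr$estpgood_A + scr$estpgood_B
  expect_true(all(diff(comb) <= 1e-12))
  scr2 <- gate_candidates(screen_library(fx$mA, fx$mB, fx$lib$molecules))
  expect_identical(scr, scr2)
  expect_warning(screen_library(fx$mA, fx$mB, fx$tr[0, ]), "empty")
})

test_that("EstPGood gating uses strict dual-model inequalities", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    estpgood_A = c(0.95, 0.95, 0.05, 0.9),
                    estpgood_B = c(0.92, 0.88, 0.09, 0.9))
  g <- gate_candidates(rec)
  expect_equal(g$gate, c("predicted_active", "neither", "predicted_inactive",
                         "neither"))
  # raising the hi cutoff can only shrink the predicted-active set
  fx <- .screen_fixture()
  n_hi <- vapply(c(0.8, 0.9, 0.95, 0.99), function(h)
    sum(gate_candidates(fx$scr, hi = h)$gate == "predicted_active"), 0L)
  expect_true(all(diff(n_hi) <= 0))
})

test_that("clustering partitions the gated set into round(N/size) clusters", {
  fx <- .screen_fixture()
  ga <- fx$scr[fx$scr$gate == "predicted_active", ]
  skip_message <- NULL
  expect_gt(nrow(ga), 4)
  part <- cluster_partition(ga, fx$lib$molecules, average_size = 5)
  n <- nrow(ga)
  expect_equal(nrow(part$clusters), max(1, floor(n / 5 + 0.5)))
  # partition: every compound in exactly one cluster, sizes add up
  expect_false(anyNA(part$records$cluster_id))
  expect_equal(sum(part$clusters$size), n)
  expect_equal(sort(unique(part$records$cluster_id)),
               part$clusters$cluster_id)
  # round-half-up arithmetic and the override
  expect_equal(nrow(cluster_partition(fx$scr[1:13, ], fx$lib$molecules,
                                      average_size = 5)$clusters), 3)
  expect_equal(nrow(cluster_partition(ga, fx$lib$molecules,
                                      n_clusters = 4)$clusters), 4)
})

test_that("duplicate structures land in the same cluster", {
  ms <- molecule_set(paste0("m", 1:6),
                     c("CCO", "CCO", "Oc1ccccc1C(C)(C)C",
                       "Oc1ccccc1C(C)(C)C", "CCCCCCCC", "CCCCCCCC"),
                     standardized = TRUE)
  rec <- data.frame(id = ms$id,
                    estpgood_A = seq(0.9, 0.4, length.out = 6),
                    estpgood_B = seq(0.9, 0.4, length.out = 6),
                    is_training = FALSE, stringsAsFactors = FALSE)
  part <- cluster_partition(rec, ms, average_size = 2)
  cl <- part$records$cluster_id
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_equal(cl[5], cl[6])
})

test_that("representative selection follows the argmax rule and skips singletons", {
  rec <- data.frame(id = c("a", "b", "c", "s", "t1", "t2"),
                    estpgood_A = c(0.99, 0.95, 0.93, 0.99, 0.99, 0.98),
                    estpgood_B = c(0.99, 0.95, 0.93, 0.99, 0.99, 0.98),
                    is_training = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
                    cluster_id = c(1L, 1L, 1L, 2L, 3L, 3L),
                    selected = FALSE, stringsAsFactors = FALSE)
  clusters <- data.frame(cluster_id = 1:3, centroid_id = c("a", "s", "t1"),
                         size = c(3L, 1L, 2L))
  expect_warning(
    out <- select_representatives(list(records = rec, clusters = clusters)),
    "no selectable")
  expect_equal(out$id[out$selected], "a")   # argmax mean EstPGood
  expect_false(out$selected[out$id == "s"]) # singleton skipped
  expect_false(any(out$selected[out$is_training]))
})

test_that("novelty scores equal exhaustive all-pairs Tanimoto", {
  novel <- standardize_molecules(molecule_set(
    c("n1", "n2", "n3"),
    c("Oc1ccccc1C", "CCCCOC(=O)C", "Oc1ccccc1")))
  train <- standardize_molecules(molecule_set(
    c("t1", "t2"), c("Oc1ccccc1", "CCOC(=O)C")))
  res <- max_pairwise_similarity(novel, train)
  fn <- featurize(novel, radius = 2)
  ft <- featurize(train, radius = 2)
  for (i in 1:3) {
    want <- max(vapply(ft, function(g) tanimoto(fn[[i]], g), 0))
    expect_equal(unname(res$max_sim[i]), want)
  }
  expect_equal(unname(res$max_sim["n3"]), 1)  # identical to t1
  expect_equal(res$nearest_id[[3]], "t1")
  expect_equal(sum(res$histogram), 3)
  expect_equal(unname(res$histogram[10]), 1)  # the [0.9,1.0] bin
})
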