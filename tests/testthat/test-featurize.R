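test_that("a single-heavy-atom molecule has exactly one environment", {
  expect_length(circular_fingerprint("C", radius = 2), 1)
  expect_length(circular_fingerprint("C", radius = 3), 1)
})

test_that("fingerprints are deterministic and respect graph isomorphism", {
  s <- standardize_smiles("CC(C)Oc1ccccc1O")
  expect_identical(circular_fingerprint(s, 2), circular_fingerprint(s, 2))
  pairs <- list(c("OCC", "C(O)C"),
                c("Oc1ccc(CC)cc1", "CCc1ccc(O)cc1"),
                c("O=C(OCC)C=Cc1ccccc1", "c1ccccc1C=CC(=O)OCC"))
  for (p in pairs) {
    f1 <- circular_fingerprint(standardize_smiles(p[1]), 2)
    f2 <- circular_fingerprint(standardize_smiles(p[2]), 2)
    expect_identical(f1, f2)
  }
})

test_that("related structures share the common-environment subset", {
  f_ethanol <- circular_fingerprint("CCO", 2)
  f_ethane <- circular_fingerprint("CC", 2)
  expect_false(identical(f_ethanol, f_ethane))
  # the two equivalent methyl carbons of ethane give one shared atom feature
  expect_gte(length(intersect(f_ethanol, f_ethane)), 1)
  expect_gt(length(f_ethanol), length(f_ethane))
})

test_that("larger radius yields a superset of environments", {
  for (s in c("CCO", "Oc1ccc(CC)cc1", "O=C(OCC)C=Cc1ccccc1")) {
    f2 <- circular_fingerprint(s, 2)
    f3 <- circular_fingerprint(s, 3)
    expect_true(all(f2 %in% f3))
    expect_gte(length(f3), length(f2))
  }
  # on a molecule wider than 2 bonds the extra shell adds new environments
  expect_gt(length(circular_fingerprint("O=C(OCC)C=Cc1ccccc1", 3)),
            length(circular_fingerprint("O=C(OCC)C=Cc1ccccc1", 2)))
})

test_that("descriptors match hand counts on reference molecules", {
  ms <- standardize_molecules(molecule_set(
    c("ethanol", "benzene", "decane"),
    c("CCO", "c1ccccc1", "CCCCCCCCCC")))
  d <- physchem_descriptors(ms)
  expect_equal(d["ethanol", "hbd"], 1)
  expect_equal(d["ethanol", "hba"], 1)
  expect_equal(d["ethanol", "rotb"], 0)
  expect_equal(d["benzene", "fpsa"], 0)
  expect_equal(d["decane", "hbd"], 0)
  expect_equal(d["decane", "hba"], 0)
  expect_equal(d["decane", "rotb"], 7)
  expect_true(all(d$mw > 0))
  expect_true(all(d$fpsa >= 0 & d$fpsa <= 1))
})

test_that("quantile binning splits at the median for B = 2", {
  ms <- fixture_small_panel()[1:4, ]
  class(ms) <- c("MoleculeSet", "data.frame")
  desc <- data.frame(alogp = 1:4, mw = c(100, 200, 300, 400), hbd = 0:3,
                     hba = 0:3, rotb = 0:3, fpsa = c(0, .1, .2, .3))
  scheme <- fit_binning_scheme(ms, bins = 2, descriptors = desc)
  expect_equal(scheme$cuts$mw, 250)
  expect_equal(findInterval(120, scheme$cuts$mw), 0)
  expect_equal(findInterval(260, scheme$cuts$mw), 1)
})

test_that("featurization adds one indicator per descriptor in a disjoint id range", {
  panel <- fixture_small_panel()
  scheme <- fit_binning_scheme(panel)
  fp_only <- featurize(panel, radius = 2)
  full <- featurize(panel, radius = 2, scheme = scheme)
  for (i in seq_along(fp_only)) {
    expect_length(full[[i]], length(fp_only[[i]]) + 6)
    expect_true(all(fp_only[[i]] < 2^30))
    desc_ids <- setdiff(full[[i]], fp_only[[i]])
    expect_true(all(desc_ids >= 2^30))
  }
})

test_that("tanimoto obeys its identities", {
  expect_equal(tanimoto(1:5, 1:5), 1)
  expect_equal(tanimoto(1:3, 4:6), 0)
  expect_equal(tanimoto(c(1, 2, 3, 4), c(3, 4, 5, 6)), 1 / 3)
  expect_equal(tanimoto(integer(0), integer(0)), 1)
  expect_equal(tanimoto(c(1, 2), c(2, 3)), tanimoto(c(2, 3), c(1, 2)))
})
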