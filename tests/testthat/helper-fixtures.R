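# Shared fixtures, memoized so the chemistry layer runs once per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# the default synthetic study panel: 58 actives / 25 inactives
fixture_training <- function() {
  fixture("training", function() generate_training_set(library_spec(seed = 11)))
}

fixture_training_features <- function() {
  fixture("training_fd", function() featurize_dataset(fixture_training()))
}

# a small labeled panel for cheap end-to-end tests
fixture_small_panel <- function() {
  fixture("small_panel", function() {
    spec <- library_spec(n_actives = 12, n_inactives = 8, seed = 5)
    generate_training_set(spec)
  })
}

# 4-molecule toy set: 2 actives share feature 1, 2 inactives share feature 2
toy_features <- function() {
  list(a1 = c(1L, 3L), a2 = c(1L, 4L), i1 = c(2L, 3L), i2 = c(2L, 4L))
}

toy_labels <- c("active", "active", "inactive", "inactive")

toy_dataset <- function() feature_dataset(toy_features(), toy_labels)
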