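#' Serialize a trained model to JSON
#'
#' Writes the base rate, the feature-id to weight map, the per-class LOO
#' score Gaussians, the decision threshold, and the featurization manifest
#' (radius, descriptor bins and cut points, training ids/labels). The round
#' trip through [read_bayes_model()] is lossless for prediction purposes.
#'
#' @param model an `orco_nb` model.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_bayes_model <- function(model, path) {
  stopifnot(inherits(model, "orco_nb"))
  obj <- list(
    p_good = model$p_good,
    n_active = model$n_active,
    n_total = model$n_total,
    feature_ids = model$feature_ids,
    weights = model$weights,
    a_counts = model$a_counts,
    t_counts = model$t_counts,
    mu_active = model$mu_active, sigma_active = model$sigma_active,
    mu_inactive = model$mu_inactive, sigma_inactive = model$sigma_inactive,
    threshold = model$threshold,
    loo = model$loo,
    radius = model$radius,
    scheme = if (is.null(model$scheme)) NULL else
      list(bins = model$scheme$bins, cuts = model$scheme$cuts),
    training_ids = model$training_ids,
    training_labels = model$training_labels,
    normalization = "raw_score / max(1, n_features)"
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trained model from JSON
#'
#' @param path JSON file written by [write_bayes_model()].
#' @return an `orco_nb` model.
#' @export
read_bayes_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scheme <- NULL
  if (!is.null(obj$scheme)) {
    scheme <- structure(list(bins = as.integer(obj$scheme$bins),
                             cuts = lapply(obj$scheme$cuts, as.numeric)),
                        class = "BinningScheme")
  }
  structure(list(
    p_good = obj$p_good,
    feature_ids = as.integer(obj$feature_ids),
    weights = as.numeric(obj$weights),
    a_counts = as.integer(obj$a_counts),
    t_counts = as.integer(obj$t_counts),
    n_active = as.integer(obj$n_active),
    n_total = as.integer(obj$n_total),
    mu_active = obj$mu_active, sigma_active = obj$sigma_active,
    mu_inactive = obj$mu_inactive, sigma_inactive = obj$sigma_inactive,
    threshold = obj$threshold,
    loo = as.numeric(obj$loo),
    radius = as.integer(obj$radius),
    scheme = scheme,
    training_ids = obj$training_ids,
    training_labels = obj$training_labels
  ), class = "orco_nb")
}
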