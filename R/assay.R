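# Wet-lab quantifications: percent-of-control inhibition with sham
# normalization, the activity call, Hill concentration-inhibition fitting,
# the model-B potency gate, and the larval chemotaxis Response Index.

#' Percent-of-control response with sham normalization
#'
#' The current response with candidate co-applied is expressed as a
#' percentage of the mean of the two preceding agonist-alone responses, then
#' normalized to the percent-of-control obtained in a vehicle-only (sham)
#' run, correcting for run-to-run rundown. Inhibition is `100 - normalized`.
#'
#' @param i_pre1,i_pre2 agonist-alone current responses (nA, >= 0).
#' @param i_test response with candidate co-applied (nA, >= 0).
#' @param sham_percent percent-of-control of the vehicle-only run (> 0).
#' @return data frame with `raw_percent`, `normalized_percent`,
#'   `inhibition_percent` (vectorized).
#' @export
percent_response <- function(i_pre1, i_pre2, i_test, sham_percent = 100) {
  pre <- (i_pre1 + i_pre2) / 2
  if (any(pre <= 0)) stop("pre-application mean must be positive (dead oocyte?)")
  if (any(sham_percent <= 0)) stop("sham_percent must be positive")
  raw <- 100 * i_test / pre
  norm <- 100 * raw / sham_percent
  data.frame(raw_percent = raw, normalized_percent = norm,
             inhibition_percent = 100 - norm)
}

#' Classify a compound from its inhibition at 3 mM
#'
#' Inactive iff inhibition is at most 20 percent of the control response at
#' the 3 mM screening concentration; active above that.
#'
#' @param inhibition_percent inhibition on the percent scale.
#' @return `"active"` or `"inactive"` (vectorized).
#' @export
classify_antagonist <- function(inhibition_percent) {
  ifelse(inhibition_percent <= 20, "inactive", "active")
}

#' Fit the Hill concentration-inhibition equation
#'
#' Nonlinear least squares of `I = Imax / (1 + (X / IC50)^n)`, with `I` the
#' percent-of-control response at inhibitor concentration `X`. All three
#' parameters are free and kept positive through a log parameterization;
#' standard errors are asymptotic (delta method on the log-scale fit).
#' Initial values: `Imax = max(response)`, `IC50 = geometric mean of the
#' concentrations`, `n = 1`. Because percent-of-control responses carry
#' relative (constant-CV) rather than constant-variance error, points are
#' weighted by `1/I^2` by default; pass `weighting = "none"` for ordinary
#' least squares.
#'
#' @param conc_um concentrations in micromolar (>= 4 points spanning at
#'   least one log unit).
#' @param response_percent percent-of-control responses.
#' @param weighting `"relative"` (weights `1/I^2`, default) or `"none"`.
#' @return a `DoseResponseFit` list: `ic50`, `hill_n`, `i_max`, `se_ic50`,
#'   `se_n`, `converged`, `ic50_in_range`, `n_points`, and the `fit` object
#'   (NULL when the optimizer failed).
#' @export
fit_concentration_inhibition <- function(conc_um, response_percent,
                                         weighting = c("relative", "none")) {
  weighting <- match.arg(weighting)
  if (length(conc_um) < 4L) stop("need at least 4 concentration points")
  if (length(conc_um) != length(response_percent)) stop("length mismatch")
  if (any(conc_um <= 0)) stop("concentrations must be positive")
  if (diff(range(log10(conc_um))) < 1) stop("concentrations must span >= 1 log unit")
  # weights are folded into the formula (rows scaled by sqrt(w)); the tiny
  # floor only guards fully blocked (zero-response) points
  w <- if (weighting == "relative") {
    1 / pmax(response_percent, max(response_percent) * 0.001)^2
  } else {
    rep(1, length(conc_um))
  }
  df <- data.frame(x = conc_um, sw = sqrt(w),
                   yw = response_percent * sqrt(w))
  start <- list(l_imax = log(max(response_percent, 1e-6)),
                l_ic50 = mean(log(conc_um)),
                l_n = 0)
  fit <- .hill_fit_cascade(df, start)
  if (is.null(fit)) {
    return(structure(list(ic50 = NA_real_, hill_n = NA_real_,
                          i_max = NA_real_, se_ic50 = NA_real_,
                          se_n = NA_real_, converged = FALSE,
                          ic50_in_range = NA, n_points = length(conc_um),
                          fit = NULL),
                     class = "DoseResponseFit"))
  }
  cf <- stats::coef(fit)
  se_log <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(e) rep(NA_real_, 3))
  ic50 <- exp(cf[["l_ic50"]])
  hill_n <- exp(cf[["l_n"]])
  i_max <- exp(cf[["l_imax"]])
  conv <- isTRUE(fit$convInfo$isConv)
  structure(list(
    ic50 = ic50,
    hill_n = hill_n,
    i_max = i_max,
    se_ic50 = ic50 * se_log[[2]],   # delta method from the log-scale SE
    se_n = hill_n * se_log[[3]],
    converged = conv,
    ic50_in_range = ic50 >= min(conc_um) && ic50 <= max(conc_um),
    n_points = length(conc_um),
    fit = fit
  ), class = "DoseResponseFit")
}

# weighted Hill fit with fallbacks. Gauss-Newton with a scale offset comes
# first (plain relative-offset convergence breaks down on zero-residual,
# i.e. noiseless, data), then Levenberg-Marquardt, then the port algorithm.
.hill_fit_cascade <- function(df, start) {
  form <- yw ~ sw * exp(l_imax) / (1 + (x / exp(l_ic50))^exp(l_n))
  fit <- tryCatch(
    stats::nls(form, data = df, start = start,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) NULL)
  if (is.null(fit)) fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) fit <- tryCatch(
    stats::nls(form, data = df, start = start, algorithm = "port",
               control = stats::nls.control(maxiter = 200)),
    error = function(e) NULL)
  fit
}

#' @export
print.DoseResponseFit <- function(x, ...) {
  if (!isTRUE(x$converged)) cat("Hill fit did NOT converge\n")
  cat(sprintf(
    "Hill fit (%d points): IC50 = %.4g +/- %.2g uM, n = %.3g +/- %.2g, Imax = %.4g%%%s\n",
    x$n_points, x$ic50, x$se_ic50, x$hill_n, x$se_n, x$i_max,
    if (isFALSE(x$ic50_in_range)) " [IC50 outside tested range]" else ""))
  invisible(x)
}

#' Fit dose-response tables per compound
#'
#' Takes a long-format assay table (columns `compound_id`,
#' `concentration_um`, `i_pre1`, `i_pre2`, `i_test`, `sham_percent`),
#' normalizes every row with [percent_response()], and fits one Hill curve
#' per compound on the pooled normalized responses.
#'
#' @param tab the assay data frame.
#' @return data frame of per-compound fits: `compound_id`, `ic50_um`,
#'   `se_ic50`, `hill_n`, `i_max`, `converged`.
#' @export
fit_dose_response_table <- function(tab) {
  need <- c("compound_id", "concentration_um", "i_pre1", "i_pre2", "i_test",
            "sham_percent")
  stopifnot(all(need %in% names(tab)))
  pr <- percent_response(tab$i_pre1, tab$i_pre2, tab$i_test, tab$sham_percent)
  out <- lapply(split(seq_len(nrow(tab)), tab$compound_id), function(rows) {
    f <- fit_concentration_inhibition(tab$concentration_um[rows],
                                      pr$normalized_percent[rows])
    data.frame(compound_id = tab$compound_id[rows[1]],
               ic50_um = f$ic50, se_ic50 = f$se_ic50, hill_n = f$hill_n,
               i_max = f$i_max, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select model-B actives from fitted potencies
#'
#' Ids with a fitted IC50 strictly below the cutoff (500 micromolar by
#' default) - the potency gate defining the second classifier's actives.
#'
#' @param fits data frame from [fit_dose_response_table()] (or any table
#'   with `compound_id` and `ic50_um`).
#' @param cutoff potency gate in micromolar.
#' @return character vector of compound ids passing the gate.
#' @export
select_model_b_actives <- function(fits, cutoff = 500) {
  fits$compound_id[!is.na(fits$ic50_um) & fits$ic50_um < cutoff]
}

#' Larval two-choice Response Index
#'
#' `RI = (S - C) / (S + C)` over larvae counted on the stimulus and control
#' sides; +1 is complete attraction, -1 complete repulsion, 0 no preference.
#' Larvae still in the starting circle or touching the center line are
#' excluded before counting and never enter S or C.
#'
#' @param s_count larvae on the stimulus side (non-negative integer).
#' @param c_count larvae on the control side (non-negative integer).
#' @return the response index in \[-1, 1\] (vectorized).
#' @export
response_index <- function(s_count, c_count) {
  if (any(s_count < 0 | c_count < 0)) stop("counts must be non-negative")
  if (any(s_count + c_count < 1)) stop("undefined trial: no larvae left a side")
  (s_count - c_count) / (s_count + c_count)
}
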