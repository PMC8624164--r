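#' Partial ROC evaluation of a suitability surface
#'
#' Presence-only model evaluation by the partial ROC / AUC-ratio bootstrap.
#' The ROC here plots sensitivity (proportion of test occurrences whose
#' suitability meets a threshold) against the proportion of the landscape
#' predicted present at that threshold, sweeping thresholds over the
#' suitability values present in the grid. The curve is restricted to the
#' domain where sensitivity is at least `1 - E` (the acceptable omission
#' rate), and the model's trapezoidal partial AUC is divided by the partial
#' AUC of the 1:1 random-expectation line over the same domain. Ratios above
#' 1 indicate performance better than random. For each bootstrap iteration a
#' fraction of the test points is resampled with replacement; the reported
#' p-value is the proportion of bootstrap ratios at or below 1 (the
#' one-sided test of "no better than random").
#'
#' @param suitability numeric matrix (or vector) of grid suitability values;
#'   `NA` marks nodata, which is excluded from the proportion-of-area
#'   calculation.
#' @param test_suit numeric vector of suitability values extracted at the
#'   held-out test occurrences (non-nodata).
#' @param E acceptable omission rate; the curve is restricted to
#'   sensitivity >= 1 - E.
#' @param n_boot number of bootstrap iterations.
#' @param resample_frac fraction of test points resampled (with replacement)
#'   per iteration.
#' @param max_thresholds cap on the number of threshold steps (quantiles of
#'   the grid's unique values) for large grids.
#' @param seed integer seed for the bootstrap.
#' @return an object of class `partial_roc`: list with `auc_ratio` (mean of
#'   the bootstrap ratios), `ratios`, `p_value`, and the settings used.
#' @export
partial_roc <- function(suitability, test_suit, E = 0.05, n_boot = 1000,
                        resample_frac = 0.5, max_thresholds = 200,
                        seed = NULL) {
  vals <- as.vector(suitability)
  vals <- vals[!is.na(vals)]
  test_suit <- test_suit[!is.na(test_suit)]
  if (length(test_suit) < 2L)
    stop("need at least 2 test occurrences with non-nodata suitability")
  stopifnot(E > 0, E < 1, n_boot >= 1, resample_frac > 0, resample_frac <= 1)
  settings <- list(E = E, n_boot = n_boot, resample_frac = resample_frac,
                   n_test = length(test_suit), seed = seed)
  uq <- sort(unique(vals))
  if (length(uq) < 2L) {
    warning("constant suitability grid: partial ROC is degenerate; ratio 1")
    return(structure(c(list(auc_ratio = 1, ratios = rep(1, n_boot),
                            p_value = 1, degenerate = TRUE), settings),
                     class = "partial_roc"))
  }
  thr <- if (length(uq) > max_thresholds)
    unique(stats::quantile(uq, seq(0, 1, length.out = max_thresholds),
                           names = FALSE, type = 7))
  else uq
  thr <- sort(thr)
  # proportion of (non-nodata) area predicted present at each threshold
  sv <- sort(vals)
  n_cells <- length(sv)
  area <- (n_cells - findInterval(thr, sv, left.open = TRUE)) / n_cells
  m <- max(1L, ceiling(resample_frac * length(test_suit)))
  ratios <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    samp <- sort(test_suit[sample.int(length(test_suit), m, replace = TRUE)])
    sens <- (m - findInterval(thr, samp, left.open = TRUE)) / m
    keep <- sens >= 1 - E
    if (sum(keep) < 2L) return(1)  # domain too narrow to integrate
    auc_model <- trapz(area[keep], sens[keep])
    auc_null <- trapz(area[keep], area[keep])
    if (auc_null <= 0) 1 else auc_model / auc_null
  }, numeric(1)))
  structure(c(list(auc_ratio = mean(ratios), ratios = ratios,
                   p_value = mean(ratios <= 1), degenerate = FALSE),
              settings),
            class = "partial_roc")
}

#' @export
print.partial_roc <- function(x, ...) {
  cat("Partial ROC evaluation (bootstrap AUC ratio)\n")
  cat(sprintf("  mean AUC ratio: %.4f\n", x$auc_ratio))
  if (x$p_value < 1 / x$n_boot)
    cat(sprintf("  p-value: < %.4g  (no bootstrap ratio <= 1 in %d draws)\n",
                1 / x$n_boot, x$n_boot))
  else
    cat(sprintf("  p-value: %.4g\n", x$p_value))
  cat(sprintf("  E = %g, %d iterations, %.0f%% resampling of %d test points\n",
              x$E, x$n_boot, 100 * x$resample_frac, x$n_test))
  if (isTRUE(x$degenerate))
    cat("  (degenerate: constant suitability grid)\n")
  invisible(x)
}

#' @export
plot.partial_roc <- function(x, ...) {
  graphics::hist(x$ratios, breaks = 30, main = "Bootstrap AUC ratios",
                 xlab = "AUC ratio", ...)
  graphics::abline(v = 1, lty = 2, col = "red")
  invisible(x)
}
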