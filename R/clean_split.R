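#' Clean occurrences and partition into training and test sets
#'
#' Applies the standard preprocessing for envelope modelling: removes
#' exact-coordinate duplicates (to keep occurrences independent), drops
#' records falling on nodata cells or outside the grid (with a warning naming
#' them), extracts every environmental variable at each record's cell, and
#' randomly partitions the cleaned records into a training fraction
#' (default 75%) and a held-out test fraction (25%).
#'
#' The split size is `floor(train_frac * n)` training records, the remainder
#' test; e.g. 40 cleaned records at 0.75 give a 30/10 split.
#'
#' @param raw an [occurrence_table()].
#' @param stack an [env_stack()] of predictor layers.
#' @param train_frac training fraction in (0, 1).
#' @param seed integer seed controlling the random partition.
#' @return an `occurrence_set`: data.frame with columns `longitude`,
#'   `latitude`, `partition` (`"train"`/`"test"`) and one extraction column
#'   per stack variable; attributes `taxon`, `variables`, `units`, `seed`.
#' @export
clean_and_split <- function(raw, stack, train_frac = 0.75, seed = NULL) {
  stopifnot(is.env_stack(stack), train_frac > 0, train_frac < 1)
  if (nrow(raw) == 0L) stop("no occurrence records supplied")
  dup <- duplicated(raw[, c("longitude", "latitude")])
  occ <- raw[!dup, , drop = FALSE]
  ext <- extract_env(stack, occ$longitude, occ$latitude)
  on_nodata <- apply(ext, 1L, anyNA)
  if (any(on_nodata)) {
    bad <- occ[on_nodata, , drop = FALSE]
    warning(sprintf(
      "dropped %d record(s) on nodata or off-grid cells: %s",
      nrow(bad),
      paste(sprintf("(%.4f, %.4f)", bad$longitude, bad$latitude),
            collapse = " ")))
    occ <- occ[!on_nodata, , drop = FALSE]
    ext <- ext[!on_nodata, , drop = FALSE]
  }
  n <- nrow(occ)
  if (n < 2L) stop("fewer than 2 records remain after cleaning")
  n_train <- floor(train_frac * n)
  if (n_train < 1L || n_train >= n)
    stop("train or test partition would be empty")
  part <- rep("test", n)
  part[with_seed(seed, sample.int(n, n_train))] <- "train"
  out <- data.frame(longitude = occ$longitude, latitude = occ$latitude,
                    partition = part, ext,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "taxon") <- occ$taxon[1]
  attr(out, "variables") <- names(stack$layers)
  attr(out, "units") <- stack$units
  attr(out, "seed") <- seed
  class(out) <- c("occurrence_set", "data.frame")
  out
}

#' Drop collinear predictor layers by sampled Pearson correlation
#'
#' Computes pairwise Pearson correlations between all layers on a random
#' sample of non-nodata cells (default 10,000 points; with replacement when
#' the grid has fewer), then greedily removes the later-listed member of any
#' pair whose `|r|` meets the threshold, keeping the earlier variable in the
#' stack's order. Layers with zero variance on the sample are dropped with a
#' warning. Deterministic given the seed and layer order.
#'
#' @param stack an [env_stack()].
#' @param n_points number of random sample cells.
#' @param threshold absolute correlation at or above which the later layer of
#'   a pair is removed.
#' @param seed integer seed for the cell sample.
#' @return character vector of retained variable names, in stack order.
#' @export
correlation_filter <- function(stack, n_points = 10000, threshold = 0.8,
                               seed = NULL) {
  stopifnot(is.env_stack(stack), n_points >= 2, threshold > 0)
  vars <- names(stack$layers)
  if (length(vars) == 1L) return(vars)
  ok_cells <- which(!is.na(stack$layers[[1]]))
  if (length(ok_cells) == 0L) stop("stack has no non-nodata cells")
  idx <- with_seed(seed,
    ok_cells[sample.int(length(ok_cells), n_points,
                        replace = length(ok_cells) < n_points)])
  samp <- vapply(stack$layers, function(m) m[idx], numeric(length(idx)))
  sds <- apply(samp, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance layer(s) on sample: %s",
                    paste(vars[sds == 0], collapse = ", ")))
    samp <- samp[, sds > 0, drop = FALSE]
    vars <- vars[sds > 0]
  }
  if (length(vars) <= 1L) return(vars)
  r <- stats::cor(samp, method = "pearson")
  keep <- rep(TRUE, length(vars))
  for (i in seq_along(vars)) {
    if (!keep[i]) next
    for (j in seq_along(vars)) {
      if (j <= i || !keep[j]) next
      if (abs(r[i, j]) >= threshold) keep[j] <- FALSE
    }
  }
  vars[keep]
}
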