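#' Fit a Bioclim envelope niche model
#'
#' Bioclim is the classic "envelope" species-distribution algorithm: for each
#' environmental variable it records the distribution of values at the
#' training occurrences, and scores a new environment by how central each of
#' its values is within that distribution. The per-variable (marginal)
#' suitability uses the percentile-distance convention
#' \deqn{s_v(x) = \min(1, 2 \cdot \min(F_v(x), 1 - F_v(x)))}
#' where \eqn{F_v} is the midpoint empirical CDF
#' \eqn{F_v(x) = (\#\{y < x\} + 0.5\,\#\{y = x\}) / n} over the training
#' values, and \eqn{s_v(x) = 0} outside the training min–max envelope. The
#' overall suitability of a cell is the minimum marginal score across
#' variables (weakest-link aggregation), so the score is 1 at the
#' per-variable medians and falls to 0 at or beyond the envelope edges.
#'
#' An optional symmetric percentile trim (e.g. `trim = 0.05`) shrinks the
#' envelope to the 5–95% training quantiles before scoring; the default is no
#' trimming (full min–max envelope).
#'
#' @param x training data: either an `occurrence_set` from
#'   [clean_and_split()] (only its `train` partition is used) or a plain
#'   data.frame of numeric environmental values, one column per variable,
#'   one row per training occurrence.
#' @param variables variables to fit; default all environmental columns.
#' @param trim symmetric percentile trim in `[0, 0.5)`; 0 keeps the full
#'   envelope.
#' @param taxon label stored with the model (taken from the occurrence set
#'   when available).
#' @param units optional named character vector of unit strings per variable.
#' @param ... unused.
#' @return an object of class `bioclim`: per-variable sorted training values
#'   with their envelope limits, plus metadata. Methods: [predict.bioclim()],
#'   [response_curve()], `print`, `summary`, `coef`, `plot`.
#' @seealso [predict.bioclim()], [response_curve()], [overlay_conditions()]
#' @export
bioclim <- function(x, ...) UseMethod("bioclim")

#' @rdname bioclim
#' @export
bioclim.occurrence_set <- function(x, variables = NULL, trim = 0, ...) {
  variables <- variables %||% attr(x, "variables")
  train <- x[x$partition == "train", variables, drop = FALSE]
  if (nrow(train) == 0L) stop("training partition is empty")
  bioclim.data.frame(train, variables = variables, trim = trim,
                     taxon = attr(x, "taxon"),
                     units = attr(x, "units")[variables], ...)
}

#' @rdname bioclim
#' @export
bioclim.data.frame <- function(x, variables = NULL, trim = 0,
                               taxon = "species", units = NULL, ...) {
  stopifnot(trim >= 0, trim < 0.5)
  variables <- variables %||% names(x)[vapply(x, is.numeric, logical(1))]
  missing_vars <- setdiff(variables, names(x))
  if (length(missing_vars) > 0L)
    stop(sprintf("variable(s) not in data: %s",
                 paste(missing_vars, collapse = ", ")))
  if (nrow(x) == 0L) stop("no training values supplied")
  envelopes <- lapply(variables, function(v) {
    vals <- sort(as.numeric(x[[v]]))
    if (anyNA(vals)) stop(sprintf("NA training value for variable '%s'", v))
    if (trim > 0) {
      q <- stats::quantile(vals, c(trim, 1 - trim), names = FALSE, type = 7)
      vals <- vals[vals >= q[1] & vals <= q[2]]
    }
    if (vals[1] == vals[length(vals)])
      warning(sprintf(
        "variable '%s' has identical training values: envelope degenerates to a point", v))
    vals
  })
  names(envelopes) <- variables
  if (is.null(units)) units <- setNames(rep("", length(variables)), variables)
  structure(list(envelopes = envelopes, variables = variables,
                 taxon = taxon, trim = trim,
                 units = setNames(as.character(units), variables),
                 n_train = nrow(x)),
            class = "bioclim")
}

# Marginal suitability of query values `x` against sorted training values.
# Midpoint ECDF, doubled and clipped; 0 outside [min, max]; a point envelope
# scores 1 at the point and 0 elsewhere.
bioclim_marginal <- function(sorted_vals, x) {
  n <- length(sorted_vals)
  lo <- sorted_vals[1]; hi <- sorted_vals[n]
  if (lo == hi) return(ifelse(is.na(x), NA_real_, as.numeric(x == lo)))
  n_le <- findInterval(x, sorted_vals)                    # #{y <= x}
  n_lt <- findInterval(x, sorted_vals, left.open = TRUE)  # #{y <  x}
  f <- (n_lt + 0.5 * (n_le - n_lt)) / n
  s <- 2 * pmin(f, 1 - f)
  s[!is.na(x) & (x < lo | x > hi)] <- 0
  pmin(pmax(s, 0), 1)
}

#' Predict Bioclim suitability
#'
#' Scores an environmental stack (returning a suitability grid) or a
#' data.frame of environments (returning a vector). The cell score is the
#' minimum marginal score over the model's variables; nodata propagates as
#' `NA`; all scores lie in `[0, 1]`.
#'
#' @param object a fitted [bioclim()] model.
#' @param newdata an [env_stack()] containing all model variables, or a
#'   data.frame with one numeric column per model variable.
#' @param ... unused.
#' @return numeric matrix (for a stack) or vector (for a data.frame) of
#'   suitability scores.
#' @export
predict.bioclim <- function(object, newdata, ...) {
  vars <- object$variables
  if (is.env_stack(newdata)) {
    missing_vars <- setdiff(vars, names(newdata$layers))
    if (length(missing_vars) > 0L)
      stop(sprintf("stack lacks model variable(s): %s",
                   paste(missing_vars, collapse = ", ")))
    out <- NULL
    for (v in vars) {
      s <- bioclim_marginal(object$envelopes[[v]],
                            as.vector(newdata$layers[[v]]))
      out <- if (is.null(out)) s else pmin(out, s)
    }
    matrix(out, nrow = nrow(newdata$layers[[1]]))
  } else {
    newdata <- as.data.frame(newdata)
    missing_vars <- setdiff(vars, names(newdata))
    if (length(missing_vars) > 0L)
      stop(sprintf("newdata lacks model variable(s): %s",
                   paste(missing_vars, collapse = ", ")))
    out <- rep(1, nrow(newdata))
    for (v in vars)
      out <- pmin(out, bioclim_marginal(object$envelopes[[v]],
                                        as.numeric(newdata[[v]])))
    out
  }
}

#' Per-variable response curve
#'
#' Evaluates the marginal suitability of one model variable on a regular grid
#' spanning the training envelope extended by 10% of its span on each side,
#' so the zero tails outside the envelope are visible. The curve is unimodal:
#' non-decreasing up to the training median (score 1) and non-increasing
#' beyond it.
#'
#' @param model a fitted [bioclim()].
#' @param variable variable name.
#' @param n_grid number of evaluation points.
#' @return a `response_curve`: data.frame with columns `value` and
#'   `suitability`; attributes `variable`, `units`, `range` (the suitable
#'   `[training min, training max]` interval), `training` (sorted training
#'   values, for exact downstream evaluation) and `taxon`.
#' @export
response_curve <- function(model, variable, n_grid = 200) {
  stopifnot(inherits(model, "bioclim"))
  if (!variable %in% model$variables)
    stop(sprintf("variable '%s' not in model (has: %s)", variable,
                 paste(model$variables, collapse = ", ")))
  vals <- model$envelopes[[variable]]
  lo <- vals[1]; hi <- vals[length(vals)]
  span <- hi - lo
  if (span == 0) span <- max(abs(lo), 1)  # point envelope: pick a visible window
  grid <- seq(lo - 0.1 * span, hi + 0.1 * span, length.out = n_grid)
  out <- data.frame(value = grid,
                    suitability = bioclim_marginal(vals, grid))
  attr(out, "variable") <- variable
  attr(out, "units") <- unname(model$units[variable])
  attr(out, "range") <- c(lo, hi)
  attr(out, "training") <- vals
  attr(out, "taxon") <- model$taxon
  class(out) <- c("response_curve", "data.frame")
  out
}

#' All response curves of a model
#'
#' @param model a fitted [bioclim()].
#' @param n_grid evaluation points per curve.
#' @return named list of [response_curve()] objects, one per model variable.
#' @export
response_curves <- function(model, n_grid = 200) {
  setNames(lapply(model$variables, response_curve, model = model,
                  n_grid = n_grid), model$variables)
}

#' @export
print.bioclim <- function(x, ...) {
  cat(sprintf("Bioclim envelope model for '%s' (%d training occurrences)\n",
              x$taxon, x$n_train))
  if (x$trim > 0)
    cat(sprintf("  envelope trimmed to %.0f-%.0f%% training percentiles\n",
                100 * x$trim, 100 * (1 - x$trim)))
  print(coef(x))
  invisible(x)
}

#' @export
coef.bioclim <- function(object, ...) {
  t(vapply(object$variables, function(v) {
    vals <- object$envelopes[[v]]
    c(min = vals[1], median = stats::median(vals),
      max = vals[length(vals)])
  }, numeric(3)))
}

#' @export
summary.bioclim <- function(object, ...) {
  tab <- as.data.frame(coef(object))
  tab$units <- unname(object$units[rownames(tab)])
  tab$n <- vapply(object$envelopes, length, integer(1))[rownames(tab)]
  structure(list(taxon = object$taxon, n_train = object$n_train,
                 trim = object$trim, table = tab),
            class = "summary.bioclim")
}

#' @export
print.summary.bioclim <- function(x, ...) {
  cat(sprintf("Bioclim envelope model: %s\n", x$taxon))
  cat(sprintf("Training occurrences: %d; percentile trim: %g\n",
              x$n_train, x$trim))
  print(x$table)
  invisible(x)
}

#' Plot Bioclim response curves
#'
#' One panel per variable, with the suitable envelope shaded and, optionally,
#' a set of published condition intervals (e.g. the Enceladus ocean
#' conditions of [enceladus_conditions()]) overlaid as shaded bands.
#'
#' @param x a fitted [bioclim()].
#' @param conditions optional `condition_set` whose intervals (matched by
#'   variable name) are shaded on the corresponding panels.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of plotted [response_curve()]s.
#' @export
plot.bioclim <- function(x, conditions = NULL, ...) {
  curves <- response_curves(x)
  nv <- length(curves)
  old <- graphics::par(mfrow = grDevices::n2mfrow(nv), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (v in names(curves)) {
    cv <- curves[[v]]
    unit <- attr(cv, "units")
    graphics::plot(cv$value, cv$suitability, type = "l", ylim = c(0, 1),
                   xlab = if (nzchar(unit)) sprintf("%s (%s)", v, unit) else v,
                   ylab = "suitability", main = v, ...)
    rng <- attr(cv, "range")
    graphics::abline(v = rng, lty = 3, col = "grey50")
    if (!is.null(conditions)) {
      row <- conditions[conditions$variable == v, , drop = FALSE]
      if (nrow(row) == 1L)
        graphics::rect(row$lower, 0, row$upper, 1,
                       col = grDevices::adjustcolor("grey", 0.4), border = NA)
    }
  }
  invisible(curves)
}
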