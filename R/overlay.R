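#' Published Enceladus ocean condition intervals
#'
#' The default registry of environmental condition intervals inferred for
#' Enceladus' subsurface ocean from Cassini-era observations and modelling:
#' salinity 5–40 PSU (5 PSU near the plume source under the ice shell, 40 PSU
#' where hydrothermal processes occur); ascending current velocity
#' 0.01–0.05 m/s in hydrothermally driven upwelling; temperature 0–50 °C
#' spanning the ambient ocean surroundings up to the water–rock interaction
#' zones (at least 50 °C where warm fluid is expelled); and dissolved
#' silicate from 0 up to an estimated 2500 µM. Silicate estimates in the
#' literature are quoted both in µM and in µmol/m³ (a factor of 10³ apart);
#' this registry uses the µM reading and records the ambiguity in the note —
#' no silent unit conversion is ever performed.
#'
#' @return a `condition_set`: data.frame with columns `variable`, `lower`,
#'   `upper`, `units`, `note`.
#' @export
enceladus_conditions <- function() {
  df <- data.frame(
    variable = c("salinity", "current_velocity", "temperature", "silicate"),
    lower = c(5, 0.01, 0, 0),
    upper = c(40, 0.05, 50, 2500),
    units = c("PSU", "m/s", "degC", "uM"),
    note = c(
      "5 PSU under the ice shell up to 40 PSU at hydrothermal sites",
      "velocity of hydrothermally driven ascending currents",
      "ambient ocean (~0-30 degC surroundings) up to >=50 degC water-rock interaction zones",
      "up to ~2500 uM; literature also quotes >2000 umol/m3 (10^3 smaller) - no conversion applied"),
    stringsAsFactors = FALSE)
  class(df) <- c("condition_set", "data.frame")
  df
}

#' Construct a condition interval set
#'
#' @param variable,lower,upper,units,note vectors defining one interval per
#'   row; `lower <= upper` is required.
#' @return a `condition_set` data.frame.
#' @export
condition_set <- function(variable, lower, upper, units, note = "") {
  stopifnot(length(variable) == length(lower),
            length(lower) == length(upper))
  if (any(lower > upper)) stop("condition intervals need lower <= upper")
  df <- data.frame(variable = as.character(variable),
                   lower = as.numeric(lower), upper = as.numeric(upper),
                   units = rep_len(as.character(units), length(variable)),
                   note = rep_len(as.character(note), length(variable)),
                   stringsAsFactors = FALSE)
  class(df) <- c("condition_set", "data.frame")
  df
}

# Exact maximum of the marginal suitability over [a, b]: the score is
# piecewise and unimodal around the training median, so the maximum is
# attained at an interval endpoint, the median, or a training value inside
# the interval. Evaluate all candidates.
max_marginal_on_interval <- function(training, a, b) {
  if (a > b) return(0)
  cand <- unique(c(a, b, stats::median(training),
                   training[training >= a & training <= b]))
  cand <- cand[cand >= a & cand <= b]
  if (length(cand) == 0L) cand <- c(a, b)
  max(bioclim_marginal(training, cand))
}

#' Overlay condition intervals on fitted response curves
#'
#' Intersects each published condition interval (e.g. the Enceladus ocean
#' registry of [enceladus_conditions()]) with the corresponding fitted
#' suitable range, and classifies the variable as `compatible` (the condition
#' interval lies entirely within the suitable range), `partially compatible`
#' (the intervals overlap but the condition is not contained), or
#' `incompatible` (no overlap). The maximum marginal suitability attained
#' anywhere on the condition interval is reported exactly (not from the
#' discretised curve grid). Units are compared after normalisation and a
#' mismatch is an error — intervals are never converted.
#'
#' @param curves a fitted [bioclim()] model, or a (possibly named) list of
#'   [response_curve()] objects covering every condition variable.
#' @param conditions a `condition_set`; default [enceladus_conditions()]
#'   restricted to the curves' variables.
#' @return an `overlap_report`: data.frame with one row per condition
#'   (`variable`, `suit_lower`, `suit_upper`, `cond_lower`, `cond_upper`,
#'   `int_lower`, `int_upper` (`NA` when empty), `max_suitability`,
#'   `verdict`, `units`).
#' @export
overlay_conditions <- function(curves, conditions = NULL) {
  if (inherits(curves, "bioclim")) curves <- response_curves(curves)
  if (inherits(curves, "response_curve")) curves <- list(curves)
  curve_vars <- vapply(curves, attr, character(1), which = "variable")
  names(curves) <- curve_vars
  if (is.null(conditions)) {
    conditions <- enceladus_conditions()
    conditions <- conditions[conditions$variable %in% curve_vars, ,
                             drop = FALSE]
  }
  stopifnot(nrow(conditions) >= 1L)
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    v <- conditions$variable[i]
    if (!v %in% curve_vars)
      stop(sprintf("no response curve for condition variable '%s'", v))
    cv <- curves[[v]]
    cu <- attr(cv, "units")
    if (nzchar(normalize_unit(cu)) && nzchar(normalize_unit(conditions$units[i])) &&
        normalize_unit(cu) != normalize_unit(conditions$units[i]))
      stop(sprintf("unit mismatch for '%s': curve in '%s', condition in '%s'",
                   v, cu, conditions$units[i]))
    suit <- attr(cv, "range")
    a <- max(suit[1], conditions$lower[i])
    b <- min(suit[2], conditions$upper[i])
    empty <- a > b
    verdict <- if (empty) "incompatible"
      else if (conditions$lower[i] >= suit[1] &&
               conditions$upper[i] <= suit[2]) "compatible"
      else "partially compatible"
    max_s <- max_marginal_on_interval(attr(cv, "training"),
                                      conditions$lower[i],
                                      conditions$upper[i])
    data.frame(variable = v, suit_lower = suit[1], suit_upper = suit[2],
               cond_lower = conditions$lower[i],
               cond_upper = conditions$upper[i],
               int_lower = if (empty) NA_real_ else a,
               int_upper = if (empty) NA_real_ else b,
               max_suitability = max_s, verdict = verdict,
               units = conditions$units[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Condition overlay on fitted response curves\n")
  for (i in seq_len(nrow(x))) {
    int <- if (is.na(x$int_lower[i])) "empty"
      else sprintf("[%.4g, %.4g]", x$int_lower[i], x$int_upper[i])
    cat(sprintf(
      "  %-18s suitable [%.4g, %.4g] %s | condition [%.4g, %.4g] -> %s (overlap %s, max suitability %.3f)\n",
      x$variable[i], x$suit_lower[i], x$suit_upper[i], x$units[i],
      x$cond_lower[i], x$cond_upper[i], x$verdict[i], int,
      x$max_suitability[i]))
  }
  invisible(x)
}
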