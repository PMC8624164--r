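#' Default synthetic variable set
#'
#' Variable names, value ranges and units for the synthetic benthic
#' environment. The four variables mirror the predictors commonly used for
#' marine archaea at coarse scale: mean benthic temperature, salinity,
#' current velocity and silicate concentration; ranges span typical open-ocean
#' benthic values.
#'
#' @return named list; each element is `list(range = c(lo, hi), units = "...")`.
#' @export
default_variables <- function() {
  list(
    temperature      = list(range = c(-2, 40),  units = "degC"),
    salinity         = list(range = c(25, 45),  units = "PSU"),
    current_velocity = list(range = c(0, 0.5),  units = "m/s"),
    silicate         = list(range = c(0, 300),  units = "uM")
  )
}

#' Default "true" environmental envelope for the virtual species
#'
#' The middle 60% of each variable's configured range: a virtual species
#' tolerant of central conditions and excluded from extremes. Used as the
#' ground truth against which envelope recovery is measured.
#'
#' @param variables variable configuration as from [default_variables()].
#' @return named list of `c(lower, upper)` per variable.
#' @export
default_true_envelope <- function(variables = default_variables()) {
  lapply(variables, function(v) {
    span <- v$range[2] - v$range[1]
    c(v$range[1] + 0.2 * span, v$range[2] - 0.2 * span)
  })
}

# 1-D box mean with edge-aware divisor, radius r (r = 0 is identity).
box1d <- function(x, r) {
  if (r <= 0) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(n, seq_len(n) + r)
  lo <- pmax(1L, seq_len(n) - r)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Isotropic moving-average smoothing: separable box filter applied along
# rows then columns, twice (two passes approximate a bell-shaped kernel).
smooth_field <- function(m, radius, passes = 2L) {
  for (p in seq_len(passes)) {
    m <- t(apply(m, 1L, box1d, r = radius))
    m <- apply(m, 2L, box1d, r = radius)
  }
  m
}

#' Generate a synthetic environmental raster stack
#'
#' Each layer is an independent white-noise field smoothed by an isotropic
#' moving-average kernel of the given radius and min–max rescaled to the
#' configured value range, giving tunable positive spatial autocorrelation.
#' Optionally a common random nodata mask (e.g. land) is applied to all
#' layers. Output is a pure function of the arguments and `seed`.
#'
#' @param nrow,ncol grid dimensions (>= 2 each).
#' @param variables per-variable configuration, as [default_variables()].
#' @param smoothness box-kernel radius in cells; 0 gives white noise.
#' @param nodata_frac fraction of cells masked as nodata in all layers.
#' @param xll,yll,cellsize grid georeferencing (decimal degrees).
#' @param seed integer seed; same seed, same stack.
#' @return an [env_stack()].
#' @export
simulate_env_stack <- function(nrow = 100, ncol = 100,
                               variables = default_variables(),
                               smoothness = 3, nodata_frac = 0,
                               xll = 0, yll = 0, cellsize = 0.1,
                               seed = NULL) {
  stopifnot(nrow >= 2, ncol >= 2, nodata_frac >= 0, nodata_frac < 1)
  with_seed(seed, {
    mask <- matrix(FALSE, nrow, ncol)
    if (nodata_frac > 0) {
      n_mask <- floor(nodata_frac * nrow * ncol)
      mask[sample.int(nrow * ncol, n_mask)] <- TRUE
    }
    layers <- lapply(variables, function(v) {
      rng <- v$range
      if (!is.numeric(rng) || length(rng) != 2L || rng[1] >= rng[2])
        stop("degenerate variable range: min must be < max")
      f <- smooth_field(matrix(stats::runif(nrow * ncol), nrow, ncol),
                        radius = smoothness)
      f <- (f - min(f)) / (max(f) - min(f))   # min-max to [0, 1]
      f <- rng[1] + f * (rng[2] - rng[1])
      f[mask] <- NA_real_
      f
    })
    units <- vapply(variables, function(v) v$units %||% "", character(1))
    env_stack(layers, units = units, xll = xll, yll = yll,
              cellsize = cellsize)
  })
}

#' Sample virtual-species occurrences from a known envelope
#'
#' Draws `n` occurrence records from the stack's cells: with probability
#' `1 - noise` a record comes from a cell whose every envelope variable lies
#' within the true limits, and with probability `noise` from an arbitrary
#' non-nodata cell (which may itself be inside the envelope). Records are
#' placed at cell centers so raster extraction is unambiguous. Sampling is
#' with replacement; duplicates are expected and removed downstream by
#' [clean_and_split()].
#'
#' @param stack an [env_stack()].
#' @param envelope named list of `c(lower, upper)` true tolerance limits;
#'   names must be stack variables.
#' @param n number of records to draw (>= 1).
#' @param noise contamination rate in `[0, 1)`.
#' @param taxon taxon label for the generated records.
#' @param seed integer seed; same inputs and seed, same records.
#' @return an [occurrence_table()] with `n` rows.
#' @export
simulate_occurrences <- function(stack, envelope, n, noise = 0.05,
                                 taxon = "virtual_species", seed = NULL) {
  stopifnot(is.env_stack(stack), n >= 1, noise >= 0, noise < 1)
  missing_vars <- setdiff(names(envelope), names(stack$layers))
  if (length(missing_vars) > 0L)
    stop(sprintf("envelope variable(s) not in stack: %s",
                 paste(missing_vars, collapse = ", ")))
  eligible <- !is.na(stack$layers[[1]])
  inside <- eligible
  for (v in names(envelope)) {
    lim <- envelope[[v]]
    inside <- inside & !is.na(stack$layers[[v]]) &
      stack$layers[[v]] >= lim[1] & stack$layers[[v]] <= lim[2]
  }
  idx_inside <- which(inside)
  idx_eligible <- which(eligible)
  if (length(idx_inside) == 0L)
    stop("empty niche: no stack cell satisfies the true envelope")
  with_seed(seed, {
    from_noise <- stats::runif(n) < noise
    cells <- integer(n)
    cells[!from_noise] <- idx_inside[sample.int(length(idx_inside),
                                                sum(!from_noise),
                                                replace = TRUE)]
    cells[from_noise] <- idx_eligible[sample.int(length(idx_eligible),
                                                 sum(from_noise),
                                                 replace = TRUE)]
    nr <- nrow(stack$layers[[1]])
    row <- ((cells - 1L) %% nr) + 1L
    col <- ((cells - 1L) %/% nr) + 1L
    xy <- cell_center(stack, row, col)
    out <- occurrence_table(taxon, xy[, "longitude"], xy[, "latitude"],
                            source = "synthetic virtual species")
    attr(out, "true_envelope") <- envelope
    out
  })
}
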