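# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Trapezoidal integral of y over x (x need not be sorted; sorted internally).
trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (length(x) < 2L) return(0)
  sum(diff(x) * (head(y, -1L) + y[-1L]) / 2)
}

# Normalise a unit string for comparison: strip whitespace, fold the micro
# sign to "u", lower-case. "µM", "uM" and " um " all compare equal.
normalize_unit <- function(u) {
  u <- gsub("µ|μ", "u", as.character(u))
  tolower(gsub("[[:space:]]", "", u))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
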