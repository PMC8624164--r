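# Independent oracles used across tests. These deliberately use naive
# loop/enumeration implementations so they stay independent of the package's
# vectorised code paths.

# Moran's I with rook adjacency, computed directly from the definition.
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; wsum <- 0
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (i < nr) { num <- num + 2 * z[i, j] * z[i + 1, j]; wsum <- wsum + 2 }
      if (j < nc) { num <- num + 2 * z[i, j] * z[i, j + 1]; wsum <- wsum + 2 }
    }
  }
  (nr * nc / wsum) * (num / sum(z^2))
}

# Brute-force midpoint-ECDF percentile score: rank counting by explicit
# comparison loops, zero outside the min-max envelope.
brute_marginal <- function(values, x) {
  n <- length(values)
  vapply(x, function(q) {
    if (q < min(values) || q > max(values)) return(0)
    if (min(values) == max(values)) return(as.numeric(q == values[1]))
    f <- (sum(values < q) + 0.5 * sum(values == q)) / n
    min(1, 2 * min(f, 1 - f))
  }, numeric(1))
}

# Small co-registered stack from explicit matrices (row 1 = north).
make_stack <- function(..., cellsize = 1, xll = 0, yll = 0, units = NULL) {
  env_stack(list(...), units = units, xll = xll, yll = yll,
            cellsize = cellsize)
}
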