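make_fit_fixture <- function(seed = 42, n = 400, noise = 0.05,
                             nrow = 60, ncol = 60) {
  st <- simulate_env_stack(nrow = nrow, ncol = ncol, seed = seed)
  truth <- default_true_envelope()
  occ <- simulate_occurrences(st, truth, n = n, noise = noise,
                              seed = seed + 1)
  list(stack = st, truth = truth, occ = occ)
}

test_that("cleaning removes exact duplicates, drops nodata records, splits 75/25", {
  m <- matrix(seq_len(16), 4)
  m[1, 1] <- NA
  st <- make_stack(v = m)
  occ <- occurrence_table("sp",
                          longitude = c(0.5, 0.5, 1.5, 2.5, 3.5, 1.5, 2.5, 3.5),
                          latitude  = c(0.5, 0.5, 1.5, 2.5, 3.5, 0.5, 1.5, 2.5))
  # one exact duplicate pair; record at (0.5, 3.5) would be the NA cell
  occ2 <- rbind(occ, occurrence_table("sp", 0.5, 3.5))
  class(occ2) <- class(occ)
  expect_warning(os <- clean_and_split(occ2, st, seed = 1), "nodata")
  expect_equal(nrow(os), 7L)  # 9 raw - 1 dup - 1 nodata
  expect_setequal(unique(os$partition), c("train", "test"))

  # 40 cleaned records at 0.75 give exactly 30 train / 10 test
  st2 <- simulate_env_stack(nrow = 30, ncol = 30, seed = 2)
  raw <- simulate_occurrences(st2, default_true_envelope(), n = 400,
                              noise = 0, seed = 3)
  raw40 <- raw[!duplicated(raw[, c("longitude", "latitude")]), ][1:40, ]
  class(raw40) <- class(raw)
  os40 <- clean_and_split(raw40, st2, seed = 4)
  expect_equal(sum(os40$partition == "train"), 30L)
  expect_equal(sum(os40$partition == "test"), 10L)

  expect_error(clean_and_split(raw40[1, ], st2), "fewer than 2")
})

test_that("collinearity filter drops the later member of correlated pairs", {
  base <- simulate_env_stack(nrow = 50, ncol = 50,
                             variables = list(a = list(range = c(0, 1),
                                                       units = "")),
                             smoothness = 0, seed = 6)$layers$a
  noise <- simulate_env_stack(nrow = 50, ncol = 50,
                              variables = list(a = list(range = c(0, 1),
                                                        units = "")),
                              smoothness = 0, seed = 7)$layers$a
  # exact copy: r = 1, copy removed
  st <- make_stack(a = base, a_copy = base)
  expect_equal(correlation_filter(st, n_points = 2000, seed = 1), "a")

  # two independent white-noise layers: both retained
  st2 <- make_stack(a = base, b = noise)
  expect_equal(correlation_filter(st2, n_points = 2000, seed = 1),
               c("a", "b"))
  expect_lt(abs(cor(as.vector(base), as.vector(noise))), 0.2)

  # b = a + small noise (sample r well above threshold): b removed, a kept
  b <- base + 0.1 * noise
  expect_gt(cor(as.vector(base), as.vector(b)), 0.8)
  st3 <- make_stack(a = base, b = b)
  expect_equal(correlation_filter(st3, n_points = 2000, seed = 1), "a")

  # constant layer dropped with warning
  st4 <- make_stack(a = base, flat = matrix(1, 50, 50))
  expect_warning(kept <- correlation_filter(st4, n_points = 500, seed = 2),
                 "zero-variance")
  expect_equal(kept, "a")
})

test_that("marginal scores follow the midpoint ECDF and match the brute-force oracle", {
  m <- bioclim(data.frame(v = c(1, 2, 3, 4, 5)))
  s <- function(x) predict(m, data.frame(v = x))
  expect_equal(s(3), 1)          # median scores 1
  expect_equal(s(6), 0)          # outside the envelope
  expect_equal(s(0.5), 0)
  expect_equal(s(2), 0.6)        # F = 1.5/5 = 0.3 -> 2F

  # oracle equivalence on small training sets, including ties
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    vals <- sort(round(runif(n, 0, 10), 1))
    if (rep %% 3 == 0) vals[2] <- vals[1]  # force ties regularly
    mm <- bioclim(data.frame(v = vals))
    q <- c(vals, runif(20, -1, 11), vals + 1e-9)
    expect_equal(predict(mm, data.frame(v = q)),
                 brute_marginal(vals, q))
  }
})

test_that("degenerate and trimmed envelopes behave as documented", {
  expect_warning(m <- bioclim(data.frame(v = rep(3, 5))), "degenerates")
  expect_equal(suppressWarnings(predict(m, data.frame(v = c(3, 2.9, 3.1)))),
               c(1, 0, 0))

  vals <- 1:100
  mt <- bioclim(data.frame(v = vals), trim = 0.05)
  rng <- attr(response_curve(mt, "v"), "range")
  # trimming drops tail training values; the envelope is the retained range
  q <- quantile(vals, c(0.05, 0.95))
  expect_equal(rng, c(min(vals[vals >= q[1]]), max(vals[vals <= q[2]])))
  expect_equal(predict(mt, data.frame(v = c(1, 100))), c(0, 0))
})

test_that("grid prediction takes the weakest marginal and propagates nodata", {
  fx <- make_fit_fixture()
  os <- clean_and_split(fx$occ, fx$stack, seed = 2)
  m <- bioclim(os)

  # a cell at the per-variable medians scores 1
  med <- as.data.frame(lapply(m$envelopes, median))
  expect_equal(predict(m, med), 1)

  # min rule: one variable outside its envelope forces 0; 0.6 vs 1 gives 0.6
  v1 <- m$envelopes[[1]]
  below <- med; below[[1]] <- v1[1] - 1
  expect_equal(predict(m, below), 0)
  # a sub-median value in one variable caps the cell below 1 (min rule)
  mixed <- med; mixed[[1]] <- sort(v1)[ceiling(0.3 * length(v1))]
  expect_lt(predict(m, mixed), 1)
  expect_gt(predict(m, mixed), 0)

  grid <- predict(m, fx$stack)
  expect_true(all(grid >= 0 & grid <= 1, na.rm = TRUE))
  # overall score never exceeds any single marginal (weakest link)
  for (v in m$variables) {
    marg <- matrix(predict(bioclim(data.frame(x = m$envelopes[[v]])),
                           data.frame(x = as.vector(fx$stack$layers[[v]]))),
                   nrow = nrow(fx$stack$layers[[v]]))
    expect_true(all(grid <= marg + 1e-12, na.rm = TRUE))
  }

  st_na <- simulate_env_stack(nrow = 20, ncol = 20, nodata_frac = 0.2,
                              seed = 30)
  occ_na <- simulate_occurrences(st_na, default_true_envelope(), n = 200,
                                 noise = 0, seed = 31)
  os_na <- clean_and_split(occ_na, st_na, seed = 32)
  g <- predict(bioclim(os_na), st_na)
  expect_identical(is.na(g), is.na(st_na$layers[[1]]))
})

test_that("training occurrences score positive inside their own envelope", {
  fx <- make_fit_fixture(seed = 77)
  os <- clean_and_split(fx$occ, fx$stack, seed = 5)
  m <- bioclim(os)
  train <- os[os$partition == "train", m$variables]
  s <- predict(m, train)
  expect_true(all(s >= 0))
  # only records at exact envelope edges may touch low scores; interior > 0
  interior <- rep(TRUE, nrow(train))
  for (v in m$variables) {
    e <- m$envelopes[[v]]
    interior <- interior & train[[v]] > e[1] & train[[v]] < e[length(e)]
  }
  expect_true(all(s[interior] > 0))
})

test_that("response curves are unimodal with zero tails and 10% margins", {
  fx <- make_fit_fixture(seed = 15)
  os <- clean_and_split(fx$occ, fx$stack, seed = 6)
  m <- bioclim(os)
  for (v in m$variables) {
    cv <- response_curve(m, v)
    rng <- attr(cv, "range")
    vals <- m$envelopes[[v]]
    expect_equal(rng, c(vals[1], vals[length(vals)]))
    span <- diff(rng)
    expect_equal(range(cv$value), c(rng[1] - 0.1 * span, rng[2] + 0.1 * span))
    expect_true(all(cv$suitability[cv$value < rng[1] |
                                     cv$value > rng[2]] == 0))
    # non-decreasing below the median, non-increasing above
    med <- median(vals)
    expect_true(all(diff(cv$suitability[cv$value <= med]) >= -1e-12))
    expect_true(all(diff(cv$suitability[cv$value >= med]) <= 1e-12))
    # and the median itself attains the maximum
    expect_equal(predict(bioclim(data.frame(x = vals)),
                         data.frame(x = med)), 1)
  }
  expect_error(response_curve(m, "not_a_var"), "not in model")
})

test_that("fitted envelopes are contained in the truth and tighten with n", {
  st <- simulate_env_stack(nrow = 60, ncol = 60, seed = 50)
  truth <- default_true_envelope()
  hausdorff <- function(n, seed) {
    occ <- simulate_occurrences(st, truth, n = n, noise = 0, seed = seed)
    os <- clean_and_split(occ, st, seed = seed)
    m <- bioclim(os)
    d <- 0
    for (v in names(truth)) {
      e <- m$envelopes[[v]]
      fit <- c(e[1], e[length(e)])
      expect_gte(fit[1], truth[[v]][1])
      expect_lte(fit[2], truth[[v]][2])
      rel <- max(abs(fit - truth[[v]])) / diff(truth[[v]])
      d <- max(d, rel)
    }
    d
  }
  expect_lt(hausdorff(3000, 1), hausdorff(30, 1))
})
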