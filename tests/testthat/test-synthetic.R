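test_that("generated stacks are reproducible, range-clamped and autocorrelated", {
  a <- simulate_env_stack(nrow = 30, ncol = 30, seed = 11)
  b <- simulate_env_stack(nrow = 30, ncol = 30, seed = 11)
  expect_identical(a, b)

  vars <- list(x = list(range = c(0, 40), units = ""))
  st <- simulate_env_stack(nrow = 40, ncol = 40, variables = vars,
                           smoothness = 2, seed = 5)
  v <- st$layers$x
  expect_true(all(v >= 0 & v <= 40))
  expect_equal(range(v), c(0, 40))  # min-max rescaling hits both ends

  # smoothing induces positive spatial autocorrelation (Moran's I oracle);
  # white noise does not
  expect_gt(morans_i(v), 0.3)
  st0 <- simulate_env_stack(nrow = 40, ncol = 40, variables = vars,
                            smoothness = 0, seed = 5)
  expect_lt(abs(morans_i(st0$layers$x)), 0.1)

  expect_error(simulate_env_stack(variables = list(
    x = list(range = c(3, 3), units = ""))), "degenerate")
})

test_that("noiseless occurrences all fall inside the true envelope", {
  st <- simulate_env_stack(nrow = 50, ncol = 50, seed = 21)
  truth <- default_true_envelope()
  occ <- simulate_occurrences(st, truth, n = 50, noise = 0, seed = 3)
  expect_equal(nrow(occ), 50L)
  ext <- extract_env(st, occ$longitude, occ$latitude)
  for (v in names(truth)) {
    expect_true(all(ext[[v]] >= truth[[v]][1]))
    expect_true(all(ext[[v]] <= truth[[v]][2]))
  }
  # determinism
  occ2 <- simulate_occurrences(st, truth, n = 50, noise = 0, seed = 3)
  expect_identical(occ, occ2)
})

test_that("contaminated sampling matches the binomial inside-fraction expectation", {
  st <- simulate_env_stack(nrow = 60, ncol = 60, seed = 8)
  truth <- default_true_envelope()
  # count eligible cells inside the envelope directly on the stack
  inside <- !is.na(st$layers[[1]])
  for (v in names(truth))
    inside <- inside & st$layers[[v]] >= truth[[v]][1] &
      st$layers[[v]] <= truth[[v]][2]
  p_in <- mean(inside)
  eps <- 0.5; n <- 2000
  occ <- simulate_occurrences(st, truth, n = n, noise = eps, seed = 13)
  ext <- extract_env(st, occ$longitude, occ$latitude)
  in_rec <- rep(TRUE, n)
  for (v in names(truth))
    in_rec <- in_rec & ext[[v]] >= truth[[v]][1] & ext[[v]] <= truth[[v]][2]
  p_exp <- 1 - eps * (1 - p_in)
  expect_lt(abs(mean(in_rec) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("an envelope no cell satisfies is rejected", {
  st <- simulate_env_stack(nrow = 10, ncol = 10, seed = 1)
  expect_error(
    simulate_occurrences(st, list(temperature = c(1000, 2000)), n = 5),
    "empty niche")
  expect_error(
    simulate_occurrences(st, list(nope = c(0, 1)), n = 5), "not in stack")
})
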