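test_that("the hydrogen budget reproduces the published arithmetic", {
  hs <- hydrogen_supply_rate(hydrogen_budget())
  expect_equal(hs$plume_release, 2.28e19)
  expect_equal(hs$ocean_remaining, 17.72e19)
  # direct arithmetic oracle: remaining / (age * volume)
  expect_equal(hs$supply_rate, 17.72e19 / (4.56e9 * 1.70e22))

  expect_error(hydrogen_budget(plume_release_rate_max = 1e12),
               "exceeds the theoretical total")
  expect_error(hydrogen_budget(ocean_volume = -1), "positive")
})

test_that("linear growth follows X = X0 + Y*St*t with exact linearity in Y", {
  p <- growth_parameters()
  t <- c(0, 1e6, 1e9, 3.5e9)
  tr <- linear_growth(p, St = 2.31e-12, t_grid = t)
  expect_equal(tr$X[1], p$X0)                        # initial condition
  expect_equal(tr$X, p$X0 + p$Y * 2.31e-12 * t)
  expect_equal(tr$cells, tr$X / p$cell_mass)
  expect_true(!is.unsorted(tr$X))

  p0 <- growth_parameters(Y = 0)
  expect_equal(linear_growth(p0, 2.31e-12, t)$X, rep(p0$X0, 4))

  p2 <- growth_parameters(Y = 0.8)
  tr2 <- linear_growth(p2, 2.31e-12, t)
  expect_equal(tr2$X - p2$X0, 2 * (tr$X - p$X0))     # doubling Y doubles gain

  # worked value: Y 0.4 g/mol, St 2.31e-12, t 3.5e9 yr, 2e-14 g cells
  expect_equal(cells_from_biomass(0.4 * 2.31e-12 * 3.5e9, 2e-14),
               1.617e11, tolerance = 1e-3)
})

test_that("biomass-to-cell conversion is plain division", {
  expect_equal(cells_from_biomass(0), 0)
  expect_equal(cells_from_biomass(2e-14, 2e-14), 1)
  expect_error(cells_from_biomass(1, 0))
})

test_that("Monod kinetics honor half-saturation, saturation and conservation", {
  # half-saturation definition, analytically
  expect_equal(monod_rate(1e-12, mumax = 2, Ks = 1e-12), 1)

  # saturation limit: S0 >> Ks, no supply, short horizon -> exponential
  p <- growth_parameters(mumax = 1, Ks = 1e-12, Y = 0.4, X0 = 1e-12)
  t <- seq(0, 5, length.out = 21)
  tr <- monod_growth(p, S0 = 1e-6, supply = 0, t_grid = t)
  expect_true(all(tr$S / (1e-12 + tr$S) > 0.99))
  expect_equal(tr$X, p$X0 * exp(p$mumax * t), tolerance = 1e-4)

  # conservation of X + Y*S with zero supply, at every output time
  p2 <- growth_parameters(mumax = 3, Ks = 5e-10, Y = 0.4, X0 = 1e-11)
  tr2 <- monod_growth(p2, S0 = 2e-9, supply = 0,
                      t_grid = seq(0, 50, length.out = 101))
  total <- tr2$X + p2$Y * tr2$S
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-6)
  # substrate exhausts and biomass plateaus at X0 + Y*S0
  expect_equal(tr2$X[101], p2$X0 + p2$Y * 2e-9, tolerance = 1e-6)
  expect_true(all(diff(tr2$X) >= -1e-20))
})

test_that("spatial scenarios give the whole-ocean and stripe-scaled concentrations", {
  fo <- scenario_concentration(scenario = "full_ocean", t = 3.5e9)
  hy <- scenario_concentration(scenario = "hydrothermal", t = 3.5e9)
  expect_equal(hy$supply_rate / fo$supply_rate, 0.09)
  expect_equal(hy$cells / fo$cells, 0.09, tolerance = 1e-6)
  expect_s3_class(fo$trajectory, "growth_trajectory")
  expect_equal(max(fo$trajectory$time), 3.5e9)
  expect_error(scenario_concentration(scenario = "warp_core"))

  # t -> 0+ recovers the initial inoculum of 1 cell/cm^3
  tiny <- scenario_concentration(scenario = "full_ocean", t = 1e-8)
  expect_equal(tiny$cells, 1, tolerance = 1e-6)
})

test_that("every default constant is registered with units and provenance", {
  tab <- growth_constants()
  expect_true(all(nzchar(tab$units)))
  expect_true(all(nzchar(tab$provenance)))
  b <- hydrogen_budget()
  expect_equal(b$plume_release_rate_max,
               tab$value[tab$name == "plume_release_rate_max"])
  p <- growth_parameters()
  expect_equal(p$Y, tab$value[tab$name == "yield_H2"])
  expect_equal(p$X0, 2e-14)  # one cell per cm^3 in mass units
})
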