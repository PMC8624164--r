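test_that("the default condition registry carries the published intervals", {
  cond <- enceladus_conditions()
  expect_s3_class(cond, "condition_set")
  row <- function(v) cond[cond$variable == v, ]
  expect_equal(unlist(row("salinity")[, c("lower", "upper")],
                      use.names = FALSE), c(5, 40))
  expect_equal(row("salinity")$units, "PSU")
  expect_equal(unlist(row("current_velocity")[, c("lower", "upper")],
                      use.names = FALSE), c(0.01, 0.05))
  expect_equal(row("current_velocity")$units, "m/s")
  expect_equal(row("silicate")$upper, 2500)
  expect_equal(row("temperature")$upper, 50)
})

test_that("verdicts follow the interval arithmetic exactly", {
  # curve with suitable salinity range [30, 41]
  sal <- response_curve(bioclim(data.frame(salinity = seq(30, 41, 0.5)),
                                units = c(salinity = "PSU")), "salinity")
  rep1 <- overlay_conditions(list(sal),
                             condition_set("salinity", 5, 40, "PSU"))
  expect_equal(rep1$verdict, "partially compatible")
  expect_equal(c(rep1$int_lower, rep1$int_upper), c(30, 40))

  # silicate envelope topping out at 150 vs condition [2000, 2500]: disjoint
  sil <- response_curve(bioclim(data.frame(silicate = seq(10, 150, 10)),
                                units = c(silicate = "uM")), "silicate")
  rep2 <- overlay_conditions(list(sil),
                             condition_set("silicate", 2000, 2500, "uM"))
  expect_equal(rep2$verdict, "incompatible")
  expect_true(is.na(rep2$int_lower))
  expect_equal(rep2$max_suitability, 0)

  # condition interval equal to the suitable range: contained
  rep3 <- overlay_conditions(list(sal),
                             condition_set("salinity", 30, 41, "PSU"))
  expect_equal(rep3$verdict, "compatible")
  expect_equal(rep3$max_suitability, 1)  # interval includes the median
})

test_that("maximum suitability on an interval is evaluated exactly", {
  vals <- c(1, 2, 3, 4, 5)
  cv <- response_curve(bioclim(data.frame(v = vals)), "v")
  # on [1.5, 2]: score is maximised at 2, where F = 0.3 -> 0.6
  rep <- overlay_conditions(list(cv), condition_set("v", 1.5, 2, ""))
  expect_equal(rep$max_suitability, 0.6)
  # interval covering the median attains 1
  rep2 <- overlay_conditions(list(cv), condition_set("v", 2, 4, ""))
  expect_equal(rep2$max_suitability, 1)
})

test_that("unit mismatches and missing curves are fatal; order is immaterial", {
  sal <- response_curve(bioclim(data.frame(salinity = seq(30, 41, 0.5)),
                                units = c(salinity = "PSU")), "salinity")
  expect_error(
    overlay_conditions(list(sal), condition_set("salinity", 5, 40, "g/kg")),
    "unit mismatch")
  expect_error(
    overlay_conditions(list(sal), condition_set("temperature", 0, 50, "degC")),
    "no response curve")
  # micro-sign spelling variants compare equal
  sil <- response_curve(bioclim(data.frame(silicate = 1:10),
                                units = c(silicate = "uM")), "silicate")
  expect_silent(overlay_conditions(list(sil),
                                   condition_set("silicate", 0, 5, "µM")))

  two <- condition_set(c("salinity", "silicate"), c(5, 0), c(40, 5),
                       c("PSU", "uM"))
  fwd <- overlay_conditions(list(sal, sil), two)
  rev <- overlay_conditions(list(sal, sil), two[2:1, ])
  expect_equal(fwd[order(fwd$variable), ], rev[order(rev$variable), ],
               ignore_attr = TRUE)
})
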