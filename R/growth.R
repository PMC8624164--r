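#' Physical and kinetic constants for the Enceladus biomass model
#'
#' Single registry of the default constants used by the hydrogen budget and
#' growth calculations, each with units and a provenance note describing the
#' observational or laboratory source. All defaults elsewhere in the growth
#' module are drawn from this table.
#'
#' @return data.frame with columns `name`, `value`, `units`, `provenance`.
#' @export
growth_constants <- function() {
  data.frame(
    name = c("plume_release_rate_max", "theoretical_total_H2",
             "solar_system_age", "ocean_volume", "ocean_thickness",
             "seafloor_area", "stripe_area_fraction", "yield_H2",
             "cell_mass", "X0_cells", "life_horizon"),
    value = c(5e9, 20e19, 4.56e9, 1.70e22, 28.5, 1.3e11, 0.09, 0.4,
              2e-14, 1, 3.5e9),
    units = c("mol H2/yr", "mol H2", "yr", "cm^3", "km", "m^2", "-",
              "g dry weight/mol H2", "g/cell", "cell/cm^3", "yr"),
    provenance = c(
      "upper bound of the observed plume H2 escape flux (1-5e9 mol/yr)",
      "theoretical maximum H2 yield of aqueous oxidation of reduced core minerals",
      "age of the solar system",
      "subsurface ocean volume for an average ocean-layer thickness of ~28.5 km",
      "average ocean-layer thickness",
      "seafloor surface area associated with the south-polar hydrothermal field",
      "fraction of the surface area covered by the south-polar tiger stripes",
      "growth yield of Methanobacterium thermoautotrophicum on H2 (65 degC, pH 7), insensitive to substrate concentration",
      "dry mass of an individual methanogen cell",
      "assumed initial inoculum concentration",
      "time comparable to the history of life on Earth"),
    stringsAsFactors = FALSE)
}

const_value <- function(name) {
  tab <- growth_constants()
  tab$value[match(name, tab$name)]
}

#' Hydrogen budget of the Enceladus ocean
#'
#' Bundles the quantities needed to derive a volumetric hydrogen supply rate:
#' the maximum plume escape rate, the theoretical total H2 producible by
#' water–rock chemistry over the age of the solar system, the ocean volume
#' and geometry, and the tiger-stripe area fraction defining the
#' hydrothermal scenario. Defaults come from [growth_constants()].
#'
#' @param plume_release_rate_max maximum plume H2 escape rate, mol/yr.
#' @param theoretical_total_H2 theoretical total H2 yield, mol.
#' @param solar_system_age yr.
#' @param ocean_volume cm^3.
#' @param ocean_thickness km.
#' @param seafloor_area m^2.
#' @param stripe_area_fraction dimensionless fraction of surface area covered
#'   by the south-polar stripes.
#' @return an object of class `hydrogen_budget`.
#' @export
hydrogen_budget <- function(
    plume_release_rate_max = const_value("plume_release_rate_max"),
    theoretical_total_H2 = const_value("theoretical_total_H2"),
    solar_system_age = const_value("solar_system_age"),
    ocean_volume = const_value("ocean_volume"),
    ocean_thickness = const_value("ocean_thickness"),
    seafloor_area = const_value("seafloor_area"),
    stripe_area_fraction = const_value("stripe_area_fraction")) {
  vals <- c(plume_release_rate_max, theoretical_total_H2, solar_system_age,
            ocean_volume, ocean_thickness, seafloor_area,
            stripe_area_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all hydrogen-budget quantities must be positive and finite")
  if (plume_release_rate_max * solar_system_age > theoretical_total_H2)
    stop("plume release over the solar system age exceeds the theoretical total H2")
  structure(list(plume_release_rate_max = plume_release_rate_max,
                 theoretical_total_H2 = theoretical_total_H2,
                 solar_system_age = solar_system_age,
                 ocean_volume = ocean_volume,
                 ocean_thickness = ocean_thickness,
                 seafloor_area = seafloor_area,
                 stripe_area_fraction = stripe_area_fraction),
            class = "hydrogen_budget")
}

#' Volumetric hydrogen supply rate from the budget
#'
#' The hydrogen available to methanogens is the theoretical total production
#' minus what the plume has vented over the age of the solar system; assuming
#' production and release at a constant rate into the ocean volume, the
#' volumetric supply rate is
#' \deqn{S_t = \frac{H_{tot} - r_{plume} \cdot t_{age}}{t_{age} \cdot V_{ocean}}}
#' in mol H2 cm^-3 yr^-1.
#'
#' @param budget a [hydrogen_budget()].
#' @return object of class `hydrogen_supply`: list with `plume_release`
#'   (mol vented over the solar system age), `ocean_remaining` (mol left for
#'   the ocean) and `supply_rate` (mol cm^-3 yr^-1).
#' @export
hydrogen_supply_rate <- function(budget = hydrogen_budget()) {
  stopifnot(inherits(budget, "hydrogen_budget"))
  released <- budget$plume_release_rate_max * budget$solar_system_age
  remaining <- budget$theoretical_total_H2 - released
  if (remaining < 0) stop("negative remaining hydrogen")
  structure(list(plume_release = released, ocean_remaining = remaining,
                 supply_rate = remaining /
                   (budget$solar_system_age * budget$ocean_volume)),
            class = "hydrogen_supply")
}

#' @export
print.hydrogen_supply <- function(x, ...) {
  cat("Hydrogen budget\n")
  cat(sprintf("  vented by plume over solar-system age: %.3g mol H2\n",
              x$plume_release))
  cat(sprintf("  remaining for the ocean:               %.4g mol H2\n",
              x$ocean_remaining))
  cat(sprintf("  volumetric supply rate St:             %.4g mol H2 cm^-3 yr^-1\n",
              x$supply_rate))
  invisible(x)
}

#' Growth parameters for hydrogenotrophic methanogens
#'
#' `Y` (biomass yield on H2) and `cell_mass` drive both growth paths; `mumax`
#' and `Ks` are required only by the Monod ODE path and ship as documented
#' placeholders (no field-constrained values exist for Enceladus conditions),
#' so the ODE path is used for structural/kinetic exploration, not for the
#' headline concentration estimates.
#'
#' @param mumax maximum specific growth rate, yr^-1 (ODE path only;
#'   placeholder default).
#' @param Ks Monod half-saturation constant, mol H2/cm^3 (ODE path only;
#'   placeholder default).
#' @param Y biomass growth yield, g dry weight per mol H2.
#' @param X0 initial biomass, g/cm^3 (default: one cell per cm^3).
#' @param cell_mass dry mass of one cell, g.
#' @return object of class `growth_parameters`.
#' @export
growth_parameters <- function(mumax = 1, Ks = 1e-12,
                              Y = const_value("yield_H2"),
                              X0 = const_value("X0_cells") *
                                const_value("cell_mass"),
                              cell_mass = const_value("cell_mass")) {
  stopifnot(Y >= 0, cell_mass > 0, X0 >= 0)
  structure(list(mumax = mumax, Ks = Ks, Y = Y, X0 = X0,
                 cell_mass = cell_mass),
            class = "growth_parameters")
}

#' Monod specific growth rate
#'
#' \eqn{\mu(S) = \mu_{max} S / (K_s + S)}; at `S = Ks` the rate is exactly
#' half of `mumax`.
#'
#' @param S substrate concentration, mol/cm^3.
#' @param mumax maximum specific growth rate, yr^-1.
#' @param Ks half-saturation constant, mol/cm^3.
#' @return specific growth rate, yr^-1.
#' @export
monod_rate <- function(S, mumax, Ks) mumax * pmax(S, 0) / (Ks + pmax(S, 0))

#' Convert biomass concentration to cell concentration
#'
#' @param X biomass, g/cm^3.
#' @param cell_mass dry mass per cell, g.
#' @return cells/cm^3.
#' @export
cells_from_biomass <- function(X, cell_mass = const_value("cell_mass")) {
  stopifnot(cell_mass > 0)
  X / cell_mass
}

new_growth_trajectory <- function(times, S, X, cell_mass, scenario) {
  out <- data.frame(time = times, S = S, X = X,
                    cells = cells_from_biomass(X, cell_mass))
  attr(out, "scenario") <- scenario
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' Supply-limited linear biomass growth
#'
#' When every mole of supplied hydrogen is converted to biomass
#' (consumption balances supply), the yield relation `dX/dt = -Y dS/dt`
#' integrates to the linear solution \eqn{X(t) = X_0 + Y S_t t}, where
#' \eqn{S_t} is the constant volumetric substrate supply rate. The `S`
#' column of the trajectory reports the cumulative substrate consumed,
#' \eqn{S_t \cdot t}.
#'
#' @param params [growth_parameters()] (only `Y`, `X0`, `cell_mass` used).
#' @param St volumetric substrate supply rate, mol H2 cm^-3 yr^-1.
#' @param t_grid non-negative, increasing times in yr.
#' @param scenario label stored on the trajectory.
#' @return a `growth_trajectory`: data.frame `time`, `S` (cumulative mol
#'   consumed per cm^3), `X` (g/cm^3), `cells` (cells/cm^3).
#' @export
linear_growth <- function(params, St, t_grid, scenario = "linear") {
  stopifnot(inherits(params, "growth_parameters"), St >= 0,
            all(t_grid >= 0), !is.unsorted(t_grid))
  X <- params$X0 + params$Y * St * t_grid
  new_growth_trajectory(t_grid, St * t_grid, X, params$cell_mass, scenario)
}

#' Monod growth ODE
#'
#' Integrates the substrate-explicit Monod system
#' \deqn{dX/dt = \mu_{max} \frac{S}{K_s + S} X, \qquad
#'       dS/dt = \mathrm{supply} - \frac{1}{Y} \mu_{max} \frac{S}{K_s + S} X}
#' with an adaptive stiff-capable integrator ([deSolve::lsoda()]). Substrate
#' is clamped at zero; with `supply = 0` the combination `X + Y S` is a
#' conserved quantity, which bounds the integration error. (As a published
#' shorthand this system is sometimes written with a minus sign on the
#' biomass equation; growth requires the positive sign used here, consistent
#' with the yield relation `dX/dt = -Y dS/dt`.)
#'
#' @param params [growth_parameters()] with positive `mumax`, `Ks`, `Y`.
#' @param S0 initial substrate concentration, mol/cm^3 (>= 0).
#' @param supply constant volumetric substrate supply, mol cm^-3 yr^-1.
#' @param t_grid output times, yr (non-negative, increasing).
#' @param rtol,atol integrator tolerances.
#' @return a `growth_trajectory` (`S` is the instantaneous substrate
#'   concentration).
#' @export
monod_growth <- function(params, S0, supply = 0, t_grid,
                         rtol = 1e-10, atol = 1e-30) {
  stopifnot(inherits(params, "growth_parameters"),
            params$mumax > 0, params$Ks > 0, params$Y > 0, S0 >= 0,
            all(t_grid >= 0), !is.unsorted(t_grid))
  derivs <- function(t, y, p) {
    mu <- monod_rate(y[["S"]], p$mumax, p$Ks)
    list(c(X = mu * y[["X"]], S = supply - mu * y[["X"]] / p$Y))
  }
  times <- unique(c(0, t_grid))
  sol <- deSolve::lsoda(c(X = params$X0, S = S0), times, derivs, params,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("Monod ODE integration failed: ",
         paste(attr(sol, "istate"), collapse = " "))
  sol <- sol[match(t_grid, sol[, "time"]), , drop = FALSE]
  S <- sol[, "S"]
  tol_neg <- max(atol, 1e-12 * max(S0, params$Ks))
  if (any(S < -tol_neg))
    stop(sprintf("substrate went negative beyond tolerance (min %.3g)",
                 min(S)))
  S <- pmax(S, 0)
  new_growth_trajectory(sol[, "time"], S, sol[, "X"], params$cell_mass,
                        "monod")
}

#' Cell concentration under the two spatial scenarios
#'
#' Evaluates the supply-limited linear solution at time `t` under either
#' spatial bookkeeping: `full_ocean` uses the whole-ocean volumetric supply
#' rate (methanogens consume all hydrogen not vented by the plume);
#' `hydrothermal` confines growth to the water column above the south-polar
#' hydrothermal field by scaling the supply rate by the tiger-stripe area
#' fraction (default 0.09). Returns the cell concentration and its nearest
#' order of magnitude.
#'
#' @param params [growth_parameters()].
#' @param budget [hydrogen_budget()].
#' @param scenario `"full_ocean"` or `"hydrothermal"`.
#' @param t evaluation time, yr (> 0).
#' @param t_grid optional time grid for the returned trajectory; default 200
#'   log-spaced points over `[1e6, t]`.
#' @return list with `scenario`, `t`, `supply_rate` (the scaled rate used),
#'   `cells` (cells/cm^3 at `t`), `order_of_magnitude`
#'   (`round(log10(cells))`) and `trajectory` (a `growth_trajectory`).
#' @export
scenario_concentration <- function(params = growth_parameters(),
                                   budget = hydrogen_budget(),
                                   scenario = c("full_ocean", "hydrothermal"),
                                   t = const_value("life_horizon"),
                                   t_grid = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(t > 0)
  St <- hydrogen_supply_rate(budget)$supply_rate
  if (scenario == "hydrothermal") St <- St * budget$stripe_area_fraction
  if (is.null(t_grid))
    t_grid <- exp(seq(log(min(1e6, t)), log(t), length.out = 200))
  t_grid <- sort(unique(c(t_grid, t)))
  traj <- linear_growth(params, St, t_grid, scenario = scenario)
  cells_t <- cells_from_biomass(params$X0 + params$Y * St * t,
                                params$cell_mass)
  list(scenario = scenario, t = t, supply_rate = St, cells = cells_t,
       order_of_magnitude = round(log10(cells_t)), trajectory = traj)
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("Growth trajectory [%s]: %d time points over %.3g - %.3g yr\n",
              attr(x, "scenario"), nrow(x), min(x$time), max(x$time)))
  cat(sprintf("  final biomass %.4g g/cm^3 = %.4g cells/cm^3\n",
              x$X[nrow(x)], x$cells[nrow(x)]))
  invisible(x)
}

#' @export
plot.growth_trajectory <- function(x, log = "xy", ...) {
  ok <- x$time > 0 & x$cells > 0
  graphics::plot(x$time[ok], x$cells[ok], type = "l", log = log,
                 xlab = "time (yr)", ylab = "cells / cm^3",
                 main = attr(x, "scenario"), ...)
  invisible(x)
}
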