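#' Default sectoral damage-function parameters
#'
#' Coefficient tables for the three temperature-driven damage sectors.
#' Energy: a per-region slope (change in energy expenditures as a share of
#' GDP per K of warming) for 12 regions. Mortality: per-region point
#' estimate and standard error of the fractional change in all-cause
#' mortality per K for 10 regions, monetized with an income-scaled value of
#' a statistical life (US 2020 base $10.05 million, income elasticity 1).
#' Agriculture: 1990 agriculture share of GDP for 16 regions, income
#' elasticity 0.31 of that share, and low/central/high piecewise-linear
#' welfare-cost functions with knots at 1, 2, 3 K. The packaged coefficient
#' values are synthetic but plausible placeholders at the documented scale;
#' all can be overridden with externally supplied tables.
#'
#' @param ... Named overrides.
#' @return Object of class `damage_params`.
#' @export
damage_params <- function(...) {
  ag_central <- outer(seq(0.4, 1.6, length.out = 16),
                      c(0.03, 0.10, 0.20))          # 16 regions x 3 knots
  p <- list(
    energy_beta = c(0.0028, 0.0012, 0.0035, 0.0019, 0.0008, 0.0042,
                    0.0022, 0.0015, 0.0031, 0.0010, 0.0025, 0.0017),
    mort_beta_mean = c(0.032, 0.011, -0.004, 0.024, 0.045, 0.008,
                       0.017, -0.002, 0.028, 0.013),
    mort_beta_se = c(0.012, 0.006, 0.005, 0.010, 0.018, 0.004,
                     0.008, 0.004, 0.011, 0.006),
    vsl_base = 10.05e6, vsl_elasticity = 1,
    ag_sigma = seq(0.03, 0.30, length.out = 16),
    ag_eps = 0.31,
    ag_knots = c(1, 2, 3),
    ag_f_low = ag_central + outer(rep(1, 16), c(-0.05, -0.08, -0.10)),
    ag_f_central = ag_central,
    ag_f_high = ag_central + outer(rep(1, 16), c(0.04, 0.12, 0.22)),
    ag_extend = TRUE,          # extend final linear segment beyond 3 K
    gdppc1990_ratio = 0.65     # country 1990 GDP pc as a fraction of 2020
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(all(p$ag_sigma >= 0 & p$ag_sigma <= 1), all(p$mort_beta_se >= 0),
            length(p$energy_beta) >= 1)
  class(p) <- "damage_params"
  p
}

#' Map countries to a sector's native regions
#'
#' Deterministic round-robin assignment of country codes to region indices
#' (12 energy, 10 mortality, 16 agriculture regions). A custom map may be
#' supplied as a data frame with columns `country` and `region`; every
#' country must then be covered (unknown country is a hard error).
#'
#' @param countries Character vector of country codes.
#' @param sector `"energy"`, `"mortality"` or `"agriculture"`.
#' @param map Optional data frame overriding the default assignment.
#' @return Integer vector of region indices, one per country.
#' @export
region_map <- function(countries, sector = c("energy", "mortality", "agriculture"),
                       map = NULL) {
  sector <- match.arg(sector)
  nreg <- c(energy = 12, mortality = 10, agriculture = 16)[[sector]]
  if (is.null(map)) {
    return(as.integer((seq_along(countries) - 1L) %% nreg + 1L))
  }
  idx <- map$region[match(countries, map$country)]
  if (anyNA(idx)) {
    stop("countries missing from ", sector, " region map: ",
         paste(countries[is.na(idx)], collapse = ", "))
  }
  if (any(idx < 1 | idx > nreg)) stop("region index outside 1..", nreg)
  as.integer(idx)
}

# Temperature series aligned to a scenario draw's years (2020-2300).
align_temp <- function(climate, years) {
  temp <- climate$temp[match(years, climate$years)]
  if (anyNA(temp)) stop("climate path does not cover scenario years")
  temp
}

# Light container for one sector's damages.
sector_slice <- function(sector, years, countries, dollars, ...) {
  structure(list(sector = sector, years = years, countries = countries,
                 dollars = dollars, ...), class = "sector_slice")
}

#' @export
print.sector_slice <- function(x, ...) {
  tot <- colSums(x$dollars)
  cat(sprintf("%s damages: %d countries, %d-%d; 2100 total %.3g USD/yr\n",
              x$sector, nrow(x$dollars), min(x$years), max(x$years),
              tot[match(2100, x$years)]))
  invisible(x)
}

#' Fit through-origin energy damage coefficients
#'
#' Regresses the net change in energy expenditures as a proportion of GDP
#' on global temperature rise, per region, with the intercept fixed at zero
#' (no expenditure change at zero warming): `beta = sum(x*y) / sum(x^2)`.
#'
#' @param table Data frame with columns `region`, `temp` (K) and `share`
#'   (expenditure-share change), at least 2 points per region.
#' @return Named numeric vector of per-region coefficients.
#' @export
fit_energy_coefficients <- function(table) {
  stopifnot(all(c("region", "temp", "share") %in% names(table)))
  vapply(split(table, table$region), function(d) {
    if (nrow(d) < 2) stop("need at least 2 points per region")
    sxx <- sum(d$temp^2)
    if (sxx == 0) stop("through-origin fit undefined: all temperatures zero")
    sum(d$temp * d$share) / sxx
  }, numeric(1))
}

#' Energy expenditure damages
#'
#' `share_{i,t} = beta_{j(i)} * T_t`; dollars are the share times country
#' GDP. Linear in temperature and homogeneous of degree one in GDP.
#'
#' @param draw `scen_draw`.
#' @param climate `climate_path`.
#' @param params `damage_params`.
#' @param map Optional country-to-region map (see [region_map()]).
#' @return A `sector_slice` with country-level dollars per year.
#' @export
energy_damages <- function(draw, climate, params = damage_params(), map = NULL) {
  temp <- align_temp(climate, draw$years)
  reg <- region_map(draw$countries, "energy", map)
  beta <- params$energy_beta[reg]
  frac <- outer(beta, temp)
  gdp <- draw$pop * draw$gdppc
  sector_slice("energy", draw$years, draw$countries, frac * gdp)
}

#' Sample mortality damage coefficients
#'
#' Draws per-region mortality slopes from normal distributions centred on
#' the point estimates with standard deviation equal to the reported
#' standard errors. A zero standard error returns the point estimate.
#'
#' @param params `damage_params`.
#' @param seed Integer seed.
#' @return Numeric vector (one slope per mortality region, 1/K).
#' @export
sample_mortality_beta <- function(params = damage_params(), seed = 1L) {
  with_seed(seed, stats::rnorm(length(params$mort_beta_mean),
                               params$mort_beta_mean, params$mort_beta_se))
}

#' Temperature-related mortality damages
#'
#' Excess deaths are `beta_{j(i)} * T_t * Population_{i,t} * (baseline
#' mortality rate)_{i,t}`; they are monetized at the country-year value of
#' a statistical life `VSL_{i,t} = VSL_base * (gdppc_{i,t} /
#' gdppc_{US,2020})^elasticity`. Excess deaths are not capped at baseline
#' deaths; the number of country-years where they exceed baseline deaths is
#' reported as a diagnostic.
#'
#' @param draw `scen_draw` (must contain country `"USA"` or supply
#'   `gdppc_ref`).
#' @param climate `climate_path`.
#' @param beta Sampled per-region slopes from [sample_mortality_beta()].
#' @param params `damage_params`.
#' @param map Optional country-to-region map.
#' @param gdppc_ref Reference GDP per capita for the VSL income scaling
#'   (default: the draw's USA value in 2020).
#' @return `sector_slice` with `dollars`, `excess_deaths`, `vsl`, and
#'   `n_exceed_baseline`.
#' @export
mortality_damages <- function(draw, climate, beta, params = damage_params(),
                              map = NULL, gdppc_ref = NULL) {
  if (any(draw$mortrate < 0)) stop("negative baseline mortality rate")
  temp <- align_temp(climate, draw$years)
  reg <- region_map(draw$countries, "mortality", map)
  if (is.null(gdppc_ref)) {
    iu <- match("USA", draw$countries)
    if (is.na(iu)) stop("draw has no 'USA' country; supply gdppc_ref")
    gdppc_ref <- draw$gdppc[iu, 1]
  }
  baseline_deaths <- draw$pop * draw$mortrate
  excess <- beta[reg] * outer(rep(1, length(reg)), temp) * baseline_deaths
  vsl <- params$vsl_base * (draw$gdppc / gdppc_ref)^params$vsl_elasticity
  sector_slice("mortality", draw$years, draw$countries, vsl * excess,
               excess_deaths = excess, vsl = vsl,
               n_exceed_baseline = sum(abs(excess) > baseline_deaths))
}

#' Sample the agriculture damage-function weight
#'
#' One draw from a triangular distribution with lower bound 0, mode 0.5 and
#' upper bound 1, by inverse-CDF sampling. The weight selects the blend of
#' the low/central/high agricultural damage functions (anchors 0, 0.5, 1).
#'
#' @param seed Integer seed.
#' @param n Number of draws.
#' @return Numeric vector in `[0, 1]`.
#' @export
sample_ag_weight <- function(seed = 1L, n = 1L) {
  u <- with_seed(seed, stats::runif(n))
  ifelse(u < 0.5, sqrt(u / 2), 1 - sqrt((1 - u) / 2))
}

# Blend the low/central/high knot tables at weight theta (anchors 0/0.5/1,
# nearest-pair linear interpolation). Returns 16 x 3 knot-value matrix.
ag_blend <- function(theta, params) {
  stopifnot(theta >= 0, theta <= 1)
  if (theta <= 0.5) {
    w <- theta / 0.5
    (1 - w) * params$ag_f_low + w * params$ag_f_central
  } else {
    w <- (theta - 0.5) / 0.5
    (1 - w) * params$ag_f_central + w * params$ag_f_high
  }
}

# Evaluate the blended piecewise-linear damage function at temperatures tv
# for every region: linear from the origin to the 1 K knot, between knots,
# and (optionally) extending the final segment beyond 3 K. Negative
# temperatures clamp to zero with a warning. Returns regions x time.
ag_f_eval <- function(fknots, tv, knots = c(1, 2, 3), extend = TRUE) {
  if (any(tv < 0)) {
    warning("negative temperature anomaly clamped to 0 in agriculture damages")
    tv <- pmax(tv, 0)
  }
  xk <- c(0, knots)
  nreg <- nrow(fknots)
  out <- matrix(0, nreg, length(tv))
  for (r in seq_len(nreg)) {
    yk <- c(0, fknots[r, ])
    tt <- pmin(tv, max(xk))
    base <- approx(xk, yk, xout = tt, rule = 2)$y
    over <- pmax(tv - max(xk), 0)
    slope_end <- (yk[length(yk)] - yk[length(yk) - 1]) /
      (xk[length(xk)] - xk[length(xk) - 1])
    out[r, ] <- base + if (extend) over * slope_end else 0
  }
  out
}

#' Agricultural damages
#'
#' `AgPctCost_{i,t} = sigma_{j(i)} * (gdppc_{i,t} / gdppc_{i,1990})^{-eps}
#' * f_theta(T_t)`, where `f_theta` is the weight-blended piecewise-linear
#' damage function (knots at 1, 2, 3 K; linear from the origin below 1 K)
#' and `sigma` the 1990 agriculture share of GDP. Dollars are the share
#' times country GDP; negative values are beneficial effects.
#'
#' @param draw `scen_draw`.
#' @param climate `climate_path`.
#' @param theta Triangular weight in `[0, 1]` from [sample_ag_weight()].
#' @param params `damage_params`.
#' @param map Optional country-to-region map.
#' @param gdppc1990 Optional countries-length vector of 1990 GDP per
#'   capita; defaults to `gdppc1990_ratio` times the 2020 value.
#' @return `sector_slice` with country-level dollars.
#' @export
agriculture_damages <- function(draw, climate, theta,
                                params = damage_params(), map = NULL,
                                gdppc1990 = NULL) {
  temp <- align_temp(climate, draw$years)
  reg <- region_map(draw$countries, "agriculture", map)
  if (is.null(gdppc1990)) gdppc1990 <- params$gdppc1990_ratio * draw$gdppc[, 1]
  fk <- ag_blend(theta, params)
  fT <- ag_f_eval(fk, temp, params$ag_knots, params$ag_extend)   # 16 x T
  income <- (draw$gdppc / gdppc1990)^(-params$ag_eps)
  pct <- params$ag_sigma[reg] * income * fT[reg, , drop = FALSE]
  gdp <- draw$pop * draw$gdppc
  sector_slice("agriculture", draw$years, draw$countries, pct * gdp,
               theta = theta)
}
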