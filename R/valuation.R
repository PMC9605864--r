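#' Discounting specification
#'
#' The packaged (rho, eta) pairs are calibrated to near-term average
#' risk-free discount rates of 1.5, 2, 2.5 and 3 percent: (0.01%, 1.02),
#' (0.2%, 1.24), (0.5%, 1.42) and (0.8%, 1.57) respectively. `rho` is the
#' pure rate of time preference (per year) and `eta` the elasticity of
#' marginal utility of consumption.
#'
#' @param rate Near-term rate label: one of `"1.5"`, `"2.0"`, `"2.5"`,
#'   `"3.0"` (numeric 1.5/2/2.5/3 accepted).
#' @return Object of class `discount_spec` with `rho`, `eta`, `label`.
#' @export
discount_spec <- function(rate = "2.0") {
  pairs <- list(`1.5` = c(rho = 0.0001, eta = 1.02),
                `2.0` = c(rho = 0.002, eta = 1.24),
                `2.5` = c(rho = 0.005, eta = 1.42),
                `3.0` = c(rho = 0.008, eta = 1.57))
  key <- sprintf("%.1f", as.numeric(rate))
  if (!key %in% names(pairs)) {
    stop("invalid near-term rate '", rate, "'; valid rates: ",
         paste(names(pairs), collapse = ", "), call. = FALSE)
  }
  p <- pairs[[key]]
  structure(list(rho = unname(p["rho"]), eta = unname(p["eta"]), label = key),
            class = "discount_spec")
}

#' @export
print.discount_spec <- function(x, ...) {
  cat(sprintf("Discounting: near-term %s%% (rho = %.2f%%, eta = %.2f)\n",
              x$label, 100 * x$rho, x$eta))
  invisible(x)
}

#' Pulse specification
#'
#' The marginal-emissions experiment: a `mass_MtC` pulse of CO2 added in
#' `year`; results are normalized per tonne of CO2 using the 44/12 CO2/C
#' mass ratio, so the per-tonne divisor is `mass_MtC * 1e6 * 44 / 12` tCO2.
#'
#' @param year Pulse year (default 2020).
#' @param mass_MtC Pulse mass in MtC (default 0.1).
#' @return Object of class `pulse_spec`.
#' @export
pulse_spec <- function(year = 2020, mass_MtC = 0.1) {
  stopifnot(mass_MtC > 0)
  structure(list(year = year, mass_MtC = mass_MtC,
                 tco2 = mass_MtC * 1e6 * 44 / 12),
            class = "pulse_spec")
}

#' World per-capita consumption path
#'
#' `c_t = (world GDP - total damages) / world population`, floored at a
#' small positive constant so marginal utility stays finite in extreme
#' draws; the number of floored years is reported. Passing zero damages
#' gives the gross path.
#'
#' @param draw `scen_draw`.
#' @param damages_total Numeric vector of total damages (USD/yr) aligned
#'   with `draw$years`, or 0.
#' @param floor Consumption floor (USD/person/yr, default 100).
#' @return List with `c` (USD/person/yr), `n_floored`, `years`.
#' @export
consumption_path <- function(draw, damages_total = 0, floor = 100) {
  gdp <- draw$world$pop * draw$world$gdppc
  cc <- (gdp - damages_total) / draw$world$pop
  nf <- sum(cc < floor)
  list(c = pmax(cc, floor), n_floored = nf, years = draw$years)
}

#' Stochastic discount factor path
#'
#' `SDF_t = (1 + rho)^-(t - 2020) * (c_t / c_2020)^-eta`, so `SDF_2020 = 1`
#' by construction.
#'
#' @param c_t Consumption path (USD/person/yr), first element is 2020.
#' @param spec `discount_spec`.
#' @param years Years matching `c_t` (default 2020-2300).
#' @return Numeric vector of discount factors.
#' @export
sdf_path <- function(c_t, spec, years = seq(2020, length.out = length(c_t))) {
  if (is.list(c_t)) { years <- c_t$years; c_t <- c_t$c }
  (1 + spec$rho)^-(years - years[1]) * (c_t / c_t[1])^-spec$eta
}

# Sum a list of sector slices into a sector x year damage matrix.
sector_totals <- function(slices) {
  t(vapply(slices, function(s) colSums(s$dollars), numeric(length(slices[[1]]$years))))
}

#' Marginal damages per tonne of CO2
#'
#' Differences damages between a pulsed and a baseline run (which share
#' every sampled parameter) summed over sectors and regions, normalized by
#' the pulse mass in tCO2.
#'
#' @param base,pulsed Lists of `sector_slice` objects (same sectors, same
#'   order).
#' @param pulse `pulse_spec`.
#' @return List with `md` (total USD/tCO2 by year), `md_sector` (sector x
#'   year matrix), `years`.
#' @export
marginal_damage_path <- function(base, pulsed, pulse = pulse_spec()) {
  stopifnot(length(base) == length(pulsed))
  mb <- sector_totals(base)
  mp <- sector_totals(pulsed)
  md_sector <- (mp - mb) / pulse$tco2
  rownames(md_sector) <- vapply(base, `[[`, character(1), "sector")
  list(md = colSums(md_sector), md_sector = md_sector,
       years = base[[1]]$years)
}

#' Present-value SC-CO2 from one draw
#'
#' The inner product of the stochastic discount factors and the marginal
#' damages over 2020-2300.
#'
#' @param md Marginal damages (USD/tCO2 by year).
#' @param sdf Discount factors, same length.
#' @return Scalar SC-CO2 (USD per tCO2).
#' @export
scc_from_draw <- function(md, sdf) {
  stopifnot(length(md) == length(sdf))
  sum(sdf * md)
}

#' Sectoral partial SC-CO2
#'
#' Partial values use only one sector's marginal damages but the same
#' discount-factor path as the total (built from the consumption path net
#' of all-sector damages), so sectoral partials sum exactly to the total.
#'
#' @param md_sector Sector x year marginal-damage matrix.
#' @param sdf Discount factors.
#' @return Named vector of partial SC-CO2 values by sector.
#' @export
partial_scc <- function(md_sector, sdf) {
  drop(md_sector %*% sdf)
}

#' Realized near-term discount rate
#'
#' The average over the first decade (2021-2030) and over draws of
#' `r_t = rho + eta * g_t`, where `g_t` is the annualized average
#' consumption growth rate from the pulse year to year t.
#'
#' @param spec `discount_spec`.
#' @param cons A consumption path (vector or [consumption_path()] output),
#'   or a list of them (one per draw).
#' @return Mean near-term rate in percent per year.
#' @export
near_term_rate <- function(spec, cons) {
  one <- function(cp) {
    cc <- if (is.list(cp)) cp$c else cp
    h <- 2:11                      # 2021-2030 relative to 2020
    g <- (cc[h] / cc[1])^(1 / (h - 1)) - 1
    mean(spec$rho + spec$eta * g)
  }
  if (is.list(cons) && !is.null(cons$c)) return(100 * one(cons))
  if (is.numeric(cons)) return(100 * one(cons))
  100 * mean(vapply(cons, one, numeric(1)))
}

#' Implicit GDP price deflator table
#'
#' Approximate annual implicit GDP price deflator index used to express
#' results in 2020 US dollars. Values are an approximation of the US
#' national-accounts deflator (2012 = 100).
#'
#' @return Data frame with `year` and `index`.
#' @export
gdp_deflator <- function() {
  data.frame(
    year = c(2000, 2005, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017,
             2018, 2019, 2020, 2021, 2022, 2023),
    index = c(81.0, 90.0, 96.1, 98.1, 100.0, 101.8, 103.6, 104.7, 105.7,
              107.9, 110.3, 112.3, 113.6, 118.4, 126.7, 131.4)
  )
}

#' Convert dollar values to 2020 USD
#'
#' Multiplies by the ratio of the 2020 deflator index to the base-year
#' index.
#'
#' @param value Dollar amount(s) in `base_year` dollars.
#' @param base_year Year the input values are expressed in.
#' @param table Deflator table (columns `year`, `index`).
#' @return Value(s) in 2020 USD.
#' @export
to_2020_usd <- function(value, base_year, table = gdp_deflator()) {
  i0 <- match(base_year, table$year)
  i1 <- match(2020, table$year)
  if (is.na(i0)) stop("base year ", base_year, " not in deflator table")
  value * table$index[i1] / table$index[i0]
}
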