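#' Default quantile anchors for the scenario generator
#'
#' The generator is calibrated to printed summary quantiles of long-run
#' probabilistic socioeconomic projections: world population in 2300
#' (5/50/95 percentiles, persons), the cumulative time-average world
#' per-capita GDP growth rate over 2020-2300 (percent per year), and global
#' net CO2 emissions in 2100 (GtCO2 per year, possibly negative).
#'
#' @return A named list of anchor sets, each a numeric vector
#'   `c(q05, q50, q95)`, plus point anchors (2020 levels, population peak).
#' @export
default_anchors <- function() {
  list(
    pop2300    = c(q05 = 2.8e9, q50 = 7.3e9, q95 = 2.1e10),
    growth     = c(q05 = 0.17, q50 = 0.88, q95 = 2.7),     # % / yr
    co2_2100   = c(q05 = -7, q50 = 17, q95 = 62),          # GtCO2 / yr
    pop2020    = 7.8e9,
    pop_peak   = 11e9,        # median peak level
    peak_year  = 2130,        # median peak year
    peak_year_sd = 15,
    gdppc2020  = 11000,       # world mean, constant 2020 USD
    gdppc_usa2020 = 63000,
    co2_2020   = 42.5,        # GtCO2 / yr
    ch4_2020   = 375,         # Mt / yr
    n2o_2020   = 10           # Mt / yr
  )
}

#' Calibrate the scenario generator from quantile anchors
#'
#' Builds a generator configuration whose sampled trajectories reproduce the
#' anchor quantiles. World population in 2300, cumulative-average growth and
#' 2100 net CO2 emissions are monotone transforms of standard normal shape
#' variables constructed so the 5/50/95 anchors are matched exactly in the
#' transform (and therefore to Monte Carlo error in any finite sample).
#'
#' @param anchors A list as returned by [default_anchors()]; entries may be
#'   overridden individually.
#' @param sensitivity Growth-emissions coupling in `[-0.99, 0.99]`: the
#'   Gaussian-copula correlation between the growth and emissions shape
#'   variables. `0` decouples them.
#' @param n_countries Number of countries for disaggregated draws (>= 1).
#' @param post2100_decline Relative decline rate of net CO2 emissions after
#'   2100 (per year).
#' @param growth_tilt Front-loading of per-capita growth: annual log-growth
#'   declines linearly in time by this relative amplitude while preserving
#'   the cumulative average exactly.
#' @param share_sd Annual standard deviation of the multiplicative random
#'   walk of country population shares (0 freezes shares at base-year
#'   values).
#' @param deterministic If TRUE, all shape variables are pinned at their
#'   medians, so every draw is the central trajectory (used to switch
#'   scenario uncertainty off entirely).
#' @return An object of class `scen_config`.
#' @export
calibrate_generator <- function(anchors = default_anchors(),
                                sensitivity = 0.5,
                                n_countries = 184,
                                post2100_decline = 0.01,
                                growth_tilt = 0.4,
                                share_sd = 0.002,
                                deterministic = FALSE) {
  a <- utils::modifyList(default_anchors(), anchors)
  check_ordered_anchors(a$pop2300, "pop2300")
  check_ordered_anchors(a$growth, "growth")
  check_ordered_anchors(a$co2_2100, "co2_2100")
  stopifnot(a$peak_year >= 2020, a$peak_year <= 2300, n_countries >= 1,
            abs(sensitivity) <= 0.99)
  cfg <- list(anchors = a,
              sensitivity = sensitivity,
              n_countries = as.integer(n_countries),
              post2100_decline = post2100_decline,
              growth_tilt = growth_tilt,
              share_sd = share_sd,
              deterministic = deterministic,
              years = 2020:2300)
  class(cfg) <- "scen_config"
  cfg
}

#' @export
print.scen_config <- function(x, ...) {
  a <- x$anchors
  cat("Scenario generator configuration\n")
  cat(sprintf("  countries: %d, years: %d-%d\n", x$n_countries,
              min(x$years), max(x$years)))
  cat(sprintf("  pop 2300 [5/50/95]: %.1f/%.1f/%.1f billion\n",
              a$pop2300[1] / 1e9, a$pop2300[2] / 1e9, a$pop2300[3] / 1e9))
  cat(sprintf("  growth 2020-2300 [5/50/95]: %.2f/%.2f/%.2f %%/yr\n",
              a$growth[1], a$growth[2], a$growth[3]))
  cat(sprintf("  CO2 2100 [5/50/95]: %.0f/%.0f/%.0f GtCO2/yr; coupling %.2f\n",
              a$co2_2100[1], a$co2_2100[2], a$co2_2100[3], x$sensitivity))
  invisible(x)
}

# World-trajectory core: given n x 3 standard-normal shape variables plus a
# peak-year draw, return annual world paths. Vectorized over draws.
world_paths <- function(cfg, z_pop, z_g, u_e, t_peak) {
  a <- cfg$anchors
  yrs <- cfg$years
  ny <- length(yrs)
  n <- length(z_pop)

  # --- population: lognormal-anchored 2300 level; log-Gaussian bump shape
  p2300 <- qanchor(z_pop, a$pop2300[1], a$pop2300[2], a$pop2300[3], log = TRUE)
  s_k <- log(a$pop2300[3] / a$pop_peak) / stats::qnorm(0.95)
  peak <- pmax(a$pop_peak * exp(z_pop * s_k), p2300 * (1 + 1e-9), a$pop2020 * 1.001)
  tp <- ifelse(peak <= p2300 * (1 + 1e-6), 2300, pmin(pmax(t_peak, 2040), 2295))
  s_left <- (tp - 2020)^2 / log(peak / a$pop2020)
  s_right <- ifelse(tp >= 2300, Inf, (2300 - tp)^2 / log(peak / p2300))
  tmat <- matrix(yrs, n, ny, byrow = TRUE)
  dpre <- (tmat - tp)^2 / s_left
  dpost <- (tmat - tp)^2 / s_right
  pop <- exp(log(peak) - ifelse(tmat <= tp, dpre, dpost))

  # --- GDP per capita: cumulative-average growth anchored; growth declines
  #     linearly in time (tilt) with the cumulative average preserved.
  g_cum <- qanchor(z_g, a$growth[1], a$growth[2], a$growth[3], log = FALSE)
  L <- log1p(g_cum / 100)                      # mean annual log growth
  tau <- (seq_len(ny - 1) - 0.5) / (ny - 1)    # (0,1), mean exactly 1/2
  tilt <- 1 + cfg$growth_tilt * (1 - 2 * tau)  # sums to ny-1 exactly
  loginc <- outer(L, tilt)                     # n x (ny-1)
  gdppc <- a$gdppc2020 * exp(cbind(0, t(apply(loginc, 1, cumsum))))

  # --- net CO2 emissions: coupled shape variable, cosine ramp to the
  #     anchored 2100 level, relative decline afterwards.
  lam <- cfg$sensitivity
  z_e <- lam * z_g + sqrt(1 - lam^2) * u_e
  e2100 <- qanchor(z_e, a$co2_2100[1], a$co2_2100[2], a$co2_2100[3], log = FALSE)
  ramp <- (1 + cos(pi * pmin(yrs - 2020, 80) / 80)) / 2    # 1 -> 0 over 2020-2100
  co2 <- matrix(ramp, n, ny, byrow = TRUE) * a$co2_2020 +
    (1 - matrix(ramp, n, ny, byrow = TRUE)) * e2100
  post <- pmax(tmat - 2100, 0)
  co2 <- ifelse(post > 0, e2100 * exp(-cfg$post2100_decline * post), co2)

  # --- CH4 / N2O: declining anchor paths scaled by an emissions-coupled
  #     lognormal factor (keeps them positive and co-moving with CO2).
  ch4_base <- 100 + (a$ch4_2020 - 100) * exp(-(yrs - 2020) / 80)
  n2o_base <- 6 + (a$n2o_2020 - 6) * exp(-(yrs - 2020) / 100)
  ch4 <- exp(0.30 * z_e) %o% ch4_base
  n2o <- exp(0.15 * z_e) %o% n2o_base

  list(years = yrs, pop = pop, gdppc = gdppc, co2 = co2, ch4 = ch4, n2o = n2o,
       g_cum = g_cum, e2100 = e2100, p2300 = p2300)
}

#' Sample an ensemble of world-level scenario trajectories
#'
#' Fast vectorized sampler of the world aggregates (population, mean GDP per
#' capita, global CO2/CH4/N2O emissions) underlying full scenario draws.
#' Used for generator calibration checks and ensemble quantiles; a full
#' country-resolved draw built by [sample_scenario()] with the same config
#' and seed index shares the identical world path.
#'
#' @param config A `scen_config` from [calibrate_generator()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return An object of class `scen_ensemble`: a list of `n x 281` matrices
#'   `pop`, `gdppc`, `co2`, `ch4`, `n2o`, the per-draw cumulative-average
#'   growth `g_cum` (%/yr), and `years`.
#' @export
sample_world_ensemble <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "scen_config"), n >= 1)
  zs <- if (isTRUE(config$deterministic)) {
    list(z_pop = rep(0, n), z_g = rep(0, n), u_e = rep(0, n),
         t_peak = rep(config$anchors$peak_year, n))
  } else {
    with_seed(seed, {
      list(z_pop = stats::rnorm(n), z_g = stats::rnorm(n),
           u_e = stats::rnorm(n),
           t_peak = stats::rnorm(n, config$anchors$peak_year,
                                 config$anchors$peak_year_sd))
    })
  }
  out <- world_paths(config, zs$z_pop, zs$z_g, zs$u_e, zs$t_peak)
  out$seed <- seed
  class(out) <- "scen_ensemble"
  out
}

# Country scaffolding shared by all draws from one config: codes, base-year
# population shares and income factors. Country 1 is the USA (needed as the
# VSL income reference); remaining codes are synthetic.
country_frame <- function(cfg) {
  nc <- cfg$n_countries
  codes <- c("USA", sprintf("C%03d", seq_len(max(nc - 1, 0))))[seq_len(nc)]
  w <- seq_len(nc)^-0.8
  shares <- w / sum(w)
  # USA holds ~4% of world population in the base year
  if (nc > 1) {
    shares <- c(0.043, shares[-1] / sum(shares[-1]) * (1 - 0.043))
  } else {
    shares <- 1
  }
  f_usa <- cfg$anchors$gdppc_usa2020 / cfg$anchors$gdppc2020
  lf <- seq(log(0.08), log(4.5), length.out = nc)
  lf[1] <- log(f_usa)
  list(codes = codes, shares0 = shares, logf0 = lf)
}

#' Sample one full country-resolved scenario draw
#'
#' Draws a joint realization of country population, GDP per capita and
#' baseline all-cause mortality rate plus global CO2/CH4/N2O emissions for
#' 2020-2300. The world path is identical to draw `draw_id` of
#' [sample_world_ensemble()] under the same config and seed. Country
#' population shares follow a slow multiplicative random walk around
#' base-year shares (renormalized each year, so country populations sum to
#' the world total exactly); country income factors converge slowly toward
#' the world frontier and are renormalized so the population-weighted mean
#' GDP per capita equals the world value exactly. Baseline mortality rates
#' follow a deterministic schedule declining with GDP per capita.
#'
#' @param config A `scen_config`.
#' @param seed Integer seed (the ensemble master seed).
#' @param draw_id Which draw of the ensemble to resolve (default 1).
#' @return An object of class `scen_draw` with matrices `pop`, `gdppc`,
#'   `mortrate` (countries x years), vectors `co2`, `ch4`, `n2o`, `years`,
#'   `countries`, and `world = list(pop, gdppc)`.
#' @export
sample_scenario <- function(config, seed = 1L, draw_id = 1L) {
  stopifnot(inherits(config, "scen_config"), draw_id >= 1)
  ens <- sample_world_ensemble(config, draw_id, seed)
  yrs <- ens$years
  ny <- length(yrs)
  nc <- config$n_countries
  cf <- country_frame(config)

  cseed <- derive_seed(seed, draw_id, "scenario")
  eps <- if (config$share_sd > 0) {
    with_seed(cseed, matrix(stats::rnorm(nc * (ny - 1), sd = config$share_sd),
                            nc, ny - 1))
  } else {
    matrix(0, nc, ny - 1)
  }

  shares <- matrix(NA_real_, nc, ny)
  shares[, 1] <- cf$shares0
  for (j in 2:ny) {
    s <- shares[, j - 1] * exp(eps[, j - 1])
    shares[, j] <- s / sum(s)
  }
  wpop <- ens$pop[draw_id, ]
  pop <- shares * matrix(wpop, nc, ny, byrow = TRUE)

  conv <- exp(-0.003 * (yrs - 2020))          # log income gap decay
  logf <- outer(cf$logf0, conv)
  f <- exp(logf)
  wm <- colSums(shares * f)                   # population-weighted mean factor
  f <- f / matrix(wm, nc, ny, byrow = TRUE)
  wgdppc <- ens$gdppc[draw_id, ]
  gdppc <- f * matrix(wgdppc, nc, ny, byrow = TRUE)

  mortrate <- pmin(pmax(0.05 * gdppc^-0.2, 0.001), 0.04)

  structure(list(
    years = yrs, countries = cf$codes,
    pop = pop, gdppc = gdppc, mortrate = mortrate,
    co2 = ens$co2[draw_id, ], ch4 = ens$ch4[draw_id, ], n2o = ens$n2o[draw_id, ],
    world = list(pop = wpop, gdppc = wgdppc),
    draw_id = as.integer(draw_id), seed = seed
  ), class = "scen_draw")
}

#' @export
print.scen_draw <- function(x, ...) {
  cat(sprintf("Scenario draw %d (seed %s): %d countries, %d-%d\n",
              x$draw_id, format(x$seed), length(x$countries),
              min(x$years), max(x$years)))
  cat(sprintf("  world pop 2100/2300: %.1f / %.1f billion\n",
              x$world$pop[x$years == 2100] / 1e9,
              x$world$pop[x$years == 2300] / 1e9))
  cat(sprintf("  net CO2 2100: %.1f GtCO2/yr\n", x$co2[x$years == 2100]))
  invisible(x)
}

validate_scen_draw <- function(d) {
  stopifnot(inherits(d, "scen_draw"))
  if (any(d$pop <= 0)) stop("scenario draw has non-positive population")
  if (any(d$gdppc <= 0)) stop("scenario draw has non-positive GDP per capita")
  if (any(d$mortrate <= 0 | d$mortrate >= 1)) {
    stop("baseline mortality rate outside (0, 1)")
  }
  if (!identical(as.integer(d$years), 2020:2300)) {
    stop("scenario years must cover 2020-2300 with no gaps")
  }
  invisible(d)
}

#' Empirical quantiles of scenario ensembles
#'
#' Computes empirical quantiles (the default linear-interpolation convention,
#' `stats::quantile` type 7) of a scenario variable at one year across draws.
#'
#' @param x A `scen_ensemble`, or a list of `scen_draw` objects.
#' @param variable One of `"pop"`, `"gdppc"`, `"co2"`, `"ch4"`, `"n2o"`
#'   (world-level at `year`), or `"growth"` (cumulative-average per-capita
#'   growth 2020-2300, %/yr; `year` ignored).
#' @param year Calendar year in 2020-2300.
#' @param probs Probabilities strictly inside (0, 1).
#' @return Named numeric vector of quantiles, monotone in `probs`.
#' @export
scenario_quantiles <- function(x, variable, year = 2300,
                               probs = c(0.05, 0.5, 0.95)) {
  stopifnot(all(probs > 0 & probs < 1))
  vars <- c("pop", "gdppc", "co2", "ch4", "n2o", "growth")
  if (!variable %in% vars) {
    stop("unknown variable '", variable, "'; expected one of: ",
         paste(vars, collapse = ", "))
  }
  if (inherits(x, "scen_ensemble")) {
    vals <- if (variable == "growth") {
      x$g_cum
    } else {
      x[[variable]][, match(year, x$years)]
    }
  } else {
    if (length(x) < 2) stop("need at least 2 draws")
    vals <- vapply(x, function(d) {
      if (variable == "growth") {
        ny <- length(d$years)
        100 * ((d$world$gdppc[ny] / d$world$gdppc[1])^(1 / (ny - 1)) - 1)
      } else if (variable %in% c("co2", "ch4", "n2o")) {
        d[[variable]][match(year, d$years)]
      } else {
        w <- d$world[[variable]] %||%
          colSums(d[[variable]] * d$pop) / colSums(d$pop)
        if (variable == "pop") w <- colSums(d$pop)
        w[match(year, d$years)]
      }
    }, numeric(1))
  }
  if (anyNA(vals)) stop("year ", year, " not covered by the ensemble")
  stats::quantile(vals, probs = probs, type = 7)
}

#' Write scenario draws to a long-format CSV
#'
#' Long format with columns `draw_id, variable, country, year, value`;
#' world-level series use country code `"WLD"`. Variables are `pop`,
#' `gdppc`, `mortrate` (per country) and `co2`, `ch4`, `n2o` (global).
#'
#' @param draws A list of `scen_draw` objects.
#' @param path Output CSV path.
#' @export
write_scenarios <- function(draws, path) {
  if (inherits(draws, "scen_draw")) draws <- list(draws)
  rows <- lapply(draws, function(d) {
    ny <- length(d$years); nc <- length(d$countries)
    cc <- rep(d$countries, times = ny)
    yy <- rep(d$years, each = nc)
    rbind(
      data.frame(draw_id = d$draw_id, variable = "pop", country = cc,
                 year = yy, value = as.vector(d$pop)),
      data.frame(draw_id = d$draw_id, variable = "gdppc", country = cc,
                 year = yy, value = as.vector(d$gdppc)),
      data.frame(draw_id = d$draw_id, variable = "mortrate", country = cc,
                 year = yy, value = as.vector(d$mortrate)),
      data.frame(draw_id = d$draw_id, variable = "co2", country = "WLD",
                 year = d$years, value = d$co2),
      data.frame(draw_id = d$draw_id, variable = "ch4", country = "WLD",
                 year = d$years, value = d$ch4),
      data.frame(draw_id = d$draw_id, variable = "n2o", country = "WLD",
                 year = d$years, value = d$n2o)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Load scenario draws from a long-format CSV
#'
#' Reads the format written by [write_scenarios()] (and used for externally
#' supplied scenario ensembles). Validates completeness: every draw must
#' cover every year 2020-2300 for every country and global series; missing
#' years or countries are a hard error naming the gaps.
#'
#' @param path CSV path.
#' @return A list of `scen_draw` objects.
#' @export
load_scenarios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("draw_id", "variable", "country", "year", "value")
  if (!all(need %in% names(df))) {
    stop("scenario file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  yrs <- 2020:2300
  lapply(split(df, df$draw_id), function(dd) {
    cx <- sort(unique(dd$country[dd$country != "WLD"]))
    if ("USA" %in% cx) cx <- c("USA", setdiff(cx, "USA"))
    grab_c <- function(v) {
      sub <- dd[dd$variable == v, ]
      miss <- setdiff(yrs, unique(sub$year))
      if (length(miss)) {
        stop("draw ", dd$draw_id[1], " variable '", v, "' missing years: ",
             paste(utils::head(miss, 10), collapse = ", "))
      }
      m <- matrix(NA_real_, length(cx), length(yrs),
                  dimnames = list(cx, yrs))
      m[cbind(match(sub$country, cx), match(sub$year, yrs))] <- sub$value
      if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)
        stop("draw ", dd$draw_id[1], " variable '", v, "' missing country/year ",
             cx[bad[1, 1]], "/", yrs[bad[1, 2]])
      }
      m
    }
    grab_g <- function(v) {
      sub <- dd[dd$variable == v & dd$country == "WLD", ]
      miss <- setdiff(yrs, sub$year)
      if (length(miss)) {
        stop("draw ", dd$draw_id[1], " global '", v, "' missing years: ",
             paste(utils::head(miss, 10), collapse = ", "))
      }
      sub$value[match(yrs, sub$year)]
    }
    pop <- grab_c("pop")
    if (any(pop < 0)) stop("negative population in draw ", dd$draw_id[1])
    gdppc <- grab_c("gdppc")
    mort <- grab_c("mortrate")
    wpop <- colSums(pop)
    d <- structure(list(
      years = yrs, countries = cx, pop = pop, gdppc = gdppc, mortrate = mort,
      co2 = grab_g("co2"), ch4 = grab_g("ch4"), n2o = grab_g("n2o"),
      world = list(pop = wpop, gdppc = colSums(gdppc * pop) / wpop),
      draw_id = as.integer(dd$draw_id[1]), seed = NA_real_
    ), class = "scen_draw")
    validate_scen_draw(d)
  })
}
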