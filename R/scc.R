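#' Run configuration for SC-CO2 estimation
#'
#' Collects everything a run needs: input mode, fidelity knobs, sampled-
#' parameter sources, sector toggles, the pulse specification, and the
#' consumption convention for discounting.
#'
#' @param mode `"synthetic"` (sample everything from the calibrated
#'   generator and priors) or `"data"` (use supplied `scenarios` /
#'   parameter tables).
#' @param scenario_config `scen_config` for synthetic scenario draws.
#' @param scenarios Optional list of `scen_draw` (data mode).
#' @param climate_source `"default-priors"`, a data frame, or a CSV path.
#' @param sealevel_source `"prior-sampler"`, a data frame, or a CSV path.
#' @param damage_parameters `damage_params()`.
#' @param sectors Character subset of
#'   `c("energy", "mortality", "agriculture", "coastal")`.
#' @param pulse `pulse_spec()`.
#' @param n_segments Number of synthetic coastal segments.
#' @param segments Optional `coastal_segments` table (overrides
#'   `n_segments`).
#' @param consumption `"net"` (GDP minus damages; default) or `"gross"`.
#' @param consumption_floor USD/person/yr floor for marginal utility.
#' @param coastal_period Coastal planning-period length (years).
#' @param capital_ratio Coastal exposed capital per person as a multiple of
#'   mean GDP per capita.
#' @return Object of class `scc_config`.
#' @export
scc_config <- function(mode = c("synthetic", "data"),
                       scenario_config = calibrate_generator(),
                       scenarios = NULL,
                       climate_source = "default-priors",
                       sealevel_source = "prior-sampler",
                       damage_parameters = damage_params(),
                       sectors = c("energy", "mortality", "agriculture", "coastal"),
                       pulse = pulse_spec(),
                       n_segments = 500,
                       segments = NULL,
                       consumption = c("net", "gross"),
                       consumption_floor = 100,
                       coastal_period = 50,
                       capital_ratio = 3) {
  mode <- match.arg(mode)
  consumption <- match.arg(consumption)
  sectors <- match.arg(sectors, several.ok = TRUE)
  if (mode == "data" && is.null(scenarios)) {
    stop("data mode requires 'scenarios' (see load_scenarios())")
  }
  structure(list(mode = mode, scenario_config = scenario_config,
                 scenarios = scenarios, climate_source = climate_source,
                 sealevel_source = sealevel_source,
                 damage_parameters = damage_parameters, sectors = sectors,
                 pulse = pulse, n_segments = n_segments, segments = segments,
                 consumption = consumption,
                 consumption_floor = consumption_floor,
                 coastal_period = coastal_period,
                 capital_ratio = capital_ratio),
            class = "scc_config")
}

# All sector damages for one model state (shared by baseline and pulse).
run_damages <- function(draw, climate, slr, segments, mort_beta, theta,
                        config) {
  out <- list()
  dp <- config$damage_parameters
  if ("energy" %in% config$sectors) {
    out$energy <- energy_damages(draw, climate, dp)
  }
  if ("mortality" %in% config$sectors) {
    out$mortality <- mortality_damages(draw, climate, mort_beta, dp)
  }
  if ("agriculture" %in% config$sectors) {
    out$agriculture <- suppressWarnings(
      agriculture_damages(draw, climate, theta, dp))
  }
  if ("coastal" %in% config$sectors) {
    out$coastal <- coastal_sector_damages(segments, slr, draw,
                                          period_length = config$coastal_period,
                                          capital_ratio = config$capital_ratio,
                                          keep_plans = FALSE)
  }
  out
}

# One complete Monte Carlo draw: joint parameter sampling, paired
# baseline/pulse runs with common random numbers, marginal damages,
# discounting. Returns the per-draw artifacts needed for (re)valuation.
run_scc_draw <- function(k, master_seed, config, spec, segments) {
  draw <- if (config$mode == "data") {
    config$scenarios[[(k - 1L) %% length(config$scenarios) + 1L]]
  } else {
    sample_scenario(config$scenario_config, seed = master_seed, draw_id = k)
  }
  cp <- sample_climate_params(config$climate_source,
                              seed = derive_seed(master_seed, k, "climate"))
  sp <- sample_sealevel_params(config$sealevel_source,
                               seed = derive_seed(master_seed, k, "sealevel"))
  dseed <- derive_seed(master_seed, k, "damages")
  mort_beta <- sample_mortality_beta(config$damage_parameters, seed = dseed)
  theta <- sample_ag_weight(seed = dseed + 13)

  clim_b <- run_climate(draw, cp)
  clim_p <- run_climate(draw, cp, pulse = config$pulse)
  need_slr <- "coastal" %in% config$sectors
  slr_b <- if (need_slr) run_sealevel(clim_b, sp, segments)
  slr_p <- if (need_slr) run_sealevel(clim_p, sp, segments)

  base <- run_damages(draw, clim_b, slr_b, segments, mort_beta, theta, config)
  pulsed <- run_damages(draw, clim_p, slr_p, segments, mort_beta, theta, config)

  mdp <- marginal_damage_path(base, pulsed, config$pulse)
  dmg_total <- colSums(sector_totals(base))
  cons <- consumption_path(draw,
                           if (config$consumption == "net") dmg_total else 0,
                           floor = config$consumption_floor)
  sdf <- sdf_path(cons, spec)
  partials <- partial_scc(mdp$md_sector, sdf)
  list(total = scc_from_draw(mdp$md, sdf), partial = partials,
       md_sector = mdp$md_sector, consumption = cons$c,
       n_floored = cons$n_floored, years = draw$years)
}

#' Monte Carlo estimation of the social cost of CO2
#'
#' For each draw, jointly samples a socioeconomic-emissions scenario,
#' climate and sea-level model parameters and damage-function parameters;
#' runs the coupled model twice (baseline, and with a small CO2 pulse in
#' 2020, sharing every sampled parameter); differences the sectoral
#' damages; and discounts the per-tonne marginal damages with the
#' stochastic discount factor implied by realized consumption growth. All
#' randomness derives from `seed` through named substreams, so draw k is
#' invariant to the total number of draws.
#'
#' @param n Number of Monte Carlo draws (>= 1).
#' @param rate Near-term discount rate label (see [discount_spec()]), or a
#'   `discount_spec`.
#' @param seed Master seed.
#' @param config `scc_config()`.
#' @param keep_paths Keep per-draw marginal-damage and consumption paths
#'   (needed by [rediscount()]; default TRUE).
#' @return Object of class `scc_result`: `draws` (data frame of per-draw
#'   total and sectoral partial SC-CO2, 2020 USD/tCO2), `mean`,
#'   `quantiles` (5/25/50/75/95%), `near_term_rate` (%), `spec`, `n`,
#'   `seed`, plus diagnostic counters.
#' @export
scc <- function(n = 100, rate = "2.0", seed = 1L, config = scc_config(),
                keep_paths = TRUE) {
  stopifnot(n >= 1)
  spec <- if (inherits(rate, "discount_spec")) rate else discount_spec(rate)
  segments <- config$segments
  if (is.null(segments) && "coastal" %in% config$sectors) {
    segments <- make_segments(config$n_segments,
                              seed = derive_seed(seed, 0, "coastal"),
                              countries = scenario_countries(config))
  }
  if (!is.null(segments)) segments <- cache_tail_grid(segments)
  sector_names <- config$sectors
  draws <- vector("list", n)
  failed <- integer(0)
  for (k in seq_len(n)) {
    draws[[k]] <- tryCatch(
      run_scc_draw(k, seed, config, spec, segments),
      error = function(e) {
        message("draw ", k, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(draws[[k]])) failed <- c(failed, k)
  }
  if (length(failed) > max(1, 0.01 * n)) {
    stop("more than 1% of draws failed (", length(failed), " of ", n, ")")
  }
  ok <- draws[!vapply(draws, is.null, logical(1))]
  tab <- data.frame(draw = setdiff(seq_len(n), failed),
                    total = vapply(ok, `[[`, numeric(1), "total"))
  for (s in sector_names) {
    tab[[s]] <- vapply(ok, function(d) d$partial[[s]], numeric(1))
  }
  qs <- stats::quantile(tab$total, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7)
  res <- structure(list(
    draws = tab,
    mean = mean(tab$total),
    mean_partial = vapply(sector_names, function(s) mean(tab[[s]]), numeric(1)),
    quantiles = qs,
    near_term_rate = near_term_rate(spec, lapply(ok, `[[`, "consumption")),
    spec = spec, n = n, seed = seed, failed = failed,
    n_floored = sum(vapply(ok, `[[`, numeric(1), "n_floored")),
    sectors = sector_names,
    config_hash = config_hash(config)
  ), class = "scc_result")
  if (keep_paths) {
    res$paths <- list(
      years = ok[[1]]$years,
      md_sector = lapply(ok, `[[`, "md_sector"),
      consumption = lapply(ok, `[[`, "consumption"))
  }
  res
}

# Countries used by synthetic segments must match the scenario draws.
scenario_countries <- function(config) {
  if (config$mode == "data") return(config$scenarios[[1]]$countries)
  country_frame(config$scenario_config)$codes
}

# Order-independent checksum of the configuration (run metadata).
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(unclass(config)), "scenarios")]),
               collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

#' Re-discount an SC-CO2 result under another near-term rate
#'
#' Reuses the stored per-draw marginal-damage and consumption paths,
#' recomputing only the stochastic discount factors, so the comparison
#' across (rho, eta) pairs holds the physical draws fixed.
#'
#' @param result `scc_result` computed with `keep_paths = TRUE`.
#' @param rate New rate label or `discount_spec`.
#' @return A new `scc_result`.
#' @export
rediscount <- function(result, rate) {
  if (is.null(result$paths)) stop("result was computed without keep_paths")
  spec <- if (inherits(rate, "discount_spec")) rate else discount_spec(rate)
  yrs <- result$paths$years
  tab <- result$draws
  for (i in seq_len(nrow(tab))) {
    sdf <- sdf_path(result$paths$consumption[[i]], spec, years = yrs)
    p <- partial_scc(result$paths$md_sector[[i]], sdf)
    tab$total[i] <- sum(p)
    for (s in result$sectors) tab[[s]][i] <- p[[s]]
  }
  out <- result
  out$draws <- tab
  out$mean <- mean(tab$total)
  out$mean_partial <- vapply(result$sectors, function(s) mean(tab[[s]]),
                             numeric(1))
  out$quantiles <- stats::quantile(tab$total, c(0.05, 0.25, 0.5, 0.75, 0.95),
                                   type = 7)
  out$near_term_rate <- near_term_rate(spec, result$paths$consumption)
  out$spec <- spec
  out
}

#' @export
print.scc_result <- function(x, ...) {
  cat(sprintf("SC-CO2 (n = %d draws, near-term rate %s%%)\n",
              x$n, x$spec$label))
  cat(sprintf("  mean: $%.1f per tCO2 (2020 USD)\n", x$mean))
  cat(sprintf("  5-95%%: $%.1f to $%.1f; median $%.1f\n",
              x$quantiles[["5%"]], x$quantiles[["95%"]], x$quantiles[["50%"]]))
  cat("  mean partial by sector:",
      paste(sprintf("%s $%.1f", names(x$mean_partial), x$mean_partial),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.scc_result <- function(object, ...) {
  out <- list(mean = object$mean, quantiles = object$quantiles,
              mean_partial = object$mean_partial,
              near_term_rate = object$near_term_rate,
              n = object$n, failed = length(object$failed),
              n_floored = object$n_floored, spec = object$spec)
  class(out) <- "summary.scc_result"
  out
}

#' @export
print.summary.scc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo SC-CO2 summary (n = %d, %d failed draws)\n",
              x$n, x$failed))
  print(x$spec)
  cat(sprintf("  realized near-term rate: %.2f%%\n", x$near_term_rate))
  cat(sprintf("  mean SC-CO2: $%.2f per tCO2 (2020 USD)\n", x$mean))
  cat("  quantiles:\n")
  print(round(x$quantiles, 1))
  cat("  mean partial SC-CO2 by sector:\n")
  print(round(x$mean_partial, 2))
  if (x$n_floored > 0) {
    cat("  consumption floor bound in", x$n_floored, "draw-years\n")
  }
  invisible(x)
}

#' @export
quantile.scc_result <- function(x, probs = c(0.05, 0.25, 0.5, 0.75, 0.95), ...) {
  stats::quantile(x$draws$total, probs = probs, type = 7)
}

#' @export
as.data.frame.scc_result <- function(x, ...) x$draws

#' Histogram of the SC-CO2 draw distribution
#'
#' @param x `scc_result`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.scc_result <- function(x, ...) {
  graphics::hist(x$draws$total, breaks = "FD",
                 main = sprintf("SC-CO2 distribution (near-term %s%%)",
                                x$spec$label),
                 xlab = "SC-CO2 (2020 USD per tCO2)", ...)
  graphics::abline(v = x$mean, lwd = 2)
  invisible(x)
}
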