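#' Generate the synthetic input fixture bundle
#'
#' Writes, deterministically from `seed`: a 100-member climate parameter
#' ensemble, a sea-level prior-sample table (500 rows from the documented
#' priors), 500 synthetic coastal segments, the sectoral damage-coefficient
#' tables, the historical-emissions and exogenous-forcing series, and a
#' 3-draw scenario file (10 countries) in the long CSV format read by
#' [load_scenarios()]. All files are plain CSV/YAML.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_countries Countries in the scenario fixture.
#' @return Invisibly, the named vector of file paths.
#' @export
make_fixtures <- function(dir, seed = 1L, n_countries = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fs <- derive_seed(seed, 0, "fixtures")
  paths <- c(
    climate_ensemble = file.path(dir, "climate_ensemble.csv"),
    sealevel_samples = file.path(dir, "sealevel_samples.csv"),
    segments = file.path(dir, "segments.csv"),
    energy_beta = file.path(dir, "energy_beta.csv"),
    mortality_beta = file.path(dir, "mortality_beta.csv"),
    agriculture = file.path(dir, "agriculture_params.csv"),
    historical_emissions = file.path(dir, "historical_emissions.csv"),
    exogenous_forcing = file.path(dir, "exogenous_forcing.csv"),
    scenarios = file.path(dir, "scenarios_3draws.csv"),
    config = file.path(dir, "run_config.yaml")
  )

  cps <- sample_climate_params("default-priors", seed = fs, n = 100)
  ens <- do.call(rbind, lapply(cps, function(p) {
    data.frame(q1 = p$q[1], q2 = p$q[2], F2x = p$F2x, r0 = p$r0,
               rU = p$rU, rT = p$rT)
  }))
  utils::write.csv(ens, paths["climate_ensemble"], row.names = FALSE)

  sls <- sample_sealevel_params("prior-sampler", seed = fs + 1, n = 500)
  slt <- do.call(rbind, lapply(sls, function(p) {
    as.data.frame(unclass(p)[names(sealevel_priors())])
  }))
  utils::write.csv(slt, paths["sealevel_samples"], row.names = FALSE)

  cfg <- calibrate_generator(n_countries = n_countries)
  seg <- make_segments(500, seed = fs + 2,
                       countries = country_frame(cfg)$codes)
  utils::write.csv(as.data.frame(seg), paths["segments"], row.names = FALSE)

  dp <- damage_params()
  utils::write.csv(data.frame(region = seq_along(dp$energy_beta),
                              beta_share_per_K = dp$energy_beta),
                   paths["energy_beta"], row.names = FALSE)
  utils::write.csv(data.frame(region = seq_along(dp$mort_beta_mean),
                              beta_per_K = dp$mort_beta_mean,
                              se = dp$mort_beta_se),
                   paths["mortality_beta"], row.names = FALSE)
  utils::write.csv(data.frame(region = seq_along(dp$ag_sigma),
                              sigma_1990 = dp$ag_sigma,
                              f_low_1K = dp$ag_f_low[, 1],
                              f_low_2K = dp$ag_f_low[, 2],
                              f_low_3K = dp$ag_f_low[, 3],
                              f_central_1K = dp$ag_f_central[, 1],
                              f_central_2K = dp$ag_f_central[, 2],
                              f_central_3K = dp$ag_f_central[, 3],
                              f_high_1K = dp$ag_f_high[, 1],
                              f_high_2K = dp$ag_f_high[, 2],
                              f_high_3K = dp$ag_f_high[, 3]),
                   paths["agriculture"], row.names = FALSE)

  utils::write.csv(historical_emissions(), paths["historical_emissions"],
                   row.names = FALSE)
  utils::write.csv(exogenous_forcing(), paths["exogenous_forcing"],
                   row.names = FALSE)

  draws <- lapply(1:3, function(k) sample_scenario(cfg, seed = fs + 3,
                                                   draw_id = k))
  write_scenarios(draws, paths["scenarios"])

  yaml::write_yaml(list(mode = "synthetic", draws = 100, seed = seed,
                        near_term_rate = "2.0",
                        sectors = c("energy", "mortality", "agriculture",
                                    "coastal"),
                        pulse = list(year = 2020, mass_MtC = 0.1),
                        countries = n_countries, segments = 500),
                   paths["config"])
  invisible(paths)
}

#' Write an SC-CO2 result to disk
#'
#' Writes the draw-level table (`draws.csv`), run metadata
#' (`metadata.json`: seed, rate, config hash, diagnostics, schema version)
#' and, when present, the per-draw marginal-damage paths
#' (`md_paths.csv`, long format) and consumption paths
#' (`consumption_paths.csv`). Everything is plain text and re-loadable with
#' [read_scc()].
#'
#' @param result `scc_result`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_scc <- function(result, dir) {
  if (!inherits(result, "scc_result")) stop("not an scc_result")
  if (nrow(result$draws) == 0) stop("empty result: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$draws, file.path(dir, "draws.csv"),
                   row.names = FALSE)
  meta <- list(schema_version = "1.0",
               n = result$n, seed = result$seed,
               rate = result$spec$label, rho = result$spec$rho,
               eta = result$spec$eta,
               mean = result$mean,
               mean_partial = as.list(result$mean_partial),
               quantiles = as.list(result$quantiles),
               near_term_rate = result$near_term_rate,
               failed = result$failed, n_floored = result$n_floored,
               sectors = result$sectors, config_hash = result$config_hash,
               package_version = as.character(utils::packageVersion("scco2")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(result$paths)) {
    md <- do.call(rbind, lapply(seq_along(result$paths$md_sector), function(i) {
      m <- result$paths$md_sector[[i]]
      data.frame(draw = result$draws$draw[i],
                 sector = rep(rownames(m), ncol(m)),
                 year = rep(result$paths$years, each = nrow(m)),
                 md = as.vector(m))
    }))
    utils::write.csv(md, file.path(dir, "md_paths.csv"), row.names = FALSE)
    cons <- do.call(rbind, lapply(seq_along(result$paths$consumption), function(i) {
      data.frame(draw = result$draws$draw[i], year = result$paths$years,
                 consumption = result$paths$consumption[[i]])
    }))
    utils::write.csv(cons, file.path(dir, "consumption_paths.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read an SC-CO2 result written by [write_scc()]
#'
#' @param dir Directory containing `draws.csv` and `metadata.json`.
#' @return An `scc_result`.
#' @export
read_scc <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "draws.csv"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  res <- structure(list(
    draws = tab, mean = meta$mean,
    mean_partial = unlist(meta$mean_partial),
    quantiles = unlist(meta$quantiles),
    near_term_rate = meta$near_term_rate,
    spec = discount_spec(meta$rate), n = meta$n, seed = meta$seed,
    failed = meta$failed %||% integer(0), n_floored = meta$n_floored,
    sectors = meta$sectors, config_hash = meta$config_hash
  ), class = "scc_result")
  mdf <- file.path(dir, "md_paths.csv")
  if (file.exists(mdf)) {
    md <- utils::read.csv(mdf)
    cons <- utils::read.csv(file.path(dir, "consumption_paths.csv"))
    years <- sort(unique(md$year))
    res$paths <- list(
      years = years,
      md_sector = lapply(split(md, md$draw), function(d) {
        m <- matrix(d$md, nrow = length(unique(d$sector)),
                    dimnames = list(unique(d$sector), years))
        m
      }),
      consumption = lapply(split(cons, cons$draw), function(d) {
        d$consumption[order(d$year)]
      }))
    names(res$paths$md_sector) <- NULL
    names(res$paths$consumption) <- NULL
  }
  res
}

#' Published reference SC-CO2 benchmarks
#'
#' Headline mean SC-CO2 values (2020 USD per tCO2) from the large-ensemble
#' study this engine re-implements, used for external validation when the
#' deposited scenario/parameter inputs are supplied in data mode. They are
#' reference values only; nothing in the package computes against them in
#' synthetic mode.
#'
#' @return Data frame with `quantity`, `rate`, `value_usd_per_tco2`.
#' @export
reference_benchmarks <- function() {
  data.frame(
    quantity = c("mean SC-CO2", "mean SC-CO2", "mean SC-CO2", "mean SC-CO2",
                 "mean partial SC-CO2 mortality",
                 "mean partial SC-CO2 agriculture",
                 "mean partial SC-CO2 energy",
                 "mean partial SC-CO2 coastal"),
    rate = c("2.0", "3.0", "2.5", "1.5", "2.0", "2.0", "2.0", "2.0"),
    value_usd_per_tco2 = c(185, 80, 118, 308, 90, 84, 9, 2)
  )
}

#' Command-line entry point
#'
#' Subcommands: `scc` (full Monte Carlo run; options `--draws`,
#' `--near-term-rate`, `--seed`, `--sectors`, `--countries`, `--segments`,
#' `--out`), `fixtures` (`--seed`, `--out`), and `validate` (fast invariant
#' suite). Returns the exit status (0 on success) rather than calling
#' `quit()`, so it is testable; the installed `cli/scco2` script wraps it.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(argv) == 0) stop("usage: scco2 <scc|fixtures|validate> [options]")
    cmd <- argv[1]
    opts <- cli_options(argv[-1])
    switch(cmd,
      fixtures = {
        out <- opts$out %||% "fixtures"
        make_fixtures(out, seed = as.integer(opts$seed %||% 1))
        message("fixtures written to ", out)
      },
      scc = {
        rate <- opts[["near-term-rate"]] %||% "2.0"
        spec <- discount_spec(rate)   # validates early, lists valid rates
        sectors <- if (is.null(opts$sectors) || opts$sectors == "all") {
          c("energy", "mortality", "agriculture", "coastal")
        } else strsplit(opts$sectors, ",")[[1]]
        cfg <- scc_config(
          scenario_config = calibrate_generator(
            n_countries = as.integer(opts$countries %||% 184)),
          n_segments = as.integer(opts$segments %||% 500),
          sectors = sectors)
        res <- scc(n = as.integer(opts$draws %||% 100), rate = spec,
                   seed = as.integer(opts$seed %||% 1), config = cfg)
        out <- opts$out %||% "scc_output"
        write_scc(res, out)
        message("run complete: config ", res$config_hash,
                ", package ", as.character(utils::packageVersion("scco2")))
        print(res)
        message("results written to ", out)
      },
      validate = {
        validate_invariants()
        message("all invariants satisfied")
      },
      stop("unknown subcommand '", cmd, "'")
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}

# Fast cross-module invariant checks used by the `validate` subcommand.
validate_invariants <- function() {
  cfg <- calibrate_generator(n_countries = 12)
  d <- sample_scenario(cfg, seed = 7)
  validate_scen_draw(d)
  stopifnot(max(abs(colSums(d$pop) - d$world$pop)) < 1e-6 * max(d$world$pop))
  cp <- run_climate(d)
  stopifnot(cp$conservation_err < 1e-9)
  p <- climate_params()
  stopifnot(abs(radiative_forcing(2 * p$C0, p$ch4$M0, p$n2o$N0, p) - p$F2x) < 1e-12)
  sl <- run_sealevel(cp)
  stopifnot(max(abs(sl$gsl - (sl$te + sl$gsic + sl$gis + sl$ais + sl$lws))) == 0)
  invisible(TRUE)
}
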