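#' Default sea-level model parameters
#'
#' Semi-empirical one-state-per-component global sea-level model driven by
#' the global temperature anomaly: thermal expansion relaxing toward an
#' equilibrium proportional to warming; glaciers and small ice caps with a
#' volume-dependent melt law; Greenland melt proportional to warming;
#' Antarctica with a baseline melt sensitivity plus a fast-disintegration
#' rate `lambda` that switches on while the Antarctic proxy temperature
#' (`gamma_ant` times the global anomaly) exceeds the threshold `Tcrit`;
#' and a constant land-water-storage trend.
#'
#' @param ... Named overrides.
#' @return Object of class `slr_params`.
#' @details Units: sensitivities in m/yr/K (thermal-expansion equilibrium
#'   sensitivity `te_s` in m/K with timescale `te_tau` yr); volumes in m of
#'   sea-level equivalent; `Tcrit` in K of Antarctic proxy temperature;
#'   `lambda` in m/yr; `lws_rate` in m/yr.
#' @export
sealevel_params <- function(...) {
  p <- list(
    te_s = 0.5, te_tau = 200,
    gsic_V0 = 0.41, gsic_beta0 = 5.8e-4, gsic_Teq = -0.15, gsic_n = 0.82,
    gis_V0 = 7.4, gis_gamma = 6e-4,
    ais_V0 = 57, ais_gamma = 4e-4, ais_Tcrit = 2.6, ais_lambda = 0.01,
    gamma_ant = 1.2,
    lws_rate = 3e-4
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(p$gsic_V0 >= 0, p$gis_V0 >= 0, p$ais_V0 >= 0, p$te_tau > 0,
            p$ais_lambda >= 0)
  class(p) <- "slr_params"
  p
}

# One annual step of each component. All take and return scalar state.

step_thermal_expansion <- function(te, temp, p) {
  te + (p$te_s * temp - te) / p$te_tau
}

# Glacier volume update; returns new volume (m SLE), bounded to [0, V0].
step_glaciers <- function(V, temp, p) {
  dV <- p$gsic_beta0 * (temp - p$gsic_Teq) * (V / p$gsic_V0)^p$gsic_n
  min(max(V - dV, 0), p$gsic_V0)
}

# Ice-sheet melt rates for one year; returns c(greenland, antarctica) melt
# in m SLE/yr before volume bounding. The fast-disintegration term applies
# while the Antarctic proxy temperature exceeds the threshold.
ice_sheet_rates <- function(temp, p) {
  gis <- max(0, p$gis_gamma * temp)
  ais <- p$ais_gamma * temp +
    if (p$gamma_ant * temp > p$ais_Tcrit) p$ais_lambda else 0
  c(gis = gis, ais = ais)
}

#' Run the component sea-level model
#'
#' Integrates all components annually along a temperature path, starting
#' from rest at the first year of the input (the historical portion of the
#' climate path provides the spin-up), then re-references every component
#' to 1900 so the total is relative to 1900 and the component sum identity
#' is exact. Local sea level at coastal segments is the global total scaled
#' by each segment's time-invariant factor.
#'
#' @param climate A `climate_path` (or list with `years` and `temp`).
#' @param params `slr_params`.
#' @param segments Optional data frame with `segment_id` and `lsl_factor`;
#'   when supplied, a `local` matrix (segments x years) is included.
#' @return Object of class `slr_path`: `years` (1900-2300), component
#'   series `te`, `gsic`, `gis`, `ais`, `lws`, their exact sum `gsl` (m vs
#'   1900), and optionally `local`.
#' @export
run_sealevel <- function(climate, params = sealevel_params(), segments = NULL) {
  yrs <- climate$years
  temp <- climate$temp
  ny <- length(yrs)
  te <- gsic <- gis <- ais <- lws <- numeric(ny)
  te_s <- 0; Vg <- params$gsic_V0
  Vgis <- params$gis_V0; Vais <- params$ais_V0
  gis_c <- 0; ais_c <- 0; lws_c <- 0
  for (i in seq_len(ny)) {
    te_s <- step_thermal_expansion(te_s, temp[i], params)
    Vg_new <- step_glaciers(Vg, temp[i], params)
    rates <- ice_sheet_rates(temp[i], params)
    m_gis <- min(rates[["gis"]], Vgis)
    m_ais <- min(rates[["ais"]], Vais)
    Vgis <- Vgis - m_gis
    Vais <- Vais - m_ais
    gis_c <- gis_c + m_gis
    ais_c <- ais_c + m_ais
    lws_c <- lws_c + params$lws_rate
    te[i] <- te_s
    gsic[i] <- params$gsic_V0 - Vg_new
    gis[i] <- gis_c
    ais[i] <- ais_c
    lws[i] <- lws_c
    Vg <- Vg_new
  }
  keep <- yrs >= 1900
  i1900 <- if (any(yrs == 1900)) which(yrs == 1900) else 1L
  ref <- function(x) (x - x[i1900])[keep]
  te <- ref(te); gsic <- ref(gsic); gis <- ref(gis); ais <- ref(ais)
  lws <- ref(lws)
  gsl <- te + gsic + gis + ais + lws
  out <- list(years = yrs[keep], te = te, gsic = gsic, gis = gis, ais = ais,
              lws = lws, gsl = gsl)
  if (!is.null(segments)) {
    out$local <- outer(segments$lsl_factor, gsl)
    rownames(out$local) <- segments$segment_id
  }
  structure(out, class = "slr_path")
}

#' @export
print.slr_path <- function(x, ...) {
  i <- match(c(2100, 2300), x$years)
  cat(sprintf("Sea-level path %d-%d (m vs 1900)\n", min(x$years), max(x$years)))
  for (k in i[!is.na(i)]) {
    cat(sprintf("  %d: total %.2f (te %.2f, glaciers %.2f, GIS %.2f, AIS %.2f)\n",
                x$years[k], x$gsl[k], x$te[k], x$gsic[k], x$gis[k], x$ais[k]))
  }
  invisible(x)
}

#' Prior specification for sea-level parameter sampling
#'
#' Independent documented priors used when no posterior sample file is
#' supplied: lognormal for positive sensitivities/timescales, truncated
#' normal for the Antarctic threshold, normal for the land-water trend.
#' `meanlog`/`sdlog` parameterize the lognormals.
#'
#' @return Named list of prior descriptions.
#' @export
sealevel_priors <- function() {
  list(
    te_s       = list(dist = "lnorm", meanlog = log(0.5), sdlog = 0.25),
    te_tau     = list(dist = "lnorm", meanlog = log(200), sdlog = 0.3),
    gsic_beta0 = list(dist = "lnorm", meanlog = log(5.8e-4), sdlog = 0.3),
    gis_gamma  = list(dist = "lnorm", meanlog = log(6e-4), sdlog = 0.4),
    ais_gamma  = list(dist = "lnorm", meanlog = log(4e-4), sdlog = 0.4),
    ais_Tcrit  = list(dist = "tnorm", mean = 2.6, sd = 0.6, lower = 1.0),
    ais_lambda = list(dist = "lnorm", meanlog = log(0.01), sdlog = 0.5),
    lws_rate   = list(dist = "norm", mean = 3e-4, sd = 1e-4)
  )
}

#' Sample sea-level model parameters
#'
#' Posterior mode: rows of a parameter sample file (data frame or CSV, one
#' row per posterior sample, columns named as in [sealevel_params()]) are
#' drawn uniformly without replacement. Prior mode (`"prior-sampler"`):
#' independent draws from [sealevel_priors()].
#'
#' @param source Data frame, CSV path, or `"prior-sampler"`.
#' @param seed Integer seed.
#' @param n Number of parameter sets.
#' @return `slr_params` (if `n == 1`) or a list thereof.
#' @export
sample_sealevel_params <- function(source = "prior-sampler", seed = 1L, n = 1L) {
  if (is.character(source) && identical(source, "prior-sampler")) {
    pr <- sealevel_priors()
    draws <- with_seed(seed, replicate(n, simplify = FALSE, {
      v <- lapply(pr, function(s) {
        switch(s$dist,
          lnorm = stats::rlnorm(1, s$meanlog, s$sdlog),
          tnorm = { x <- stats::rnorm(1, s$mean, s$sd)
                    while (x < s$lower) x <- stats::rnorm(1, s$mean, s$sd)
                    x },
          norm = stats::rnorm(1, s$mean, s$sd))
      })
      do.call(sealevel_params, v)
    }))
  } else {
    tab <- if (is.character(source)) {
      utils::read.csv(source, stringsAsFactors = FALSE)
    } else source
    need <- names(sealevel_priors())
    if (!all(need %in% names(tab))) {
      stop("sea-level sample file missing columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
    if (n > nrow(tab)) stop("requested more sets than sample rows")
    idx <- with_seed(seed, sample.int(nrow(tab), n, replace = FALSE))
    draws <- lapply(idx, function(i) do.call(sealevel_params, as.list(tab[i, need])))
  }
  if (n == 1L) draws[[1]] else draws
}
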