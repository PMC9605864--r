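#' Default climate emulator parameters
#'
#' Parameters of the reduced-complexity, emissions-driven climate emulator:
#' a four-pool impulse-response carbon cycle whose timescales are scaled by
#' a state-dependent factor alpha (solved each year so the 100-year
#' integrated impulse response iIRF100 matches `r0 + rU * U + rT * T`),
#' logarithmic CO2 forcing, square-root CH4/N2O forcing, and a two-box
#' thermal response. Defaults follow the widely used v1.6.2 configuration
#' of this emulator family; all values are configuration, not constants.
#'
#' @param ... Named overrides of any default element.
#' @return An object of class `climate_params`.
#' @details Units: `a` dimensionless partition fractions (sum 1); `tau`
#'   years; `r0` years; `rU` years per GtC; `rT` years per K; `C0` ppm;
#'   `F2x` W/m2; `q` K per (W/m2); `d` years; gas lifetimes years;
#'   `GtC_per_ppm` GtC per ppm CO2. `exo_forcing` is an annual data frame
#'   (`year`, `value` in W/m2) of all non-CO2/CH4/N2O forcing.
#' @export
climate_params <- function(...) {
  p <- list(
    a   = c(0.2173, 0.2240, 0.2824, 0.2763),
    tau = c(1e6, 394.4, 36.54, 4.304),
    r0 = 35, rU = 0.019, rT = 4.165,
    C0 = 278, F2x = 3.71, GtC_per_ppm = 2.124,
    q = c(0.33, 0.41), d = c(239, 4.1),
    ch4 = list(lifetime = 9.3, M0 = 722, alpha = 0.036, Mt_per_ppb = 2.82),
    n2o = list(lifetime = 121, N0 = 270, alpha = 0.12, Mt_per_ppb = 7.75),
    alpha_bounds = c(0.01, 100),
    exo_forcing = exogenous_forcing()
  )
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(abs(sum(p$a) - 1) < 1e-9, all(p$tau > 0), all(p$q > 0),
            all(p$d > 0), p$F2x > 0)
  class(p) <- "climate_params"
  p
}

#' @export
print.climate_params <- function(x, ...) {
  cat("Climate emulator parameters\n")
  cat(sprintf("  ECS implied: %.2f K; F2x %.2f W/m2; C0 %.0f ppm\n",
              x$F2x * sum(x$q), x$F2x, x$C0))
  cat(sprintf("  iIRF100: r0 %.1f + %.3f U + %.2f T\n", x$r0, x$rU, x$rT))
  invisible(x)
}

# 100-year integrated impulse response at timescale scaling alpha.
iirf100 <- function(alpha, p) {
  at <- alpha * p$tau
  sum(p$a * at * (1 - exp(-100 / at)))
}

#' Solve the carbon-cycle timescale scaling factor
#'
#' Finds alpha > 0 such that the 100-year integrated impulse response
#' `sum(a_i * alpha * tau_i * (1 - exp(-100 / (alpha * tau_i))))` equals the
#' state-dependent target `r0 + rU * U + rT * T`. The response is strictly
#' increasing in alpha, so bisection finds the unique root; targets outside
#' the attainable range at the configured bounds are clamped with a warning.
#'
#' @param target Target iIRF100 (years).
#' @param params `climate_params`.
#' @param tol Absolute tolerance on the response (years).
#' @param warm Optional previous root used to tighten the initial bracket
#'   (the bounds themselves still apply; the root is identical).
#' @param warn Emit a warning when the target is clamped at a bound
#'   (default TRUE; [run_climate()] instead counts clamped years).
#' @return Scalar alpha.
#' @export
solve_alpha <- function(target, params, tol = 1e-7, warm = NULL, warn = TRUE) {
  a <- params$a; tau <- params$tau
  f <- function(al) {
    at <- al * tau
    sum(a * at * (1 - exp(-100 / at)))
  }
  blo <- params$alpha_bounds[1]; bhi <- params$alpha_bounds[2]
  flo <- f(blo); fhi <- f(bhi)
  if (target <= flo) {
    if (warn) warning("iIRF100 target ", signif(target, 6),
                      " below attainable range; alpha clamped to ", blo)
    return(blo)
  }
  if (target >= fhi) {
    if (warn) warning("iIRF100 target ", signif(target, 6),
                      " above attainable range; alpha clamped to ", bhi)
    return(bhi)
  }
  lo <- blo; hi <- bhi
  if (!is.null(warm)) {                       # expand around previous root
    l <- max(warm / 1.3, blo); h <- min(warm * 1.3, bhi)
    while (f(l) > target && l > blo) l <- max(l / 2, blo)
    while (f(h) < target && h < bhi) h <- min(h * 2, bhi)
    lo <- l; hi <- h
  }
  for (i in 1:100) {
    mid <- sqrt(lo * hi)                      # bisection in log alpha
    fm <- f(mid)
    if (abs(fm - target) < tol) return(mid)
    if (fm < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# One annual carbon-cycle step. state: list(R (4 pools, GtC), U (GtC
# cumulative land+ocean uptake)). E in GtC/yr. Conservation E - d(sum R) -
# dU = 0 holds exactly by construction.
step_carbon <- function(state, E, alpha, p) {
  at <- alpha * p$tau
  dec <- exp(-1 / at)
  Rnew <- state$R * dec + p$a * E * at * (1 - dec)
  dR <- sum(Rnew) - sum(state$R)
  state$U <- state$U + (E - dR)
  state$R <- Rnew
  state$conc <- p$C0 + sum(Rnew) / p$GtC_per_ppm
  state
}

#' Radiative forcing from greenhouse-gas concentrations
#'
#' CO2 contributes `(F2x / ln 2) * ln(C / C0)`; CH4 and N2O use square-root
#' forms `alpha * (sqrt(X) - sqrt(X0))`; `exo` (W/m2) is added for all other
#' agents.
#'
#' @param co2_ppm,ch4_ppb,n2o_ppb Concentrations (must be positive).
#' @param params `climate_params`.
#' @param exo Exogenous forcing (W/m2), default 0.
#' @return Total forcing (W/m2); vectorized over concentrations.
#' @export
radiative_forcing <- function(co2_ppm, ch4_ppb, n2o_ppb, params, exo = 0) {
  if (any(co2_ppm <= 0) || any(ch4_ppb <= 0) || any(n2o_ppb <= 0)) {
    stop("concentrations must be positive")
  }
  params$F2x / log(2) * log(co2_ppm / params$C0) +
    params$ch4$alpha * (sqrt(ch4_ppb) - sqrt(params$ch4$M0)) +
    params$n2o$alpha * (sqrt(n2o_ppb) - sqrt(params$n2o$N0)) +
    exo
}

# One annual step of the two-box thermal response; Tb length-2 box vector.
step_temperature <- function(Tb, forcing, p) {
  dec <- exp(-1 / p$d)
  Tb * dec + p$q * forcing * (1 - dec)
}

#' Run the climate emulator over 1750-2300
#'
#' Drives the emulator with packaged historical global emissions
#' (1750-2019) spliced to a scenario draw (2020-2300), optionally adding a
#' CO2 pulse in one year. The annual loop solves the state-dependent
#' carbon-cycle scaling, steps the four CO2 pools and the CH4/N2O one-box
#' models, computes forcing (including the packaged exogenous non-CO2/CH4/
#' N2O series) and steps the two thermal boxes. The reported temperature
#' anomaly is re-referenced to the 1850-1900 mean.
#'
#' @param draw A `scen_draw` (CO2 in GtCO2/yr; CH4, N2O in Mt/yr), or `NULL`
#'   to run history only to 2019.
#' @param params `climate_params`.
#' @param pulse Optional `pulse_spec()`; its mass is added to CO2 emissions
#'   in the pulse year.
#' @param history Data frame from [historical_emissions()].
#' @return An object of class `climate_path`: annual `years`, `co2_ppm`,
#'   `ch4_ppb`, `n2o_ppb`, `forcing` (W/m2), `temp` (K vs 1850-1900),
#'   `alpha`, `n_clamped` (years where the iIRF100 target was outside the
#'   attainable range and alpha sat at a bound), and `conservation_err`
#'   (max absolute carbon imbalance, GtC).
#' @export
run_climate <- function(draw, params = climate_params(), pulse = NULL,
                        history = historical_emissions()) {
  yrs <- 1750:if (is.null(draw)) 2019 else 2300
  ny <- length(yrs)
  co2_gtc <- numeric(ny); ch4_mt <- numeric(ny); n2o_mt <- numeric(ny)
  ih <- match(history$year, yrs)
  co2_gtc[ih] <- history$co2_GtC
  ch4_mt[ih] <- history$ch4_Mt
  n2o_mt[ih] <- history$n2o_Mt
  if (!is.null(draw)) {
    is <- match(draw$years, yrs)
    co2_gtc[is] <- draw$co2 / (44 / 12)      # GtCO2 -> GtC
    ch4_mt[is] <- draw$ch4
    n2o_mt[is] <- draw$n2o
  }
  if (!is.null(pulse)) {
    iy <- match(pulse$year, yrs)
    if (is.na(iy)) stop("pulse year outside simulation span")
    co2_gtc[iy] <- co2_gtc[iy] + pulse$mass_MtC / 1000
  }
  exo <- approx(params$exo_forcing$year, params$exo_forcing$value, xout = yrs,
                rule = 2)$y

  # CH4/N2O one-box decay precomputation
  dch4 <- exp(-1 / params$ch4$lifetime)
  dn2o <- exp(-1 / params$n2o$lifetime)
  ech4 <- ch4_mt / params$ch4$Mt_per_ppb * params$ch4$lifetime * (1 - dch4)
  en2o <- n2o_mt / params$n2o$Mt_per_ppb * params$n2o$lifetime * (1 - dn2o)

  conc <- numeric(ny); Fr <- numeric(ny); Tg <- numeric(ny)
  Mv <- numeric(ny); Nv <- numeric(ny)
  alphas <- numeric(ny)
  st <- list(R = numeric(4), U = 0)
  Tb <- c(0, 0)
  M <- params$ch4$M0; N <- params$n2o$N0
  Tcur <- 0
  cons_err <- 0
  al <- NULL
  n_clamped <- 0L
  for (i in seq_len(ny)) {
    target <- params$r0 + params$rU * st$U + params$rT * Tcur
    al <- solve_alpha(target, params, warm = al, warn = FALSE)
    if (al <= params$alpha_bounds[1] || al >= params$alpha_bounds[2]) {
      n_clamped <- n_clamped + 1L
    }
    alphas[i] <- al
    tot0 <- sum(st$R) + st$U
    st <- step_carbon(st, co2_gtc[i], al, params)
    cons_err <- max(cons_err, abs(sum(st$R) + st$U - tot0 - co2_gtc[i]))
    M <- params$ch4$M0 + (M - params$ch4$M0) * dch4 + ech4[i]
    N <- params$n2o$N0 + (N - params$n2o$N0) * dn2o + en2o[i]
    Fr[i] <- radiative_forcing(st$conc, M, N, params, exo[i])
    Tb <- step_temperature(Tb, Fr[i], params)
    Tcur <- sum(Tb)
    conc[i] <- st$conc
    Mv[i] <- M; Nv[i] <- N
    Tg[i] <- Tcur
  }
  ref <- mean(Tg[yrs >= 1850 & yrs <= 1900])
  structure(list(years = yrs, co2_ppm = conc,
                 ch4_ppb = Mv, n2o_ppb = Nv,
                 forcing = Fr, temp = Tg - ref, temp_raw = Tg,
                 alpha = alphas, n_clamped = n_clamped,
                 conservation_err = cons_err),
            class = "climate_path")
}

#' @export
print.climate_path <- function(x, ...) {
  i2100 <- match(2100, x$years)
  cat(sprintf("Climate path %d-%d\n", min(x$years), max(x$years)))
  if (!is.na(i2100)) {
    cat(sprintf("  2100: CO2 %.0f ppm, T %.2f K (vs 1850-1900)\n",
                x$co2_ppm[i2100], x$temp[i2100]))
  }
  cat(sprintf("  max carbon imbalance: %.2e GtC\n", x$conservation_err))
  invisible(x)
}

#' Sample climate emulator parameters
#'
#' In ensemble mode, draws one member uniformly (without replacement across
#' `n`) from a calibrated parameter ensemble (a data frame or CSV with one
#' row per member). In prior mode, samples independent documented priors
#' around the default configuration (truncated normals on the thermal
#' amplitudes, forcing at doubling, and carbon-cycle feedback coefficients).
#'
#' @param source A data frame / CSV path (ensemble mode) or `"default-priors"`.
#' @param seed Integer seed.
#' @param n Number of parameter sets.
#' @return A list of `climate_params` of length `n` (a single
#'   `climate_params` if `n == 1`).
#' @export
sample_climate_params <- function(source = "default-priors", seed = 1L, n = 1L) {
  base <- climate_params()
  if (is.character(source) && identical(source, "default-priors")) {
    draws <- with_seed(seed, {
      replicate(n, simplify = FALSE, {
        q1 <- max(stats::rnorm(1, 0.33, 0.06), 0.05)
        q2 <- max(stats::rnorm(1, 0.41, 0.15), 0.05)
        climate_params(q = c(q1, q2),
                       F2x = max(stats::rnorm(1, 3.71, 0.25), 2),
                       r0 = max(stats::rnorm(1, 35, 3), 20),
                       rU = max(stats::rnorm(1, 0.019, 0.003), 0.001),
                       rT = max(stats::rnorm(1, 4.165, 0.8), 0))
      })
    })
  } else {
    ens <- if (is.character(source)) {
      utils::read.csv(source, stringsAsFactors = FALSE)
    } else source
    need <- c("q1", "q2", "F2x", "r0", "rU", "rT")
    if (!all(need %in% names(ens))) {
      stop("climate ensemble missing columns: ",
           paste(setdiff(need, names(ens)), collapse = ", "))
    }
    if (n > nrow(ens)) stop("requested more members than ensemble rows")
    idx <- with_seed(seed, sample.int(nrow(ens), n, replace = FALSE))
    draws <- lapply(idx, function(i) {
      climate_params(q = c(ens$q1[i], ens$q2[i]), F2x = ens$F2x[i],
                     r0 = ens$r0[i], rU = ens$rU[i], rT = ens$rT[i])
    })
  }
  if (n == 1L) draws[[1]] else draws
}

#' Synthetic historical global greenhouse-gas emissions, 1750-2019
#'
#' A smooth analytic approximation to the historical global totals used to
#' spin the emulator up to an internally consistent 2020 state: logistic
#' growth of CO2 (fossil plus land use, GtC/yr) and logistic ramps of
#' anthropogenic CH4 and N2O (Mt/yr). This is a synthetic stand-in series,
#' shaped so the spun-up 2020 CO2 concentration and temperature anomaly land
#' near observed values (about 412 ppm and 1.2 K); it is not an observational
#' dataset.
#'
#' @return Data frame with `year`, `co2_GtC`, `ch4_Mt`, `n2o_Mt`.
#' @export
historical_emissions <- function() {
  y <- 1750:2019
  co2 <- 0.05 + 11.5 / (1 + exp(-(y - 1967) / 21))
  ch4 <- 8 + 367 / (1 + exp(-(y - 1952) / 27))
  n2o <- 0.3 + 10.2 / (1 + exp(-(y - 1960) / 30))
  data.frame(year = y, co2_GtC = co2, ch4_Mt = ch4, n2o_Mt = n2o)
}

#' Synthetic exogenous forcing series, 1750-2300
#'
#' Annual net radiative forcing (W/m2) from agents outside the explicit
#' CO2/CH4/N2O chemistry (aerosols, ozone, other gases), shaped like a
#' middle-of-the-road scenario: growing negative aerosol forcing through the
#' late 20th century, partial recovery as air quality improves, plus a small
#' positive ozone/other-gas term. Synthetic stand-in series.
#'
#' @return Data frame with `year`, `value` (W/m2).
#' @export
exogenous_forcing <- function() {
  y <- 1750:2300
  aero <- -1.1 / (1 + exp(-(y - 1955) / 18)) *
    ifelse(y > 2010, pmax(0.35, 1 - (y - 2010) / 120), 1)
  oz <- 0.45 / (1 + exp(-(y - 1960) / 25))
  data.frame(year = y, value = aero + oz)
}
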