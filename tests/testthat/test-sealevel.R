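sp0 <- sealevel_params()

test_that("thermal expansion relaxes to its equilibrium and freezes at tau=Inf", {
  expect_equal(scco2:::step_thermal_expansion(0, 0, sp0), 0)
  te <- 0
  for (i in 1:3000) te <- scco2:::step_thermal_expansion(te, 2, sp0)
  expect_equal(te, sp0$te_s * 2, tolerance = 1e-4)
  frozen <- sealevel_params(te_tau = 1e12)
  expect_lt(abs(scco2:::step_thermal_expansion(0.1, 5, frozen) - 0.1), 1e-10)
})

test_that("glacier melt is zero without sensitivity and bounded by the volume", {
  none <- sealevel_params(gsic_beta0 = 0)
  expect_equal(scco2:::step_glaciers(0.3, 4, none), 0.3)
  # strong forcing exhausts the reservoir but never goes negative
  V <- sp0$gsic_V0
  hot <- sealevel_params(gsic_beta0 = 0.05)
  for (i in 1:200) V <- scco2:::step_glaciers(V, 5, hot)
  expect_gte(V, 0)
  # small-temperature linearization matches a finite difference
  dT <- 1e-6
  v1 <- scco2:::step_glaciers(0.3, 1, sp0)
  v2 <- scco2:::step_glaciers(0.3, 1 + dT, sp0)
  slope_fd <- (v2 - v1) / dT
  slope_an <- -sp0$gsic_beta0 * (0.3 / sp0$gsic_V0)^sp0$gsic_n
  expect_equal(slope_fd, slope_an, tolerance = 1e-6)
})

test_that("Antarctic fast disintegration switches on exactly at the threshold", {
  yrs <- 1900:2150
  temp <- seq(0, 3, length.out = length(yrs))
  clim <- structure(list(years = yrs, temp = temp), class = "climate_path")
  tripped <- sealevel_params(ais_Tcrit = 2.0, ais_lambda = 0.02)
  untripped <- sealevel_params(ais_Tcrit = 2.0, ais_lambda = 0)
  a1 <- run_sealevel(clim, tripped)
  a0 <- run_sealevel(clim, untripped)
  proxy <- tripped$gamma_ant * temp
  below <- proxy <= tripped$ais_Tcrit
  # identical while the proxy temperature stays below the threshold
  expect_equal(a1$ais[below], a0$ais[below])
  # the melt rate jumps by exactly lambda in the crossing year
  cross <- which(!below)[1]
  r1 <- diff(a1$ais)[cross - 1]
  r0 <- diff(a0$ais)[cross - 1]
  expect_equal(r1 - r0, tripped$ais_lambda, tolerance = 1e-12)
})

test_that("ice contributions never exceed initial volumes under extreme warming", {
  yrs <- 1900:4000
  clim <- structure(list(years = yrs, temp = rep(30, length(yrs))),
                    class = "climate_path")
  hot <- sealevel_params(gis_V0 = 0.05, ais_V0 = 0.08, gis_gamma = 0.01,
                         ais_gamma = 0.01, ais_Tcrit = 1, ais_lambda = 0.05)
  path <- run_sealevel(clim, hot)
  expect_lte(max(path$gis), hot$gis_V0 + 1e-12)
  expect_lte(max(path$ais), hot$ais_V0 + 1e-12)
  expect_lte(max(path$gsic), hot$gsic_V0 + 1e-12)
})

test_that("components add exactly and downscaling scales the global series", {
  d <- tiny_draw(n_countries = 6)
  clim <- run_climate(d)
  seg <- make_segments(5, seed = 2, countries = d$countries)
  seg$lsl_factor <- c(1, 0, 0.5, 2, 1.3)
  for (s in 1:20) {
    pars <- sample_sealevel_params("prior-sampler", seed = s)
    path <- run_sealevel(clim, pars, seg)
    expect_identical(path$gsl, path$te + path$gsic + path$gis + path$ais + path$lws)
    expect_identical(path$local[1, ], path$gsl)
    expect_true(all(path$local[2, ] == 0))
    expect_equal(path$local[4, ], 2 * path$gsl)
  }
})

test_that("prior sampler moments match the configured priors", {
  n <- 4000
  ps <- sample_sealevel_params("prior-sampler", seed = 10, n = n)
  pr <- sealevel_priors()
  for (nm in c("te_s", "gis_gamma", "ais_lambda")) {
    s <- pr[[nm]]
    vals <- vapply(ps, `[[`, numeric(1), nm)
    mu <- exp(s$meanlog + s$sdlog^2 / 2)
    sd1 <- sqrt((exp(s$sdlog^2) - 1)) * mu
    expect_lt(abs(mean(vals) - mu), 3 * sd1 / sqrt(n))
  }
})

test_that("posterior-file mode samples rows verbatim and reproducibly", {
  tab <- as.data.frame(lapply(sealevel_priors(), function(s) {
    if (s$dist == "lnorm") exp(s$meanlog) else s$mean
  }))
  one <- sample_sealevel_params(tab, seed = 1)
  expect_equal(one$te_s, tab$te_s)
  expect_identical(sample_sealevel_params(tab, seed = 2)$ais_Tcrit,
                   sample_sealevel_params(tab, seed = 2)$ais_Tcrit)
})
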