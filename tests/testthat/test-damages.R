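dp <- damage_params()

test_that("through-origin energy fit matches the closed-form estimator", {
  tab <- data.frame(region = 1, temp = c(1, 2, 3), share = c(0.002, 0.006, 0.007))
  expect_equal(unname(fit_energy_coefficients(tab)), 0.035 / 14)
  # an exact line is recovered exactly
  tab2 <- data.frame(region = "A", temp = c(0.5, 1.7, 2.9), share = 0.004 * c(0.5, 1.7, 2.9))
  expect_equal(unname(fit_energy_coefficients(tab2)), 0.004)
  expect_error(fit_energy_coefficients(
    data.frame(region = 1, temp = c(0, 0), share = c(0, 1))), "undefined")
})

test_that("noisy through-origin fit recovers the true slope within 3 SE", {
  set.seed(7)
  beta <- 0.003
  x <- runif(50, 0.5, 4)
  y <- beta * x * (1 + rnorm(50, 0, 0.1))
  tab <- data.frame(region = 1, temp = x, share = y)
  bhat <- unname(fit_energy_coefficients(tab))
  resid <- y - bhat * x
  se <- sqrt(sum(resid^2) / (49 * sum(x^2)))
  expect_lt(abs(bhat - beta), 3 * se)
})

test_that("energy damages are linear in temperature and homogeneous in GDP", {
  d <- tiny_draw()
  z <- energy_damages(d, flat_climate(0), dp)
  expect_true(all(z$dollars == 0))
  s2 <- energy_damages(d, flat_climate(2), dp)
  s4 <- energy_damages(d, flat_climate(4), dp)
  expect_equal(s4$dollars, 2 * s2$dollars)
  # share beta * T: a region with beta 0.005 at T = 2 gives fraction 0.01
  dp2 <- damage_params(energy_beta = rep(0.005, 12))
  s <- energy_damages(d, flat_climate(2), dp2)
  expect_equal(s$dollars, 0.01 * d$pop * d$gdppc)
  # doubling GDP doubles dollar damages
  d2 <- d; d2$gdppc <- 2 * d$gdppc
  expect_equal(energy_damages(d2, flat_climate(2), dp2)$dollars,
               2 * s$dollars, tolerance = 1e-12)
})

test_that("mortality coefficient sampling is centred and seed-stable", {
  fixed <- damage_params(mort_beta_se = rep(0, 10))
  expect_identical(sample_mortality_beta(fixed, seed = 3), fixed$mort_beta_mean)
  expect_identical(sample_mortality_beta(dp, seed = 8),
                   sample_mortality_beta(dp, seed = 8))
  n <- 10000
  b1 <- vapply(seq_len(n), function(s) sample_mortality_beta(dp, seed = s)[1],
               numeric(1))
  expect_lt(abs(mean(b1) - dp$mort_beta_mean[1]),
            3 * dp$mort_beta_se[1] / sqrt(n))
})

test_that("mortality damages follow the excess-deaths and VSL identities", {
  d <- tiny_draw()
  beta <- rep(0.01, 10)
  m <- mortality_damages(d, flat_climate(1.5), beta, dp)
  # 0.01/K * 1.5 K * baseline deaths
  expect_equal(m$excess_deaths, 0.015 * d$pop * d$mortrate, tolerance = 1e-12)
  # monetization identity dollars / excess deaths = VSL, per country-year
  expect_equal(m$dollars / m$excess_deaths, m$vsl, tolerance = 1e-12)
  # USA in 2020 is the income reference: VSL exactly the base value
  iu <- match("USA", d$countries)
  expect_equal(m$vsl[iu, 1], 10.05e6)
  # half the reference income gives half the VSL under unit elasticity
  half <- d
  half$gdppc[2, ] <- d$gdppc[iu, 1] / 2
  m2 <- mortality_damages(half, flat_climate(1.5), beta, dp)
  expect_equal(unname(m2$vsl[2, 1]), 5.025e6)
})

test_that("a 1,000-death baseline with beta 0.01 and T 1.5 yields 15 excess deaths", {
  d <- tiny_draw(n_countries = 2)
  d$pop[, ] <- 1e5
  d$mortrate[, ] <- 0.01          # baseline deaths = 1,000 per country-year
  m <- mortality_damages(d, flat_climate(1.5), rep(0.01, 10), dp)
  expect_equal(unname(m$excess_deaths[1, 1]), 15)
})

test_that("triangular agriculture weight has the documented distribution", {
  th <- sample_ag_weight(seed = 1, n = 10000)
  expect_true(all(th >= 0 & th <= 1))
  # symmetric triangular(0, 0.5, 1): mean 0.5, var 1/24
  expect_lt(abs(mean(th) - 0.5), 3 * sqrt(1 / 24 / 10000))
  expect_lt(abs(mean(th <= 0.5) - 0.5), 3 * sqrt(0.25 / 10000))
  expect_identical(sample_ag_weight(seed = 2), sample_ag_weight(seed = 2))
})

test_that("agriculture weight blends the parameterizations at the anchors", {
  expect_equal(scco2:::ag_blend(0.5, dp), dp$ag_f_central)
  expect_equal(scco2:::ag_blend(0, dp), dp$ag_f_low)
  expect_equal(scco2:::ag_blend(1, dp), dp$ag_f_high)
  expect_equal(scco2:::ag_blend(0.75, dp), (dp$ag_f_central + dp$ag_f_high) / 2)
})

test_that("agriculture damages are piecewise linear with base-year identity", {
  d <- tiny_draw()
  # income factor 1 when gdppc equals its 1990 value
  a <- agriculture_damages(d, flat_climate(2), theta = 0.5, dp,
                           gdppc1990 = NULL)
  a1 <- agriculture_damages(d, flat_climate(2), theta = 0.5, dp,
                            gdppc1990 = d$gdppc[, 1])
  reg <- region_map(d$countries, "agriculture")
  frac2020 <- a1$dollars[, 1] / (d$pop[, 1] * d$gdppc[, 1])
  expect_equal(unname(frac2020), dp$ag_sigma[reg] * dp$ag_f_central[reg, 2],
               tolerance = 1e-12)
  # piecewise linearity between knots: value at 1.5 K is the knot midpoint
  f15 <- agriculture_damages(d, flat_climate(1.5), 0.5, dp,
                             gdppc1990 = d$gdppc[, 1])$dollars[, 1]
  f1 <- agriculture_damages(d, flat_climate(1), 0.5, dp,
                            gdppc1990 = d$gdppc[, 1])$dollars[, 1]
  f2 <- agriculture_damages(d, flat_climate(2), 0.5, dp,
                            gdppc1990 = d$gdppc[, 1])$dollars[, 1]
  expect_equal(f15, (f1 + f2) / 2, tolerance = 1e-9)
  # negative anomalies clamp to zero damages with a warning
  expect_warning(z <- agriculture_damages(d, flat_climate(-1), 0.5, dp),
                 "clamped")
  expect_true(all(z$dollars == 0))
})

test_that("agriculture can be beneficial (negative damages) at low warming", {
  d <- tiny_draw()
  low <- agriculture_damages(d, flat_climate(1), theta = 0, dp,
                             gdppc1990 = d$gdppc[, 1])
  expect_lt(min(low$dollars), 0)
})

test_that("region maps cover every country and fail on unknown countries", {
  cc <- c("USA", "C001", "C002")
  expect_identical(region_map(cc, "mortality"), 1:3)
  custom <- data.frame(country = c("USA", "C001"), region = c(4, 2))
  expect_error(region_map(cc, "energy", custom), "C002")
  expect_identical(region_map(cc[1:2], "energy", custom), c(4L, 2L))
})

test_that("summing country damages reproduces region-level computation", {
  d <- tiny_draw(n_countries = 24)
  s <- energy_damages(d, flat_climate(2), dp)
  reg <- region_map(d$countries, "energy")
  by_region <- rowsum(s$dollars, reg)
  gdp_region <- rowsum(d$pop * d$gdppc, reg)
  expect_equal(by_region, gdp_region * dp$energy_beta[as.integer(rownames(by_region))] * 2,
               tolerance = 1e-12, ignore_attr = TRUE)
})
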