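p0 <- climate_params()

test_that("alpha solver returns the identity root and matches a grid oracle", {
  # when the target equals the response at alpha = 1, the root is 1
  target1 <- sum(p0$a * p0$tau * (1 - exp(-100 / p0$tau)))
  expect_equal(solve_alpha(target1, p0), 1, tolerance = 1e-6)
  # independent dense-grid search oracle for an inflated target (1.5x the
  # alpha = 1 response, inside the attainable range at the default bounds)
  grid <- exp(seq(log(0.01), log(100), length.out = 200001))
  resp <- vapply(grid, function(al) {
    at <- al * p0$tau
    sum(p0$a * at * (1 - exp(-100 / at)))
  }, numeric(1))
  a_grid <- grid[which.min(abs(resp - 1.5 * target1))]
  expect_equal(solve_alpha(1.5 * target1, p0), a_grid, tolerance = 1e-4)
})

test_that("alpha targets outside the attainable range clamp with a warning", {
  lo <- p0$alpha_bounds[1]
  expect_warning(a <- solve_alpha(1e-6, p0), "clamped")
  expect_equal(a, lo)
  expect_warning(b <- solve_alpha(1e9, p0), "clamped")
  expect_equal(b, p0$alpha_bounds[2])
})

test_that("carbon step has a pre-industrial fixed point and conserves mass", {
  st <- list(R = numeric(4), U = 0)
  st2 <- scco2:::step_carbon(st, 0, 1, p0)
  expect_equal(st2$R, numeric(4))
  expect_equal(st2$U, 0)
  expect_equal(st2$conc, p0$C0)
  # conservation across a random emission sequence
  set.seed(1)
  E <- rnorm(200, 5, 4)
  st <- list(R = numeric(4), U = 0)
  for (e in E) {
    tot0 <- sum(st$R) + st$U
    st <- scco2:::step_carbon(st, e, 1.3, p0)
    expect_lt(abs(sum(st$R) + st$U - tot0 - e), 1e-9)
  }
})

test_that("constant emissions match the analytic 4-exponential convolution", {
  # with alpha fixed at 1, the discrete update is exactly the convolution of
  # E with the pool impulse responses a_i * exp(-s/tau_i) sampled annually
  E <- 8
  n <- 100
  st <- list(R = numeric(4), U = 0)
  for (k in seq_len(n)) st <- scco2:::step_carbon(st, E, 1, p0)
  # closed form: R_i(n) = a_i E tau_i (1-d_i) * (1 - d_i^n) / (1 - d_i)
  d <- exp(-1 / p0$tau)
  Ri <- p0$a * E * p0$tau * (1 - d) * (1 - d^n) / (1 - d)
  expect_equal(st$R, Ri, tolerance = 1e-6)
})

test_that("forcing satisfies the zero, doubling and quadrupling identities", {
  expect_equal(radiative_forcing(p0$C0, p0$ch4$M0, p0$n2o$N0, p0), 0)
  expect_equal(radiative_forcing(2 * p0$C0, p0$ch4$M0, p0$n2o$N0, p0), p0$F2x)
  expect_equal(radiative_forcing(4 * p0$C0, p0$ch4$M0, p0$n2o$N0, p0),
               2 * p0$F2x)
  expect_error(radiative_forcing(-1, p0$ch4$M0, p0$n2o$N0, p0), "positive")
})

test_that("two-box temperature reaches the closed-form equilibrium", {
  Tb <- c(0, 0)
  expect_equal(scco2:::step_temperature(Tb, 0, p0), c(0, 0))
  Fc <- 3
  for (i in 1:5000) Tb <- scco2:::step_temperature(Tb, Fc, p0)
  expect_equal(sum(Tb), Fc * sum(p0$q), tolerance = 1e-4)
  # sustained 2xCO2 forcing gives the implied equilibrium climate sensitivity
  Tb <- c(0, 0)
  for (i in 1:5000) Tb <- scco2:::step_temperature(Tb, p0$F2x, p0)
  expect_equal(sum(Tb), p0$F2x * sum(p0$q), tolerance = 1e-4)
})

test_that("zero pulse reproduces the baseline path bit-for-bit", {
  d <- tiny_draw(n_countries = 6)
  base <- run_climate(d, p0)
  same <- run_climate(d, p0, pulse = pulse_spec(mass_MtC = 1e-12))
  expect_equal(base$temp, same$temp, tolerance = 1e-10)
  expect_lt(base$conservation_err, 1e-9)
})

test_that("pulse warming is nonnegative and linear in pulse mass", {
  d <- tiny_draw(n_countries = 6)
  base <- run_climate(d, p0)
  p1 <- run_climate(d, p0, pulse = pulse_spec(mass_MtC = 0.1))
  p2 <- run_climate(d, p0, pulse = pulse_spec(mass_MtC = 0.2))
  post <- base$years >= 2020
  dT1 <- p1$temp[post] - base$temp[post]
  dT2 <- p2$temp[post] - base$temp[post]
  expect_true(all(dT1 >= -1e-15))
  rel <- abs(dT2[-1] - 2 * dT1[-1]) / pmax(abs(2 * dT1[-1]), 1e-300)
  expect_lt(max(rel[dT1[-1] > 1e-12]), 0.01)
})

test_that("ensemble sampling is uniform, seeded, and validates columns", {
  ens <- data.frame(q1 = seq(0.2, 0.4, length.out = 10), q2 = 0.4,
                    F2x = 3.7, r0 = 35, rU = 0.019, rT = 4.2)
  one <- sample_climate_params(ens[1, , drop = FALSE], seed = 4)
  expect_equal(one$q[1], ens$q1[1])
  expect_identical(sample_climate_params(ens, seed = 11)$q,
                   sample_climate_params(ens, seed = 11)$q)
  # frequency of each row over repeated single draws ~ multinomial
  n <- 2000
  rows <- vapply(seq_len(n), function(s) {
    sample_climate_params(ens, seed = s)$q[1]
  }, numeric(1))
  freq <- table(factor(rows, levels = ens$q1))
  se <- sqrt(n * (1 / 10) * (9 / 10))
  expect_true(all(abs(freq - n / 10) < 3 * se))
  expect_error(sample_climate_params(data.frame(q1 = 1), seed = 1),
               "missing columns")
})
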