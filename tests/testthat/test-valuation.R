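test_that("discount specs map rate labels to the packaged (rho, eta) pairs", {
  s <- discount_spec("2.0")
  expect_equal(c(s$rho, s$eta), c(0.002, 1.24))
  expect_equal(discount_spec(1.5)$eta, 1.02)
  expect_equal(discount_spec("2.5")$rho, 0.005)
  expect_equal(discount_spec(3)$eta, 1.57)
  expect_error(discount_spec(2.2), "valid rates")
})

test_that("consumption path nets out damages and respects the floor", {
  d <- tiny_draw()
  gross <- consumption_path(d, 0)
  expect_equal(gross$c, d$world$gdppc)
  gdp <- d$world$pop * d$world$gdppc
  ten <- consumption_path(d, 0.1 * gdp)
  expect_equal(ten$c, 0.9 * d$world$gdppc, tolerance = 1e-12)
  crushed <- consumption_path(d, 2 * gdp)
  expect_true(all(crushed$c == 100))
  expect_equal(crushed$n_floored, length(d$years))
})

test_that("SDF satisfies the eta = 0 and constant-growth reductions", {
  yrs <- 2020:2300
  cc <- rep(50000, length(yrs))
  s0 <- discount_spec("2.0"); s0$eta <- 0
  expect_equal(sdf_path(cc, s0, yrs), (1 + s0$rho)^-(yrs - 2020))
  g <- 0.015
  cg <- 50000 * (1 + g)^(yrs - 2020)
  s <- discount_spec("2.0")
  expect_equal(sdf_path(cg, s, yrs),
               (1 + s$rho)^-(yrs - 2020) * (1 + g)^(-s$eta * (yrs - 2020)))
  # direct-evaluation oracle at t = 2030
  expect_equal(sdf_path(cg, s, yrs)[yrs == 2030],
               exp(-10 * log(1.002) - 12.4 * log(1.015)))
  expect_equal(sdf_path(cg, s, yrs)[1], 1)
})

test_that("marginal damages difference pulsed and baseline runs per tonne", {
  yrs <- 2020:2300
  mk <- function(x) list(scco2:::sector_slice("energy", yrs, "USA",
                                              matrix(x, 1, length(yrs))))
  pu <- pulse_spec()
  same <- marginal_damage_path(mk(5), mk(5), pu)
  expect_true(all(same$md == 0))
  diff1 <- marginal_damage_path(mk(0), mk(pu$tco2), pu)
  expect_true(all(diff1$md == 1))   # tracer: normalization applied exactly once
  expect_equal(pu$tco2, 0.1e6 * 44 / 12)
})

test_that("SC-CO2 aggregation is an exact inner product", {
  md <- c(rep(1, 10), rep(0, 271))
  sdf <- rep(1, 281)
  expect_equal(scc_from_draw(md, sdf), 10)
  expect_equal(scc_from_draw(md, sdf / 2), 5)
  # compensated shuffled-order summation oracle
  set.seed(3)
  md2 <- rnorm(281) * exp(rnorm(281, 0, 3))
  sdf2 <- runif(281)
  o <- sample(281)
  kahan <- 0; comp <- 0
  for (x in (md2 * sdf2)[o]) {
    y <- x - comp
    t <- kahan + y
    comp <- (t - kahan) - y
    kahan <- t
  }
  expect_equal(scc_from_draw(md2, sdf2), kahan,
               tolerance = 1e-9)
})

test_that("partial SC-CO2 values share the total's discount path and add up", {
  yrs <- 2020:2300
  md_sector <- rbind(energy = runif(281), mortality = runif(281),
                     agriculture = runif(281) - 0.5, coastal = runif(281) / 10)
  sdf <- runif(281)
  p <- partial_scc(md_sector, sdf)
  expect_equal(sum(p), scc_from_draw(colSums(md_sector), sdf),
               tolerance = 1e-12)
  # zeroing all but one sector makes that partial the total
  solo <- md_sector; solo[-1, ] <- 0
  expect_equal(partial_scc(solo, sdf)[["energy"]],
               scc_from_draw(colSums(solo), sdf))
})

test_that("near-term rate reduces to rho + eta g under deterministic growth", {
  s <- discount_spec("2.5"); s$eta <- 0
  cc <- 50000 * (1.02)^(0:280)
  expect_equal(near_term_rate(s, cc), 100 * s$rho)
  s1 <- discount_spec("2.5"); s1$rho <- 0.005; s1$eta <- 1
  cg <- 50000 * (1.015)^(0:280)
  expect_equal(near_term_rate(s1, cg), 2.0)
  # brute-force per-draw averaging oracle
  s2 <- discount_spec("2.0")
  cons <- lapply(1:5, function(k) 40000 * (1 + 0.01 + 0.002 * k)^(0:280))
  oracle <- mean(vapply(cons, function(cc) {
    g <- vapply(2:11, function(i) (cc[i] / cc[1])^(1 / (i - 1)) - 1, numeric(1))
    mean(s2$rho + s2$eta * g)
  }, numeric(1)))
  expect_equal(near_term_rate(s2, cons), 100 * oracle)
})

test_that("deflator conversion is identity at 2020 and round-trips", {
  expect_equal(to_2020_usd(100, 2020), 100)
  v <- to_2020_usd(100, 2011)
  back <- v * gdp_deflator()$index[gdp_deflator()$year == 2011] /
    gdp_deflator()$index[gdp_deflator()$year == 2020]
  expect_equal(back, 100, tolerance = 1e-12)
  toy <- data.frame(year = c(2005, 2020), index = c(50, 100))
  expect_equal(to_2020_usd(7, 2005, toy), 14)
  expect_error(to_2020_usd(1, 1850), "not in deflator table")
})
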