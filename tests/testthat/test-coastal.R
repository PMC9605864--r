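test_that("GEV return levels match the Gumbel closed form and are monotone", {
  expect_equal(gev_return_level(1, 0.5, 0, 100), 1 - 0.5 * log(-log(0.99)))
  expect_equal(round(gev_return_level(1, 0.5, 0, 100), 2), 3.30)
  expect_error(gev_return_level(1, 0.5, 0, 1), "exceed 1")
  rls <- gev_return_level(1, 0.5, 0.1, c(10, 100, 1000))
  expect_true(all(diff(rls) > 0))
  # scale 0 degenerates to the location
  expect_equal(gev_return_level(0.7, 0, 0.1, 100), 0.7)
})

test_that("exposure is linear in height and matches a trapezoid oracle", {
  seg <- make_segments(1, seed = 3)
  e0 <- segment_exposure(seg, 0)
  expect_equal(e0$population, 0)
  e1 <- segment_exposure(seg, 1)
  e2 <- segment_exposure(seg, 2)
  expect_equal(e2$value, 2 * e1$value)
  # trapezoid integration of the uniform value density over elevation
  grid <- seq(0, 2, by = 1e-4)
  dens <- rep(seg$length_km / seg$slope * seg$density * 3e4, length(grid))
  oracle <- sum((dens[-1] + dens[-length(grid)]) / 2 * diff(grid))
  expect_equal(e2$value, oracle, tolerance = 1e-6)
})

test_that("strategy costs behave sanely in a becalmed world", {
  seg <- make_segments(1, seed = 5)
  seg$gev_scale <- 0
  seg$gev_loc <- -5            # surges never reach land
  lsl <- rep(0, 100)
  expect_equal(strategy_costs(seg, lsl, "noAdapt"), 0)
  expect_equal(strategy_costs(seg, lsl, "retreat", rp = 100), 0)
  expect_gt(strategy_costs(seg, lsl, "protect", rp = 100), 0)
  expect_error(strategy_costs(seg, lsl, "abandonship"), "unknown strategy")
})

test_that("noAdapt cost is monotone in sea level; protection cost in height", {
  seg <- make_segments(1, seed = 6)
  lsl <- seq(0, 0.8, length.out = 100)
  c1 <- strategy_costs(seg, lsl, "noAdapt")
  c2 <- strategy_costs(seg, lsl + 0.5, "noAdapt")
  expect_gte(c2, c1)
  p10 <- strategy_costs(seg, lsl, "protect", rp = 10)
  p1000 <- strategy_costs(seg, lsl, "protect", rp = 1000)
  # higher design height costs more construction; total NPV may differ but
  # the wall for RP 1000 is never cheaper to build
  z10 <- gev_return_level(seg$gev_loc, seg$gev_scale, seg$gev_shape, 10)
  z1000 <- gev_return_level(seg$gev_loc, seg$gev_scale, seg$gev_shape, 1000)
  expect_gt(z1000, z10)
  expect_gt(seg$protect_cost * seg$length_km * (max(lsl) + z1000),
            seg$protect_cost * seg$length_km * (max(lsl) + z10))
  expect_true(is.finite(p10) && is.finite(p1000))
})

test_that("least-cost choice equals exhaustive enumeration on 50 segments", {
  segs <- make_segments(50, seed = 11)
  yrs <- 2020:2100
  cand <- scco2:::coastal_candidates()
  for (i in 1:50) {
    seg <- segs[i, ]
    lsl <- seq(0, 0.04 * i, length.out = length(yrs))   # varying severity
    plan <- least_cost_adaptation(seg, lsl, years = yrs,
                                  period_length = length(yrs))
    # independent enumeration through the scalar costing path
    npv <- vapply(seq_len(nrow(cand)), function(k) {
      strategy_costs(seg, lsl, cand$strategy[k],
                     rp = if (is.na(cand$rp[k])) 100 else cand$rp[k])
    }, numeric(1))
    best <- which(npv <= min(npv) + 1e-9)[1]
    expect_equal(plan$periods$strategy[1], cand$strategy[best])
    expect_equal(plan$periods$npv[1], npv[best], tolerance = 1e-9)
    expect_lte(plan$periods$npv[1], min(npv) + 1e-6)
  }
})

test_that("zero sea-level rise and no surge risk selects noAdapt", {
  segs <- make_segments(20, seed = 12)
  segs$gev_scale <- 0
  segs$gev_loc <- -5
  lsl <- matrix(0, 20, 281)
  res <- scco2:::plan_segments(segs, lsl, 2020:2300, 0.04, 50, 3e4)
  for (p in res$plans) expect_true(all(p$periods$strategy == "noAdapt"))
})

test_that("coastal damages are deterministic and partition across countries", {
  d <- tiny_draw(n_countries = 8)
  clim <- run_climate(d)
  segs <- make_segments(30, seed = 13, countries = d$countries)
  slr <- run_sealevel(clim, sealevel_params(), segs)
  c1 <- coastal_sector_damages(segs, slr, d)
  c2 <- coastal_sector_damages(segs, slr, d)
  expect_identical(c1$dollars, c2$dollars)
  # summing country damages equals summing segment-level annual costs
  lsl <- slr$local[, match(d$years, slr$years)]
  lsl <- lsl - lsl[, 1]
  res <- scco2:::plan_segments(segs, lsl, d$years, 0.04, 50,
                               3 * mean(d$gdppc[, 1]), keep_plans = FALSE)
  expect_equal(colSums(c1$dollars), colSums(res$annual), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("coastal damages vary only through the sea-level path", {
  d <- tiny_draw(n_countries = 6)
  segs <- make_segments(15, seed = 14, countries = d$countries)
  clim <- run_climate(d)
  base <- run_sealevel(clim, sealevel_params(), segs)
  c_base <- coastal_sector_damages(segs, base, d)
  # same SLR object again: bit-identical damages
  expect_identical(coastal_sector_damages(segs, base, d)$dollars,
                   c_base$dollars)
  # a higher sea-level path weakly increases total realized cost
  hi <- base
  hi$local <- base$local + outer(rep(0.3, nrow(base$local)),
                                 pmax(base$years - 2020, 0) / 280)
  c_hi <- coastal_sector_damages(segs, hi, d)
  expect_gte(sum(c_hi$dollars), sum(c_base$dollars))
})

test_that("chosen plans are never beaten by any recorded candidate", {
  d <- tiny_draw(n_countries = 5)
  segs <- make_segments(25, seed = 15, countries = d$countries)
  clim <- run_climate(d)
  slr <- run_sealevel(clim, sealevel_params(), segs)
  cd <- coastal_sector_damages(segs, slr, d)
  for (p in cd$plans) {
    expect_true(all(p$periods$npv <= apply(p$candidate_npv, 1, min) + 1e-9))
  }
})
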