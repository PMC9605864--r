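#' Generate synthetic coastal segments
#'
#' A seeded synthetic stand-in for a global coastal-segment database: each
#' segment has a coast length, a linear elevation-area profile slope,
#' population density, an owning country, generalized extreme value (GEV)
#' storm-surge parameters, unit costs for protection and relocation, and a
#' local sea-level scaling factor.
#'
#' @param n Number of segments (default 500).
#' @param seed Integer seed.
#' @param countries Country codes to own segments (recycled at random).
#' @return Data frame of class `coastal_segments`.
#' @export
make_segments <- function(n = 500, seed = 1L, countries = c("USA", sprintf("C%03d", 1:183))) {
  seg <- with_seed(seed, {
    data.frame(
      segment_id = sprintf("S%04d", seq_len(n)),
      country = sample(countries, n, replace = TRUE),
      length_km = stats::rlnorm(n, log(20), 0.6),
      slope = stats::rlnorm(n, log(1.5), 0.5),       # m elevation per km inland
      density = stats::rlnorm(n, log(80), 1.0),      # persons per km2
      gev_loc = stats::runif(n, 0.5, 2.0),           # m
      gev_scale = stats::runif(n, 0.1, 0.6),         # m
      gev_shape = stats::runif(n, 0.0, 0.25),
      protect_cost = stats::rlnorm(n, log(5e6), 0.4),  # USD per km per m height
      reloc_cost = stats::rlnorm(n, log(3e4), 0.5),    # USD per person
      lsl_factor = pmin(pmax(stats::rnorm(n, 1, 0.15), 0.3), 1.7)
    )
  })
  class(seg) <- c("coastal_segments", "data.frame")
  seg
}

#' GEV storm-surge return level
#'
#' Quantile of the generalized extreme value distribution at probability
#' `1 - 1/rp`. Uses the Gumbel closed form when `shape == 0`; degenerates
#' to `loc` when `scale == 0`.
#'
#' @param loc,scale,shape GEV parameters (m, m, dimensionless).
#' @param rp Return period in years, must exceed 1.
#' @return Surge height (m), strictly increasing in `rp` when `scale > 0`.
#' @export
gev_return_level <- function(loc, scale, shape, rp) {
  if (any(rp <= 1)) stop("return period must exceed 1 year")
  p <- 1 - 1 / rp
  ll <- -log(p)
  ifelse(scale == 0, loc,
         ifelse(shape == 0, loc - scale * log(ll),
                loc + scale / shape * (ll^(-shape) - 1)))
}

# GEV survival function S(y) = P(surge > y), vectorized over y.
gev_survival <- function(y, loc, scale, shape) {
  if (scale == 0) return(as.numeric(y < loc))
  z <- (y - loc) / scale
  if (shape == 0) {
    1 - exp(-exp(-z))
  } else {
    t <- 1 + shape * z
    out <- numeric(length(y))
    pos <- t > 0
    out[pos] <- 1 - exp(-t[pos]^(-1 / shape))
    if (shape > 0) out[!pos] <- 1 else out[!pos] <- 0  # below/above support
    out
  }
}

# Per-segment tail integrals TI(a) = int_a^Inf S(y) dy on a common height
# grid (numeric trapezoid; the GEV upper tail beyond the grid is
# negligible at the grid cap). Returns list(grid, TI [n_seg x n_grid]).
segment_tail_grid <- function(segments, cap = 30, step = 0.05) {
  cached <- attr(segments, "tail_grid")
  if (!is.null(cached)) return(cached)
  grid <- seq(0, cap, by = step)
  S <- t(vapply(seq_len(nrow(segments)), function(i) {
    gev_survival(grid, segments$gev_loc[i], segments$gev_scale[i],
                 segments$gev_shape[i])
  }, numeric(length(grid))))
  n <- length(grid)
  seg_int <- (S[, -n, drop = FALSE] + S[, -1, drop = FALSE]) / 2 * step
  TI <- cbind(t(apply(seg_int, 1, function(r) rev(cumsum(rev(r))))), 0)
  list(grid = grid, TI = TI)
}

# Precompute and attach the tail grid so repeated planner calls over the
# same segment table (e.g. across Monte Carlo draws) reuse it.
cache_tail_grid <- function(segments) {
  attr(segments, "tail_grid") <- segment_tail_grid(segments)
  segments
}

# Linear interpolation of one segment's tail integral at heights a >= 0.
ti_at <- function(tg, i, a) {
  a <- pmin(pmax(a, 0), max(tg$grid))
  j <- pmin(findInterval(a, tg$grid), length(tg$grid) - 1)
  w <- (a - tg$grid[j]) / (tg$grid[j + 1] - tg$grid[j])
  (1 - w) * tg$TI[i, j] + w * tg$TI[i, j + 1]
}

#' Exposure below a given height
#'
#' With a linear elevation-area profile, the area below height `h` is
#' `length_km * h / slope` (km2); exposed population is area times density
#' and exposed value is population times capital per person.
#'
#' @param segment One-row segment data frame.
#' @param height Height above the datum (m).
#' @param capital_per_person USD of exposed capital per exposed person.
#' @return List with `area_km2`, `population`, `value`.
#' @export
segment_exposure <- function(segment, height, capital_per_person = 3e4) {
  area <- segment$length_km * pmax(height, 0) / segment$slope
  popx <- area * segment$density
  list(area_km2 = area, population = popx, value = popx * capital_per_person)
}

# NPV cost of one strategy over one planning period for one segment.
# lsl: local sea level for the period years (m); df: discount factors
# relative to the period start; state: list(retreat_line, wall) carried
# between periods; damage_frac: share of flooded value lost per event-year.
strategy_period_cost <- function(seg, i, tg, lsl, df, strategy, rp, state,
                                 capital_per_person, damage_frac = 0.25,
                                 maint_frac = 0.02) {
  pop_m <- seg$length_km[i] / seg$slope[i] * seg$density[i]   # persons per m
  val_m <- pop_m * capital_per_person                          # USD per m
  s_end <- lsl[length(lsl)]
  ds <- pmax(diff(c(lsl[1], lsl)), 0)
  annual <- numeric(length(lsl))
  onetime <- 0
  if (strategy == "noAdapt") {
    annual <- val_m * ds + damage_frac * val_m * ti_at(tg, i, rep(0, length(lsl)))
    new_state <- state
  } else if (strategy == "retreat") {
    z <- gev_return_level(seg$gev_loc[i], seg$gev_scale[i], seg$gev_shape[i], rp)
    line <- max(s_end + z, state$retreat_line, 0)
    band <- max(line - max(state$retreat_line, 0), 0)
    onetime <- band * (pop_m * seg$reloc_cost[i] + val_m)
    annual <- damage_frac * val_m * ti_at(tg, i, line - lsl)
    new_state <- list(retreat_line = line, wall = state$wall)
  } else if (strategy == "protect") {
    z <- gev_return_level(seg$gev_loc[i], seg$gev_scale[i], seg$gev_shape[i], rp)
    # walls carry a 0.5 m freeboard and are never designed below it
    wall <- max(s_end + z + 0.5, state$wall, 0.5)
    onetime <- seg$protect_cost[i] * seg$length_km[i] * max(wall - state$wall, 0)
    annual <- maint_frac * seg$protect_cost[i] * seg$length_km[i] * wall +
      damage_frac * val_m * ti_at(tg, i, wall - lsl)
    new_state <- list(retreat_line = state$retreat_line, wall = wall)
  } else {
    stop("unknown strategy '", strategy, "'")
  }
  list(npv = onetime + sum(df * annual), onetime = onetime, annual = annual,
       state = new_state)
}

#' NPV cost of one adaptation strategy for one segment
#'
#' Computes the net-present-value cost of `noAdapt`, `retreat` or
#' `protect` (the latter two at a surge return period `rp`) over a planning
#' horizon, under a local sea-level path and a constant discount rate.
#' `noAdapt` pays permanent inundation losses plus expected annual storm
#' damages; `retreat` pays relocation and abandonment for everything below
#' the end-of-period sea level plus the `rp`-year surge, with residual
#' expected damages beyond that line; `protect` pays construction
#' proportional to length and wall height plus maintenance, with residual
#' overtopping damages.
#'
#' @param segment One-row segment data frame (from [make_segments()]).
#' @param lsl Numeric local sea-level path over the period (m).
#' @param strategy `"noAdapt"`, `"retreat"` or `"protect"`.
#' @param rp Return period (years) for retreat/protect.
#' @param disc_rate Annual discount rate within the period.
#' @param capital_per_person Exposed capital per person (USD).
#' @return NPV cost in USD.
#' @export
strategy_costs <- function(segment, lsl, strategy, rp = 100, disc_rate = 0.04,
                           capital_per_person = 3e4) {
  tg <- segment_tail_grid(segment)
  df <- (1 + disc_rate)^-(seq_along(lsl) - 1)
  strategy_period_cost(segment, 1L, tg, lsl, df, strategy, rp,
                       list(retreat_line = 0, wall = 0),
                       capital_per_person)$npv
}

#' Least-cost adaptation plan for one segment
#'
#' For each planning period, evaluates the seven candidate strategies
#' (`noAdapt`; `retreat` and `protect` at return periods 10, 100 and 1000
#' years) and selects the cheapest by NPV, with ties broken toward
#' `noAdapt`, then `retreat`, then lower return periods. Retreat lines and
#' wall heights persist across periods.
#'
#' @param segment One-row segment data frame.
#' @param lsl Local sea-level path, one value per year from 2020.
#' @param years Calendar years matching `lsl`.
#' @param disc_rate Annual discount rate.
#' @param period_length Planning-period length in years (default 50).
#' @param capital_per_person Exposed capital per person (USD).
#' @return Object of class `adaptation_plan`: per-period chosen strategy,
#'   return period, NPV cost, all candidate NPVs, and the realized annual
#'   cost series.
#' @export
least_cost_adaptation <- function(segment, lsl, years = seq(2020, by = 1, length.out = length(lsl)),
                                  disc_rate = 0.04, period_length = 50,
                                  capital_per_person = 3e4) {
  res <- plan_segments(segment, matrix(lsl, nrow = 1), years, disc_rate,
                       period_length, capital_per_person)
  plan <- res$plans[[1]]
  plan$annual_cost <- res$annual[1, ]
  structure(plan, class = "adaptation_plan")
}

# Candidate table shared by the planner: tie-break order.
coastal_candidates <- function() {
  data.frame(strategy = c("noAdapt", "retreat", "retreat", "retreat",
                          "protect", "protect", "protect"),
             rp = c(NA, 10, 100, 1000, 10, 100, 1000))
}

# Tail-integral lookup for a heights matrix A (segments x k), rows aligned
# with tg$TI rows; uniform grid makes the bin index arithmetic.
ti_mat <- function(tg, A) {
  step <- tg$grid[2] - tg$grid[1]
  n <- length(tg$grid)
  ns <- nrow(A)
  a <- pmin(pmax(A, 0), tg$grid[n])
  j <- pmin(a %/% step + 1, n - 1)
  w <- (a - (j - 1) * step) / step
  idx <- rep.int(seq_len(ns), ncol(A)) + (as.vector(j) - 1) * ns
  T1 <- tg$TI[idx]
  T2 <- tg$TI[idx + ns]
  matrix((1 - as.vector(w)) * T1 + as.vector(w) * T2, ns)
}

# Vector planner over segments: evaluates all seven candidate strategies
# for every segment per planning period with matrix arithmetic, picks the
# least-cost one (tie-break by candidate order: noAdapt, retreat, protect,
# lower return periods first), and carries retreat lines / wall heights
# across periods. Returns per-segment plans and the realized annual cost
# matrix (segments x years). Formulas mirror strategy_period_cost exactly.
plan_segments <- function(segments, lsl_mat, years, disc_rate, period_length,
                          capital_per_person, damage_frac = 0.25,
                          maint_frac = 0.02, keep_plans = TRUE) {
  tg <- segment_tail_grid(segments)
  ns <- nrow(segments)
  ny <- length(years)
  starts <- seq(1, ny, by = period_length)
  cand <- coastal_candidates()
  nc <- nrow(cand)
  cn <- paste0(cand$strategy, ifelse(is.na(cand$rp), "", cand$rp))
  pop_m <- segments$length_km / segments$slope * segments$density
  val_m <- pop_m * capital_per_person
  zrp <- matrix(sapply(c(10, 100, 1000), function(rp) {
    gev_return_level(segments$gev_loc, segments$gev_scale, segments$gev_shape, rp)
  }), nrow = ns)                            # ns x 3
  annual <- matrix(0, ns, ny)
  retreat_line <- rep(0, ns); wall <- rep(0, ns)
  chosen <- array(NA_character_, c(ns, length(starts)))
  chosen_rp <- array(NA_real_, c(ns, length(starts)))
  chosen_npv <- array(NA_real_, c(ns, length(starts)))
  allnpv <- array(NA_real_, c(ns, length(starts), nc),
                  dimnames = list(NULL, NULL, cn))
  for (p in seq_along(starts)) {
    idx <- starts[p]:min(starts[p] + period_length - 1, ny)
    np <- length(idx)
    df <- (1 + disc_rate)^-(seq_len(np) - 1)
    lsl_p <- lsl_mat[, idx, drop = FALSE]
    s_end <- lsl_p[, np]
    ds <- pmax(lsl_p - cbind(lsl_p[, 1], lsl_p[, -np, drop = FALSE]), 0)
    npv <- matrix(NA_real_, ns, nc)
    ann <- vector("list", nc)
    one <- vector("list", nc)
    new_line <- vector("list", nc)
    new_wall <- vector("list", nc)
    # noAdapt
    ann[[1]] <- val_m * ds + damage_frac * val_m * tg$TI[, 1]
    one[[1]] <- rep(0, ns)
    new_line[[1]] <- retreat_line; new_wall[[1]] <- wall
    npv[, 1] <- as.vector(ann[[1]] %*% df)
    for (k in 2:4) {                        # retreat at rp 10/100/1000
      line <- pmax(s_end + zrp[, k - 1], retreat_line, 0)
      band <- pmax(line - pmax(retreat_line, 0), 0)
      one[[k]] <- band * (pop_m * segments$reloc_cost + val_m)
      ann[[k]] <- damage_frac * val_m * ti_mat(tg, line - lsl_p)
      new_line[[k]] <- line; new_wall[[k]] <- wall
      npv[, k] <- one[[k]] + as.vector(ann[[k]] %*% df)
    }
    for (k in 5:7) {                        # protect at rp 10/100/1000
      w <- pmax(s_end + zrp[, k - 4] + 0.5, wall, 0.5)
      one[[k]] <- segments$protect_cost * segments$length_km * pmax(w - wall, 0)
      ann[[k]] <- maint_frac * segments$protect_cost * segments$length_km * w +
        damage_frac * val_m * ti_mat(tg, w - lsl_p)
      new_line[[k]] <- retreat_line; new_wall[[k]] <- w
      npv[, k] <- one[[k]] + as.vector(ann[[k]] %*% df)
    }
    best <- max.col(-npv - 1e-9 * col(npv), ties.method = "first")
    allnpv[, p, ] <- npv
    chosen[, p] <- cand$strategy[best]
    chosen_rp[, p] <- cand$rp[best]
    chosen_npv[, p] <- npv[cbind(seq_len(ns), best)]
    for (k in seq_len(nc)) {
      sel <- best == k
      if (!any(sel)) next
      a <- ann[[k]]
      annual[sel, idx] <- if (is.matrix(a)) a[sel, , drop = FALSE] else
        matrix(a[sel], sum(sel), np)
      annual[sel, idx[1]] <- annual[sel, idx[1]] + one[[k]][sel]
      retreat_line[sel] <- new_line[[k]][sel]
      wall[sel] <- new_wall[[k]][sel]
    }
  }
  plans <- if (keep_plans) {
    lapply(seq_len(ns), function(i) {
      list(segment_id = segments$segment_id[i],
           periods = data.frame(start_year = years[starts],
                                strategy = chosen[i, ], rp = chosen_rp[i, ],
                                npv = chosen_npv[i, ]),
           candidate_npv = matrix(allnpv[i, , ], length(starts), nc,
                                  dimnames = list(NULL, cn)),
           total_npv = sum(chosen_npv[i, ] * (1 + disc_rate)^-(starts - 1)))
    })
  }
  list(plans = plans, annual = annual)
}

#' @export
print.adaptation_plan <- function(x, ...) {
  cat("Least-cost coastal adaptation plan for", x$segment_id, "\n")
  print(x$periods, row.names = FALSE)
  invisible(x)
}

#' Coastal-sector damages from least-cost adaptation
#'
#' Runs the deterministic least-cost planner for every segment against its
#' local sea-level path and maps realized annual costs (relocation,
#' construction, maintenance, storm and inundation losses) to the owning
#' countries. All uncertainty enters through the sea-level path.
#'
#' @param segments `coastal_segments` data frame.
#' @param slr A `slr_path` containing a `local` matrix (segments x years),
#'   or a matrix of local sea level.
#' @param draw `scen_draw` (defines countries, years and the capital scale:
#'   capital per person defaults to `capital_ratio` times the owning
#'   country's 2020 GDP per capita, averaged over countries).
#' @param disc_rate Annual discount rate used inside the planner.
#' @param period_length Planning-period length (years).
#' @param capital_ratio Capital per person as a multiple of GDP per capita.
#' @param keep_plans Attach the per-segment plan objects (default TRUE;
#'   disabled inside Monte Carlo loops where only dollars are needed).
#' @return `sector_slice` with country-level dollars per year.
#' @export
coastal_sector_damages <- function(segments, slr, draw, disc_rate = 0.04,
                                   period_length = 50, capital_ratio = 3,
                                   keep_plans = TRUE) {
  years <- draw$years
  lsl <- if (inherits(slr, "slr_path")) {
    if (is.null(slr$local)) stop("slr_path has no local downscaling")
    slr$local[, match(years, slr$years), drop = FALSE]
  } else {
    slr
  }
  lsl <- lsl - lsl[, 1]              # sea-level rise relative to 2020
  cap <- capital_ratio * mean(draw$gdppc[, 1])
  res <- plan_segments(segments, lsl, years, disc_rate, period_length, cap,
                       keep_plans = keep_plans)
  dollars <- matrix(0, length(draw$countries), length(years),
                    dimnames = list(draw$countries, years))
  ci <- match(segments$country, draw$countries)
  if (anyNA(ci)) stop("segment owner not among draw countries")
  for (i in seq_len(nrow(segments))) {
    dollars[ci[i], ] <- dollars[ci[i], ] + res$annual[i, ]
  }
  sector_slice("coastal", years, draw$countries, dollars, plans = res$plans)
}
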