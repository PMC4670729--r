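# Growth-rate estimation from plate kinetics.

test_that("exact log-linear data are fitted exactly", {
  tt <- seq(0, 200, by = 2)
  ps <- makePlate(tt, 0.05 * exp(0.01 * tt))
  # lm warns about the perfect fit on exact data; that is the point here
  f <- suppressWarnings(fitGrowthRate(ps, policy = "growing",
                                      bounds = c(0.049, 1)))
  expect_equal(growthRate(f), 0.01, tolerance = 1e-10)
  expect_equal(f@r_squared, 1, tolerance = 1e-12)
})

test_that("slope equals the normal-equations oracle on the identical points", {
  cfg <- simConfig("M9-glc", seed = 42)
  ps <- simulateBatch(cfg, 1000, seed = 42)
  f <- fitGrowthRate(ps, policy = "growing")
  tt <- plateTime(ps)
  A <- absorbance(ps)[, 1] - cfg@A_bg
  idx <- which(tt >= f@window[1] & tt <= f@window[2])
  expect_equal(length(idx), f@n_points)
  expect_equal(growthRate(f), normalEquationsSlope(tt[idx], log(A[idx])),
               tolerance = 1e-12)
})

test_that("five replicates recover the reference rate within its reported band", {
  cfg <- simConfig("M9-glc", seed = 1)
  rates <- vapply(1:5, function(k)
    growthRate(fitGrowthRate(simulateBatch(cfg, 1000, seed = 1000 + k),
                             policy = "growing")), numeric(1))
  expect_lt(abs(mean(rates) - 0.012), 0.0008)
})

test_that("fitted rate is invariant under absorbance rescaling with an explicit window", {
  tt <- seq(0, 300, by = 2)
  A <- 0.02 * exp(0.011 * tt) * exp(rnorm(length(tt), 0, 0.01))
  f1 <- fitGrowthRate(makePlate(tt, A), window = c(100, 250), background = 0)
  f2 <- fitGrowthRate(makePlate(tt, 7 * A), window = c(100, 250), background = 0)
  expect_equal(growthRate(f1), growthRate(f2), tolerance = 1e-12)
})

test_that("windows with too few or non-positive samples are rejected", {
  tt <- seq(0, 20, by = 2)
  ps <- makePlate(tt, 0.04 + 0 * tt)
  expect_error(fitGrowthRate(ps, policy = "growing"), "window")
  ps2 <- makePlate(tt, c(rep(0.1, 6), rep(-0.01, 5)))
  expect_error(fitGrowthRate(ps2, window = c(0, 21), background = 0),
               "non-positive")
})

test_that("condition summaries follow the 2-SEM definition exactly", {
  gf <- function(r) new("GrowthFit", rate = r, se = 1e-4, window = c(0, 100),
                        n_points = 10L, r_squared = 0.99, regime = "growing",
                        well = "w", iptg_uM = 1000)
  s0 <- summarizeCondition(list(gf(0.01), gf(0.01), gf(0.01)))
  expect_equal(s0@mean_rate, 0.01)
  expect_equal(s0@ci_halfwidth, 0)
  s1 <- summarizeCondition(list(gf(0.010), gf(0.014)))
  expect_equal(s1@mean_rate, 0.012)
  expect_equal(s1@ci_halfwidth, 2 * sd(c(0.010, 0.014)) / sqrt(2))
  expect_equal(s1@ci_halfwidth, 0.004)
  # direct recomputation from a simulated replicate set
  cfg <- simConfig("M9-glc", seed = 4)
  ps <- simulateDoseSeries(cfg, levels = 1000, replicates = 5)
  fits <- conditionTable(ps, policy = "growing")
  s <- summarizeCondition(fits)
  expect_equal(s@mean_rate, mean(fits$rate), tolerance = 1e-15)
  expect_equal(s@ci_halfwidth, 2 * sd(fits$rate) / sqrt(5), tolerance = 1e-15)
  # mixed conditions are refused
  bad <- list(gf(0.01), new("GrowthFit", rate = 0.01, se = 1e-4,
                            window = c(0, 100), n_points = 10L,
                            r_squared = 0.99, regime = "growing",
                            well = "v", iptg_uM = 10))
  expect_error(summarizeCondition(bad), "mix")
})

test_that("replicate confidence halfwidth scales as 1/sqrt(n)", {
  gf <- function(r) new("GrowthFit", rate = r, se = 1e-4, window = c(0, 100),
                        n_points = 10L, r_squared = 0.99, regime = "growing",
                        well = "w", iptg_uM = 1000)
  set.seed(7)
  ci_at <- function(n, reps = 300) {
    mean(replicate(reps, {
      rates <- 0.012 + rnorm(n, 0, 5e-4)
      summarizeCondition(lapply(rates, gf))@ci_halfwidth
    }))
  }
  ci <- vapply(c(2, 8, 32), ci_at, numeric(1))
  # expected E[ci_n] = 2 * c4(n) * sigma / sqrt(n), c4 the chi-mean factor
  c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  expected <- 2 * c4(c(2, 8, 32)) * 5e-4 / sqrt(c(2, 8, 32))
  expect_equal(ci / expected, rep(1, 3), tolerance = 0.08)
})

test_that("absorbance-OD conversion uses the pathlength factor", {
  expect_equal(absorbanceToOD(0), 0)
  expect_equal(absorbanceToOD(0.5), 1.17)
  a <- c(0.03, 0.2, 0.45)
  expect_equal(absorbanceToOD(a) / 2.34, a, tolerance = 1e-12)
  expect_error(absorbanceToOD(-0.1), "non-negative")
})

test_that("escape detection finds regrowth after the arrest window", {
  tt <- seq(0, 2880, by = 10)
  flat <- makePlate(tt, rep(0.04, length(tt)))
  expect_false(detectEscape(flat, arrest_window_end = 1440,
                            background = 0)$escaped)
  # exponential escape starting at 1800 min
  A <- ifelse(tt < 1800, 0.04, 0.04 * exp(0.01 * (tt - 1800)))
  esc <- detectEscape(makePlate(tt, pmin(A, 0.6)), arrest_window_end = 1440,
                      background = 0)
  expect_true(esc$escaped)
  # linear-scan oracle for the crossing time
  t_oracle <- tt[which(tt > 1440 & pmin(A, 0.6) > 0.1)[1]]
  expect_equal(esc$t_escape, t_oracle)
  expect_error(detectEscape(makePlate(seq(0, 100, 10), rep(0.04, 11)),
                            arrest_window_end = 1440), "before")
})

test_that("escaper counting matches the number of programmed escape mutants", {
  cfg <- simConfig("M9-glc", seed = 8)
  esc_at <- c(rep(NA, 31), 1600, 2000)   # 2 escapers among 33 cultures
  wells <- lapply(seq_along(esc_at), function(k)
    simulateBatch(cfg, iptg = 0, duration = 2880,
                  escape_time = if (is.na(esc_at[k])) NULL else esc_at[k],
                  well = sprintf("c%02d", k), seed = 3000 + k))
  plate <- combinePlates(wells)
  n_esc <- sum(vapply(colnames(plate), function(w)
    detectEscape(plate, well = w, arrest_window_end = 1440)$escaped,
    logical(1)))
  expect_equal(n_esc, 2L)
})
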