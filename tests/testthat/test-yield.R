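# Spline-derivative instantaneous yield estimation.

test_that("spline derivatives reproduce polynomial derivatives", {
  t <- seq(0, 300, by = 10)
  # linear trends are in the null space of the roughness penalty: exact
  lin <- fitConcentrationSpline(t, 2 - 0.004 * t)
  expect_equal(lin$deriv(seq(20, 280, by = 20)),
               rep(-0.004, 14), tolerance = 1e-9)
  # cubics are recovered at central interior points (natural boundary
  # conditions distort the fit near the edges)
  v <- 1e-4 * t^3 - 0.02 * t^2 + t + 5
  cub <- fitConcentrationSpline(t, v)
  centre <- c(140, 150, 160)
  expect_equal(cub$deriv(centre), 3e-4 * centre^2 - 0.04 * centre + 1,
               tolerance = 1e-8)
  expect_error(cub$value(400), "outside")
  expect_error(fitConcentrationSpline(t[1:5], v[1:5]), "8 samples")
})

test_that("a noisy linear decay slope is recovered within 10 percent", {
  set.seed(9)
  t <- seq(0, 600, by = 10)
  sp <- fitConcentrationSpline(t, 3 - 0.004 * t + rnorm(length(t), 0, 0.02))
  inner <- seq(60, 540, by = 20)
  expect_true(all(abs(sp$deriv(inner) / -0.004 - 1) < 0.10))
})

test_that("spline derivatives agree with central differences on clean simulator output", {
  cfg <- noiseFreeConfig()
  # fine sampling keeps the finite-difference oracle's own O(h^2) error
  # below the comparison tolerance
  pr <- simulateProduction(cfg, "R-gly", dt = 5, noise_conc_cv = 0,
                           noise_conc_floor = 0)
  sp <- fitConcentrationSpline(pr@time, pr@glycerol)
  h <- diff(pr@time[1:2])
  mid <- pr@time[-c(1, length(pr@time))]
  fd <- (pr@glycerol[-(1:2)] - pr@glycerol[1:(length(pr@time) - 2)]) / (2 * h)
  big <- abs(fd) > 0.1 * max(abs(fd))
  expect_true(all(abs(sp$deriv(mid[big]) / fd[big] - 1) < 0.02))
})

test_that("linear concentration data give the constant closed-form yield", {
  t <- seq(0, 600, by = 20)
  glc <- fitConcentrationSpline(t, 2 - 0.002 * t)
  gly <- fitConcentrationSpline(t, 0.3 * 0.002 * t)
  y <- instantaneousYield(gly, glc, window = c(50, 550))
  expect_equal(y@Y, rep(0.30, length(y@Y)), tolerance = 1e-9)
})

test_that("vanishing consumption is masked, not divided through", {
  t <- seq(0, 600, by = 10)
  # consumption stops halfway
  glc_v <- ifelse(t < 300, 2 - 0.004 * t, 2 - 0.004 * 300)
  gly_v <- ifelse(t < 300, 0.001 * t, 0.3)
  glc <- fitConcentrationSpline(t, glc_v, spar = 0.3)
  gly <- fitConcentrationSpline(t, gly_v, spar = 0.3)
  y <- instantaneousYield(gly, glc, window = c(50, 550))
  expect_true(any(is.na(y@Y)))
  expect_true(all(is.finite(y@Y[!is.na(y@Y)])))
  expect_error(instantaneousYield(gly, glc, window = c(420, 550)),
               "consumption")
  expect_error(instantaneousYield(gly, glc, window = c(50, 900)),
               "outside")
})

test_that("yield is invariant to time shifts and concentration offsets", {
  set.seed(4)
  t <- seq(0, 600, by = 20)
  glc_v <- 2 - 0.002 * t - 1e-6 * t^2 + rnorm(length(t), 0, 0.005)
  gly_v <- 0.0008 * t + 5e-7 * t^2 + rnorm(length(t), 0, 0.005)
  base <- instantaneousYield(fitConcentrationSpline(t, gly_v),
                             fitConcentrationSpline(t, glc_v), c(100, 500))
  shifted <- instantaneousYield(fitConcentrationSpline(t + 137, gly_v + 3),
                                fitConcentrationSpline(t + 137, glc_v + 11),
                                c(100, 500) + 137)
  expect_equal(shifted@Y, base@Y, tolerance = 1e-6)
})

test_that("replicate averaging matches the brute-force recomputation", {
  t <- seq(0, 600, by = 20)
  mk <- function(const) {
    glc <- fitConcentrationSpline(t, 2 - 0.002 * t)
    gly <- fitConcentrationSpline(t, const * 0.002 * t)
    instantaneousYield(gly, glc, c(50, 550))
  }
  same <- averageYieldProfiles(list(mk(0.4), mk(0.4)))
  expect_equal(same@Y, rep(0.4, length(same@Y)), tolerance = 1e-9)
  expect_equal(same@ci_halfwidth, rep(0, length(same@Y)), tolerance = 1e-9)
  two <- averageYieldProfiles(list(mk(0.3), mk(0.5)))
  expect_equal(two@Y, rep(0.4, length(two@Y)), tolerance = 1e-9)
  expect_equal(two@ci_halfwidth, rep(2 * sd(c(0.3, 0.5)) / sqrt(2),
                                     length(two@Y)), tolerance = 1e-8)
  # six simulated replicates vs per-timepoint recomputation
  cfg <- simConfig("M9-glc", seed = 6)
  profs <- lapply(1:6, function(r) suppressWarnings(
    productionYield(simulateProduction(cfg, "R-gly", replicate = r,
                                       seed = 600 + r))))
  avg <- averageYieldProfiles(profs)
  vals <- sapply(profs, function(p) approx(p@time, p@Y, avg@time)$y)
  expect_equal(avg@Y, rowMeans(vals), tolerance = 1e-12)
  expect_equal(avg@ci_halfwidth, 2 * apply(vals, 1, sd) / sqrt(6),
               tolerance = 1e-12)
})

test_that("constitutive producer yield is constant; arrest doubles it", {
  cfg <- noiseFreeConfig()
  yW <- productionYield(simulateProduction(cfg, "W-gly", noise_conc_cv = 0,
                                           noise_conc_floor = 0))
  relspread <- diff(range(yW@Y, na.rm = TRUE)) / mean(yW@Y, na.rm = TRUE)
  expect_lt(relspread, 0.05)
  yR <- productionYield(simulateProduction(cfg, "R-gly", noise_conc_cv = 0,
                                           noise_conc_floor = 0))
  ratio <- max(yR@Y, na.rm = TRUE) / mean(yW@Y, na.rm = TRUE)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
  # estimated Y tracks the simulator's instantaneous flux ratio (finely
  # resolved state so the reference ratio is itself accurate)
  st <- attr(simulateProduction(cfg, "R-gly", dt = 5, noise_conc_cv = 0,
                                noise_conc_floor = 0), "state")
  mids <- (st$time[-1] + st$time[-nrow(st)]) / 2
  truth <- approx(mids, diff(st$gly) / -diff(st$glc), yR@time)$y
  ok <- !is.na(yR@Y)
  expect_true(all(abs(yR@Y[ok] / truth[ok] - 1) < 0.10))
})
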