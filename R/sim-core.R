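# ODE core of the growth-switch simulator.
#
# State vector: c (beta' pool, a.u.), g (realized growth rate, min^-1),
# i/m (immature/mature reporter, a.u.), B (biomass, absorbance units),
# glc/gly (g/L). The realized growth rate relaxes toward the RNAP-set target
# mu(c) with time constant tau_g, capturing the slow proteome readjustment
# that gives the observed lags on arrest and recovery. Transcription, growth
# and uptake are all gated by the glucose Monod factor so that every state
# stays bounded through glucose exhaustion.

switchRHS <- function(t, y, pr) {
  s <- y[6] / (y[6] + pr$K_glc)
  geff <- y[2] * s
  p <- pr$p_fun(t) * s
  mu_t <- pr$mu_max * y[1]^pr$n / (y[1]^pr$n + pr$K^pr$n)
  # plain strains take up glucose stoichiometrically with growth (plus a
  # small maintenance flux); the engineered glycerol producers pull a fixed
  # specific flux through the heterologous DHAP drain irrespective of growth
  q <- if (pr$uptake == "flux") pr$q_max * y[5] * s
       else (geff / pr$Y_abs + pr$q_maint * s) * y[5]
  dc <- p - geff * y[1]
  dg <- (mu_t - y[2]) / pr$tau_g
  di <- p - (pr$k_mat + geff) * y[3]
  dm <- pr$k_mat * y[3] - geff * y[4]
  dB <- geff * y[5]
  dglc <- -q
  dgly <- pr$f_branch * max(q - geff * y[5] / pr$Y_abs, 0)
  list(c(dc, dg, di, dm, dB, dglc, dgly))
}

# Integrate the switch ODEs with a piecewise-constant promoter activity.
# `segments` is a data.frame(t_start, p) with t_start[1] == 0; output on
# `times`. Returns a data.frame of the noise-free trajectory.
integrateSwitch <- function(config, segments, times, q_max = NULL,
                            f_branch = NULL, glc0 = NULL, B0 = NULL,
                            c0 = NULL, uptake = c("growth", "flux")) {
  uptake <- match.arg(uptake)
  stopifnot(segments$t_start[1] == 0, !is.unsorted(segments$t_start, strictly = TRUE))
  q_max <- if (is.null(q_max)) config@q_max else q_max
  f_branch <- if (is.null(f_branch)) config@f_branch else f_branch
  glc0 <- if (is.null(glc0)) config@glc0 else glc0
  B0 <- if (is.null(B0)) config@A0 else B0
  c0 <- if (is.null(c0)) config@c0 else c0
  mu0 <- growthLaw(c0, config)
  i0 <- if (c0 > 0) min(config@k_tx_max / (config@k_mat + mu0), c0) else 0
  y0 <- c(c = c0, g = mu0, i = i0, m = c0 - i0, B = B0, glc = glc0, gly = 0)
  pr <- list(mu_max = config@mu_max, n = config@hill_n, K = config@hill_K,
             tau_g = config@tau_g, k_mat = config@k_mat, K_glc = config@K_glc,
             q_max = q_max, Y_abs = config@y_biomass_abs, f_branch = f_branch,
             q_maint = 0.05 * config@mu_max / config@y_biomass_abs,
             uptake = uptake, p_fun = NULL)
  t_end <- max(times)
  bounds <- c(segments$t_start, t_end)
  out <- NULL
  y <- y0
  for (k in seq_len(nrow(segments))) {
    t0 <- bounds[k]; t1 <- bounds[k + 1]
    if (t1 <= t0) next
    pk <- segments$p[k]
    pr$p_fun <- function(t) pk
    tt <- sort(unique(c(t0, times[times > t0 & times <= t1], t1)))
    seg <- deSolve::ode(y, tt, switchRHS, pr, method = "lsoda",
                        atol = 1e-9, rtol = 1e-8)
    y <- seg[nrow(seg), -1]
    undershoot <- min(c(y, 0))
    if (undershoot < -1e-6)
      gsStop("gs_integration_error",
             "state went negative during integration (min %.3g at t=%.1f min)",
             undershoot, t1)
    y <- pmax(y, 0)
    out <- rbind(out, seg[-nrow(seg), , drop = FALSE])
  }
  out <- rbind(out, c(t_end, y))
  out <- as.data.frame(out)
  names(out) <- c("time", "c", "g", "i", "m", "B", "glc", "gly")
  out[out$time %in% times, , drop = FALSE]
}

# Turn an IPTG schedule into promoter-activity segments.
scheduleToSegments <- function(config, schedule, strainMode = "R",
                               escape_time = NULL, duration = NULL) {
  if (is.numeric(schedule) && length(schedule) == 1)
    schedule <- data.frame(time_min = 0, iptg_uM = schedule)
  if (!all(c("time_min", "iptg_uM") %in% names(schedule)))
    gsStop("gs_input_error", "schedule needs columns time_min and iptg_uM")
  if (schedule$time_min[1] != 0 || any(schedule$time_min < 0))
    gsStop("gs_input_error", "schedule times must start at 0 and be non-negative")
  if (is.unsorted(schedule$time_min, strictly = TRUE))
    gsStop("gs_input_error", "schedule times must be strictly increasing")
  seg <- data.frame(
    t_start = schedule$time_min,
    p = promoterActivity(schedule$iptg_uM, config, strainMode)
  )
  if (!is.null(escape_time) && is.finite(escape_time)) {
    # escape mutant: rpoBC becomes constitutive at escape_time
    seg <- seg[seg$t_start < escape_time, , drop = FALSE]
    seg <- rbind(seg, data.frame(t_start = escape_time, p = config@k_tx_max))
  }
  seg
}
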