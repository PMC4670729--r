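# Independent oracles used across the suite. These reimplement the checked
# quantities by a different route (fixed-step integration, closed forms,
# normal equations, exhaustive enumeration) and must stay independent of the
# package internals they validate.

# Fixed-step classical RK4 integration of the switch ODEs at constant
# promoter activity. Deliberately hand-coded, independent of deSolve.
rk4Switch <- function(config, p_const, duration, dt = 0.01,
                      out_every = 2, uptake = "growth", q_max = NULL,
                      f_branch = NULL, B0 = NULL, glc0 = NULL) {
  mu_max <- config@mu_max; n <- config@hill_n; K <- config@hill_K
  tau <- config@tau_g; kmat <- config@k_mat; Kg <- config@K_glc
  Y <- config@y_biomass_abs
  qmx <- if (is.null(q_max)) config@q_max else q_max
  qmt <- 0.05 * config@mu_max / Y
  fb <- if (is.null(f_branch)) config@f_branch else f_branch
  B0 <- if (is.null(B0)) config@A0 else B0
  glc0 <- if (is.null(glc0)) config@glc0 else glc0
  c0 <- config@c0
  mu0 <- mu_max * c0^n / (c0^n + K^n)
  i0 <- if (c0 > 0) min(config@k_tx_max / (kmat + mu0), c0) else 0
  y <- c(c0, mu0, i0, c0 - i0, B0, glc0, 0)
  deriv <- function(y) {
    s <- y[6] / (y[6] + Kg)
    geff <- y[2] * s
    p <- p_const * s
    mu_t <- mu_max * y[1]^n / (y[1]^n + K^n)
    q <- if (uptake == "flux") qmx * y[5] * s
         else (geff / Y + qmt * s) * y[5]
    c(p - geff * y[1],
      (mu_t - y[2]) / tau,
      p - (kmat + geff) * y[3],
      kmat * y[3] - geff * y[4],
      geff * y[5],
      -q,
      fb * max(q - geff * y[5] / Y, 0))
  }
  nstep <- round(duration / dt)
  keep <- round(out_every / dt)
  out <- matrix(NA_real_, nstep %/% keep + 1, 8)
  out[1, ] <- c(0, y)
  row <- 1
  for (k in seq_len(nstep)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (k %% keep == 0) {
      row <- row + 1
      out[row, ] <- c(k * dt, y)
    }
  }
  colnames(out) <- c("time", "c", "g", "i", "m", "B", "glc", "gly")
  as.data.frame(out)
}

# OLS slope by explicit normal equations (no lm()).
normalEquationsSlope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Enumerate vertices of {v : S v = 0, lb <= v <= ub} by fixing subsets of
# variables at bounds and solving the remaining square system; returns the
# maximal value of obj'v over feasible vertices.
vertexEnumerationMax <- function(obj, S, lb, ub, tol = 1e-8) {
  n <- ncol(S); m <- nrow(S)
  free_needed <- n - qr(S)$rank
  best <- -Inf
  fix_sets <- combn(n, n - qr(S)$rank, simplify = FALSE)
  feasible <- function(v) all(v >= lb - tol) && all(v <= ub + tol) &&
    max(abs(S %*% v)) < tol
  for (fix in fix_sets) {
    rest <- setdiff(seq_len(n), fix)
    A <- S[, rest, drop = FALSE]
    if (qr(A)$rank < length(rest)) next
    grid <- expand.grid(rep(list(c("lb", "ub")), length(fix)),
                        stringsAsFactors = FALSE)
    for (g in seq_len(nrow(grid))) {
      vfix <- ifelse(unlist(grid[g, ]) == "lb", lb[fix], ub[fix])
      rhs <- -S[, fix, drop = FALSE] %*% vfix
      sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[fix] <- vfix; v[rest] <- sol
      if (feasible(v)) best <- max(best, sum(obj * v))
    }
  }
  best
}

# Build a minimal single-well PlateSeries from explicit vectors.
makePlate <- function(time, A, F = NULL, well = "w1", iptg = 1000,
                      A_bg = 0) {
  PlateSeries(
    time = time,
    absorbance = matrix(A, ncol = 1, dimnames = list(NULL, well)),
    fluorescence = if (is.null(F)) NULL else
      matrix(F, ncol = 1, dimnames = list(NULL, well)),
    wellData = data.frame(well = well, strain = "R", medium = "M9-glc",
                          iptg_uM = iptg, replicate = 1L, row.names = well),
    A_bg = A_bg
  )
}

noiseFreeConfig <- function(medium = "M9-glc", ...) {
  simConfig(medium, noise_abs = 0, noise_fluo = 0, ...)
}
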