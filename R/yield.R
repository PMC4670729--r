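#' Fit a smoothing spline to a concentration time course
#'
#' Cubic smoothing spline with the smoothing parameter chosen by generalized
#' cross-validation, exposing the fitted value and its analytic first
#' derivative at arbitrary times inside the data range. Differentiating
#' noisy concentration data requires this regularization; the spline's
#' analytic derivative avoids the noise amplification of finite differences.
#'
#' @param time sampling times (min), strictly increasing, >= 8 samples.
#' @param values concentrations (g/L).
#' @param spar optional fixed smoothing parameter (bypasses GCV).
#' @param max_df cap on the equivalent degrees of freedom. Substrate and
#'   product curves are smooth saturation-shaped curves; when GCV
#'   occasionally chases noise (its known failure mode on short series) the
#'   fit is repeated at this df.
#' @return An object of class \code{concSpline}: a list with functions
#'   \code{value(t)} and \code{deriv(t)} and the data \code{range}.
#'   Evaluation outside the range is an error.
#' @examples
#' t <- seq(0, 600, by = 30)
#' sp <- fitConcentrationSpline(t, 2 - 0.002 * t)
#' sp$deriv(300)
#' @export
fitConcentrationSpline <- function(time, values, spar = NULL, max_df = 8) {
  if (length(time) < 8)
    gsStop("gs_insufficient_data",
           "need >= 8 samples for a concentration spline (got %d)", length(time))
  if (is.unsorted(time, strictly = TRUE))
    gsStop("gs_input_error", "time must be strictly increasing")
  sp <- if (is.null(spar)) smooth.spline(time, values, cv = FALSE)
        else smooth.spline(time, values, spar = spar)
  if (is.null(spar) && !is.null(max_df) && sp$df > max_df) {
    # only rein GCV in when the fit is genuinely absorbing noise; an exact
    # (noise-free) series is left at the near-interpolating GCV choice
    noisy <- sd(values - predict(sp, time)$y) > 1e-6 * max(sd(values), 1e-12)
    if (noisy) sp <- smooth.spline(time, values, df = max_df)
  }
  rng <- range(time)
  guard <- function(t) {
    if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9))
      gsStop("gs_out_of_range",
             "evaluation at t outside the fitted range [%g, %g]",
             rng[1], rng[2])
  }
  structure(list(
    value = function(t) { guard(t); predict(sp, t)$y },
    deriv = function(t) { guard(t); predict(sp, t, deriv = 1)$y },
    range = rng, spline = sp
  ), class = "concSpline")
}

#' Instantaneous glycerol production yield
#'
#' The time-varying mass yield \code{Y(t) = -(d gly/dt) / (d glc/dt)}, i.e.
#' grams of glycerol formed per gram of glucose consumed, evaluated on a
#' uniform grid inside the analysis window from the analytic spline
#' derivatives. Biomass normalization cancels exactly in the ratio of
#' specific rates and is therefore omitted. Points where the glucose
#' consumption rate is below \code{eps_frac} times its maximal magnitude
#' are masked (\code{NA}) -- the ratio is not well defined there.
#'
#' @param gly \code{concSpline} of the glycerol time course.
#' @param glc \code{concSpline} of the glucose time course.
#' @param window evaluation window \code{c(t0, t1)} (min); defaults used in
#'   the reference analysis are \code{c(250, 450)} for the constitutive
#'   producer and \code{c(250, 700)} for the switchable producer.
#' @param n_grid number of evaluation points.
#' @param eps_frac mask threshold as a fraction of the maximal glucose
#'   consumption rate inside the window.
#' @return A \linkS4class{YieldProfile}.
#' @export
instantaneousYield <- function(gly, glc, window, n_grid = 101,
                               eps_frac = 0.05) {
  if (window[1] < glc$range[1] || window[2] > glc$range[2] ||
      window[1] < gly$range[1] || window[2] > gly$range[2])
    gsStop("gs_out_of_range", "window [%g, %g] outside the fitted data range",
           window[1], window[2])
  tt <- seq(window[1], window[2], length.out = n_grid)
  dglc <- glc$deriv(tt)
  dgly <- gly$deriv(tt)
  cons <- -dglc  # consumption rate, should be positive
  # mask threshold relative to the maximal consumption rate of the whole
  # experiment, not just the window
  full <- seq(glc$range[1], glc$range[2], length.out = 201)
  eps <- eps_frac * max(-glc$deriv(full))
  if (max(cons) <= 0 || all(cons < eps))
    gsStop("gs_degenerate_window",
           "no measurable glucose consumption in window [%g, %g]",
           window[1], window[2])
  Y <- ifelse(cons >= eps, dgly / cons, NA_real_)
  nbad <- sum(Y > 1.1 | Y < -0.1, na.rm = TRUE)  # beyond theoretical max + 10%
  if (nbad > 0)
    warning(sprintf("%d yield point(s) outside the plausible range [0, 1.1]",
                    nbad))
  new("YieldProfile", time = tt, Y = Y,
      ci_halfwidth = rep(NA_real_, length(tt)), window = window)
}

#' Average yield profiles across replicates
#'
#' Pointwise replicate mean and 2 x SEM on the common evaluation grid,
#' restricted to the intersection of the windows; grid points masked in any
#' replicate stay masked.
#'
#' @param profiles list of \linkS4class{YieldProfile} objects evaluated on
#'   grids of equal resolution.
#' @return A \linkS4class{YieldProfile} with \code{ci_halfwidth} filled.
#' @export
averageYieldProfiles <- function(profiles) {
  if (length(profiles) < 2)
    gsStop("gs_input_error", "need >= 2 profiles to average")
  w1 <- max(vapply(profiles, function(p) p@window[1], numeric(1)))
  w2 <- min(vapply(profiles, function(p) p@window[2], numeric(1)))
  if (w2 <= w1)
    gsStop("gs_degenerate_window", "profile windows do not overlap")
  tt <- profiles[[1]]@time
  tt <- tt[tt >= w1 & tt <= w2]
  if (!length(tt))
    gsStop("gs_degenerate_window", "no common evaluation points")
  vals <- vapply(profiles, function(p) approx(p@time, p@Y, tt)$y,
                 numeric(length(tt)))
  vals <- matrix(vals, nrow = length(tt))
  m <- rowMeans(vals)
  s <- apply(vals, 1, sd)
  n <- length(profiles)
  new("YieldProfile", time = tt, Y = m, ci_halfwidth = 2 * s / sqrt(n),
      window = c(w1, w2))
}

#' Yield profile of one production run
#'
#' Convenience wrapper: splines both concentration series of a
#' \linkS4class{ProductionSeries} and evaluates the instantaneous yield.
#'
#' @param series a \linkS4class{ProductionSeries}.
#' @param window evaluation window (min); default picked by strain label
#'   (\code{c(250, 450)} for W-gly, \code{c(250, 700)} for R-gly).
#' @param glc_floor concentrations are only informative while glucose
#'   remains non-negligible; samples after glucose drops below this
#'   fraction of its initial value are excluded from the spline fits
#'   (the flat post-exhaustion phase would otherwise distort the GCV
#'   smoothing). The window is clipped accordingly.
#' @param ... passed to \code{\link{instantaneousYield}}.
#' @return A \linkS4class{YieldProfile}.
#' @export
productionYield <- function(series, window = NULL, glc_floor = 0.025, ...) {
  if (is.null(window))
    window <- if (series@strain == "W-gly") c(250, 450) else c(250, 700)
  below <- which(series@glucose < glc_floor * max(series@glucose))
  keep <- if (length(below)) seq_len(max(below[1] - 1, 8))
          else seq_along(series@time)
  glc <- fitConcentrationSpline(series@time[keep], series@glucose[keep])
  gly <- fitConcentrationSpline(series@time[keep], series@glycerol[keep])
  window[2] <- min(window[2], max(series@time[keep]))
  instantaneousYield(gly, glc, window, ...)
}

setMethod("show", "YieldProfile", function(object) {
  ok <- !is.na(object@Y)
  cat(sprintf(
    "YieldProfile on [%g, %g] min: %d/%d points evaluable, Y in [%.3g, %.3g]\n",
    object@window[1], object@window[2], sum(ok), length(ok),
    min(object@Y[ok]), max(object@Y[ok])))
  invisible(NULL)
})
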