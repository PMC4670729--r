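#' Background-correct absorbance and fluorescence
#'
#' Subtracts the medium/plate absorbance background and removes cellular
#' autofluorescence from the fluorescence channel. Autofluorescence is
#' modeled as linear in biomass, \code{F_auto = f0 + a * A}, with \code{f0}
#' and \code{a} regressed from a control culture of an untagged strain grown
#' in the same medium; the fitted coefficients are stored in
#' \code{metadata(x)$autofluorescence}. Negative corrected values are
#' clipped to 0 and counted.
#'
#' @param series a \linkS4class{PlateSeries} of reporter-tagged wells.
#' @param control a \linkS4class{PlateSeries} of untagged control wells on an
#'   overlapping time grid, or \code{NULL} to fall back (with a warning) to
#'   the constant coefficients in \code{fallback}.
#' @param background medium absorbance background; defaults to the plate's
#'   recorded value.
#' @param fallback named list \code{list(f0 =, a =)} used when no control is
#'   given.
#' @return The corrected \linkS4class{PlateSeries} (background absorbance 0).
#' @export
correctBackground <- function(series, control = NULL, background = NULL,
                              fallback = list(f0 = 0, a = 0)) {
  if (is.null(background)) {
    background <- plateBackground(series)
    if (is.na(background)) background <- 0
  }
  tt <- plateTime(series)
  A <- absorbance(series) - background
  F_ <- fluorescence(series)
  if (is.null(F_))
    gsStop("gs_input_error", "series has no fluorescence assay")
  if (!is.null(control)) {
    ctt <- plateTime(control)
    keep <- ctt %in% tt
    if (!any(keep))
      gsStop("gs_input_error", "control shares no timepoints with the series")
    ca <- as.vector(absorbance(control)[keep, , drop = FALSE]) - background
    cf <- as.vector(fluorescence(control)[keep, , drop = FALSE])
    fit <- lm(cf ~ ca)
    f0 <- unname(coef(fit)[1]); a <- unname(coef(fit)[2])
  } else {
    warning("no control culture given; using constant background coefficients")
    f0 <- fallback$f0; a <- fallback$a
  }
  Fc <- F_ - f0 - a * A
  nneg <- sum(Fc < 0) + sum(A < 0)
  A[A < 0] <- 0
  Fc[Fc < 0] <- 0
  out <- PlateSeries(time = tt, absorbance = A, fluorescence = Fc,
                     wellData = wellInfo(series), A_bg = 0)
  metadata(out)$states <- metadata(series)$states
  metadata(out)$autofluorescence <- list(f0 = f0, a = a, n_clipped = nneg)
  out
}

#' Reconstruct the total reporter concentration from fluorescence
#'
#' The measured fluorescence concentration proxy \code{rho = F/A} only sees
#' the mature fluorophore. Because maturation is first order with rate
#' \code{k_mat} and both species are diluted by growth at rate \code{mu},
#' the immature pool can be reconstructed as
#' \code{iota = (d rho/dt + mu * rho) / k_mat}, with the derivative taken
#' from a generalized cross-validated smoothing spline. The total reporter
#' concentration \code{rho + iota} is proportional to the total beta' pool
#' when the reporter is a translational fusion. At steady state the formula
#' reduces to \code{rho_total = rho * (1 + mu / k_mat)}.
#'
#' @param series a background-corrected \linkS4class{PlateSeries} (see
#'   \code{\link{correctBackground}}).
#' @param well well identifier (optional for single-well series).
#' @param k_mat maturation rate (min^-1), > 0.
#' @param mu dilution rate: a number, a \linkS4class{GrowthFit}, or a vector
#'   along the time grid.
#' @param min_abs samples with absorbance below this are excluded from the
#'   profile (ratio F/A unstable near zero biomass).
#' @return A \linkS4class{ReporterProfile}.
#' @export
reconstructTotalReporter <- function(series, well = NULL, k_mat = 0.028,
                                     mu, min_abs = 1e-3) {
  if (k_mat <= 0) gsStop("gs_input_error", "k_mat must be positive")
  if (is.null(well)) {
    if (ncol(series) != 1)
      gsStop("gs_input_error", "multi-well series: name the well")
    well <- colnames(series)[1]
  }
  if (is(mu, "GrowthFit")) mu <- mu@rate
  tt <- plateTime(series)
  A <- absorbance(series)[, well]
  F_ <- fluorescence(series)[, well]
  keep <- which(A > min_abs)
  if (length(keep) < 8)
    gsStop("gs_insufficient_data",
           "only %d usable samples in well '%s' (need >= 8 for the spline)",
           length(keep), well)
  rho <- F_[keep] / A[keep]
  sp <- smooth.spline(tt[keep], rho, cv = FALSE)  # GCV smoothing
  drho <- predict(sp, tt[keep], deriv = 1)$y
  rho_s <- predict(sp, tt[keep])$y
  mu_v <- if (length(mu) == 1) rep(mu, length(keep)) else mu[keep]
  iota <- (drho + mu_v * rho_s) / k_mat
  new("ReporterProfile", time = tt[keep], rho_raw = rho,
      rho_total = rho_s + iota, mu_used = mu_v)
}

#' Steady-state reporter concentration of one well
#'
#' The median of the maturation-corrected reporter concentration over the
#' steady-state window -- the same window used for the growing-regime growth
#' fit, or the arrested window (beyond 1000 min) for arrested conditions.
#'
#' @param profile a \linkS4class{ReporterProfile}.
#' @param window time window \code{c(t0, t1)} (min), typically
#'   \code{fit@window} of the condition's \linkS4class{GrowthFit}.
#' @return The median concentration (RFU per absorbance unit).
#' @export
steadyStateConcentration <- function(profile, window) {
  idx <- profile@time >= window[1] & profile@time <= window[2]
  if (!any(idx))
    gsStop("gs_insufficient_data", "no reporter samples in window [%g, %g]",
           window[1], window[2])
  median(profile@rho_total[idx])
}

#' Per-condition steady-state beta' levels from a dose series
#'
#' Convenience wrapper running background correction, growth fitting,
#' maturation correction and steady-state extraction for every well of a
#' dose series, then aggregating replicates per IPTG level.
#'
#' @param series a reporter-tagged dose-series \linkS4class{PlateSeries}.
#' @param control untagged control series for \code{\link{correctBackground}}.
#' @param k_mat maturation rate (min^-1).
#' @param fits optional precomputed \code{\link{conditionTable}} of the
#'   series (saves refitting).
#' @return A data.frame with one row per level: \code{iptg_uM},
#'   \code{concentration} (replicate mean of the per-well medians),
#'   \code{ci_halfwidth} (2 SEM), \code{n_replicates}, and the matching
#'   replicate-mean growth \code{rate}.
#' @export
steadyStateLevels <- function(series, control = NULL, k_mat = 0.028,
                              fits = NULL) {
  corr <- correctBackground(series, control)
  if (is.null(fits)) fits <- conditionTable(series, policy = "auto")
  rows <- lapply(seq_len(nrow(fits)), function(i) {
    w <- fits$well[i]
    prof <- reconstructTotalReporter(corr, well = w, k_mat = k_mat,
                                     mu = fits$rate[i])
    win <- c(fits$window_start[i], fits$window_end[i])
    data.frame(well = w, iptg_uM = fits$iptg_uM[i],
               conc = steadyStateConcentration(prof, win),
               rate = fits$rate[i])
  })
  tab <- do.call(rbind, rows)
  agg <- lapply(split(tab, tab$iptg_uM), function(d) {
    data.frame(iptg_uM = d$iptg_uM[1], concentration = mean(d$conc),
               ci_halfwidth = 2 * sd(d$conc) / sqrt(nrow(d)),
               n_replicates = nrow(d), rate = mean(d$rate))
  })
  out <- do.call(rbind, agg)
  out[order(out$iptg_uM), , drop = FALSE]
}
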