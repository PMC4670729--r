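#' Build a dose-response curve from per-well growth fits
#'
#' @param fits a data.frame from \code{\link{conditionTable}} covering
#'   several IPTG levels with replicates.
#' @return A \linkS4class{DoseResponseCurve} (levels sorted increasing).
#' @export
doseResponseCurve <- function(fits) {
  summ <- lapply(split(fits, fits$iptg_uM), summarizeCondition)
  lv <- vapply(summ, function(s) s@iptg_uM, numeric(1))
  o <- order(lv)
  new("DoseResponseCurve",
      levels = unname(lv[o]),
      mean_rates = unname(vapply(summ, function(s) s@mean_rate,
                                 numeric(1))[o]),
      ci_halfwidths = unname(vapply(summ, function(s) s@ci_halfwidth,
                                    numeric(1))[o]))
}

setMethod("show", "DoseResponseCurve", function(object) {
  cat("DoseResponseCurve:\n")
  print(data.frame(iptg_uM = object@levels,
                   rate = signif(object@mean_rates, 4),
                   ci = signif(object@ci_halfwidths, 3)), row.names = FALSE)
  invisible(NULL)
})

#' Locate the switching threshold on tested inducer levels
#'
#' The growth switch is characterized by a jump of the growth rate between
#' two adjacent tested IPTG levels. The threshold is reported as that
#' bracket, never interpolated: \code{lower} is the largest tested level
#' whose mean rate is below \code{arrest_cutoff} (default one fifth of the
#' maximal observed rate), \code{upper} the next tested level, which must
#' already grow at half the maximal rate or more for the switch to count as
#' sharp.
#'
#' @param curve a \linkS4class{DoseResponseCurve} with >= 3 levels.
#' @param arrest_cutoff rate below which a condition counts as arrested
#'   (min^-1); defaults to \code{0.2 * max(mean_rates)}.
#' @return A \linkS4class{ThresholdBracket}.
#' @examples
#' cv <- new("DoseResponseCurve",
#'           levels = c(0, 10, 20, 30, 40, 50, 100, 1000),
#'           mean_rates = c(0, 0, 0, 0.009, 0.011, rep(0.012, 3)),
#'           ci_halfwidths = rep(0, 8))
#' detectThreshold(cv)
#' @export
detectThreshold <- function(curve, arrest_cutoff = NULL) {
  lv <- curve@levels; r <- curve@mean_rates
  if (length(lv) < 3)
    gsStop("gs_input_error", "need >= 3 tested levels to bracket a threshold")
  if (is.null(arrest_cutoff)) arrest_cutoff <- 0.2 * max(r)
  arrested <- r < arrest_cutoff
  if (all(arrested) || max(r) <= 0)
    gsStop("gs_no_threshold", "all conditions are arrested; no threshold")
  if (!any(arrested))
    gsStop("gs_no_threshold", "all conditions are growing; no threshold")
  # classification must be monotone: no growing level below an arrested one
  lastArr <- max(which(arrested))
  firstGrow <- min(which(!arrested))
  if (firstGrow < lastArr)
    gsStop("gs_ambiguous_threshold",
           "non-monotone classification: growing at %s uM below arrested at %s uM",
           paste(lv[!arrested & seq_along(lv) < lastArr], collapse = ","),
           paste(lv[arrested & seq_along(lv) > firstGrow], collapse = ","))
  if (r[lastArr + 1] < 0.5 * max(r))
    gsStop("gs_no_threshold",
           "no sharp switch: rate at %g uM is %.3g, below half the maximum %.3g",
           lv[lastArr + 1], r[lastArr + 1], max(r))
  new("ThresholdBracket", lower = lv[lastArr], upper = lv[lastArr + 1])
}

setMethod("show", "ThresholdBracket", function(object) {
  cat(sprintf("ThresholdBracket: (%g, %g] uM IPTG\n", object@lower, object@upper))
  invisible(NULL)
})

#' Michaelis-Menten fit of growth rate above the switching threshold
#'
#' Least-squares fit of \code{vmax * x / (x + Km)} with
#' \code{x = IPTG - lower}, on the tested levels strictly above the lower
#' bracket edge, so that the fitted curve is 0 at and below the threshold.
#'
#' @param curve a \linkS4class{DoseResponseCurve}.
#' @param bracket a \linkS4class{ThresholdBracket} from
#'   \code{\link{detectThreshold}}.
#' @return An \linkS4class{MMFit}.
#' @export
fitMichaelisMenten <- function(curve, bracket) {
  keep <- curve@levels > bracket@lower
  if (sum(keep) < 3)
    gsStop("gs_insufficient_data",
           "only %d levels above the threshold (need >= 3)", sum(keep))
  x <- curve@levels[keep] - bracket@lower
  y <- curve@mean_rates[keep]
  # separable least squares: for fixed Km the optimal vmax is linear, so
  # profile Km on a log grid and polish by golden-section search (robust to
  # the near-flat curves a sharp switch produces, where a joint Newton-type
  # fit has a singular gradient)
  rssAt <- function(logKm) {
    h <- x / (x + exp(logKm))
    v <- sum(h * y) / sum(h * h)
    sum((y - v * h)^2)
  }
  grid <- seq(log(min(x) / 100), log(max(x) * 100), length.out = 200)
  r <- vapply(grid, rssAt, numeric(1))
  k0 <- which.min(r)
  opt <- optimize(rssAt, interval = grid[c(max(k0 - 1, 1),
                                           min(k0 + 1, length(grid)))],
                  tol = 1e-10)
  Km <- exp(opt$minimum)
  h <- x / (x + Km)
  vmax <- sum(h * y) / sum(h * h)
  new("MMFit", vmax = vmax, Km = Km,
      threshold_used = bracket@lower, rss = opt$objective)
}

#' Predict from a Michaelis-Menten threshold fit
#'
#' @param fit an \linkS4class{MMFit}.
#' @param iptg inducer concentrations (uM).
#' @return predicted rates; 0 at and below the threshold.
#' @export
predictMM <- function(fit, iptg) {
  x <- pmax(iptg - fit@threshold_used, 0)
  fit@vmax * x / (x + fit@Km)
}

#' Fit a Hill function to growth rate versus beta' concentration
#'
#' Least squares of \code{vmax * x^n / (x^n + K^n)} in natural scale with
#' multi-start over the exponent (log-linearization is ill-conditioned for
#' near-switch data). Starts at \code{n} in \{1, 2, 4, 8, 12, 16\} and keeps
#' the best converged fit by residual sum of squares.
#'
#' @param x beta' steady-state concentrations (positive, any consistent
#'   relative units).
#' @param y mean growth rates (min^-1).
#' @param fix_vmax optional: fix the asymptote to this value instead of
#'   fitting it (e.g. the wild-type rate); default free.
#' @param starts Hill-exponent starting values.
#' @return A \linkS4class{HillFit}.
#' @examples
#' x <- exp(seq(log(0.2), log(5), length.out = 20))
#' y <- 1 * x^4 / (x^4 + 1)
#' fitHill(x, y)
#' @export
fitHill <- function(x, y, fix_vmax = NULL, starts = c(1, 2, 4, 8, 12, 16)) {
  if (length(x) < 5)
    gsStop("gs_insufficient_data", "need >= 5 points for a Hill fit")
  if (any(x <= 0)) gsStop("gs_input_error", "x must be positive")
  best <- NULL
  diag_msgs <- character()
  for (n0 in starts) {
    fit <- try({
      if (is.null(fix_vmax))
        nlsLM(y ~ v * x^n / (x^n + K^n),
              start = list(v = max(y), n = n0, K = median(x)),
              lower = c(1e-12, 1, min(x) * 1e-3),
              upper = c(Inf, 200, max(x) * 1e3),
              control = nls.lm.control(maxiter = 500))
      else
        nlsLM(y ~ fix_vmax * x^n / (x^n + K^n),
              start = list(n = n0, K = median(x)),
              lower = c(1, min(x) * 1e-3), upper = c(200, max(x) * 1e3),
              control = nls.lm.control(maxiter = 500))
    }, silent = TRUE)
    if (inherits(fit, "try-error")) {
      diag_msgs <- c(diag_msgs, attr(fit, "condition")$message)
      next
    }
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    gsStop("gs_fit_failure", "Hill fit failed from all starts: %s",
           paste(unique(diag_msgs), collapse = "; "))
  cf <- coef(best$fit)
  new("HillFit",
      n = unname(cf["n"]), K = unname(cf["K"]),
      vmax = if (is.null(fix_vmax)) unname(cf["v"]) else fix_vmax,
      rss = best$rss)
}

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: n = %.3g, K = %.4g, vmax = %.4g, rss = %.3g\n",
              object@n, object@K, object@vmax, object@rss))
  invisible(NULL)
})

setMethod("show", "MMFit", function(object) {
  cat(sprintf("MMFit (origin %g uM): vmax = %.4g, Km = %.4g uM, rss = %.3g\n",
              object@threshold_used, object@vmax, object@Km, object@rss))
  invisible(NULL)
})
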