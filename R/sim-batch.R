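#' Simulate one microplate well of the growth-switch strain
#'
#' Integrates the mechanistic switch model for a single well and returns the
#' observed plate-reader signals: absorbance \code{A = B + A_bg} with
#' multiplicative lognormal noise, and fluorescence
#' \code{F = phi * m * B + autofluo * B + f0} with additive Gaussian noise
#' (SD equal to \code{noise_fluo} times the maximal clean signal), sampled
#' every \code{dt_sample} minutes.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param iptg inducer concentration (uM), either a single number or a
#'   schedule \code{data.frame(time_min, iptg_uM)} with strictly increasing
#'   times starting at 0.
#' @param duration run length (min).
#' @param strainMode \code{"R"} (engineered, IPTG-dependent rpoBC) or
#'   \code{"W"} (natural constitutive control).
#' @param tagged if \code{FALSE}, the strain carries no fluorescent reporter
#'   and only autofluorescence is observed (used as the background-correction
#'   control).
#' @param escape_time optional time (min) at which an escape mutation makes
#'   rpoBC transcription constitutive.
#' @param well well identifier.
#' @param replicate replicate index recorded in the metadata.
#' @param seed RNG seed for the measurement noise; defaults to
#'   \code{config@seed}. Noise is skipped entirely when both noise SDs are 0.
#' @return A \linkS4class{PlateSeries} with one well. The noise-free hidden
#'   state trajectory is kept in \code{metadata(x)$states[[well]]}.
#' @examples
#' ps <- simulateBatch(simConfig("M9-glc", noise_abs = 0, noise_fluo = 0),
#'                     iptg = 1000, duration = 400)
#' head(absorbance(ps))
#' @export
simulateBatch <- function(config, iptg, duration = 1200,
                          strainMode = c("R", "W"), tagged = TRUE,
                          escape_time = NULL, well = "w1", replicate = 1L,
                          seed = NULL) {
  strainMode <- match.arg(strainMode)
  if (duration <= 0) gsStop("gs_input_error", "duration must be positive")
  seg <- scheduleToSegments(config, iptg, strainMode, escape_time)
  times <- seq(0, duration, by = config@dt_sample)
  tr <- integrateSwitch(config, seg, times)
  A_clean <- tr$B + config@A_bg
  F_clean <- (if (tagged) config@phi * tr$m * tr$B else 0) +
    config@autofluo * tr$B + config@f0
  if (is.null(seed)) seed <- config@seed
  if (config@noise_abs > 0 || config@noise_fluo > 0) {
    noise <- withSeed(seed, list(
      a = rnorm(length(A_clean), 0, 1),
      f = rnorm(length(F_clean), 0, 1)
    ))
    A_obs <- A_clean * exp(config@noise_abs * noise$a)
    F_obs <- F_clean + config@noise_fluo * max(F_clean) * noise$f
  } else {
    A_obs <- A_clean
    F_obs <- F_clean
  }
  iptg0 <- if (is.numeric(iptg) && length(iptg) == 1) iptg else iptg$iptg_uM[1]
  ps <- PlateSeries(
    time = tr$time,
    absorbance = matrix(A_obs, ncol = 1, dimnames = list(NULL, well)),
    fluorescence = matrix(F_obs, ncol = 1, dimnames = list(NULL, well)),
    wellData = data.frame(
      well = well,
      strain = if (strainMode == "W") "W" else "R",
      medium = config@medium, iptg_uM = iptg0,
      replicate = as.integer(replicate), row.names = well
    ),
    A_bg = config@A_bg
  )
  metadata(ps)$states <- setNames(list(tr), well)
  metadata(ps)$seed <- seed
  ps
}

#' Simulate a full IPTG dose series
#'
#' One \code{\link{simulateBatch}} run per (level, replicate) combination
#' with replicate-specific derived seeds, combined into a single multi-well
#' \linkS4class{PlateSeries}. The default levels are the eight
#' concentrations of the reference characterization experiment.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param levels IPTG concentrations (uM).
#' @param replicates number of replicate wells per level.
#' @param duration run length (min).
#' @return A \linkS4class{PlateSeries} with \code{length(levels) * replicates}
#'   wells named \code{I<level>_r<rep>}.
#' @examples
#' ps <- simulateDoseSeries(simConfig("M9-glc", seed = 1),
#'                          levels = c(0, 1000), replicates = 2,
#'                          duration = 600)
#' wellInfo(ps)
#' @export
simulateDoseSeries <- function(config,
                               levels = c(0, 10, 20, 30, 40, 50, 100, 1000),
                               replicates = 5, duration = 1200) {
  if (!length(levels)) gsStop("gs_input_error", "empty IPTG level list")
  if (replicates < 1) gsStop("gs_input_error", "replicates must be >= 1")
  wells <- list()
  k <- 0
  for (lv in levels) for (r in seq_len(replicates)) {
    k <- k + 1
    wells[[k]] <- simulateBatch(
      config, iptg = lv, duration = duration,
      well = sprintf("I%g_r%d", lv, r), replicate = r,
      seed = deriveSeed(config@seed, k)
    )
  }
  combinePlates(wells)
}

#' Combine single-well plates into one multi-well PlateSeries
#'
#' All inputs must share the same time grid.
#'
#' @param plates list of \linkS4class{PlateSeries}.
#' @return A combined \linkS4class{PlateSeries}.
#' @export
combinePlates <- function(plates) {
  tt <- plateTime(plates[[1]])
  for (p in plates[-1])
    if (!isTRUE(all.equal(plateTime(p), tt)))
      gsStop("gs_input_error", "plates share no common time grid")
  A <- do.call(cbind, lapply(plates, assay, "absorbance"))
  F_ <- do.call(cbind, lapply(plates, function(p)
    if ("fluorescence" %in% names(assays(p))) assay(p, "fluorescence")
    else matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(assay(p)))))
  cd <- do.call(rbind, lapply(plates, function(p) as.data.frame(colData(p))))
  ps <- PlateSeries(time = tt, absorbance = A, fluorescence = F_,
                    wellData = cd,
                    A_bg = metadata(plates[[1]])$A_bg)
  metadata(ps)$states <- do.call(c, lapply(plates, function(p) metadata(p)$states))
  ps
}
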