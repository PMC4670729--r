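#' Simulate a glycerol production batch culture
#'
#' Shake-flask style run of the glycerol-producing strains. Both strains
#' carry the heterologous GPD1-GPP2 fusion that drains dihydroxyacetone
#' phosphate to glycerol; this doubles their specific glucose uptake relative
#' to biomass needs, and the fraction \code{f_branch} of the non-biomass
#' carbon flux is recovered as extracellular glycerol. \code{"W-gly"} grows
#' at the medium's maximal rate until glucose exhaustion; \code{"R-gly"}
#' (grown without IPTG) arrests as the preculture RNA polymerase dilutes
#' out, after which uptake continues at the maintenance level and the
#' glycerol yield rises toward \code{f_branch}.
#'
#' @param config a \linkS4class{SimConfig} (the medium calibration supplies
#'   \code{mu_max}; \code{glc0} defaults to 2 g/L).
#' @param strain \code{"W-gly"} or \code{"R-gly"}.
#' @param duration run length (min).
#' @param dt sampling interval (min); concentrations are assayed about every
#'   30 min.
#' @param B0 inoculum biomass (absorbance units).
#' @param f_branch glycerol branch fraction; defaults to 0.6 (taken from
#'   \code{config} when set there).
#' @param noise_conc_cv relative SD of the enzymatic glucose/glycerol
#'   assays (assays are run at matched dilutions, so the error scales with
#'   the measured concentration); set 0 for a noise-free run.
#' @param noise_conc_floor additive SD floor (g/L), the assay detection
#'   limit.
#' @param replicate replicate index.
#' @param seed RNG seed; defaults to \code{config@seed}.
#' @return A \linkS4class{ProductionSeries}. The noise-free trajectory is
#'   attached as \code{attr(x, "state")}.
#' @examples
#' pr <- simulateProduction(simConfig("M9-glc"), "R-gly", noise_conc = 0)
#' max(pr@glycerol)
#' @export
simulateProduction <- function(config, strain = c("W-gly", "R-gly"),
                               duration = 1200, dt = 30, B0 = 6e-4,
                               f_branch = NULL, noise_conc_cv = 0.01,
                               noise_conc_floor = 0.002,
                               replicate = 1L, seed = NULL) {
  strain <- match.arg(strain)
  if (config@glc0 <= 0) gsStop("gs_input_error", "glc0 must be positive")
  if (is.null(f_branch))
    f_branch <- if (config@f_branch > 0) config@f_branch else 0.6
  q_max <- 2 * config@mu_max / config@y_biomass_abs
  mode <- if (strain == "W-gly") "W" else "R"
  seg <- scheduleToSegments(config, 0, strainMode = mode)
  times <- seq(0, duration, by = dt)
  tr <- integrateSwitch(config, seg, times, q_max = q_max,
                        f_branch = f_branch, B0 = B0, uptake = "flux")
  if (is.null(seed)) seed <- config@seed
  od <- 2.34 * tr$B
  glc <- tr$glc
  gly <- tr$gly
  if (noise_conc_cv > 0 || config@noise_abs > 0) {
    nz <- withSeed(seed, list(a = rnorm(length(od)), g1 = rnorm(length(od)),
                              g2 = rnorm(length(od))))
    od <- od * exp(config@noise_abs * nz$a)
    glc <- pmax(glc + (noise_conc_cv * glc + noise_conc_floor) * nz$g1, 0)
    gly <- pmax(gly + (noise_conc_cv * gly + noise_conc_floor) * nz$g2, 0)
  }
  out <- new("ProductionSeries", time = tr$time, od600 = od, glucose = glc,
             glycerol = gly, strain = strain, replicate = as.integer(replicate))
  attr(out, "state") <- tr
  out
}

setMethod("show", "ProductionSeries", function(object) {
  cat(sprintf(
    "ProductionSeries '%s' (rep %d): %d samples over %g min; glc %g -> %.3g g/L, gly max %.3g g/L\n",
    object@strain, object@replicate, length(object@time), max(object@time),
    object@glucose[1], min(object@glucose), max(object@glycerol)))
  invisible(NULL)
})
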