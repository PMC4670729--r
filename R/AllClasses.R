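# S4 classes for the growth-switch analysis chain.

#' Simulator configuration
#'
#' Parameters of the mechanistic ODE model of the rpoBC growth switch. All
#' rates are per minute, concentrations of the beta' pool in arbitrary units
#' (a.u.; the Hill half-saturation constant \code{hill_K} sets the scale),
#' biomass in background-corrected absorbance units, sugars in g/L.
#'
#' @slot medium calibration key, one of \code{"M9-glc"}, \code{"M9-glc-CAA"},
#'   \code{"LB-glc"}, \code{"M9-succ"}.
#' @slot mu_max maximal growth rate supported by the medium (min^-1).
#' @slot hill_n Hill exponent of growth rate vs beta' concentration.
#' @slot hill_K beta' concentration at half-maximal growth (a.u.).
#' @slot c_sat steady-state beta' concentration at saturating IPTG, in units
#'   of \code{hill_K}; fixes the maximal promoter activity
#'   \code{k_tx_max = mu(c_sat) * c_sat}.
#' @slot k_tx_max maximal rpoBC promoter activity (a.u./min).
#' @slot K_iptg IPTG concentration at half-maximal induction (uM).
#' @slot iptg_hill effective Hill exponent of the induction function.
#' @slot k_mat reporter maturation rate (min^-1).
#' @slot c0 beta' concentration carried over from the preculture (a.u.).
#' @slot A0 initial background-corrected absorbance.
#' @slot A_bg background absorbance of medium and plate.
#' @slot glc0 initial glucose (g/L).
#' @slot y_biomass_abs biomass yield, absorbance units per g/L glucose.
#' @slot q_max maximal specific glucose uptake, g/(L * absorbance unit * min).
#' @slot K_glc Monod constant of glucose uptake (g/L).
#' @slot f_branch fraction of non-biomass glucose carbon routed to glycerol.
#' @slot tau_g relaxation time of the realized growth rate toward the
#'   RNAP-set target (min).
#' @slot phi fluorescence gain, RFU per (a.u. * absorbance unit).
#' @slot autofluo autofluorescence coefficient, RFU per absorbance unit of
#'   biomass.
#' @slot f0 constant medium fluorescence background (RFU).
#' @slot noise_abs relative (multiplicative lognormal) absorbance noise SD.
#' @slot noise_fluo additive fluorescence noise SD, as a fraction of the
#'   maximal fluorescence signal of the run.
#' @slot dt_sample sampling interval (min).
#' @slot L0 newborn cell length (um), lineage mode.
#' @slot L_div division length threshold (um), lineage mode.
#' @slot c_div beta' concentration below which division is blocked (a.u.).
#' @slot sigma_div lognormal SD of division asymmetry.
#' @slot cell_cv cell-to-cell CV of the elongation-rate multiplier.
#' @slot noise_len relative length measurement noise SD.
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  medium = "character",
  mu_max = "numeric", hill_n = "numeric", hill_K = "numeric",
  c_sat = "numeric", k_tx_max = "numeric",
  K_iptg = "numeric", iptg_hill = "numeric",
  k_mat = "numeric", c0 = "numeric",
  A0 = "numeric", A_bg = "numeric",
  glc0 = "numeric", y_biomass_abs = "numeric", q_max = "numeric",
  K_glc = "numeric", f_branch = "numeric", tau_g = "numeric",
  phi = "numeric", autofluo = "numeric", f0 = "numeric",
  noise_abs = "numeric", noise_fluo = "numeric", dt_sample = "numeric",
  L0 = "numeric", L_div = "numeric", c_div = "numeric",
  sigma_div = "numeric", cell_cv = "numeric", noise_len = "numeric",
  seed = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  num <- c("mu_max", "hill_K", "c_sat", "k_tx_max", "K_iptg", "k_mat", "c0",
           "A0", "A_bg", "glc0", "y_biomass_abs", "q_max", "K_glc", "tau_g",
           "phi", "autofluo", "f0", "noise_abs", "noise_fluo", "dt_sample",
           "L0", "L_div", "c_div", "sigma_div", "cell_cv", "noise_len")
  for (s in num) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single non-negative number", s))
  }
  if (object@hill_n < 1) msg <- c(msg, "'hill_n' must be >= 1")
  if (object@iptg_hill < 1) msg <- c(msg, "'iptg_hill' must be >= 1")
  if (object@f_branch < 0 || object@f_branch > 1)
    msg <- c(msg, "'f_branch' must lie in [0, 1]")
  if (object@dt_sample <= 0) msg <- c(msg, "'dt_sample' must be positive")
  if (length(msg)) msg else TRUE
})

#' Plate-reader time series
#'
#' A \linkS4class{SummarizedExperiment} holding per-well absorbance (and
#' optionally fluorescence) time courses. Assays are time x well matrices;
#' \code{rowData} carries the shared time grid (\code{time_min});
#' \code{colData} the per-well condition metadata (\code{strain},
#' \code{medium}, \code{iptg_uM}, \code{replicate}).
#'
#' @exportClass PlateSeries
setClass("PlateSeries", contains = "SummarizedExperiment")

setValidity("PlateSeries", function(object) {
  msg <- character()
  if (!"time_min" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'time_min'")
  else {
    tt <- rowData(object)$time_min
    if (any(diff(tt) <= 0)) msg <- c(msg, "time grid must be strictly increasing")
  }
  if (!"absorbance" %in% names(assays(object)))
    msg <- c(msg, "assay 'absorbance' is required")
  need <- c("strain", "medium", "iptg_uM", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Exponential growth-rate fit
#'
#' @slot rate fitted exponential rate (min^-1).
#' @slot se standard error of the rate (min^-1).
#' @slot window fitting window \code{c(t_start, t_end)} (min).
#' @slot n_points number of samples used.
#' @slot r_squared coefficient of determination of the log-linear fit.
#' @slot regime \code{"growing"} or \code{"arrested"}.
#' @slot well well identifier.
#' @slot iptg_uM inducer concentration of the well (uM).
#' @exportClass GrowthFit
setClass("GrowthFit", representation(
  rate = "numeric", se = "numeric", window = "numeric", n_points = "integer",
  r_squared = "numeric", regime = "character", well = "character",
  iptg_uM = "numeric"
))

setValidity("GrowthFit", function(object) {
  msg <- character()
  if (object@n_points < 5) msg <- c(msg, "a growth fit needs >= 5 points")
  if (object@se < 0) msg <- c(msg, "'se' must be non-negative")
  if (!object@regime %in% c("growing", "arrested"))
    msg <- c(msg, "'regime' must be 'growing' or 'arrested'")
  if (length(msg)) msg else TRUE
})

#' Replicate summary of one condition
#'
#' @slot iptg_uM inducer concentration (uM).
#' @slot mean_rate replicate mean growth rate (min^-1).
#' @slot ci_halfwidth 2 x SEM of the rate (min^-1).
#' @slot n_replicates number of replicate fits.
#' @slot regime majority regime across replicates.
#' @exportClass ConditionSummary
setClass("ConditionSummary", representation(
  iptg_uM = "numeric", mean_rate = "numeric", ci_halfwidth = "numeric",
  n_replicates = "integer", regime = "character"
))

#' Dose-response curve (inducer level vs mean growth rate)
#'
#' @slot levels tested IPTG levels (uM), strictly increasing.
#' @slot mean_rates replicate-mean rates (min^-1).
#' @slot ci_halfwidths 2 x SEM per level (min^-1).
#' @exportClass DoseResponseCurve
setClass("DoseResponseCurve", representation(
  levels = "numeric", mean_rates = "numeric", ci_halfwidths = "numeric"
))

setValidity("DoseResponseCurve", function(object) {
  msg <- character()
  if (any(diff(object@levels) <= 0))
    msg <- c(msg, "'levels' must be strictly increasing")
  if (length(object@mean_rates) != length(object@levels) ||
      length(object@ci_halfwidths) != length(object@levels))
    msg <- c(msg, "levels, mean_rates, ci_halfwidths must have equal length")
  if (length(msg)) msg else TRUE
})

#' Switching-threshold bracket
#'
#' The threshold is reported as a bracket of adjacent tested levels, never
#' interpolated: growth is arrested at \code{lower} and clearly on at
#' \code{upper}.
#'
#' @slot lower largest tested level classified arrested (uM).
#' @slot upper next tested level, classified growing (uM).
#' @exportClass ThresholdBracket
setClass("ThresholdBracket", representation(lower = "numeric", upper = "numeric"))

#' Hill-function fit
#'
#' @slot n Hill exponent.
#' @slot K half-saturation (units of the abscissa).
#' @slot vmax asymptotic rate (min^-1).
#' @slot rss residual sum of squares.
#' @exportClass HillFit
setClass("HillFit", representation(
  n = "numeric", K = "numeric", vmax = "numeric", rss = "numeric"
))

setValidity("HillFit", function(object) {
  msg <- character()
  if (object@n < 1) msg <- c(msg, "'n' must be >= 1")
  if (object@K <= 0) msg <- c(msg, "'K' must be positive")
  if (object@vmax <= 0) msg <- c(msg, "'vmax' must be positive")
  if (length(msg)) msg else TRUE
})

#' Michaelis-Menten fit above the switching threshold
#'
#' Fitted on inducer levels strictly above the threshold, with the abscissa
#' shifted to the threshold origin so the curve is 0 at and below it.
#'
#' @slot vmax asymptotic rate (min^-1).
#' @slot Km half-saturation above threshold (uM).
#' @slot threshold_used lower bracket edge used as origin (uM).
#' @slot rss residual sum of squares.
#' @exportClass MMFit
setClass("MMFit", representation(
  vmax = "numeric", Km = "numeric", threshold_used = "numeric", rss = "numeric"
))

#' Reporter concentration profile
#'
#' @slot time time grid (min).
#' @slot rho_raw measured mature-reporter concentration proxy F/A (RFU per
#'   absorbance unit).
#' @slot rho_total maturation-corrected total reporter concentration.
#' @slot mu_used dilution rate used in the correction (min^-1).
#' @exportClass ReporterProfile
setClass("ReporterProfile", representation(
  time = "numeric", rho_raw = "numeric", rho_total = "numeric",
  mu_used = "numeric"
))

#' Steady-state reporter level of one condition
#'
#' @slot iptg_uM inducer concentration (uM).
#' @slot concentration median maturation-corrected reporter concentration over
#'   the steady-state window (RFU per absorbance unit).
#' @slot ci_halfwidth 2 x SEM across replicates.
#' @slot n_replicates number of replicates.
#' @exportClass SteadyStateLevel
setClass("SteadyStateLevel", representation(
  iptg_uM = "numeric", concentration = "numeric", ci_halfwidth = "numeric",
  n_replicates = "integer"
))

#' Batch production time course
#'
#' @slot time sampling times (min).
#' @slot od600 optical density (600 nm).
#' @slot glucose glucose concentration (g/L).
#' @slot glycerol glycerol concentration (g/L).
#' @slot strain strain label (\code{"W-gly"} or \code{"R-gly"}).
#' @slot replicate replicate identifier.
#' @exportClass ProductionSeries
setClass("ProductionSeries", representation(
  time = "numeric", od600 = "numeric", glucose = "numeric",
  glycerol = "numeric", strain = "character", replicate = "integer"
))

setValidity("ProductionSeries", function(object) {
  msg <- character()
  n <- length(object@time)
  if (any(diff(object@time) <= 0)) msg <- c(msg, "time must be strictly increasing")
  if (length(object@od600) != n || length(object@glucose) != n ||
      length(object@glycerol) != n)
    msg <- c(msg, "time, od600, glucose, glycerol must have equal length")
  if (any(object@glycerol < 0)) msg <- c(msg, "glycerol must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Time-varying production yield profile
#'
#' @slot time evaluation grid (min), inside \code{window}.
#' @slot Y instantaneous yield, g glycerol per g glucose; \code{NA} where the
#'   glucose consumption rate is below the mask threshold.
#' @slot ci_halfwidth 2 x SEM across replicates (\code{NA} for single runs).
#' @slot window evaluation window \code{c(t_start, t_end)} (min).
#' @exportClass YieldProfile
setClass("YieldProfile", representation(
  time = "numeric", Y = "numeric", ci_halfwidth = "numeric", window = "numeric"
))

setValidity("YieldProfile", function(object) {
  msg <- character()
  if (length(object@Y) != length(object@time))
    msg <- c(msg, "Y and time must have equal length")
  if (length(msg)) msg else TRUE
})

#' Single-cell lineage experiment
#'
#' Length tracks of mother cells in a microfluidic (mother-machine style)
#' device, plus the simulator's ground-truth division log and environment
#' trajectory when produced by \code{\link{simulateLineage}}.
#'
#' @slot tracks data.frame with columns \code{cell_id}, \code{time_min},
#'   \code{length_um}.
#' @slot divisions data.frame with columns \code{cell_id},
#'   \code{division_time_min} (ground truth if simulated).
#' @slot env data.frame with the environment trajectory (\code{time_min},
#'   \code{c}, \code{growth_rate}); may have zero rows for imported data.
#' @exportClass LineageSet
setClass("LineageSet", representation(
  tracks = "data.frame", divisions = "data.frame", env = "data.frame"
))

setValidity("LineageSet", function(object) {
  msg <- character()
  need <- c("cell_id", "time_min", "length_um")
  if (!all(need %in% names(object@tracks)))
    msg <- c(msg, "tracks needs columns cell_id, time_min, length_um")
  else if (any(object@tracks$length_um <= 0))
    msg <- c(msg, "lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' Constraint-based metabolic model
#'
#' @slot metabolites metabolite identifiers (rows of \code{S}).
#' @slot reactions reaction identifiers (columns of \code{S}).
#' @slot S stoichiometric matrix (metabolites x reactions).
#' @slot lb,ub flux bounds (mmol/gDW/h).
#' @slot exchanges named list of designated exchange reaction ids
#'   (\code{glucose}, \code{product}, \code{oxygen}).
#' @slot maintenance id of the non-growth-associated maintenance reaction.
#' @slot gam id of the growth-associated maintenance reaction, or \code{NA}.
#' @slot biomass id of the biomass reaction, or \code{NA}.
#' @exportClass MetabolicModel
setClass("MetabolicModel", representation(
  metabolites = "character", reactions = "character", S = "matrix",
  lb = "numeric", ub = "numeric", exchanges = "list",
  maintenance = "character", gam = "character", biomass = "character"
))

setValidity("MetabolicModel", function(object) {
  msg <- character()
  if (nrow(object@S) != length(object@metabolites) ||
      ncol(object@S) != length(object@reactions))
    msg <- c(msg, "S dimensions must match metabolite/reaction ids")
  if (length(object@lb) != ncol(object@S) || length(object@ub) != ncol(object@S))
    msg <- c(msg, "bounds must have one entry per reaction")
  else if (any(object@lb > object@ub))
    msg <- c(msg, "lower bounds must not exceed upper bounds")
  ids <- unlist(object@exchanges)
  bad <- setdiff(c(ids, object@maintenance), c(object@reactions, NA))
  bad <- bad[!is.na(bad)]
  if (length(bad))
    msg <- c(msg, paste0("designated reactions absent from model: ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Flux balance analysis result
#'
#' @slot objective_flux optimal flux of the objective reaction (mmol/gDW/h).
#' @slot fluxes full optimal flux vector, named by reaction.
#' @slot mass_yield g product per g substrate.
#' @slot status solver status (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}).
#' @exportClass FBAResult
setClass("FBAResult", representation(
  objective_flux = "numeric", fluxes = "numeric", mass_yield = "numeric",
  status = "character"
))
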