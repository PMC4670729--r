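# Tidy CSV readers/writers and the end-to-end reproduction pipeline.
#
# One canonical long schema per data kind:
#   plate:      well, time_min, absorbance, fluorescence, strain, medium,
#               iptg_uM, replicate
#   production: time_min, od600, glucose_g_per_L, glycerol_g_per_L, strain,
#               replicate
#   lineage:    cell_id, time_min, length_um  (+ companion division log)

#' Export a PlateSeries as tidy CSV
#'
#' @param series a \linkS4class{PlateSeries}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePlateCsv <- function(series, path) {
  write.csv(plateToTidy(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writePlateCsv the tidy data.frame (one observation per row).
#' @export
plateToTidy <- function(series) {
  tt <- plateTime(series)
  cd <- wellInfo(series)
  F_ <- fluorescence(series)
  rows <- lapply(colnames(series), function(w) {
    data.frame(well = w, time_min = tt,
               absorbance = absorbance(series)[, w],
               fluorescence = if (is.null(F_)) NA_real_ else F_[, w],
               strain = cd[w, "strain"], medium = cd[w, "medium"],
               iptg_uM = cd[w, "iptg_uM"], replicate = cd[w, "replicate"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a tidy plate CSV into a PlateSeries
#'
#' Validates the schema, requires a shared strictly increasing time grid,
#' and rejects duplicated (well, time) pairs naming the offending rows.
#'
#' @param path CSV file in the canonical plate schema.
#' @param A_bg background absorbance to record with the plate.
#' @return A \linkS4class{PlateSeries}.
#' @export
readPlateCsv <- function(path, A_bg = NA_real_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "time_min", "absorbance", "fluorescence", "strain",
            "medium", "iptg_uM", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gsStop("gs_schema_error", "'%s' lacks column(s): %s", basename(path),
           paste(miss, collapse = ", "))
  key <- paste(df$well, df$time_min)
  if (anyDuplicated(key))
    gsStop("gs_schema_error",
           "duplicated (well, time) pair(s) at row(s): %s",
           paste(which(duplicated(key)), collapse = ", "))
  plateFromTidy(df, A_bg = A_bg)
}

#' @describeIn readPlateCsv build a PlateSeries from a tidy data.frame.
#' @param df tidy data.frame in the canonical plate schema.
#' @export
plateFromTidy <- function(df, A_bg = NA_real_) {
  wells <- unique(df$well)
  tt <- sort(unique(df$time_min))
  A <- matrix(NA_real_, length(tt), length(wells),
              dimnames = list(NULL, wells))
  F_ <- A
  for (w in wells) {
    d <- df[df$well == w, ]
    o <- match(d$time_min, tt)
    A[o, w] <- d$absorbance
    F_[o, w] <- d$fluorescence
  }
  if (anyNA(A))
    gsStop("gs_schema_error", "wells do not share a common time grid")
  cd <- df[!duplicated(df$well),
           c("well", "strain", "medium", "iptg_uM", "replicate")]
  rownames(cd) <- cd$well
  PlateSeries(time = tt, absorbance = A,
              fluorescence = if (all(is.na(F_))) NULL else F_,
              wellData = cd, A_bg = A_bg)
}

#' Production series CSV round trip
#'
#' @param series a \linkS4class{ProductionSeries} (or list of them).
#' @param path file path.
#' @return \code{path} (write) or a list of \linkS4class{ProductionSeries}
#'   (read).
#' @export
writeProductionCsv <- function(series, path) {
  if (is(series, "ProductionSeries")) series <- list(series)
  rows <- lapply(series, function(s)
    data.frame(time_min = s@time, od600 = s@od600,
               glucose_g_per_L = s@glucose, glycerol_g_per_L = s@glycerol,
               strain = s@strain, replicate = s@replicate))
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeProductionCsv read the canonical production schema.
#' @export
readProductionCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "od600", "glucose_g_per_L", "glycerol_g_per_L",
            "strain", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    gsStop("gs_schema_error", "'%s' lacks column(s): %s", basename(path),
           paste(miss, collapse = ", "))
  lapply(split(df, interaction(df$strain, df$replicate, drop = TRUE)),
         function(d)
           new("ProductionSeries", time = d$time_min, od600 = d$od600,
               glucose = d$glucose_g_per_L, glycerol = d$glycerol_g_per_L,
               strain = d$strain[1], replicate = as.integer(d$replicate[1])))
}

#' Length-track CSV round trip
#'
#' @param lineages a \linkS4class{LineageSet}.
#' @param path track CSV path; the ground-truth division log goes to
#'   \code{sub("\\\\.csv$", "_divisions.csv", path)}.
#' @return \code{path} (write) or a \linkS4class{LineageSet} (read; the
#'   division log is loaded when present).
#' @export
writeLengthTracks <- function(lineages, path) {
  write.csv(lineages@tracks, path, row.names = FALSE, quote = FALSE)
  dpath <- sub("\\.csv$", "_divisions.csv", path)
  write.csv(lineages@divisions, dpath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeLengthTracks read tracks (and divisions if present).
#' @export
readLengthTracks <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "length_um")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    gsStop("gs_schema_error", "'%s' lacks column(s): %s", basename(path),
           paste(miss, collapse = ", "))
  dpath <- sub("\\.csv$", "_divisions.csv", path)
  dv <- if (file.exists(dpath)) read.csv(dpath, stringsAsFactors = FALSE)
        else data.frame(cell_id = character(0), division_time_min = numeric(0))
  new("LineageSet", tracks = tr, divisions = dv,
      env = data.frame(time_min = numeric(0), c = numeric(0),
                       growth_rate = numeric(0)))
}

#' Pipeline run configuration
#'
#' @param scenario which stages to run: \code{"dose"} (plate kinetics +
#'   reporter + dose-response), \code{"production"} (yield analysis),
#'   \code{"lineage"}, \code{"fba"}, or \code{"repro"} (all of them).
#' @param medium medium calibration key.
#' @param seed integer master seed; every stage's randomness derives from it.
#' @param out_dir output directory for stage artifacts.
#' @param overrides named list of \linkS4class{SimConfig} overrides.
#' @param replicates replicate wells per condition.
#' @return A validated configuration list of class \code{gsRunConfig}.
#' @export
runConfig <- function(scenario = "repro", medium = "M9-glc", seed = 1,
                      out_dir = tempfile("growthswitch_"),
                      overrides = list(), replicates = 5) {
  scenario <- match.arg(scenario,
                        c("repro", "dose", "production", "lineage", "fba"))
  if (!medium %in% mediaCalibrations()$medium)
    gsStop("gs_config_error", "unknown medium calibration '%s'", medium)
  bad <- setdiff(names(overrides), slotNames("SimConfig"))
  if (length(bad))
    gsStop("gs_config_error", "unknown override key(s): %s",
           paste(bad, collapse = ", "))
  structure(list(scenario = scenario, medium = medium, seed = seed,
                 out_dir = out_dir, overrides = overrides,
                 replicates = replicates),
            class = "gsRunConfig")
}

#' Run the end-to-end reproduction pipeline
#'
#' Simulates the configured scenario and runs every matching analysis stage
#' in order (simulate, growth rates, reporter, dose-response, production
#' yield, lineage, FBA), writing each artifact as CSV/JSON into the output
#' directory. The returned manifest lists every file with its md5 checksum
#' plus the configuration snapshot, so a rerun with the same seed is
#' checkably identical.
#'
#' @param config a \code{\link{runConfig}}.
#' @return The manifest (list), invisibly written to
#'   \code{manifest.json} as well.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "gsRunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(simConfig, c(list(medium = config$medium, seed = config$seed),
                              config$overrides))
  arts <- character(0)
  results <- list()
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    arts <<- c(arts, path)
    path
  }
  doDose <- config$scenario %in% c("repro", "dose")
  doProd <- config$scenario %in% c("repro", "production")
  doLin <- config$scenario %in% c("repro", "lineage")
  doFBA <- config$scenario %in% c("repro", "fba")
  if (doDose) {
    ps <- simulateDoseSeries(cfg, replicates = config$replicates)
    emit("plate_dose.csv", function(p) writePlateCsv(ps, p))
    fits <- conditionTable(ps, policy = "auto")
    emit("growth_fits.csv", function(p)
      write.csv(fits, p, row.names = FALSE, quote = FALSE))
    ctrl <- simulateBatch(simConfig(config$medium,
                                    seed = deriveSeed(config$seed, 999)),
                          iptg = 1000, tagged = FALSE, well = "ctrl")
    lv <- steadyStateLevels(ps, control = ctrl, fits = fits)
    emit("steady_state_levels.csv", function(p)
      write.csv(lv, p, row.names = FALSE, quote = FALSE))
    curve <- doseResponseCurve(fits)
    br <- detectThreshold(curve)
    mm <- fitMichaelisMenten(curve, br)
    hf <- fitHill(lv$concentration, lv$rate)
    results$threshold <- c(lower = br@lower, upper = br@upper)
    results$mm <- c(vmax = mm@vmax, Km = mm@Km)
    results$hill <- c(n = hf@n, K = hf@K, vmax = hf@vmax)
    emit("dose_response.csv", function(p)
      write.csv(data.frame(iptg_uM = curve@levels, rate = curve@mean_rates,
                           ci = curve@ci_halfwidths, mm = predictMM(mm, curve@levels)),
                p, row.names = FALSE, quote = FALSE))
  }
  if (doProd) {
    runs <- list()
    for (st in c("W-gly", "R-gly")) for (r in seq_len(config$replicates)) {
      runs[[paste(st, r)]] <- simulateProduction(
        cfg, st, replicate = r, seed = deriveSeed(config$seed, 200 + r +
                                                    100 * (st == "R-gly")))
    }
    emit("production.csv", function(p) writeProductionCsv(runs, p))
    prof <- lapply(runs, productionYield)
    isW <- grepl("^W", names(prof))
    avgW <- averageYieldProfiles(prof[isW])
    avgR <- averageYieldProfiles(prof[!isW])
    results$yield <- c(
      W_mean = mean(avgW@Y, na.rm = TRUE),
      R_max = max(avgR@Y, na.rm = TRUE),
      ratio = max(avgR@Y, na.rm = TRUE) / mean(avgW@Y, na.rm = TRUE))
    emit("yield_profiles.csv", function(p)
      write.csv(rbind(
        data.frame(strain = "W-gly", time_min = avgW@time, Y = avgW@Y,
                   ci = avgW@ci_halfwidth),
        data.frame(strain = "R-gly", time_min = avgR@time, Y = avgR@Y,
                   ci = avgR@ci_halfwidth)),
        p, row.names = FALSE, quote = FALSE))
  }
  if (doLin) {
    sched <- data.frame(time_min = c(0, 300, 660),
                        iptg_uM = c(1000, 0, 1000))
    ls <- simulateLineage(cfg, sched, n_cells = 50)
    emit("lineage_tracks.csv", function(p) writeLengthTracks(ls, p))
    segs <- lineageRates(ls)
    curve <- populationGrowthCurve(segs)
    emit("lineage_curve.csv", function(p)
      write.csv(curve, p, row.names = FALSE, quote = FALSE))
    lag <- detectArrestRecovery(curve, 300, 660)
    results$lineage <- c(lag_to_decline = lag$lag_to_decline,
                         lag_to_recovery = lag$lag_to_recovery)
  }
  if (doFBA) {
    model <- applyYieldConstraints(toyGlycerolModel())
    fba <- maximizeProductYield(model)
    results$fba <- c(objective_flux = fba@objective_flux,
                     mass_yield = fba@mass_yield)
    emit("fba_fluxes.csv", function(p)
      write.csv(data.frame(reaction = names(fba@fluxes), flux = fba@fluxes),
                p, row.names = FALSE, quote = FALSE))
  }
  manifest <- list(
    config = unclass(config),
    results = results,
    artifacts = lapply(arts, function(p)
      list(file = basename(p), md5 = unname(md5sum(p))))
  )
  write_json(manifest, file.path(config$out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
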