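# Single-cell lineage analysis: generation segmentation, elongation rates,
# time-binned population growth curves, arrest/recovery detection.

#' Segment a length track into generations at division events
#'
#' A division is called between consecutive frames when the length ratio
#' \code{length[k+1] / length[k]} falls below \code{drop_fraction}
#' (default 0.7 -- robust to ~10 percent measurement noise for roughly
#' symmetric division). Segments are the maximal runs between divisions;
#' the first and last segments of a track are marked censored (their birth
#' or division was not observed). Filamenting tracks with no division yield
#' a single censored segment.
#'
#' @param track data.frame with columns \code{cell_id}, \code{time_min},
#'   \code{length_um} for a single cell (>= 6 frames), or a
#'   \linkS4class{LineageSet} together with \code{cell}.
#' @param cell cell id when \code{track} is a \linkS4class{LineageSet}.
#' @param drop_fraction division-call threshold on the frame-to-frame
#'   length ratio.
#' @return data.frame with one row per segment: \code{cell_id},
#'   \code{birth_time}, \code{division_time} (\code{NA} when censored),
#'   \code{start}, \code{end} (frame indices), \code{n_frames},
#'   \code{censored}.
#' @export
segmentGenerations <- function(track, cell = NULL, drop_fraction = 0.7) {
  if (is(track, "LineageSet")) {
    if (is.null(cell)) gsStop("gs_input_error", "name the cell to segment")
    track <- track@tracks[track@tracks$cell_id == cell, , drop = FALSE]
  }
  n <- nrow(track)
  if (n < 6)
    gsStop("gs_insufficient_data", "track has %d frames (need >= 6)", n)
  L <- track$length_um
  tt <- track$time_min
  drops <- which(L[-1] / L[-n] < drop_fraction)  # division between k and k+1
  starts <- c(1, drops + 1)
  ends <- c(drops, n)
  out <- data.frame(
    cell_id = track$cell_id[1],
    birth_time = tt[starts],
    division_time = c(tt[ends[-length(ends)] + 1], NA_real_),
    start = starts, end = ends,
    n_frames = ends - starts + 1,
    censored = FALSE
  )
  out$censored[1] <- TRUE
  out$censored[nrow(out)] <- TRUE
  out
}

#' Per-generation elongation rate
#'
#' OLS slope of \code{log(length)} against time within one generation
#' segment.
#'
#' @param segment one row of \code{\link{segmentGenerations}} output.
#' @param track the matching single-cell track data.frame.
#' @return list with \code{rate} (min^-1), \code{se}, \code{r_squared};
#'   \code{NULL} (with a message) for segments shorter than 3 frames.
#' @export
fitElongationRate <- function(segment, track) {
  idx <- segment$start:segment$end
  if (length(idx) < 3) {
    message(sprintf("segment of %s at %g min skipped: %d frames < 3",
                    segment$cell_id, segment$birth_time, length(idx)))
    return(NULL)
  }
  f <- logLinearFit(track$time_min[idx], log(track$length_um[idx]))
  list(rate = f$slope, se = f$se, r_squared = f$r_squared)
}

#' Segment and fit all lineages of an experiment
#'
#' @param lineages a \linkS4class{LineageSet}.
#' @param drop_fraction see \code{\link{segmentGenerations}}.
#' @param keep_censored include censored first/last segments (excluded from
#'   rate statistics by default: their observation windows are biased).
#' @return data.frame of segments with fitted \code{rate}, \code{se},
#'   \code{r_squared} columns added.
#' @export
lineageRates <- function(lineages, drop_fraction = 0.7,
                         keep_censored = FALSE) {
  out <- lapply(split(lineages@tracks, lineages@tracks$cell_id), function(tr) {
    seg <- segmentGenerations(tr, drop_fraction = drop_fraction)
    fits <- lapply(seq_len(nrow(seg)), function(i)
      fitElongationRate(seg[i, ], tr))
    ok <- !vapply(fits, is.null, logical(1))
    seg <- seg[ok, , drop = FALSE]
    seg$rate <- vapply(fits[ok], function(f) f$rate, numeric(1))
    seg$se <- vapply(fits[ok], function(f) f$se, numeric(1))
    seg$r_squared <- vapply(fits[ok], function(f) f$r_squared, numeric(1))
    # segment end time for binning (division time or last observed frame)
    seg$end_time <- ifelse(is.na(seg$division_time),
                           tr$time_min[seg$end], seg$division_time)
    seg
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!keep_censored) out <- out[!out$censored, , drop = FALSE]
  out
}

#' Time-binned population growth curve
#'
#' Each generation's elongation rate is assigned to every time bin it
#' overlaps, weighted by the number of its frames falling in the bin; bins
#' report the weighted mean and the equally weighted SD. Empty bins are
#' omitted (not zero-filled).
#'
#' @param segments data.frame from \code{\link{lineageRates}} (needs
#'   \code{birth_time}, \code{end_time}, \code{rate}).
#' @param bin_width bin width (min).
#' @param frame_interval imaging interval used to convert overlap durations
#'   to frame counts.
#' @param t_range optional \code{c(t0, t1)} range to bin over; default spans
#'   the segments.
#' @return data.frame with \code{bin_center}, \code{mean_rate}, \code{sd},
#'   \code{n_cells}.
#' @export
populationGrowthCurve <- function(segments, bin_width = 30,
                                  frame_interval = 10, t_range = NULL) {
  if (is.null(t_range))
    t_range <- c(min(segments$birth_time), max(segments$end_time))
  edges <- seq(floor(t_range[1] / bin_width) * bin_width,
               ceiling(t_range[2] / bin_width) * bin_width, by = bin_width)
  rows <- lapply(seq_len(length(edges) - 1), function(b) {
    lo <- edges[b]; hi <- edges[b + 1]
    ov <- pmin(segments$end_time, hi) - pmax(segments$birth_time, lo)
    sel <- ov > 0
    if (!any(sel)) return(NULL)
    w <- ov[sel] / frame_interval   # frames in bin
    r <- segments$rate[sel]
    m <- sum(w * r) / sum(w)
    v <- sum(w * (r - m)^2) / sum(w)
    data.frame(bin_center = (lo + hi) / 2, mean_rate = m, sd = sqrt(v),
               n_cells = length(unique(segments$cell_id[sel])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect growth arrest and recovery lags from a population curve
#'
#' Given the inducer removal and re-addition times, reports
#' \code{lag_to_decline}: time from removal to the first bin whose mean rate
#' falls below 90 percent of the pre-removal mean, and
#' \code{lag_to_recovery}: time from re-addition to the first bin whose mean
#' rate exceeds 90 percent of that reference.
#'
#' @param curve data.frame from \code{\link{populationGrowthCurve}}.
#' @param removal_time,readdition_time schedule event times (min).
#' @param ref_fraction threshold fraction of the pre-removal mean.
#' @return list with \code{pre_removal_rate}, \code{lag_to_decline},
#'   \code{lag_to_recovery} (min; \code{NA} when never crossed).
#' @export
detectArrestRecovery <- function(curve, removal_time, readdition_time,
                                 ref_fraction = 0.9) {
  rng <- range(curve$bin_center)
  if (removal_time < rng[1] || readdition_time > rng[2])
    gsStop("gs_input_error",
           "schedule events [%g, %g] outside the curve range [%g, %g]",
           removal_time, readdition_time, rng[1], rng[2])
  pre <- curve$mean_rate[curve$bin_center < removal_time]
  if (!length(pre))
    gsStop("gs_input_error", "no bins before the removal event")
  ref <- mean(pre)
  after_rm <- curve[curve$bin_center > removal_time &
                      curve$bin_center <= readdition_time, , drop = FALSE]
  dec <- after_rm$bin_center[after_rm$mean_rate < ref_fraction * ref]
  after_add <- curve[curve$bin_center > readdition_time, , drop = FALSE]
  rec <- after_add$bin_center[after_add$mean_rate > ref_fraction * ref]
  list(pre_removal_rate = ref,
       lag_to_decline = if (length(dec)) dec[1] - removal_time else NA_real_,
       lag_to_recovery = if (length(rec)) rec[1] - readdition_time else NA_real_)
}
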