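#' Construct a PlateSeries
#'
#' @param time shared time grid (min), strictly increasing.
#' @param absorbance time x well matrix of absorbance readings.
#' @param fluorescence optional time x well matrix of fluorescence readings.
#' @param wellData data.frame of per-well metadata with columns \code{well},
#'   \code{strain}, \code{medium}, \code{iptg_uM}, \code{replicate}.
#' @param A_bg background absorbance recorded with the plate (used as the
#'   fallback background when no blank well is available).
#' @return A \linkS4class{PlateSeries}.
#' @export
PlateSeries <- function(time, absorbance, fluorescence = NULL, wellData,
                        A_bg = NA_real_) {
  a <- list(absorbance = absorbance)
  if (!is.null(fluorescence)) a$fluorescence <- fluorescence
  ps <- new("PlateSeries", SummarizedExperiment(
    assays = a,
    rowData = DataFrame(time_min = time),
    colData = DataFrame(wellData)
  ))
  metadata(ps)$A_bg <- A_bg
  validObject(ps)
  ps
}

#' @describeIn PlateSeries the shared time grid (min).
#' @param x a \linkS4class{PlateSeries}.
#' @export
plateTime <- function(x) rowData(x)$time_min

#' @describeIn PlateSeries the absorbance assay matrix.
#' @export
absorbance <- function(x) assay(x, "absorbance")

#' @describeIn PlateSeries the fluorescence assay matrix (or NULL).
#' @export
fluorescence <- function(x) {
  if ("fluorescence" %in% names(assays(x))) assay(x, "fluorescence") else NULL
}

#' @describeIn PlateSeries the per-well metadata as a data.frame.
#' @export
wellInfo <- function(x) as.data.frame(colData(x))

#' @describeIn PlateSeries the plate background absorbance (may be NA).
#' @export
plateBackground <- function(x) {
  bg <- metadata(x)$A_bg
  if (is.null(bg)) NA_real_ else bg
}

setMethod("show", "PlateSeries", function(object) {
  tt <- plateTime(object)
  cat(sprintf("PlateSeries: %d wells x %d timepoints (%g-%g min)\n",
              ncol(object), nrow(object), min(tt), max(tt)))
  cd <- wellInfo(object)
  cat(sprintf("  media: %s | IPTG levels (uM): %s\n",
              paste(unique(cd$medium), collapse = ", "),
              paste(sort(unique(cd$iptg_uM)), collapse = ", ")))
  invisible(NULL)
})
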