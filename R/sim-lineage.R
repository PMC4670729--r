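#' Simulate single-cell lineages in a perfused microfluidic device
#'
#' Mother cells trapped in dead-end channels elongate exponentially at the
#' population growth rate set by the shared medium (fresh medium is
#' perfused, so glucose is never limiting) and divide by a sizer rule:
#' division fires when the length reaches \code{L_div}, with lognormal
#' asymmetry noise on the division fraction, but is blocked while the beta'
#' pool is below \code{c_div} (depleted cells filament). Exact division
#' times are logged as ground truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param iptg schedule \code{data.frame(time_min, iptg_uM)} or a single
#'   concentration.
#' @param n_cells number of lineages (one mother cell each).
#' @param frame_interval imaging interval (min).
#' @param duration run length (min).
#' @return A \linkS4class{LineageSet}: measured length tracks, the
#'   ground-truth division log, and the environment trajectory.
#' @examples
#' ls <- simulateLineage(simConfig("M9-glc", cell_cv = 0, sigma_div = 0,
#'                                 noise_len = 0),
#'                       iptg = 1000, n_cells = 3, duration = 300)
#' head(ls@tracks)
#' @export
simulateLineage <- function(config, iptg = 1000, n_cells = 100,
                            frame_interval = 10, duration = 1200) {
  if (frame_interval <= 0) gsStop("gs_input_error", "frame_interval must be positive")
  if (n_cells < 1) gsStop("gs_input_error", "n_cells must be >= 1")
  seg <- scheduleToSegments(config, iptg, "R")
  fine <- seq(0, duration, by = 1)
  env <- integrateSwitch(config, seg, fine, glc0 = 1e8, B0 = config@A0)
  # cumulative growth integral (trapezoid on the 1-min grid)
  g <- env$g
  G <- c(0, cumsum((g[-1] + g[-length(g)]) / 2))
  Gat <- function(t) approx(fine, G, t, rule = 2)$y
  cat_ <- function(t) approx(fine, env$c, t, rule = 2)$y
  frames <- seq(0, duration, by = frame_interval)
  tracks <- vector("list", n_cells)
  divs <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    rnd <- withSeed(deriveSeed(config@seed, 5000 + cell), list(
      u0 = runif(1),
      mult = exp(rnorm(1, 0, config@cell_cv)),
      asym = rnorm(400, 0, config@sigma_div),
      meas = rnorm(length(frames), 0, 1)
    ))
    mult <- rnd$mult
    Lb <- config@L0 * 2^rnd$u0   # random cell age at loading
    tb <- 0
    ev_t <- numeric(0)
    gen_tb <- tb; gen_Lb <- Lb
    k <- 0
    repeat {
      k <- k + 1
      # size threshold crossing: mult*(G(t)-G(tb)) = log(L_div/Lb);
      # filamented newborns longer than L_div are due immediately
      gap <- max(log(config@L_div / gen_Lb[k]), 0)
      target <- Gat(tb) + gap / mult
      if (target > G[length(G)]) break
      idx <- which(G >= target)[1]
      if (idx == 1) t_size <- fine[1]
      else {
        # linear inverse interpolation of G
        t_size <- fine[idx - 1] +
          (target - G[idx - 1]) / (G[idx] - G[idx - 1] + 1e-300)
      }
      # division blocked while beta' is below c_div (filamentation)
      if (cat_(t_size) < config@c_div) {
        ok <- which(fine >= t_size & env$c >= config@c_div)
        if (!length(ok)) break
        t_size <- fine[ok[1]]
      }
      t_size <- max(t_size, tb + 1)   # successive divisions stay ordered
      if (t_size >= duration) break
      frac <- 0.5 * exp(rnd$asym[k])
      frac <- min(max(frac, 0.3), 0.7)
      ev_t <- c(ev_t, t_size)
      L_at_div <- gen_Lb[k] * exp(mult * (Gat(t_size) - Gat(gen_tb[k])))
      gen_tb <- c(gen_tb, t_size)
      gen_Lb <- c(gen_Lb, L_at_div * frac)
      tb <- t_size
    }
    # lengths at frame times
    gi <- findInterval(frames, gen_tb)
    L <- gen_Lb[gi] * exp(mult * (Gat(frames) - Gat(gen_tb[gi])))
    Lobs <- L * exp(config@noise_len * rnd$meas)
    id <- sprintf("cell%03d", cell)
    tracks[[cell]] <- data.frame(cell_id = id, time_min = frames,
                                 length_um = Lobs)
    divs[[cell]] <- if (length(ev_t))
      data.frame(cell_id = id, division_time_min = ev_t)
    else data.frame(cell_id = character(0), division_time_min = numeric(0))
  }
  new("LineageSet",
      tracks = do.call(rbind, tracks),
      divisions = do.call(rbind, divs),
      env = data.frame(time_min = fine, c = env$c, growth_rate = env$g))
}

setMethod("show", "LineageSet", function(object) {
  cat(sprintf("LineageSet: %d cells, %d frames each, %d logged divisions\n",
              length(unique(object@tracks$cell_id)),
              length(unique(object@tracks$time_min)),
              nrow(object@divisions)))
  invisible(NULL)
})
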