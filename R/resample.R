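#' Resample time series onto the normalised gait-cycle grid
#'
#' Interpolates all channels linearly onto `n_pre + n_cycle` frames: `n_pre`
#' pre-frames before heel-strike (retained so a causal electromechanical
#' delay can be applied) followed by `n_cycle` frames spanning 0--100% of
#' the gait cycle. The pre-frame spacing equals the cycle frame spacing
#' `tf / (n_cycle - 1)`, so the pre-window covers `n_pre / (n_cycle - 1)`
#' of a cycle period before heel-strike.
#'
#' @param time numeric vector of sample times, seconds, strictly increasing.
#' @param series numeric matrix (frames x channels) or vector sampled at
#'   `time`.
#' @param heel_strike_window `c(t_start, t_end)`: the heel-strike times
#'   bounding the cycle (0% and 100%).
#' @param n_cycle number of frames over the cycle (default 101).
#' @param n_pre number of pre-frames (default 20).
#' @return matrix with `n_pre + n_cycle` rows; attribute `"time"` carries the
#'   resampled frame times and `"cycle_duration"` the period `tf`.
#' @export
resample_to_cycle <- function(time, series, heel_strike_window,
                              n_cycle = 101L, n_pre = 20L) {
  if (length(heel_strike_window) != 2 ||
      heel_strike_window[2] <= heel_strike_window[1])
    stop("heel_strike_window must be c(t_start, t_end) with t_end > t_start")
  series <- as.matrix(series)
  if (nrow(series) != length(time))
    stop("series must have one row per time sample")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  t0 <- heel_strike_window[1]
  tf <- diff(heel_strike_window)
  dt <- tf / (n_cycle - 1)
  grid <- t0 + (seq_len(n_pre + n_cycle) - n_pre - 1) * dt
  if (grid[1] < time[1] - 1e-12)
    stop("insufficient pre-window data: need samples from ",
         signif(grid[1], 6), " s but recording starts at ",
         signif(time[1], 6), " s")
  if (grid[length(grid)] > time[length(time)] + 1e-12)
    stop("window end exceeds the data span")
  out <- apply(series, 2L, function(col)
    stats::approx(time, col, xout = grid, rule = 2)$y)
  out <- matrix(out, nrow = n_pre + n_cycle,
                dimnames = list(NULL, colnames(series)))
  attr(out, "time") <- grid
  attr(out, "cycle_duration") <- tf
  out
}
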