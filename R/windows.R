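#' Time window on a sample grid
#'
#' A closed interval `[start_ms, end_ms]` sampled at `sample_rate_hz`, with
#' inclusive endpoints: the window holds
#' `(end_ms - start_ms) * fs / 1000 + 1` samples. At 1000 Hz a window of
#' interest of \[-250; 600\] ms therefore holds 600 + 250 + 1 = 851 samples,
#' and an epoch window of \[-660; 1010\] ms holds 1671.
#'
#' @param start_ms window start in milliseconds (may be negative).
#' @param end_ms window end in milliseconds; must exceed `start_ms`.
#' @param sample_rate_hz sampling rate in Hz (default 1000).
#' @return An object of class `time_window`.
#' @examples
#' n_samples(time_window(-250, 600))   # 851
#' n_samples(time_window(-200, 1500))  # 1701
#' @export
time_window <- function(start_ms, end_ms, sample_rate_hz = 1000) {
  stopifnot(is.numeric(start_ms), is.numeric(end_ms),
            length(start_ms) == 1L, length(end_ms) == 1L,
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  if (end_ms <= start_ms) {
    stop("time_window: end_ms (", end_ms, ") must be greater than start_ms (",
         start_ms, ")")
  }
  structure(
    list(start_ms = start_ms, end_ms = end_ms,
         sample_rate_hz = sample_rate_hz),
    class = "time_window"
  )
}

#' @export
print.time_window <- function(x, ...) {
  cat(sprintf("<time_window [%g; %g] ms @ %g Hz, %d samples>\n",
              x$start_ms, x$end_ms, x$sample_rate_hz, n_samples(x)))
  invisible(x)
}

#' Number of samples in a time window (inclusive endpoints)
#'
#' @param window a [time_window].
#' @return Integer sample count.
#' @export
n_samples <- function(window) {
  stopifnot(inherits(window, "time_window"))
  as.integer(round((window$end_ms - window$start_ms) *
                     window$sample_rate_hz / 1000)) + 1L
}

#' Sample times of a window, in milliseconds
#'
#' @param window a [time_window].
#' @return Numeric vector of length [n_samples()].
#' @export
window_times <- function(window) {
  dt <- 1000 / window$sample_rate_hz
  window$start_ms + dt * (seq_len(n_samples(window)) - 1L)
}

#' Symmetrically expand a window of interest into an epoch window
#'
#' The per-participant epoch window is the window of interest padded by
#' `tau_ms` on both sides: `[start - tau; end + tau]`. `tau_ms` is first
#' rounded up to a multiple of `round_up_to_ms` (default 10 ms, the
#' granularity used when 406.37 ms is taken as 410 ms) and then to the sample
#' grid.
#'
#' @param interest a [time_window] (window of interest).
#' @param tau_ms padding in ms, typically `mean(IFI) + sd(IFI)`.
#' @param round_up_to_ms granularity to which `tau_ms` is rounded up.
#' @return A [time_window].
#' @export
expand_window <- function(interest, tau_ms, round_up_to_ms = 10) {
  stopifnot(inherits(interest, "time_window"), tau_ms >= 0)
  tau <- ceiling(tau_ms / round_up_to_ms) * round_up_to_ms
  dt <- 1000 / interest$sample_rate_hz
  tau <- ceiling(tau / dt) * dt
  time_window(interest$start_ms - tau, interest$end_ms + tau,
              interest$sample_rate_hz)
}

# Map a time in ms to a 1-based sample index on a window's grid, rounding
# half up. Deterministic quantization used by every epoching/design path.
ms_to_index <- function(t_ms, window) {
  as.integer(floor((t_ms - window$start_ms) * window$sample_rate_hz / 1000
                   + 0.5)) + 1L
}

# Round an onset in ms onto the sample grid of rate fs (half up), returning ms.
quantize_ms <- function(t_ms, sample_rate_hz) {
  dt <- 1000 / sample_rate_hz
  floor(t_ms / dt + 0.5) * dt
}

# Is `inner` fully contained in `outer`? (same sample rate assumed)
window_contains <- function(outer, inner) {
  inner$start_ms >= outer$start_ms && inner$end_ms <= outer$end_ms
}
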