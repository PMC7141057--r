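#' Time-locked average estimator
#'
#' The classical evoked-potential estimate: the pointwise mean over epochs,
#' per channel. Unbiased only when a single response falls inside each
#' epoch; with overlapping responses the expectation equals the sum of the
#' lag distributions convolved with the underlying kernel (see
#' [overlap_decomposition()]).
#'
#' @param epochs an `epoch_set` with at least one epoch.
#' @return An [efrp_kernel] on the epoch window.
#' @export
average_epochs <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  e <- n_epochs(epochs)
  if (e < 1L) stop("average_epochs: empty epoch set")
  vals <- apply(epochs$data, c(2L, 3L), mean)
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1L)
  efrp_kernel(vals, epochs$window, label = paste0(epochs$lock_class,
                                                  "_average"))
}

#' Analytic overlap decomposition of the average
#'
#' For each lag distribution Q_f of neighboring events, the expected
#' contamination of the time-locked average is the discrete convolution
#' ov_f = Q_f * a of that distribution with the underlying kernel a,
#' evaluated at full support and then cropped to the estimation window (so
#' border samples are exact). Distributions at negative offsets are the
#' previous-response overlaps, positive offsets the subsequent ones.
#'
#' @param distributions named or offset-indexed list of `lag_distribution`
#'   objects (e.g. the output of [lag_distribution()] for offsets -1, +1,
#'   ...).
#' @param kernel the underlying [efrp_kernel].
#' @param window [time_window] to crop to (default: the kernel window).
#' @return A list of class `overlap_components`: one [efrp_kernel] per input
#'   distribution (same names), plus attribute `window`.
#' @export
overlap_decomposition <- function(distributions, kernel, window = NULL) {
  stopifnot(inherits(kernel, "efrp_kernel"))
  if (inherits(distributions, "lag_distribution")) {
    distributions <- list(distributions)
  }
  if (is.null(window)) window <- kernel$window
  dt <- 1000 / window$sample_rate_hz
  out <- lapply(distributions, function(q) {
    stopifnot(inherits(q, "lag_distribution"))
    if (!length(q$mass)) return(zero_kernel(window, ncol(kernel$values),
                                            label = "overlap"))
    if (length(q$lags_ms) > 1L &&
        any(abs(diff(q$lags_ms) - dt) > 1e-9)) {
      stop("lag distribution grid does not match the kernel sample rate")
    }
    convolve_mass_kernel(q$mass, q$lags_ms[1], kernel, window,
                         label = "overlap")
  })
  structure(out, class = "overlap_components", window = window)
}

#' Expected average under overlap: kernel plus all overlap components
#'
#' Convenience wrapper computing `a + sum_f Q_f * a` over a window — the
#' noise-free expectation of [average_epochs()] when every neighboring
#' event evokes the same kernel.
#'
#' @param epochs an `epoch_set` (supplies the lag distributions).
#' @param kernel ground-truth [efrp_kernel].
#' @param target_class class of the overlapping events (default: the lock
#'   class).
#' @return An [efrp_kernel] on the epoch window.
#' @export
expected_average <- function(epochs, kernel, target_class = NULL) {
  if (is.null(target_class)) target_class <- epochs$lock_class
  win <- epochs$window
  offs <- relative_ranks_present(epochs, target_class)
  qs <- lapply(offs, function(f) lag_distribution(epochs, target_class, f))
  total <- crop_or_pad_kernel(kernel, win)
  if (length(qs)) {
    ovs <- overlap_decomposition(qs, kernel, window = win)
    for (ov in ovs) total$values <- total$values + ov$values
  }
  total
}

# Place a kernel onto a (possibly larger) window grid, zero outside.
crop_or_pad_kernel <- function(kernel, window) {
  out <- matrix(0, n_samples(window), ncol(kernel$values))
  for (ch in seq_len(ncol(kernel$values))) {
    out[, ch] <- crop_timed(kernel$values[, ch], kernel$window$start_ms,
                            window)
  }
  efrp_kernel(out, window, kernel$label)
}
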