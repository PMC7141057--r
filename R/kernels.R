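#' Evoked-response kernel
#'
#' One evoked-response waveform over an estimation window: a samples x
#' channels matrix of amplitudes in microvolts on the window's sample grid.
#'
#' @param values numeric vector or samples x channels matrix.
#' @param window a [time_window]; `n_samples(window)` must match `nrow(values)`.
#' @param label class token the kernel responds to (e.g. `"fixation"`).
#' @return An object of class `efrp_kernel`.
#' @export
efrp_kernel <- function(values, window, label = "kernel") {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  stopifnot(inherits(window, "time_window"),
            nrow(values) == n_samples(window),
            all(is.finite(values)))
  structure(list(values = values, window = window, label = label),
            class = "efrp_kernel")
}

#' @export
print.efrp_kernel <- function(x, ...) {
  cat(sprintf("<efrp_kernel '%s' [%g; %g] ms, %d samples x %d channel(s)>\n",
              x$label, x$window$start_ms, x$window$end_ms,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.data.frame.efrp_kernel <- function(x, ...) {
  df <- data.frame(time_ms = window_times(x$window))
  v <- x$values
  colnames(v) <- paste0("ch", seq_len(ncol(v)))
  cbind(df, as.data.frame(v))
}

#' Parametric kernel specification: a sum of Gaussian bumps
#'
#' Each component is a Gaussian bump `amplitude * exp(-(t - peak)^2 / (2 w^2))`
#' — a closed-form stand-in for evoked components such as the lambda wave
#' (occipital positivity peaking near 100 ms after fixation onset).
#'
#' @param components a data.frame (or list coercible to one) with columns
#'   `peak_ms`, `amplitude_uV`, `width_ms` (all widths > 0).
#' @param window a [time_window] over which the kernel is rendered.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(components, window) {
  components <- as.data.frame(components)
  stopifnot(all(c("peak_ms", "amplitude_uV", "width_ms") %in%
                  names(components)),
            all(components$width_ms > 0),
            inherits(window, "time_window"))
  structure(list(components = components, window = window),
            class = "kernel_spec")
}

#' Render a kernel spec into an [efrp_kernel]
#'
#' @param spec a [kernel_spec].
#' @param label class token for the rendered kernel.
#' @param channel_gains per-channel multiplicative gains (default 1, one
#'   channel); a vector of length C yields a C-channel kernel.
#' @return An [efrp_kernel].
#' @export
render_kernel <- function(spec, label = "kernel", channel_gains = 1) {
  stopifnot(inherits(spec, "kernel_spec"))
  t <- window_times(spec$window)
  base <- rep(0, length(t))
  for (k in seq_len(nrow(spec$components))) {
    cmp <- spec$components[k, ]
    base <- base + cmp$amplitude_uV *
      exp(-(t - cmp$peak_ms)^2 / (2 * cmp$width_ms^2))
  }
  efrp_kernel(outer(base, channel_gains), spec$window, label = label)
}

#' Crop a kernel to a sub-window
#'
#' @param kernel an [efrp_kernel].
#' @param window a [time_window] contained in the kernel's window (same rate).
#' @return An [efrp_kernel] on `window`.
#' @export
crop_kernel <- function(kernel, window) {
  stopifnot(inherits(kernel, "efrp_kernel"), inherits(window, "time_window"))
  if (!window_contains(kernel$window, window)) {
    stop("crop window [", window$start_ms, "; ", window$end_ms,
         "] not contained in kernel window [", kernel$window$start_ms, "; ",
         kernel$window$end_ms, "]")
  }
  i0 <- ms_to_index(window$start_ms, kernel$window)
  idx <- i0 + seq_len(n_samples(window)) - 1L
  efrp_kernel(kernel$values[idx, , drop = FALSE], window, kernel$label)
}
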