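# Timed-series helpers: a "timed" vector is values + the time (ms) of its
# first sample on a fixed sample grid. Discrete convolution shifts the origin
# by the sum of the two origins; computed at full support, cropping is the
# caller's job (keeps border samples of any later crop exact).

# Full linear convolution; returns list(values, start_ms).
conv_timed <- function(a, a_start, b, b_start) {
  if (!length(a) || !length(b)) {
    return(list(values = numeric(0), start_ms = a_start + b_start))
  }
  v <- stats::convolve(a, rev(b), type = "open")
  list(values = v, start_ms = a_start + b_start)
}

# Resample a timed series onto the grid of `window` (same rate assumed),
# zero outside its support.
crop_timed <- function(values, start_ms, window) {
  dt <- 1000 / window$sample_rate_hz
  n <- n_samples(window)
  out <- numeric(n)
  if (length(values)) {
    # index of first output sample within `values`
    off <- round((window$start_ms - start_ms) / dt)
    src <- off + seq_len(n)
    ok <- src >= 1 & src <= length(values)
    out[ok] <- values[src[ok]]
  }
  out
}

# Convolve a lag distribution with a (possibly multichannel) kernel and crop
# to `window`; returns an efrp_kernel on `window`.
convolve_mass_kernel <- function(mass, mass_start_ms, kernel, window,
                                 label = kernel$label) {
  out <- matrix(0, n_samples(window), ncol(kernel$values))
  for (ch in seq_len(ncol(kernel$values))) {
    cv <- conv_timed(mass, mass_start_ms, kernel$values[, ch],
                     kernel$window$start_ms)
    out[, ch] <- crop_timed(cv$values, cv$start_ms, window)
  }
  efrp_kernel(out, window, label = label)
}
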