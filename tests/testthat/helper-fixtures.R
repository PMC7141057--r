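# Shared builders for tiny deterministic sessions used across the suite.

# One-trial recording with a hand-placed impulse, for index-arithmetic checks.
impulse_recording <- function(impulse_abs_ms, amplitude = 7, total_ms = 4000,
                              fs = 1000) {
  n <- round(total_ms * fs / 1000) + 1
  dat <- matrix(0, 1, n)
  dat[1, round(impulse_abs_ms * fs / 1000) + 1] <- amplitude
  recording(dat, fs, c("1" = 0))
}

# Event stream with fixations at given onsets; `onsets` is a list with one
# sorted numeric vector per trial.
fixation_events <- function(onsets) {
  if (!is.list(onsets)) onsets <- list(onsets)
  df <- do.call(rbind, lapply(seq_along(onsets), function(tr) {
    data.frame(trial_id = tr, class = "fixation", onset_ms = onsets[[tr]],
               rank = seq_along(onsets[[tr]]))
  }))
  event_stream(df$trial_id, df$class, df$onset_ms, df$rank)
}

# Direct O(N^2) discrete convolution oracle on timed series.
brute_conv <- function(a, a_start, b, b_start, window) {
  dt <- 1000 / window$sample_rate_hz
  out <- numeric(n_samples(window))
  tout <- window_times(window)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      t <- a_start + (i - 1) * dt + b_start + (j - 1) * dt
      k <- which(abs(tout - t) < dt / 2)
      if (length(k) == 1) out[k] <- out[k] + a[i] * b[j]
    }
  }
  out
}

# Small noiseless session: regular fixations, known kernel.
toy_session <- function(n_trials = 3, ifi = 400, first = 600, fs = 1000,
                        kernel_window = time_window(0, 300, fs)) {
  onsets <- lapply(seq_len(n_trials), function(tr) seq(first, 3500, by = ifi))
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(tr) {
    data.frame(trial_id = tr,
               class = c("stimulus", rep("fixation", length(onsets[[tr]]))),
               onset_ms = c(0, onsets[[tr]]),
               rank = c(NA, seq_along(onsets[[tr]])))
  }))
  events <- event_stream(ev$trial_id, ev$class, ev$onset_ms, ev$rank)
  kern <- render_kernel(kernel_spec(data.frame(
    peak_ms = c(80, 180), amplitude_uV = c(6, -2), width_ms = c(25, 40)),
    kernel_window), "fixation")
  kernels <- list(fixation = kern,
                  stimulus = efrp_kernel(matrix(0, n_samples(kernel_window), 1),
                                         kernel_window, "stimulus"))
  rec <- render_session(events, kernels, sample_rate_hz = fs)
  list(recording = rec, events = events, kernel = kern, kernels = kernels)
}
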