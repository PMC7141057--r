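#' Extract time-locked epochs from a continuous recording
#'
#' Cuts one fixed-length multichannel segment around every lock event. Each
#' epoch stores, alongside its samples, the lock-relative onsets of *all*
#' events of the same trial (also those outside the epoch window, whose
#' response tails may still reach into it); these drive the overlap
#' diagnostics and the deconvolution design.
#'
#' Lock events whose window would run past the edges of the recording are
#' rejected with a message; the count is kept in `n_rejected`.
#'
#' @param rec a [recording].
#' @param events full `event_stream` of the session.
#' @param lock_class class label of the lock events (e.g. `"fixation"`,
#'   `"stimulus"`).
#' @param window a [time_window] relative to the lock onset; its sample rate
#'   must match the recording.
#' @param lock_events optional `event_stream` restricting which events of
#'   `lock_class` act as locks (e.g. the output of [select_ranks()]); all of
#'   `events` is still used to annotate co-occurring events.
#' @return An object of class `epoch_set` with fields `data`
#'   (E x N_e x channels array), `events` (per-epoch data.frame of
#'   `class`, `rank`, `rel_onset_ms`), `lock` (per-epoch trial/rank of the
#'   lock), `window`, `lock_class`, `ch_names`, `n_rejected`.
#' @export
extract_epochs <- function(rec, events, lock_class, window,
                           lock_events = NULL) {
  stopifnot(inherits(rec, "recording"), inherits(window, "time_window"))
  if (abs(window$sample_rate_hz - rec$sample_rate_hz) > 1e-9) {
    stop("window sample rate (", window$sample_rate_hz,
         " Hz) does not match recording (", rec$sample_rate_hz, " Hz)")
  }
  locks <- if (is.null(lock_events)) {
    events[events$class == lock_class, , drop = FALSE]
  } else {
    lock_events[lock_events$class == lock_class, , drop = FALSE]
  }
  if (nrow(locks) == 0L) {
    stop("no events of lock class '", lock_class, "'")
  }
  fs <- rec$sample_rate_hz
  ne <- n_samples(window)
  n_total <- ncol(rec$data)
  pre <- round(-window$start_ms * fs / 1000)   # samples before lock
  keep <- list(); ep_events <- list(); lock_meta <- list()
  n_rejected <- 0L
  for (i in seq_len(nrow(locks))) {
    tr <- locks$trial_id[i]
    t_abs <- rec$trial_onset_ms[as.character(tr)] + locks$onset_ms[i]
    s0 <- as.integer(floor(t_abs * fs / 1000 + 0.5)) + 1L  # lock sample
    first <- s0 - pre
    last <- first + ne - 1L
    if (first < 1L || last > n_total) { n_rejected <- n_rejected + 1L; next }
    keep[[length(keep) + 1L]] <- rec$data[, first:last, drop = FALSE]
    same_trial <- events[events$trial_id == tr, , drop = FALSE]
    ep_events[[length(ep_events) + 1L]] <- data.frame(
      class = same_trial$class,
      rank = same_trial$rank,
      rel_onset_ms = same_trial$onset_ms - locks$onset_ms[i],
      stringsAsFactors = FALSE
    )
    lock_meta[[length(lock_meta) + 1L]] <- data.frame(
      trial_id = tr, rank = locks$rank[i], onset_ms = locks$onset_ms[i])
  }
  if (!length(keep)) {
    stop("all ", nrow(locks), " lock event(s) fell too close to the ",
         "recording edge")
  }
  if (n_rejected > 0L) {
    message("extract_epochs: rejected ", n_rejected,
            " epoch(s) at the recording edge")
  }
  e <- length(keep)
  data <- array(0, dim = c(e, ne, nrow(rec$data)))
  for (i in seq_len(e)) data[i, , ] <- t(keep[[i]])
  structure(
    list(data = data, events = ep_events,
         lock = do.call(rbind, lock_meta),
         window = window, lock_class = lock_class,
         ch_names = rec$ch_names, n_rejected = n_rejected),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set %d epochs x %d samples x %d channel(s), lock '%s' [%g; %g] ms>\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$lock_class,
    x$window$start_ms, x$window$end_ms))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$data)[1]

#' Baseline correction
#'
#' Subtracts, per channel (and per epoch for epoch sets), the mean over the
#' baseline interval — conventionally \[-200; -100\] ms before the lock, a
#' period free of saccade-generation activity.
#'
#' @param x an [efrp_kernel] or `epoch_set`.
#' @param baseline a [time_window] contained in the object's window.
#' @return The same type of object, with zero mean over the baseline.
#' @export
baseline_correct <- function(x, baseline = NULL) {
  UseMethod("baseline_correct")
}

baseline_indices <- function(window, baseline) {
  if (is.null(baseline)) baseline <- time_window(-200, -100,
                                                 window$sample_rate_hz)
  if (!window_contains(window, baseline)) {
    stop("baseline [", baseline$start_ms, "; ", baseline$end_ms,
         "] ms not inside window [", window$start_ms, "; ",
         window$end_ms, "] ms")
  }
  ms_to_index(baseline$start_ms, window) +
    seq_len(n_samples(baseline)) - 1L
}

#' @export
baseline_correct.efrp_kernel <- function(x, baseline = NULL) {
  idx <- baseline_indices(x$window, baseline)
  mu <- colMeans(x$values[idx, , drop = FALSE])
  x$values <- sweep(x$values, 2L, mu)
  x
}

#' @export
baseline_correct.epoch_set <- function(x, baseline = NULL) {
  idx <- baseline_indices(x$window, baseline)
  for (ch in seq_len(dim(x$data)[3])) {
    mu <- apply(x$data[, idx, ch, drop = FALSE], 1L, mean)
    x$data[, , ch] <- x$data[, , ch] - mu
  }
  x
}

#' Normalized lag distribution of neighboring events
#'
#' For each epoch, locates the event of `target_class` at rank offset
#' `relative_rank` from the lock (-1 = immediately previous, +1 =
#' immediately subsequent) and accumulates its lock-relative onset into a
#' histogram on the sample grid, normalized by the number of epochs E.
#' Epochs lacking such an event contribute no mass, so `sum(mass) <= 1`,
#' with equality iff every epoch contributes exactly one event.
#'
#' Rank offsets use the events' `rank` labels when both the lock and the
#' targets carry ranks; otherwise the events of `target_class` are ordered
#' by onset and offset positionally from the lock time.
#'
#' @param epochs an `epoch_set`.
#' @param target_class class of the neighboring events.
#' @param relative_rank nonzero integer rank offset from the lock.
#' @return An object of class `lag_distribution`: `lags_ms` (sample-grid
#'   lags), `mass` (nonnegative, sums to <= 1), `n_epochs`.
#' @export
lag_distribution <- function(epochs, target_class, relative_rank) {
  stopifnot(inherits(epochs, "epoch_set"), relative_rank != 0)
  e <- n_epochs(epochs)
  fs <- epochs$window$sample_rate_hz
  dt <- 1000 / fs
  lags <- numeric(0)
  for (i in seq_len(e)) {
    ev <- epochs$events[[i]]
    tgt <- ev[ev$class == target_class, , drop = FALSE]
    if (!nrow(tgt)) next
    lock_rank <- epochs$lock$rank[i]
    if (!is.na(lock_rank) && target_class == epochs$lock_class &&
        all(!is.na(tgt$rank))) {
      hit <- tgt$rel_onset_ms[tgt$rank == lock_rank + relative_rank]
    } else {
      o <- sort(tgt$rel_onset_ms)
      nneg <- sum(o < 0)
      pos <- if (any(o == 0)) {         # lock itself among the targets
        nneg + 1L + relative_rank
      } else {
        nneg + if (relative_rank > 0) relative_rank else relative_rank + 1L
      }
      hit <- if (pos >= 1 && pos <= length(o)) o[pos] else numeric(0)
    }
    if (length(hit) == 1L) lags <- c(lags, quantize_ms(hit, fs))
  }
  if (!length(lags)) {
    return(structure(list(lags_ms = numeric(0), mass = numeric(0),
                          n_epochs = e),
                     class = "lag_distribution"))
  }
  grid <- seq(min(lags), max(lags), by = dt)
  mass <- vapply(grid, function(g) sum(abs(lags - g) < dt / 2), 0) / e
  structure(list(lags_ms = grid, mass = mass, n_epochs = e),
            class = "lag_distribution")
}

#' @export
print.lag_distribution <- function(x, ...) {
  cat(sprintf("<lag_distribution %d lag(s), total mass %.3f over %d epochs>\n",
              length(x$lags_ms), sum(x$mass), x$n_epochs))
  invisible(x)
}

# Rank offsets (relative to the lock) that carry any mass across an epoch
# set, for a given class; 0 is excluded (it is the lock itself).
relative_ranks_present <- function(epochs, target_class) {
  offs <- integer(0)
  for (i in seq_len(n_epochs(epochs))) {
    ev <- epochs$events[[i]]
    tgt <- ev[ev$class == target_class, , drop = FALSE]
    if (!nrow(tgt)) next
    lock_rank <- epochs$lock$rank[i]
    if (!is.na(lock_rank) && target_class == epochs$lock_class &&
        all(!is.na(tgt$rank))) {
      offs <- union(offs, tgt$rank - lock_rank)
    } else {
      o <- sort(tgt$rel_onset_ms)
      npos <- sum(o > 0); nneg <- sum(o < 0)
      offs <- union(offs, c(seq_len(npos), -seq_len(nneg)))
    }
  }
  sort(setdiff(offs, 0L))
}
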