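#' Event stream constructor / validator
#'
#' An event stream is a data frame with one row per event and columns
#' `trial_id` (integer), `class` (character token such as `"stimulus"` or
#' `"fixation"`), `onset_ms` (milliseconds from trial start) and optionally
#' `rank` (positive integer position of the event within its trial and class,
#' consecutive from 1 in onset order — used for fixations).
#'
#' @param trial_id integer vector.
#' @param class character vector of class labels.
#' @param onset_ms numeric vector of onsets in ms from trial start.
#' @param rank optional integer vector (NA allowed, e.g. for stimulus
#'   events); must increase with onset within a trial and class. A complete
#'   session numbers fixations consecutively from 1; subsets (such as
#'   selected lock events) keep their original ranks.
#' @return A `data.frame` of class `event_stream`, sorted by trial and onset.
#' @export
event_stream <- function(trial_id, class, onset_ms, rank = NULL) {
  n <- length(trial_id)
  stopifnot(length(class) == n, length(onset_ms) == n)
  if (is.null(rank)) rank <- rep(NA_integer_, n)
  stopifnot(length(rank) == n)
  ev <- data.frame(trial_id = as.integer(trial_id),
                   class = as.character(class),
                   onset_ms = as.numeric(onset_ms),
                   rank = as.integer(rank),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$trial_id, ev$onset_ms), , drop = FALSE]
  rownames(ev) <- NULL
  validate_event_stream(ev)
  structure(ev, class = c("event_stream", "data.frame"))
}

validate_event_stream <- function(ev) {
  need <- c("trial_id", "class", "onset_ms", "rank")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("event stream missing columns: ",
                         paste(miss, collapse = ", "))
  for (tr in unique(ev$trial_id)) {
    for (cl in unique(ev$class[ev$trial_id == tr])) {
      sub <- ev[ev$trial_id == tr & ev$class == cl, , drop = FALSE]
      o <- sub$onset_ms
      if (any(diff(o) <= 0)) {
        stop("onsets must be strictly increasing within trial ", tr,
             " class '", cl, "'")
      }
      r <- sub$rank[!is.na(sub$rank)]
      if (length(r) >= 2 && any(diff(r) <= 0)) {
        stop("ranks must increase with onset order (trial ", tr,
             ", class '", cl, "')")
      }
    }
  }
  invisible(ev)
}

#' Read / write an event table
#'
#' CSV or TSV (decided from the file extension) with columns
#' `trial_id, class, onset_ms` and optionally `rank`.
#'
#' @param path file path.
#' @return [read_event_table()] returns an `event_stream`.
#' @export
read_event_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  event_stream(df$trial_id, df$class, df$onset_ms,
               rank = if ("rank" %in% names(df)) df$rank else NULL)
}

#' @param events an `event_stream`.
#' @rdname read_event_table
#' @export
write_event_table <- function(events, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(events), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inter-fixation intervals of an event stream
#'
#' The IFI is the onset-to-onset difference between consecutive fixations
#' within a trial (current fixation duration plus subsequent saccade
#' duration).
#'
#' @param events an `event_stream`.
#' @param class event class treated as fixations.
#' @return Numeric vector of IFIs in ms (possibly empty).
#' @export
inter_fixation_intervals <- function(events, class = "fixation") {
  fx <- events[events$class == class, , drop = FALSE]
  unlist(lapply(split(fx$onset_ms, fx$trial_id), function(o) {
    if (length(o) >= 2) diff(sort(o)) else numeric(0)
  }), use.names = FALSE)
}

#' Per-participant epoch window from oculomotor statistics
#'
#' Expands the window of interest by `tau = mean(IFI) + sd(IFI)` on both
#' sides, so that an epoch always covers the responses of the adjacent
#' (previous and subsequent) fixations. With a tau of about 410 ms and an
#' interest window of \[-250; 600\] ms this yields \[-660; 1010\] ms
#' (1671 samples at 1000 Hz).
#'
#' @param events an `event_stream` with at least one computable IFI.
#' @param interest the [time_window] of interest.
#' @param class fixation class label.
#' @param round_up_to_ms granularity to which tau is rounded up (default 10).
#' @return A [time_window].
#' @export
epoch_window_for_participant <- function(events, interest,
                                         class = "fixation",
                                         round_up_to_ms = 10) {
  ifi <- inter_fixation_intervals(events, class = class)
  if (length(ifi) < 1L) {
    stop("no inter-fixation intervals computable: need >= 2 fixations in ",
         ">= 1 trial")
  }
  sd_ifi <- if (length(ifi) >= 2L) stats::sd(ifi) else 0
  tau <- mean(ifi) + sd_ifi
  expand_window(interest, tau, round_up_to_ms = round_up_to_ms)
}

#' Randomly select fixation ranks within each trial
#'
#' Draws `draws` ranks uniformly in `[low, high]` per trial (with
#' replacement; duplicate draws collapse to unique events) and returns the
#' corresponding fixation events. Trials whose maximum available rank is
#' below `low` are skipped; the number skipped is reported via the
#' `n_skipped` attribute and a message.
#'
#' @param events an `event_stream`.
#' @param low,high inclusive rank bounds (defaults 3 and 9).
#' @param draws draws per trial (default 3).
#' @param seed optional integer seed for reproducibility.
#' @param class fixation class label.
#' @return An `event_stream` of selected fixation events, with attributes
#'   `n_skipped` (trials without any eligible rank) and `n_duplicate`
#'   (draws collapsed because they repeated a rank).
#' @export
select_ranks <- function(events, low = 3, high = 9, draws = 3, seed = NULL,
                         class = "fixation") {
  stopifnot(low <= high, draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  fx <- events[events$class == class & !is.na(events$rank), , drop = FALSE]
  sel <- list(); n_skipped <- 0L; n_dup <- 0L
  for (tr in unique(fx$trial_id)) {
    sub <- fx[fx$trial_id == tr, , drop = FALSE]
    hi_avail <- min(high, max(sub$rank))
    if (hi_avail < low) { n_skipped <- n_skipped + 1L; next }
    avail <- seq.int(low, hi_avail)
    r <- avail[sample.int(length(avail), draws, replace = TRUE)]
    ur <- unique(r)
    n_dup <- n_dup + (length(r) - length(ur))
    sel[[length(sel) + 1L]] <- sub[sub$rank %in% ur, , drop = FALSE]
  }
  if (!length(sel)) stop("select_ranks: no trial has a fixation of rank >= ",
                         low)
  out <- do.call(rbind, sel)
  out <- out[order(out$trial_id, out$onset_ms), , drop = FALSE]
  rownames(out) <- NULL
  if (n_skipped > 0L) {
    message("select_ranks: skipped ", n_skipped,
            " trial(s) with max rank < ", low)
  }
  structure(out, class = c("event_stream", "data.frame"),
            n_skipped = n_skipped, n_duplicate = n_dup)
}
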