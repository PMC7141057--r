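#' Continuous multichannel recording
#'
#' A channels-by-samples numeric matrix plus its sampling rate and the
#' absolute start time (in recording ms) of each trial. Event onsets are
#' expressed in ms from trial start; the absolute onset of an event is
#' `trial_onset_ms[trial] + onset_ms`.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sample_rate_hz sampling rate in Hz.
#' @param trial_onset_ms named numeric vector: start of each trial, in ms from
#'   the beginning of the recording; names are trial ids.
#' @param ch_names optional channel names.
#' @return An object of class `recording`.
#' @export
recording <- function(data, sample_rate_hz, trial_onset_ms,
                      ch_names = NULL) {
  data <- as.matrix(data)
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(data)))
  stopifnot(length(ch_names) == nrow(data), sample_rate_hz > 0)
  structure(
    list(data = data, sample_rate_hz = sample_rate_hz,
         trial_onset_ms = trial_onset_ms, ch_names = ch_names),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %d ch x %d samples @ %g Hz, %d trial(s)>\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              length(x$trial_onset_ms)))
  invisible(x)
}

#' Write / read a recording as plain text
#'
#' Format: header lines `# sfreq <Hz>`, `# ch_names <tab separated>`,
#' `# trial_ids ...`, `# trial_onset_ms ...`, followed by one
#' tab-separated row of samples per channel.
#'
#' @param rec a [recording].
#' @param path file path.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# sfreq", format(rec$sample_rate_hz, digits = 15)),
    paste("# ch_names", paste(rec$ch_names, collapse = "\t")),
    paste("# trial_ids", paste(names(rec$trial_onset_ms), collapse = "\t")),
    paste("# trial_onset_ms",
          paste(format(rec$trial_onset_ms, digits = 15), collapse = "\t"))
  ), con)
  utils::write.table(rec$data, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 4L)
  get <- function(key) {
    line <- hdr[startsWith(hdr, paste0("# ", key))]
    if (!length(line)) stop("recording file missing header '", key, "'")
    strsplit(sub(paste0("^# ", key, " "), "", line), "\t")[[1]]
  }
  sfreq <- as.numeric(get("sfreq"))
  ch <- get("ch_names")
  ids <- get("trial_ids")
  onsets <- as.numeric(get("trial_onset_ms"))
  names(onsets) <- ids
  dat <- as.matrix(utils::read.table(path, skip = 4L, sep = "\t"))
  dimnames(dat) <- NULL
  recording(dat, sfreq, onsets, ch_names = ch)
}
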