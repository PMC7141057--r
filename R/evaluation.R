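#' Baseline-interval variance of a kernel estimate
#'
#' Population variance (denominator n) of the kernel samples over the
#' baseline interval, per channel, averaged over channels. A reliable
#' estimate stabilizes during the baseline; residual overlap inflates this
#' variance.
#'
#' @param kernel an [efrp_kernel].
#' @param interval a [time_window] inside the kernel window (default
#'   \[-200; -100\] ms).
#' @return Nonnegative real.
#' @export
baseline_variance <- function(kernel, interval = NULL) {
  stopifnot(inherits(kernel, "efrp_kernel"))
  if (is.null(interval)) {
    interval <- time_window(-200, -100, kernel$window$sample_rate_hz)
  }
  idx <- baseline_indices(kernel$window, interval)
  v <- apply(kernel$values[idx, , drop = FALSE], 2L, function(col) {
    mean((col - mean(col))^2)
  })
  mean(v)
}

#' Tail deviation from zero
#'
#' Mean absolute amplitude over a late interval (default \[450; 600\] ms),
#' probing the expected return to zero of the evoked response at the end of
#' the estimation window; residual subsequent-response overlap keeps it
#' elevated.
#'
#' @param kernel an [efrp_kernel].
#' @param interval a [time_window] inside the kernel window.
#' @return Nonnegative real (microvolts).
#' @export
tail_deviation <- function(kernel, interval = NULL) {
  stopifnot(inherits(kernel, "efrp_kernel"))
  if (is.null(interval)) {
    interval <- time_window(450, 600, kernel$window$sample_rate_hz)
  }
  idx <- baseline_indices(kernel$window, interval)
  mean(abs(kernel$values[idx, , drop = FALSE]))
}

#' Root-mean-square error between a kernel estimate and ground truth
#'
#' Computed over the overlap of both windows (or a supplied window),
#' pooled over channels.
#'
#' @param estimate,truth [efrp_kernel]s on the same sample rate.
#' @param window optional [time_window] to restrict the comparison.
#' @return Nonnegative real (microvolts).
#' @export
kernel_rmse <- function(estimate, truth, window = NULL) {
  if (is.null(window)) {
    window <- time_window(max(estimate$window$start_ms,
                              truth$window$start_ms),
                          min(estimate$window$end_ms, truth$window$end_ms),
                          estimate$window$sample_rate_hz)
  }
  a <- crop_or_pad_kernel(estimate, window)$values
  b <- crop_or_pad_kernel(truth, window)$values
  sqrt(mean((a - b)^2))
}

#' Run and compare the three estimators on one fixture
#'
#' Extracts epochs once per required window, runs the requested methods on
#' identical data, applies a common baseline correction, and reports
#' baseline-interval variance, tail deviation, RMSE versus ground truth
#' (when the fixture carries it) and runtime per method. Fully
#' deterministic for a deterministic fixture.
#'
#' @param fixture a list as returned by [make_fixture()] (fields
#'   `recording`, `events`, `lock_events`, `lock_class`, `windows`, and
#'   optionally `kernels` for ground truth).
#' @param methods subset of `c("average", "adjar", "glm")`.
#' @param baseline [time_window] for the common baseline correction.
#' @param tail_interval [time_window] for [tail_deviation()].
#' @param adjar an [adjar_config] (defaults derived from the fixture's
#'   interest window).
#' @return An object of class `comparison_report`: per-method list of
#'   metrics (`baseline_variance`, `tail_deviation`, `rmse`,
#'   `runtime_s`, method-specific diagnostics) plus `estimates` (the
#'   baseline-corrected kernels) and metadata.
#' @export
compare_methods <- function(fixture,
                            methods = c("average", "adjar", "glm"),
                            baseline = NULL, tail_interval = NULL,
                            adjar = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  interest <- fixture$windows$interest
  fs <- interest$sample_rate_hz
  if (is.null(baseline)) baseline <- time_window(-200, -100, fs)
  if (is.null(tail_interval)) {
    tail_interval <- time_window(450, min(600, interest$end_ms), fs)
  }
  truth <- fixture$kernels[[fixture$lock_class]]
  report <- list(); estimates <- list()
  epochs_interest <- NULL; epochs_full <- NULL
  get_interest <- function() {
    if (is.null(epochs_interest)) {
      epochs_interest <<- extract_epochs(fixture$recording, fixture$events,
                                         fixture$lock_class, interest,
                                         lock_events = fixture$lock_events)
    }
    epochs_interest
  }
  get_full <- function() {
    if (is.null(epochs_full)) {
      epochs_full <<- extract_epochs(fixture$recording, fixture$events,
                                     fixture$lock_class,
                                     fixture$windows$epoch,
                                     lock_events = fixture$lock_events)
    }
    epochs_full
  }
  finish <- function(kernel, t0, extra = list()) {
    k <- baseline_correct(kernel, baseline)
    metrics <- list(
      baseline_variance = baseline_variance(k, baseline),
      tail_deviation = tail_deviation(k, tail_interval),
      runtime_s = as.numeric(Sys.time()) - t0)
    if (!is.null(truth)) {
      tr <- baseline_correct(crop_or_pad_kernel(truth, interest), baseline)
      metrics$rmse <- kernel_rmse(k, tr, window = interest)
    }
    list(kernel = k, metrics = c(metrics, extra))
  }
  for (m in methods) {
    t0 <- as.numeric(Sys.time())
    res <- tryCatch(switch(m,
      average = finish(average_epochs(get_interest()), t0),
      adjar = {
        ep <- get_full()
        cfg <- if (is.null(adjar)) adjar_config(interest) else adjar
        qp <- lag_distribution(ep, fixture$lock_class, -1L)
        qn <- lag_distribution(ep, fixture$lock_class, +1L)
        ad <- run_adjar(ep, qp, qn, cfg)
        finish(ad$estimate, t0,
               extra = list(n_iterations = ad$n_iterations,
                            converged = ad$converged))
      },
      glm = {
        ep <- get_full()
        cls <- glm_class(fixture$lock_class, fixture$lock_class, interest)
        fit <- solve_glm(build_design(ep, cls), ep)
        finish(fit$kernels[[1]], t0,
               extra = list(gram_condition = fit$gram_condition,
                            rank_deficient = fit$rank_deficient))
      }), error = function(e) {
        stop("method '", m, "' failed: ", conditionMessage(e))
      })
    report[[m]] <- res$metrics
    estimates[[m]] <- res$kernel
  }
  structure(list(methods = report, estimates = estimates,
                 preset = fixture$preset, seed = fixture$seed,
                 baseline = c(baseline$start_ms, baseline$end_ms),
                 tail_interval = c(tail_interval$start_ms,
                                   tail_interval$end_ms)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report", if (!is.null(x$preset)) paste0("'", x$preset, "'"),
      ">\n")
  for (m in names(x$methods)) {
    mm <- x$methods[[m]]
    cat(sprintf("  %-8s baseline var %.4g, tail dev %.4g%s\n", m,
                mm$baseline_variance, mm$tail_deviation,
                if (!is.null(mm$rmse)) sprintf(", RMSE %.4g", mm$rmse) else ""))
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param report a `comparison_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  out <- list(preset = report$preset, seed = report$seed,
              baseline_ms = report$baseline,
              tail_interval_ms = report$tail_interval,
              methods = report$methods)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
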