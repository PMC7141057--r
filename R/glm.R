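#' Event-class configuration for GLM deconvolution
#'
#' A class gathers the events whose evoked response is assumed identical and
#' estimated as one kernel: a class label plus an optional rank range, and
#' the estimation window of the kernel. The canonical configurations are
#' one class (all fixations, the averaging analogue), two classes (stimulus
#' + all fixations) and three classes (stimulus + first fixation +
#' subsequent fixations).
#'
#' @param name kernel name in the result.
#' @param class event class label to match.
#' @param window [time_window] of the class's kernel, relative to event
#'   onset.
#' @param rank_min,rank_max inclusive rank bounds (default: any rank,
#'   including unranked events).
#' @return An object of class `glm_class`.
#' @export
glm_class <- function(name, class, window, rank_min = NULL,
                      rank_max = NULL) {
  stopifnot(inherits(window, "time_window"))
  structure(list(name = name, class = class, window = window,
                 rank_min = rank_min, rank_max = rank_max),
            class = "glm_class")
}

matches_class <- function(cfg, class, rank) {
  ok <- class == cfg$class
  if (!is.null(cfg$rank_min)) ok <- ok & !is.na(rank) & rank >= cfg$rank_min
  if (!is.null(cfg$rank_max)) ok <- ok & !is.na(rank) & rank <= cfg$rank_max
  ok
}

#' Standard stimulus-onset model configurations
#'
#' @param n_classes 1 (fixations only — used for fixation-locked
#'   deconvolution), 2 (stimulus + all fixations) or 3 (stimulus + first
#'   fixation + subsequent fixations).
#' @param stimulus_window estimation window for the stimulus kernel
#'   (conventionally the whole epoch window).
#' @param fixation_window estimation window for the fixation kernel(s).
#' @param fixation_class,stimulus_class event class labels.
#' @return List of [glm_class] objects.
#' @export
onset_model_classes <- function(n_classes, stimulus_window, fixation_window,
                                fixation_class = "fixation",
                                stimulus_class = "stimulus") {
  stopifnot(n_classes %in% 1:3)
  if (n_classes == 1) {
    return(list(glm_class("a", fixation_class, fixation_window)))
  }
  if (n_classes == 2) {
    return(list(glm_class("s", stimulus_class, stimulus_window),
                glm_class("a1plus", fixation_class, fixation_window,
                          rank_min = 1)))
  }
  list(glm_class("s", stimulus_class, stimulus_window),
       glm_class("a1", fixation_class, fixation_window,
                 rank_min = 1, rank_max = 1),
       glm_class("a2plus", fixation_class, fixation_window, rank_min = 2))
}

#' Build the sparse stacked-Toeplitz design matrix
#'
#' Row block i covers the samples of epoch i (epoch-major stacking, N =
#' N_e x E rows in total); the column block of class c holds one column per
#' lag of the class's estimation window. Every event matched by class c at
#' epoch-relative onset tau contributes a diagonal stripe of ones: a one at
#' (row of epoch sample at `tau + w0 + j dt`, class column j) for each lag
#' j, with rows falling outside the epoch truncated (partial kernels are
#' estimated from partial evidence rather than discarding epochs). With a
#' stimulus class of N_s lags and two fixation classes of N_a lags each,
#' the design has N_s + 2 N_a columns.
#'
#' @param epochs an `epoch_set`.
#' @param classes list of [glm_class] configurations; each event may be
#'   matched by at most one class (a configuration error otherwise).
#' @return An object of class `design_matrix`: `D` (sparse dgCMatrix),
#'   `classes`, `col_blocks` (named list of column index vectors),
#'   `n_epochs`, `n_samples_epoch`, `epoch_rows` (list of row indices per
#'   epoch), `window`.
#' @export
build_design <- function(epochs, classes) {
  stopifnot(inherits(epochs, "epoch_set"), length(classes) >= 1)
  if (inherits(classes, "glm_class")) classes <- list(classes)
  fs <- epochs$window$sample_rate_hz
  ne <- n_samples(epochs$window)
  e <- n_epochs(epochs)
  ncols_per <- vapply(classes, function(cf) n_samples(cf$window), 0L)
  col_start <- cumsum(c(0L, ncols_per[-length(ncols_per)]))
  names(col_start) <- vapply(classes, `[[`, "", "name")
  ii <- list(); jj <- list()
  for (i in seq_len(e)) {
    ev <- epochs$events[[i]]
    hit <- matrix(FALSE, nrow(ev), length(classes))
    for (c in seq_along(classes)) {
      hit[, c] <- matches_class(classes[[c]], ev$class, ev$rank)
    }
    if (any(rowSums(hit) > 1L)) {
      bad <- which(rowSums(hit) > 1L)[1]
      stop("event (class '", ev$class[bad], "', rank ", ev$rank[bad],
           ") matched by more than one model class")
    }
    row0 <- (i - 1L) * ne
    for (c in seq_along(classes)) {
      cf <- classes[[c]]
      nc <- ncols_per[c]
      for (tau in ev$rel_onset_ms[hit[, c]]) {
        # epoch-grid index of the kernel's first lag for this event
        r1 <- ms_to_index(tau + cf$window$start_ms, epochs$window)
        j <- seq_len(nc)
        r <- r1 + j - 1L
        ok <- r >= 1L & r <= ne
        if (any(ok)) {
          ii[[length(ii) + 1L]] <- row0 + r[ok]
          jj[[length(jj) + 1L]] <- col_start[c] + j[ok]
        }
      }
    }
  }
  D <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                            x = 1, dims = c(e * ne, sum(ncols_per)))
  col_blocks <- lapply(seq_along(classes), function(c)
    col_start[c] + seq_len(ncols_per[c]))
  names(col_blocks) <- names(col_start)
  structure(list(D = D, classes = classes, col_blocks = col_blocks,
                 n_epochs = e, n_samples_epoch = ne,
                 epoch_rows = lapply(seq_len(e), function(i)
                   (i - 1L) * ne + seq_len(ne)),
                 window = epochs$window),
            class = "design_matrix")
}

#' Design matrix of the averaging model
#'
#' The one-class design in which every epoch has exactly one event — its
#' lock — at lag zero and the estimation window equals the epoch window:
#' stacked identity blocks, whose least-squares solution is the plain
#' time-locked average and whose Gram matrix is `E x I` with condition
#' number exactly 1.
#'
#' @param epochs an `epoch_set`.
#' @param name class/kernel name in the design (default `"lock"`).
#' @return A `design_matrix` with a single class named after `name`.
#' @export
averaging_design <- function(epochs, name = "lock") {
  ep <- epochs
  for (i in seq_along(ep$events)) {
    ev <- ep$events[[i]]
    lockdf <- data.frame(class = name, rank = NA_integer_,
                         rel_onset_ms = 0, stringsAsFactors = FALSE)
    ep$events[[i]] <- lockdf
  }
  build_design(ep, list(glm_class(name, name, epochs$window)))
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix %d x %d (%d epochs x %d samples; classes: %s)>\n",
              nrow(x$D), ncol(x$D), x$n_epochs, x$n_samples_epoch,
              paste(names(x$col_blocks), collapse = ", ")))
  invisible(x)
}

# Flatten an epoch set into the epoch-major N x channels response matrix.
flatten_epochs <- function(epochs) {
  e <- n_epochs(epochs); ne <- dim(epochs$data)[2]
  n_ch <- dim(epochs$data)[3]
  x <- matrix(0, e * ne, n_ch)
  for (i in seq_len(e)) {
    x[(i - 1L) * ne + seq_len(ne), ] <- epochs$data[i, , ]
  }
  x
}

solve_lsq <- function(D, x) {
  # normal equations with Cholesky (Gram matrices here are small relative to
  # the design and well within double precision at the condition numbers of
  # these models); eigendecomposition pseudo-inverse fallback gives the
  # minimum-norm solution when the design is rank deficient
  G <- as.matrix(Matrix::crossprod(D))
  b <- as.matrix(Matrix::crossprod(D, x))
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (!is.null(R)) {
    co <- backsolve(R, backsolve(R, b, transpose = TRUE))
    if (all(is.finite(co))) return(list(coef = co, rank_deficient = FALSE))
  }
  eg <- eigen(G, symmetric = TRUE)
  tol <- max(eg$values, 0) * .Machine$double.eps * nrow(G)
  pos <- eg$values > tol
  V <- eg$vectors[, pos, drop = FALSE]
  co <- V %*% (crossprod(V, b) / eg$values[pos])
  list(coef = co, rank_deficient = sum(pos) < ncol(G))
}

#' Solve the deconvolution least-squares problem
#'
#' Per channel, finds `a = argmin ||x - D a||^2` as the normal-equations
#' solution `(D'D)^-1 D' x` (Cholesky on the sparse-accumulated Gram
#' matrix); a rank-deficient design falls back to the minimum-norm solution
#' (eigendecomposition pseudo-inverse) with `rank_deficient = TRUE`. All
#' channels share the design and are solved jointly.
#'
#' @param design a `design_matrix`.
#' @param epochs the `epoch_set` the design was built from.
#' @return An object of class `glm_result`: `kernels` (named list of
#'   [efrp_kernel], one per class), `residual_norm` (Frobenius norm of
#'   `x - D a`), `gram_condition` (see [gram_condition_number()]),
#'   `rank_deficient`.
#' @export
solve_glm <- function(design, epochs) {
  stopifnot(inherits(design, "design_matrix"), inherits(epochs, "epoch_set"))
  x <- flatten_epochs(epochs)
  if (nrow(x) != nrow(design$D)) {
    stop("design rows (", nrow(design$D), ") do not match epoch samples (",
         nrow(x), ")")
  }
  sol <- solve_lsq(design$D, x)
  kernels <- lapply(seq_along(design$classes), function(c) {
    cf <- design$classes[[c]]
    efrp_kernel(sol$coef[design$col_blocks[[c]], , drop = FALSE],
                cf$window, label = cf$name)
  })
  names(kernels) <- names(design$col_blocks)
  resid <- x - as.matrix(design$D %*% sol$coef)
  structure(list(kernels = kernels,
                 residual_norm = sqrt(sum(resid^2)),
                 gram_condition = gram_condition_number(design),
                 rank_deficient = sol$rank_deficient),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf(
    "<glm_result kernels: %s; residual %.4g; Gram condition %.4g%s>\n",
    paste(names(x$kernels), collapse = ", "), x$residual_norm,
    x$gram_condition, if (x$rank_deficient) " (rank deficient)" else ""))
  invisible(x)
}

#' Condition number of the Gram matrix D'D
#'
#' The 2-norm condition number (ratio of extreme eigenvalues of the
#' symmetric positive semi-definite Gram matrix), the standard warning
#' indicator of estimation reliability: the averaging design (one class,
#' every event at lag zero, estimation window equal to the epoch window)
#' has condition number exactly 1; jittered multi-class designs grow into
#' the hundreds or thousands, and +Inf signals singularity.
#'
#' @param design a `design_matrix` (or a plain matrix/Matrix).
#' @return Positive real, possibly `Inf`.
#' @export
gram_condition_number <- function(design) {
  D <- if (inherits(design, "design_matrix")) design$D else design
  G <- as.matrix(Matrix::crossprod(D))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev); lmin <- min(ev)
  if (lmin <= lmax * .Machine$double.eps * nrow(G)) return(Inf)
  lmax / lmin
}

#' Bootstrap variance of GLM kernel estimates
#'
#' Resamples epochs (the trial-level unit) with replacement, re-solves the
#' deconvolution per replication, and reports the per-sample variance of
#' each class kernel across replications (averaged over channels), plus the
#' mean variance over a summary window. Replications in which a class
#' receives no event are redrawn (capped retry count). Optionally the Gram
#' condition number is recomputed per replication to characterize its
#' sampling distribution.
#'
#' @param epochs an `epoch_set`.
#' @param classes list of [glm_class] configurations.
#' @param replications number of bootstrap replications (default 10000).
#' @param seed optional integer seed.
#' @param summary_window [time_window] over which per-sample variances are
#'   averaged for the summary (default: each class's own window).
#' @param include_condition recompute the condition number per replication.
#' @param max_retries redraw cap per replication for empty classes.
#' @return An object of class `bootstrap_report`: `replications`,
#'   `variance` (named list of per-sample variance vectors),
#'   `summary_mean_variance` (named numeric), `condition` (vector or NULL),
#'   `n_redrawn`, `seed`.
#' @export
bootstrap_variance <- function(epochs, classes, replications = 10000,
                               seed = NULL, summary_window = NULL,
                               include_condition = FALSE,
                               max_retries = 100L) {
  stopifnot(replications >= 2)
  if (!is.null(seed)) set.seed(seed)
  design <- build_design(epochs, classes)
  x <- flatten_epochs(epochs)
  e <- design$n_epochs; ne <- design$n_samples_epoch
  n_ch <- ncol(x)
  # columns that any event can touch, per class, to detect empty classes
  est <- vector("list", length(design$col_blocks))
  names(est) <- names(design$col_blocks)
  for (nm in names(est)) {
    est[[nm]] <- array(0, dim = c(replications,
                                  length(design$col_blocks[[nm]]), n_ch))
  }
  cond <- if (include_condition) numeric(replications) else NULL
  n_redrawn <- 0L
  class_cols <- design$col_blocks
  for (r in seq_len(replications)) {
    for (attempt in seq_len(max_retries)) {
      idx <- sample.int(e, e, replace = TRUE)
      rows <- unlist(lapply(idx, function(i) (i - 1L) * ne + seq_len(ne)))
      Db <- design$D[rows, , drop = FALSE]
      nz <- Matrix::colSums(Db) > 0
      empty <- vapply(class_cols, function(cb) !any(nz[cb]), TRUE)
      if (!any(empty)) break
      n_redrawn <- n_redrawn + 1L
      if (attempt == max_retries) {
        stop("bootstrap_variance: a class stayed empty after ",
             max_retries, " redraws")
      }
    }
    xb <- x[rows, , drop = FALSE]
    sol <- solve_lsq(Db, xb)
    for (c in seq_along(class_cols)) {
      est[[c]][r, , ] <- sol$coef[class_cols[[c]], ]
    }
    if (include_condition) cond[r] <- gram_condition_number(Db)
  }
  variance <- lapply(seq_along(class_cols), function(c) {
    v <- apply(est[[c]], c(2L, 3L), stats::var)
    rowMeans(matrix(v, ncol = n_ch))
  })
  names(variance) <- names(class_cols)
  summary_mean <- vapply(seq_along(class_cols), function(c) {
    cf <- design$classes[[c]]
    v <- variance[[c]]
    if (is.null(summary_window)) return(mean(v))
    if (!window_contains(cf$window, summary_window)) return(mean(v))
    idx <- ms_to_index(summary_window$start_ms, cf$window) +
      seq_len(n_samples(summary_window)) - 1L
    mean(v[idx])
  }, 0)
  names(summary_mean) <- names(class_cols)
  structure(list(replications = replications, variance = variance,
                 summary_mean_variance = summary_mean,
                 condition = cond, n_redrawn = n_redrawn, seed = seed),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("<bootstrap_report %d replications; mean variance: %s>\n",
              x$replications,
              paste(sprintf("%s=%.4g", names(x$summary_mean_variance),
                            x$summary_mean_variance), collapse = ", ")))
  invisible(x)
}
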