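# Correlated components analysis.
#
# CorrCA finds electrode weightings w maximizing the ratio of between-subject
# to within-subject covariance of the projected data, w'Rb w / w'Rw w. The
# maximizers are the eigenvectors of Rw^-1 Rb; they are computed here through
# the symmetric equivalent on the Rw^(-1/2) transform for numerical
# stability. ISC of a projected component is the mean pairwise Pearson
# correlation between subjects' component time courses.

#' Between- and within-subject covariance of an aligned cohort
#'
#' With `R_kl` the channels x channels cross-covariance between subjects k
#' and l, the within-subject covariance is `Rw = (1/N) sum_k R_kk` and the
#' between-subject covariance is `Rb = (1/(N(N-1))) sum_{k != l} R_kl`.
#'
#' @param eeg a [multisubject_eeg()] with at least 2 subjects.
#' @return A `covariance_pair`: list with `Rb`, `Rw`, `n_subjects`,
#'   `n_samples`.
#' @export
compute_covariances <- function(eeg) {
  assert_eeg(eeg)
  n <- n_subjects(eeg); d <- n_channels(eeg); tt <- n_samples(eeg)
  if (n < 2) stop("need at least 2 subjects to compute Rb")
  if (tt < 2) stop("zero-length data")
  rw <- matrix(0, d, d)
  ssum <- matrix(0, d, tt)
  rkk_sum <- matrix(0, d, d)
  for (i in seq_len(n)) {
    xi <- subject_matrix(eeg, i)
    xi <- xi - rowMeans(xi)
    rkk <- tcrossprod(xi) / (tt - 1)
    rkk_sum <- rkk_sum + rkk
    ssum <- ssum + xi
  }
  rw <- rkk_sum / n
  rall <- tcrossprod(ssum) / (tt - 1)   # sum over all k,l of R_kl
  rb <- (rall - rkk_sum) / (n * (n - 1))
  structure(list(Rb = (rb + t(rb)) / 2, Rw = (rw + t(rw)) / 2,
                 n_subjects = n, n_samples = tt),
            class = "covariance_pair")
}

#' Pool covariance pairs over stimuli
#'
#' Element-wise mean of `Rb` and `Rw` over videos (equal weight per video),
#' so all stimuli share one set of projection vectors and per-video ISC
#' values can be meaningfully averaged.
#'
#' @param pairs list of `covariance_pair` objects of equal dimension.
#' @return A pooled `covariance_pair`.
#' @export
pool_covariances <- function(pairs) {
  if (length(pairs) == 0) stop("empty list of covariance pairs")
  d <- nrow(pairs[[1]]$Rb)
  for (p in pairs)
    if (!all(dim(p$Rb) == d) || !all(dim(p$Rw) == d))
      stop("covariance dimension mismatch across videos")
  rb <- Reduce(`+`, lapply(pairs, `[[`, "Rb")) / length(pairs)
  rw <- Reduce(`+`, lapply(pairs, `[[`, "Rw")) / length(pairs)
  structure(list(Rb = rb, Rw = rw,
                 n_subjects = pairs[[1]]$n_subjects,
                 n_samples = sum(vapply(pairs, `[[`, numeric(1), "n_samples"))),
            class = "covariance_pair")
}

pinv <- function(m, tol = 1e-12) {
  s <- svd(m)
  keep <- s$d > max(s$d) * tol
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Fit correlated components from pooled covariances
#'
#' Solves the generalized eigenproblem for `Rw^-1 Rb` after shrinkage
#' regularization `Rw_reg = (1 - s) Rw + s mean(diag(Rw)) I` (zero-filled bad
#' channels can make `Rw` singular). Eigenvalues are returned in descending
#' order; the forward-model scalp projections are `A = Rw W (W' Rw W)^-1`,
#' and each component's sign is fixed so its largest-magnitude forward-model
#' entry is positive.
#'
#' @param pooled a `covariance_pair` (typically from [pool_covariances()]).
#' @param k number of components to keep.
#' @param shrinkage regularization weight in `[0, 1]`.
#' @return A `corrca_model`: list with `W` (D x k), `eigenvalues`, `A`
#'   (D x k), `shrinkage`.
#' @export
fit_corrca <- function(pooled, k = 3, shrinkage = 0.1) {
  rb <- pooled$Rb; rw <- pooled$Rw
  d <- nrow(rw)
  if (k > d) stop("k cannot exceed the number of channels")
  if (shrinkage < 0 || shrinkage > 1) stop("shrinkage must be in [0, 1]")
  rw_reg <- (1 - shrinkage) * rw +
    shrinkage * mean(diag(rw)) * diag(d)
  ew <- eigen(rw_reg, symmetric = TRUE)
  if (min(ew$values) <= max(ew$values) * 1e-12)
    stop("Rw is singular; increase the shrinkage regularization")
  isqrt <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  m <- isqrt %*% rb %*% isqrt
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  w <- isqrt %*% em$vectors[, seq_len(k), drop = FALSE]
  lambda <- em$values[seq_len(k)]
  a <- rw %*% w %*% pinv(t(w) %*% rw %*% w)
  for (j in seq_len(k)) {
    mx <- which.max(abs(a[, j]))
    if (length(mx) && a[mx, j] < 0) {
      a[, j] <- -a[, j]
      w[, j] <- -w[, j]
    }
  }
  structure(list(W = w, eigenvalues = lambda, A = a, shrinkage = shrinkage),
            class = "corrca_model")
}

#' @export
print.corrca_model <- function(x, ...) {
  cat(sprintf("<corrca_model> %d channels -> %d components, shrinkage %g\n",
              nrow(x$W), ncol(x$W), x$shrinkage))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Project a cohort onto correlated components
#'
#' `y[i, k, t] = sum_d W[d, k] x[i, d, t]`. The attribute `zero_mask`
#' (subjects x samples) marks samples that are zero-filled across all
#' channels for a subject, so windowed ISC can discount them.
#'
#' @param eeg a [multisubject_eeg()].
#' @param model a `corrca_model` whose `W` matches the channel dimension.
#' @return N x K x T array of component time courses.
#' @export
project_components <- function(eeg, model) {
  assert_eeg(eeg)
  w <- model$W
  if (nrow(w) != n_channels(eeg))
    stop("model channel dimension does not match the data")
  n <- n_subjects(eeg); k <- ncol(w); tt <- n_samples(eeg)
  out <- array(0, dim = c(n, k, tt))
  zm <- matrix(FALSE, n, tt)
  for (i in seq_len(n)) {
    xi <- subject_matrix(eeg, i)
    out[i, , ] <- crossprod(w, xi)
    zm[i, ] <- colSums(xi != 0) == 0
  }
  attr(out, "zero_mask") <- zm
  attr(out, "subject_ids") <- eeg$subject_ids
  attr(out, "group") <- eeg$group
  attr(out, "fs") <- eeg$fs
  attr(out, "video_id") <- eeg$video_id
  out
}

# mean pairwise Pearson correlation of a target row against reference rows
# (target excluded from its own reference set); NA rows (zero variance) are
# skipped pairwise.
row_cor_means <- function(x, targets, reference) {
  cm <- suppressWarnings(stats::cor(t(x)))
  vapply(targets, function(tg) {
    refs <- setdiff(reference, tg)
    if (length(refs) == 0) return(NA_real_)
    mean(cm[tg, refs], na.rm = TRUE)
  }, numeric(1))
}

#' Leave-one-out ISC of each subject against a reference cohort
#'
#' For every target subject and component, computes the mean Pearson
#' correlation between the target's component time course and that of each
#' reference-group member (the target itself excluded when it belongs to the
#' reference), per video; per-component values are then averaged across
#' videos and the strongest `k_report` components are summed into the
#' subject's reported ISC.
#'
#' @param projections one N x K x T array from [project_components()], or a
#'   list of them (one per video).
#' @param reference integer indices of the reference subjects (the healthy
#'   cohort).
#' @param targets integer indices of subjects to score (default: all).
#' @param k_report number of strongest components summed in the reported ISC.
#' @return A data.frame with one row per subject, video and component
#'   (columns `subject`, `group`, `video`, `component`, `isc`, `topk_sum`),
#'   with attribute `summary`: one row per subject with across-video mean
#'   per-component ISC (`comp1..compK`) and their `k_report` sum `isc_topk`.
#' @export
loo_isc_table <- function(projections, reference, targets = NULL,
                          k_report = 3) {
  if (!is.list(projections)) projections <- list(projections)
  n <- dim(projections[[1]])[1]; k <- dim(projections[[1]])[2]
  if (k_report > k) stop("k_report cannot exceed the number of components")
  if (is.null(targets)) targets <- seq_len(n)
  if (length(setdiff(reference, seq_len(n))))
    stop("reference indices out of range")
  ids <- attr(projections[[1]], "subject_ids") %||% as.character(seq_len(n))
  grp <- attr(projections[[1]], "group") %||% rep("healthy", n)
  rows <- list()
  acc <- array(0, dim = c(length(targets), k, length(projections)))
  for (v in seq_along(projections)) {
    pv <- projections[[v]]
    vid <- attr(pv, "video_id") %||% v
    per_comp <- sapply(seq_len(k), function(kk) {
      x <- pv[, kk, , drop = FALSE]
      dim(x) <- dim(pv)[c(1, 3)]
      row_cor_means(x, targets, reference)
    })
    per_comp <- matrix(per_comp, nrow = length(targets))
    acc[, , v] <- per_comp
    tk <- rowSums(per_comp[, seq_len(k_report), drop = FALSE])
    rows[[v]] <- data.frame(
      subject = rep(ids[targets], k),
      group = rep(grp[targets], k),
      video = vid,
      component = rep(seq_len(k), each = length(targets)),
      isc = as.vector(per_comp),
      topk_sum = rep(tk, k))
  }
  out <- do.call(rbind, rows)
  avg <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  avg <- matrix(avg, nrow = length(targets))
  summary_df <- data.frame(subject = ids[targets], group = grp[targets])
  for (kk in seq_len(k)) summary_df[[paste0("comp", kk)]] <- avg[, kk]
  summary_df$isc_topk <- rowSums(avg[, seq_len(k_report), drop = FALSE])
  attr(out, "summary") <- summary_df
  attr(out, "k_report") <- k_report
  out
}

#' Across-video subject summary of a leave-one-out ISC table
#' @param isc result of [loo_isc_table()].
#' @return The per-subject summary data.frame (see [loo_isc_table()]).
#' @export
isc_summary <- function(isc) attr(isc, "summary")

#' Within-group ISC with group-only component fitting
#'
#' Refits the correlated components using only the given group's data (pooled
#' over videos) and computes each member's leave-one-out ISC against the
#' remaining members — the check that a group with low synchrony to a
#' reference cohort may still be synchronized internally.
#'
#' @param eeg_list list of [multisubject_eeg()] per video.
#' @param group_label which group to analyze (`"patient"` or `"healthy"`).
#' @param k_report components summed in the reported ISC.
#' @param shrinkage regularization for the refit.
#' @return As [loo_isc_table()], for the group members only.
#' @export
within_group_isc <- function(eeg_list, group_label = "patient",
                             k_report = 3, shrinkage = 0.1) {
  if (!is.list(eeg_list)) eeg_list <- list(eeg_list)
  idx <- which(eeg_list[[1]]$group == group_label)
  if (length(idx) < 3)
    stop("within-group ISC needs at least 3 subjects in the group")
  sub <- lapply(eeg_list, function(e) {
    multisubject_eeg(e$data[idx, , , drop = FALSE], e$fs, e$channel_labels,
                     e$subject_ids[idx], e$group[idx], e$video_id)
  })
  pooled <- pool_covariances(lapply(sub, compute_covariances))
  model <- fit_corrca(pooled, k = max(k_report, 3), shrinkage = shrinkage)
  proj <- lapply(sub, project_components, model = model)
  res <- loo_isc_table(proj, reference = seq_along(idx), k_report = k_report)
  attr(res, "model") <- model
  res
}

#' Sliding-window grid
#'
#' Windows of `window_length` seconds advanced by `step` seconds
#' (`step = window_length - overlap`); the number of windows is
#' `floor((T_sec - window_length) / step) + 1`.
#'
#' @param n_samples total samples.
#' @param fs sampling rate, Hz.
#' @param window_length window length, seconds.
#' @param step hop between window starts, seconds.
#' @return data.frame with `window`, `start_sample`, `end_sample`,
#'   `start_s`, `end_s`.
#' @export
window_grid <- function(n_samples, fs, window_length = 1.5, step = 0.3) {
  if (step <= 0) stop("step must be positive (overlap < window length)")
  win <- round(window_length * fs)
  stp <- round(step * fs)
  if (win > n_samples) stop("window longer than the recording")
  if (stp < 1) stop("step shorter than one sample")
  starts <- seq.int(1L, n_samples - win + 1L, by = stp)
  data.frame(window = seq_along(starts),
             start_sample = starts, end_sample = starts + win - 1L,
             start_s = (starts - 1L) / fs,
             end_s = (starts - 1L + win) / fs)
}

#' Time-resolved ISC over sliding windows
#'
#' Leave-one-out per-component ISC computed on each window's samples with the
#' projection vectors fitted on the whole recording (no per-window refit).
#' Windows in which more than `zero_frac_max` of a subject's samples are
#' zero-filled are set missing for that subject.
#'
#' @param projections one N x K x T array from [project_components()].
#' @param reference reference subject indices.
#' @param targets target subject indices (default all).
#' @param window_length,step window parameters in seconds.
#' @param k_report components summed into `topk_sum`.
#' @param zero_frac_max maximal tolerated fraction of zero-filled samples.
#' @return data.frame with one row per target, window and component
#'   (`subject`, `window`, `start_s`, `end_s`, `component`, `isc`,
#'   `topk_sum`), attribute `grid` carrying the window grid.
#' @export
time_resolved_isc <- function(projections, reference, targets = NULL,
                              window_length = 1.5, step = 0.3,
                              k_report = 3, zero_frac_max = 0.5) {
  fs <- attr(projections, "fs")
  if (is.null(fs)) stop("projections must carry an `fs` attribute")
  n <- dim(projections)[1]; k <- dim(projections)[2]
  tt <- dim(projections)[3]
  if (is.null(targets)) targets <- seq_len(n)
  grid <- window_grid(tt, fs, window_length, step)
  zm <- attr(projections, "zero_mask")
  ids <- attr(projections, "subject_ids") %||% as.character(seq_len(n))
  nw <- nrow(grid)
  vals <- array(NA_real_, dim = c(length(targets), k, nw))
  for (wi in seq_len(nw)) {
    idx <- grid$start_sample[wi]:grid$end_sample[wi]
    bad_subj <- if (is.null(zm)) rep(FALSE, n) else
      rowMeans(zm[, idx, drop = FALSE]) > zero_frac_max
    for (kk in seq_len(k)) {
      x <- projections[, kk, idx, drop = FALSE]
      dim(x) <- c(n, length(idx))
      x[bad_subj, ] <- NA_real_
      cm <- suppressWarnings(stats::cor(t(x)))
      vals[, kk, wi] <- vapply(targets, function(tg) {
        refs <- setdiff(reference, tg)
        if (bad_subj[tg] || length(refs) == 0) return(NA_real_)
        mean(cm[tg, refs], na.rm = TRUE)
      }, numeric(1))
    }
  }
  rows <- do.call(rbind, lapply(seq_len(nw), function(wi) {
    pc <- matrix(vals[, , wi], nrow = length(targets))
    data.frame(subject = ids[targets],
               window = wi, start_s = grid$start_s[wi],
               end_s = grid$end_s[wi],
               component = rep(seq_len(k), each = length(targets)),
               isc = as.vector(pc),
               topk_sum = rep(rowSums(pc[, seq_len(k_report), drop = FALSE]),
                              k))
  }))
  attr(rows, "grid") <- grid
  attr(rows, "window_length") <- window_length
  attr(rows, "step") <- step
  rows
}
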