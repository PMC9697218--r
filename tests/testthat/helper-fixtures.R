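# Shared fixtures: small cohorts and independent arithmetic oracles.

# quick cohort wrapper with small defaults for unit tests
tiny_cohort <- function(n_healthy = 4, n_patient = 3, duration = 4,
                        n_videos = 1, seed = 1L, ...) {
  generate_cohort(cohort_spec(n_healthy = n_healthy, n_patient = n_patient,
                              duration = duration, n_videos = n_videos,
                              seed = seed, ...))
}

# brute-force double-loop Rb/Rw oracle (sample covariance, denominator T-1)
cov_pair_oracle <- function(arr) {
  n <- dim(arr)[1]; d <- dim(arr)[2]; tt <- dim(arr)[3]
  xc <- lapply(seq_len(n), function(i) {
    m <- arr[i, , , drop = FALSE]; dim(m) <- c(d, tt)
    m - rowMeans(m)
  })
  rkl <- function(k, l) tcrossprod(xc[[k]], xc[[l]]) / (tt - 1)
  rw <- matrix(0, d, d); rb <- matrix(0, d, d)
  for (k in seq_len(n)) rw <- rw + rkl(k, k)
  for (k in seq_len(n)) for (l in seq_len(n))
    if (k != l) rb <- rb + rkl(k, l)
  list(Rw = rw / n, Rb = rb / (n * (n - 1)))
}

# random symmetric positive-definite matrix
random_spd <- function(d) {
  a <- matrix(stats::rnorm(d * d), d)
  crossprod(a) + 0.5 * diag(d)
}

# projections array with metadata attributes, for spectral/window tests
proj_array <- function(mat_list, fs, ids = NULL, group = NULL) {
  n <- length(mat_list); k <- nrow(mat_list[[1]]); tt <- ncol(mat_list[[1]])
  out <- array(0, dim = c(n, k, tt))
  for (i in seq_len(n)) out[i, , ] <- mat_list[[i]]
  attr(out, "fs") <- fs
  attr(out, "subject_ids") <- ids %||% as.character(seq_len(n))
  attr(out, "group") <- group %||% rep("healthy", n)
  attr(out, "zero_mask") <- matrix(FALSE, n, tt)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
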