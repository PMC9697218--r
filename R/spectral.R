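#' Averaged-periodogram (Welch) power spectral density
#'
#' Hann-tapered segments with 50% overlap by default. One-sided density;
#' the integral of `psd * df` over frequency approximates the signal's
#' variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param seg_seconds segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return data.frame with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_seconds = 2, overlap = 0.5) {
  nseg <- min(length(x), round(seg_seconds * fs))
  if (nseg < 8) stop("segment too short for a spectral estimate")
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq.int(1L, length(x) - nseg + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  u <- sum(win^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * win
    p <- abs(stats::fft(seg))^2 / (fs * u)
    p <- p[seq_len(nf)]
    if (nseg %% 2 == 0) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  data.frame(freq = (seq_len(nf) - 1) * fs / nseg, psd = acc / length(starts))
}

band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$psd[sel])
}

#' Relative alpha-band power of component time courses
#'
#' For each subject, video and component, the data are projected onto the
#' strongest correlated components and the alpha-band (8-12 Hz) power is
#' divided by the broadband power; per subject, the relative power is
#' averaged across videos and summed over the `k_report` strongest
#' components, yielding one attention-related covariate per participant.
#' The broadband interval defaults to the full one-sided spectrum
#' `[0, fs/2]`.
#'
#' @param projections one N x K x T array from [project_components()] or a
#'   list of them (one per video).
#' @param band alpha band, Hz.
#' @param broadband reference band, Hz; `NULL` means `[0, fs/2]`.
#' @param k_report components summed per subject.
#' @param seg_seconds Welch segment length in seconds.
#' @return data.frame with one row per subject: `subject`, `group`, `alpha`
#'   (summed relative alpha power, in `[0, k_report]`); attribute `detail`
#'   has the per-subject, per-video, per-component values.
#' @export
component_alpha <- function(projections, band = c(8, 12), broadband = NULL,
                            k_report = 3, seg_seconds = 2) {
  if (!is.list(projections)) projections <- list(projections)
  fs <- attr(projections[[1]], "fs")
  if (is.null(fs)) stop("projections must carry an `fs` attribute")
  if (is.null(broadband)) broadband <- c(0, fs / 2)
  if (band[1] < broadband[1] || band[2] > broadband[2])
    stop("alpha band must lie within the broadband interval")
  n <- dim(projections[[1]])[1]
  k <- dim(projections[[1]])[2]
  if (k < k_report) stop("need projections for at least k_report components")
  ids <- attr(projections[[1]], "subject_ids") %||% as.character(seq_len(n))
  grp <- attr(projections[[1]], "group") %||% rep("healthy", n)
  detail <- list()
  rel <- array(NA_real_, dim = c(n, k_report, length(projections)))
  for (v in seq_along(projections)) {
    pv <- projections[[v]]
    for (i in seq_len(n)) {
      for (kk in seq_len(k_report)) {
        psd <- welch_psd(pv[i, kk, ], fs, seg_seconds)
        broad <- band_power(psd, broadband)
        if (broad <= 0) {
          message("zero broadband power: subject ", ids[i], ", component ",
                  kk, ", video ", v)
          next
        }
        rel[i, kk, v] <- band_power(psd, band) / broad
      }
    }
    detail[[v]] <- data.frame(subject = rep(ids, k_report),
                              video = v,
                              component = rep(seq_len(k_report), each = n),
                              rel_alpha = as.vector(rel[, , v]))
  }
  per_subject <- apply(rel, c(1, 2), mean, na.rm = TRUE)
  out <- data.frame(subject = ids, group = grp,
                    alpha = rowSums(per_subject))
  attr(out, "detail") <- do.call(rbind, detail)
  out
}
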