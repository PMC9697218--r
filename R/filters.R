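# Zero-phase frequency-domain filtering.
#
# No filter-design package is assumed: the band-pass is realized directly in
# the frequency domain with raised-cosine transition bands, which is exactly
# zero-phase (a requirement here, since ISC depends on temporal alignment
# across subjects). Transition bands: the high-pass ramps from zero at
# hp_cutoff/2 up to unity at hp_cutoff; the low-pass ramps from unity at
# lp_cutoff down to zero at 1.3 * lp_cutoff (clipped at Nyquist). One octave
# into either stopband the gain is identically zero, comfortably beyond the
# 20 dB attenuation the pipeline requires.

fft_gain <- function(freqs, hp_cutoff = NULL, lp_cutoff = NULL, nyquist) {
  g <- rep(1, length(freqs))
  if (!is.null(hp_cutoff) && hp_cutoff > 0) {
    f0 <- hp_cutoff / 2
    ramp <- (freqs - f0) / (hp_cutoff - f0)
    hg <- ifelse(freqs <= f0, 0,
                 ifelse(freqs >= hp_cutoff, 1,
                        0.5 * (1 - cos(pi * ramp))))
    g <- g * hg
  }
  if (!is.null(lp_cutoff)) {
    f1 <- min(1.3 * lp_cutoff, nyquist)
    ramp <- (freqs - lp_cutoff) / (f1 - lp_cutoff)
    lg <- ifelse(freqs <= lp_cutoff, 1,
                 ifelse(freqs >= f1, 0,
                        0.5 * (1 + cos(pi * ramp))))
    g <- g * lg
  }
  g
}

# Filter the rows of a channels x samples matrix (or a single vector).
fft_bandpass <- function(x, fs, hp_cutoff = NULL, lp_cutoff = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  tt <- ncol(x)
  nyq <- fs / 2
  if (!is.null(lp_cutoff) && lp_cutoff >= nyq)
    stop("low-pass cutoff must be below the Nyquist frequency")
  if (!is.null(hp_cutoff) && !is.null(lp_cutoff) && hp_cutoff >= lp_cutoff)
    stop("high-pass cutoff must be below low-pass cutoff")
  freqs <- (seq_len(tt) - 1) / tt * fs
  folded <- pmin(freqs, fs - freqs)   # two-sided spectrum, symmetric gain
  g <- fft_gain(folded, hp_cutoff, lp_cutoff, nyq)
  sp <- stats::mvfft(t(x))
  out <- t(Re(stats::mvfft(sp * g, inverse = TRUE))) / tt
  if (vec) out <- drop(out)
  out
}

# Band-limited unit-variance Gaussian noise, rows = independent series.
bandlimited_noise <- function(n_series, n_samples, fs, band = c(1, 45)) {
  x <- matrix(stats::rnorm(n_series * n_samples), nrow = n_series)
  y <- fft_bandpass(x, fs, hp_cutoff = band[1], lp_cutoff = band[2])
  sdv <- apply(y, 1, stats::sd)
  sdv[sdv == 0] <- 1
  y / sdv
}

# Evaluate code with a temporary RNG state so generators are reproducible
# without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
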