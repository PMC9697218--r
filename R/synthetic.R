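#' Specification of a synthetic EEG cohort
#'
#' Describes a two-group cohort (healthy controls and patients) whose EEG is
#' driven by a small number of latent source signals shared by every subject
#' and mixed into the channels through fixed scalp topographies. The groups
#' differ in the gain with which each subject expresses the shared sources
#' (healthy > patient), which is the mechanism by which patients end up less
#' correlated with the healthy cohort. Patients can additionally share a
#' source of their own (`patient_shared_gain`), giving them residual mutual
#' synchrony without synchrony to controls.
#'
#' Defaults state the emulated study design: two groups of 23, 19 channels at
#' 500 Hz, 4 video blocks. `duration` defaults to 60 s per video (30000
#' samples, the scale at which parameter-recovery properties of the pipeline
#' are stated); full-length 360 s blocks are configurable.
#'
#' @param n_healthy,n_patient subjects per group.
#' @param n_channels EEG channels (19 = shared 10-20 montage).
#' @param fs sampling rate, Hz.
#' @param duration seconds per video block.
#' @param n_videos number of stimulus blocks.
#' @param n_sources number of latent sources shared by all subjects.
#' @param mixing optional D x K channel-topography matrix; random orthonormal
#'   columns (drawn from `seed`) when `NULL`.
#' @param gain_healthy,gain_patient per-subject amplitude of the shared
#'   response in each group; the group contrast requires
#'   `gain_healthy > gain_patient`.
#' @param patient_shared_gain amplitude of an additional source shared only
#'   among patients (their residual within-group synchrony); 0 disables it.
#' @param noise_sd SD of additive channel noise.
#' @param alpha_fraction proportion of noise power placed in the 8-12 Hz
#'   alpha band (the rest is broadband 1-45 Hz).
#' @param artifact_spec list with counts per subject used by
#'   [inject_artifacts()]: `n_ocular`, `n_bad_channels`, `n_spikes`.
#' @param seed RNG seed; a fixed seed makes the cohort bit-identical.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_healthy = 23, n_patient = 23,
                        n_channels = 19, fs = 500, duration = 60,
                        n_videos = 4, n_sources = 3, mixing = NULL,
                        gain_healthy = 1, gain_patient = 0.5,
                        patient_shared_gain = 0.3,
                        noise_sd = 1, alpha_fraction = 0.2,
                        artifact_spec = list(n_ocular = 0,
                                             n_bad_channels = 0,
                                             n_spikes = 0),
                        seed = 1L) {
  if (n_sources < 1 || n_channels < n_sources)
    stop("need n_channels >= n_sources >= 1")
  if (fs <= 0) stop("fs must be positive")
  if (duration <= 0 || n_videos < 1) stop("invalid duration or n_videos")
  if (gain_healthy < 0 || gain_patient < 0 || patient_shared_gain < 0)
    stop("gains must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (alpha_fraction < 0 || alpha_fraction > 1)
    stop("alpha_fraction must be in [0, 1]")
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_channels || ncol(mixing) != n_sources)
      stop("mixing must be n_channels x n_sources")
  }
  structure(list(
    n_healthy = n_healthy, n_patient = n_patient,
    n_channels = n_channels, fs = fs, duration = duration,
    n_videos = n_videos, n_sources = n_sources, mixing = mixing,
    gain_healthy = gain_healthy, gain_patient = gain_patient,
    patient_shared_gain = patient_shared_gain,
    noise_sd = noise_sd, alpha_fraction = alpha_fraction,
    artifact_spec = artifact_spec, seed = as.integer(seed)),
    class = "cohort_spec")
}

default_channel_labels <- function(d) {
  if (d == 19) montage_1020_19() else sprintf("Ch%02d", seq_len(d))
}

random_orthonormal <- function(d, k) {
  qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))[, seq_len(k), drop = FALSE]
}

# channel noise: broadband 1-45 Hz with a configurable fraction of its power
# concentrated in the 8-12 Hz alpha band
channel_noise <- function(d, tt, fs, noise_sd, alpha_fraction) {
  if (noise_sd == 0) return(matrix(0, d, tt))
  broad <- bandlimited_noise(d, tt, fs, band = c(1, 45))
  if (alpha_fraction == 0) return(noise_sd * broad)
  alpha <- bandlimited_noise(d, tt, fs, band = c(8, 12))
  noise_sd * (sqrt(1 - alpha_fraction) * broad + sqrt(alpha_fraction) * alpha)
}

#' Generate a synthetic multi-subject EEG cohort
#'
#' Every subject's channel data is
#' `gain_i * mixing %*% sources + noise`, with the same source time courses
#' for all subjects of both groups (plus, for patients, a patient-only shared
#' source). The returned ground truth carries the sources, topographies and
#' per-subject gains so that downstream estimates (forward models, ISC levels)
#' can be checked against the generating model.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `eeg` (one [multisubject_eeg()] per video) and `truth`
#'   (source time courses per video, true mixing, patient-source mixing,
#'   subject gains, group labels).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  d <- spec$n_channels; k <- spec$n_sources
  tt <- round(spec$duration * spec$fs)
  n <- spec$n_healthy + spec$n_patient
  if (n < 2) stop("need at least 2 subjects")
  ids <- c(sprintf("H%d", seq_len(spec$n_healthy)),
           sprintf("P%d", seq_len(spec$n_patient)))
  grp <- c(rep("healthy", spec$n_healthy), rep("patient", spec$n_patient))
  gains <- ifelse(grp == "healthy", spec$gain_healthy, spec$gain_patient)
  labels <- default_channel_labels(d)

  with_seed(spec$seed, {
    mixing <- if (is.null(spec$mixing)) random_orthonormal(d, k) else spec$mixing
    pat_mix <- random_orthonormal(d, 1)
    sources <- lapply(seq_len(spec$n_videos), function(v)
      bandlimited_noise(k, tt, spec$fs))
    pat_sources <- lapply(seq_len(spec$n_videos), function(v)
      bandlimited_noise(1, tt, spec$fs))
    eeg <- vector("list", spec$n_videos)
    for (v in seq_len(spec$n_videos)) {
      arr <- array(0, dim = c(n, d, tt))
      shared <- mixing %*% sources[[v]]
      pat_shared <- pat_mix %*% pat_sources[[v]]
      for (i in seq_len(n)) {
        xi <- gains[i] * shared
        if (grp[i] == "patient" && spec$patient_shared_gain > 0)
          xi <- xi + spec$patient_shared_gain * pat_shared
        xi <- xi + channel_noise(d, tt, spec$fs, spec$noise_sd,
                                 spec$alpha_fraction)
        arr[i, , ] <- xi
      }
      eeg[[v]] <- multisubject_eeg(arr, spec$fs, labels, ids, grp, video_id = v)
    }
    truth <- list(source_timecourses = sources, true_mixing = mixing,
                  patient_mixing = pat_mix, patient_sources = pat_sources,
                  subject_gains = gains, group = grp, subject_ids = ids)
    list(eeg = eeg, truth = truth)
  })
}

#' Inject stereotyped artifacts into a cohort video
#'
#' Adds the three artifact families the preprocessing chain is designed to
#' remove: ocular-like low-frequency frontal transients (asymmetric across
#' Fp1/Fp2, as real blinks and saccades are), whole-segment high-power
#' channels, and isolated large spikes. All insertion positions are recorded
#' in the returned `artifact_log` attribute so recovery can be verified.
#'
#' @param eeg a [multisubject_eeg()].
#' @param spec the [cohort_spec()] whose `artifact_spec` gives per-subject
#'   counts `n_ocular`, `n_bad_channels`, `n_spikes`.
#' @param seed RNG seed for artifact placement (default derived from the spec).
#' @return The modified `multisubject_eeg` with attribute `artifact_log`.
#' @export
inject_artifacts <- function(eeg, spec, seed = spec$seed + 7919L) {
  assert_eeg(eeg)
  as <- spec$artifact_spec
  n_oc <- as$n_ocular %||% 0; n_bad <- as$n_bad_channels %||% 0
  n_sp <- as$n_spikes %||% 0
  if (n_oc == 0 && n_bad == 0 && n_sp == 0) {
    attr(eeg, "artifact_log") <- list(ocular = NULL, bad = NULL, spikes = NULL)
    return(eeg)
  }
  n <- n_subjects(eeg); d <- n_channels(eeg); tt <- n_samples(eeg)
  blink_len <- round(0.4 * eeg$fs)
  if (n_oc * 2 * blink_len > tt)
    stop("ocular artifact rate implies overlap beyond the data length")
  fw <- frontal_weights(eeg$channel_labels)
  blink <- blink_waveform(blink_len)
  log_oc <- list(); log_bad <- list(); log_sp <- list()
  with_seed(seed, {
    for (i in seq_len(n)) {
      xi <- subject_matrix(eeg, i)
      ch_sd <- apply(xi, 1, stats::sd)
      if (n_oc > 0) {
        starts <- sort(sample.int(tt - blink_len, n_oc))
        amp <- 10 * max(stats::median(ch_sd), .Machine$double.eps)
        for (s in starts) {
          idx <- s:(s + blink_len - 1)
          xi[, idx] <- xi[, idx] + amp * (fw %o% blink)
        }
        log_oc[[length(log_oc) + 1L]] <-
          data.frame(subject = eeg$subject_ids[i], start = starts,
                     length = blink_len)
      }
      if (n_sp > 0) {
        chs <- sample.int(d, n_sp, replace = TRUE)
        pos <- sample.int(tt, n_sp)
        for (j in seq_len(n_sp)) {
          sd_j <- max(ch_sd[chs[j]], .Machine$double.eps)
          xi[chs[j], pos[j]] <- xi[chs[j], pos[j]] + 50 * sd_j
        }
        log_sp[[length(log_sp) + 1L]] <-
          data.frame(subject = eeg$subject_ids[i], channel = chs, sample = pos)
      }
      if (n_bad > 0) {
        # a broken electrode has far more power than the rest; note that the
        # across-channel 4-SD rule self-inflates its SD, so only channels
        # near the maximal attainable z-score (D-1)/sqrt(D) get flagged --
        # 30x the mean channel power is comfortably in that regime
        pw <- rowMeans(xi^2)
        chs <- sample.int(d, n_bad)
        for (ch in chs) {
          target <- 30 * mean(pw)
          if (pw[ch] <= 0) xi[ch, ] <- stats::rnorm(tt, sd = sqrt(target))
          else xi[ch, ] <- xi[ch, ] * sqrt(target / pw[ch])
        }
        log_bad[[length(log_bad) + 1L]] <-
          data.frame(subject = eeg$subject_ids[i], channel = chs)
      }
      eeg$data[i, , ] <- xi
    }
  })
  attr(eeg, "artifact_log") <- list(
    ocular = if (length(log_oc)) do.call(rbind, log_oc) else NULL,
    bad = if (length(log_bad)) do.call(rbind, log_bad) else NULL,
    spikes = if (length(log_sp)) do.call(rbind, log_sp) else NULL)
  eeg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# asymmetric frontal topography of an ocular transient
frontal_weights <- function(labels) {
  w <- stats::setNames(rep(0, length(labels)), labels)
  pick <- function(lab, val) if (lab %in% labels) w[lab] <<- val
  pick("Fp1", 1); pick("Fp2", 0.65)
  pick("F7", 0.35); pick("F8", 0.25); pick("F3", 0.3); pick("F4", 0.2)
  if (all(w == 0)) { w[1] <- 1; if (length(w) > 1) w[2] <- 0.65 }
  unname(w)
}

# smooth low-frequency bump (blink-like)
blink_waveform <- function(len) {
  t <- seq(0, 1, length.out = len)
  exp(-((t - 0.5) / 0.18)^2)
}

#' Generate synthetic pose-keypoint tracks with known movement labels
#'
#' Emulates the per-frame output of a pose-estimation network on a video with
#' scripted limb movements. Outside movement epochs every keypoint only
#' jitters (displacements strictly below `lower`, mimicking camera shake);
#' within an epoch the scripted limb's keypoints translate by per-frame steps
#' drawn strictly between the detection thresholds; scene cuts displace the
#' whole pose by more than `upper` in a single frame. The returned ground
#' truth labels each frame `arm`, `leg`, `both` or `neither`.
#'
#' @param frames number of video frames.
#' @param fps frames per second.
#' @param script `NULL` or a data.frame with columns `limb` (`"arm"`/`"leg"`),
#'   `start`, `end` (1-based frame indices, inclusive).
#' @param scene_cuts integer frames at whose onset a cut occurs.
#' @param frame_size `c(width, height)` in pixels.
#' @param lower,upper the displacement thresholds (pixels/frame) the track is
#'   constructed against.
#' @param n_people people in the scene; scripted movement applies to person 1.
#' @param seed RNG seed.
#' @return list with `track` (a `keypoint_track`) and `truth` (per-frame
#'   labels plus the script).
#' @export
generate_keypoint_tracks <- function(frames, fps, script = NULL,
                                     scene_cuts = integer(0),
                                     frame_size = c(1280, 720),
                                     lower = 5, upper = 50,
                                     n_people = 1, seed = 1L) {
  if (frames < 2) stop("need at least 2 frames")
  if (upper <= 2.4 * lower)
    stop("upper threshold too close to lower to script unambiguous movement")
  if (!is.null(script)) {
    script <- as.data.frame(script)
    stopifnot(all(c("limb", "start", "end") %in% names(script)))
    if (any(script$start < 1 | script$end > frames | script$start > script$end))
      stop("script epochs must lie within [1, frames]")
    if (!all(script$limb %in% c("arm", "leg")))
      stop("script limb must be 'arm' or 'leg'")
  }
  w <- frame_size[1]; h <- frame_size[2]
  if (1.6 * upper > min(w, h) / 4)
    stop("scripted displacement outside representable frame")
  base <- body25_template(w, h)        # 25 x 2
  nk <- nrow(base)
  arm_idx <- body25_limbs()$arm + 1L   # to 1-based
  leg_idx <- body25_limbs()$leg + 1L

  labels <- rep("neither", frames)
  if (!is.null(script)) {
    arm_f <- rep(FALSE, frames); leg_f <- rep(FALSE, frames)
    for (r in seq_len(nrow(script))) {
      idx <- script$start[r]:script$end[r]
      if (script$limb[r] == "arm") arm_f[idx] <- TRUE else leg_f[idx] <- TRUE
    }
    labels[arm_f & !leg_f] <- "arm"
    labels[!arm_f & leg_f] <- "leg"
    labels[arm_f & leg_f] <- "both"
  }

  coords <- array(0, dim = c(frames, n_people, nk, 3))
  with_seed(seed, {
    for (p in seq_len(n_people)) {
      origin <- c(stats::runif(1, w * 0.35, w * 0.65),
                  stats::runif(1, h * 0.4, h * 0.6)) - c(w / 2, h / 2)
      pos <- sweep(base, 2, origin, `+`)
      arm_off <- c(0, 0); leg_off <- c(0, 0)
      arm_dir <- stats::runif(1, 0, 2 * pi); leg_dir <- stats::runif(1, 0, 2 * pi)
      for (f in seq_len(frames)) {
        if (f > 1 && f %in% scene_cuts) {
          ctr <- c(w / 2, h / 2)
          cdir <- ctr - colMeans(pos)
          cdir <- cdir / max(sqrt(sum(cdir^2)), 1)
          pos <- sweep(pos, 2, 1.6 * upper * cdir, `+`)
        }
        th <- stats::runif(nk, 0, 2 * pi)
        jit <- stats::runif(nk, 0, 0.3 * lower) * cbind(cos(th), sin(th))
        fpos <- pos + jit
        if (p == 1 && labels[f] %in% c("arm", "both") && f > 1) {
          step <- stats::runif(1, 1.7 * lower, 0.95 * upper - 0.6 * lower)
          mv <- reflect_step(pos[arm_idx, , drop = FALSE], arm_dir, step, w, h)
          arm_dir <- mv$dir
          pos[arm_idx, ] <- sweep(pos[arm_idx, , drop = FALSE], 2, mv$vec, `+`)
          fpos[arm_idx, ] <- pos[arm_idx, ] + jit[arm_idx, ]
        }
        if (p == 1 && labels[f] %in% c("leg", "both") && f > 1) {
          step <- stats::runif(1, 1.7 * lower, 0.95 * upper - 0.6 * lower)
          mv <- reflect_step(pos[leg_idx, , drop = FALSE], leg_dir, step, w, h)
          leg_dir <- mv$dir
          pos[leg_idx, ] <- sweep(pos[leg_idx, , drop = FALSE], 2, mv$vec, `+`)
          fpos[leg_idx, ] <- pos[leg_idx, ] + jit[leg_idx, ]
        }
        coords[f, p, , 1] <- pmin(pmax(fpos[, 1], 0), w)
        coords[f, p, , 2] <- pmin(pmax(fpos[, 2], 0), h)
        coords[f, p, , 3] <- stats::runif(nk, 0.6, 0.95)
      }
    }
  })
  track <- keypoint_track(coords, fps, frame_size)
  list(track = track,
       truth = list(labels = factor(labels,
                                    levels = c("arm", "leg", "both", "neither")),
                    script = script, scene_cuts = scene_cuts))
}

# step of given magnitude in direction `dir`, reflected off frame bounds
reflect_step <- function(pts, dir, step, w, h) {
  margin <- 2 * step + 5
  vec <- step * c(cos(dir), sin(dir))
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  if (lo[1] + vec[1] < margin || hi[1] + vec[1] > w - margin)
    vec[1] <- -vec[1]
  if (lo[2] + vec[2] < margin || hi[2] + vec[2] > h - margin)
    vec[2] <- -vec[2]
  list(vec = vec, dir = atan2(vec[2], vec[1]))
}

# BODY_25 landmark template, roughly anthropometric, centered on the frame
body25_template <- function(w, h) {
  cx <- w / 2; cy <- h / 2; s <- h / 720 * 100
  pts <- matrix(c(
     0.0, -1.9,    # 0 nose
     0.0, -1.5,    # 1 neck
    -0.45, -1.5,   # 2 r shoulder
    -0.55, -0.9,   # 3 r elbow
    -0.6, -0.3,    # 4 r wrist
     0.45, -1.5,   # 5 l shoulder
     0.55, -0.9,   # 6 l elbow
     0.6, -0.3,    # 7 l wrist
     0.0,  0.0,    # 8 mid hip
    -0.25, 0.0,    # 9 r hip
    -0.3,  0.8,    # 10 r knee
    -0.3,  1.6,    # 11 r ankle
     0.25, 0.0,    # 12 l hip
     0.3,  0.8,    # 13 l knee
     0.3,  1.6,    # 14 l ankle
    -0.1, -2.0,    # 15 r eye
     0.1, -2.0,    # 16 l eye
    -0.2, -1.95,   # 17 r ear
     0.2, -1.95,   # 18 l ear
     0.4,  1.75,   # 19 l big toe
     0.45, 1.75,   # 20 l small toe
     0.25, 1.65,   # 21 l heel
    -0.4,  1.75,   # 22 r big toe
    -0.45, 1.75,   # 23 r small toe
    -0.25, 1.65),  # 24 r heel
    ncol = 2, byrow = TRUE)
  sweep(pts * s, 2, c(cx, cy), `+`)
}

# default limb keypoints (0-based BODY_25 indices): elbows+wrists, knees+ankles
body25_limbs <- function() {
  list(arm = c(3L, 4L, 6L, 7L), leg = c(10L, 11L, 13L, 14L))
}

#' Load the packaged patient clinical/cognitive scores table
#'
#' The 23-patient table of demographics, diagnosis (AMC or OBPL) and ordinal
#' clinical/cognitive assessment scores that the correlation and mixed-model
#' analyses consume. GMD (general motor development) ranges 1-14, 14 being a
#' healthy child's score.
#'
#' @return A data.frame with 23 rows and columns Code, Age, Sex, Diagnosis,
#'   Paresis, CNS_Damage, DMD, GMD, Attention, Auditory_Memory, Visual_Memory,
#'   Story.
#' @export
load_scores_fixture <- function() {
  path <- system.file("extdata", "patient_scores.tsv", package = "corrisc")
  if (path == "" || !file.exists(path))
    stop("packaged patient_scores.tsv fixture is missing")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Code", "Age", "Sex", "Diagnosis", "Paresis", "CNS_Damage",
            "DMD", "GMD", "Attention", "Auditory_Memory", "Visual_Memory",
            "Story")
  if (!identical(names(df), need) || nrow(df) != 23)
    stop("patient scores fixture is corrupt")
  if (any(is.na(df$Diagnosis)) || any(df$GMD < 1 | df$GMD > 14))
    stop("patient scores fixture fails validation (Diagnosis/GMD)")
  df
}
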