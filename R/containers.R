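#' Canonical 19-channel 10-20 montage
#'
#' The electrode set shared by common 19- and 32-channel clinical EEG caps,
#' used as the default common montage when aligning cohorts recorded with
#' different systems.
#'
#' @return Character vector of 19 channel labels in canonical order.
#' @export
montage_1020_19 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Multi-subject EEG container
#'
#' Aligned EEG of several subjects watching the same stimulus: an
#' N subjects x D channels x T samples array plus metadata. All subjects must
#' share channel count, channel order, length and sampling rate; temporal
#' alignment across subjects is what ISC analysis relies on.
#'
#' @param data numeric array, N x D x T.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of length D.
#' @param subject_ids character vector of length N.
#' @param group character vector of length N, values in `"healthy"`/`"patient"`.
#' @param video_id identifier of the stimulus block (e.g. 1-4).
#'
#' @return An object of class `multisubject_eeg`.
#' @export
multisubject_eeg <- function(data, fs, channel_labels, subject_ids,
                             group = rep("healthy", dim(data)[1]),
                             video_id = 1L) {
  if (length(dim(data)) != 3L)
    stop("`data` must be an N x D x T array")
  n <- dim(data)[1]; d <- dim(data)[2]; tt <- dim(data)[3]
  if (tt <= 0L) stop("T must be positive")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive sampling rate")
  if (length(channel_labels) != d)
    stop("channel_labels length must equal channel dimension")
  if (length(subject_ids) != n)
    stop("subject_ids length must equal subject dimension")
  group <- as.character(group)
  if (length(group) != n || !all(group %in% c("healthy", "patient")))
    stop("group must be length N with values 'healthy' or 'patient'")
  structure(
    list(data = data, fs = fs,
         channel_labels = as.character(channel_labels),
         subject_ids = as.character(subject_ids),
         group = group, video_id = video_id),
    class = "multisubject_eeg")
}

#' @export
print.multisubject_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multisubject_eeg> video %s: %d subjects x %d channels x %d samples @ %g Hz\n",
              as.character(x$video_id), d[1], d[2], d[3], x$fs))
  cat(sprintf("  groups: %d healthy, %d patient\n",
              sum(x$group == "healthy"), sum(x$group == "patient")))
  invisible(x)
}

#' @export
dim.multisubject_eeg <- function(x) dim(x$data)

n_subjects <- function(eeg) dim(eeg$data)[1]
n_channels <- function(eeg) dim(eeg$data)[2]
n_samples  <- function(eeg) dim(eeg$data)[3]

# one subject's D x T matrix
subject_matrix <- function(eeg, i) {
  m <- eeg$data[i, , , drop = FALSE]
  dim(m) <- dim(eeg$data)[2:3]
  m
}

assert_eeg <- function(eeg) {
  if (!inherits(eeg, "multisubject_eeg"))
    stop("expected a `multisubject_eeg` object")
  invisible(eeg)
}

# Keypoint track: frames x people x keypoints x 3 (x, y, confidence),
# confidence 0 marks a missing detection.
keypoint_track <- function(coords, fps, frame_size) {
  if (length(dim(coords)) != 4L || dim(coords)[4] != 3L)
    stop("coords must be frames x people x keypoints x 3")
  if (fps <= 0) stop("fps must be positive")
  structure(list(coords = coords, fps = fps,
                 frame_size = as.numeric(frame_size)),
            class = "keypoint_track")
}

#' @export
print.keypoint_track <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<keypoint_track> %d frames, up to %d people, %d keypoints @ %g fps (%gx%g px)\n",
              d[1], d[2], d[3], x$fps, x$frame_size[1], x$frame_size[2]))
  invisible(x)
}
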