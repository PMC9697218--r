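# External formats. The interchange matrix format is deliberately plain:
# one tab-delimited file per subject per video (rows = channels, columns =
# samples) with a JSON sidecar holding sampling rate, channel labels and
# subject metadata. EDF support is a minimal self-contained implementation of
# the continuous 16-bit EDF layout (1-second data records), enough to
# round-trip the synthetic cohorts through the same files a clinical system
# would produce.

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write a cohort video to the delimited matrix format
#'
#' One TSV per subject (rows = channels, columns = samples) plus a JSON
#' sidecar with `fs`, `channel_labels`, `subject_id`, `group`, `video_id`.
#'
#' @param eeg a [multisubject_eeg()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of TSV paths written.
#' @export
write_eeg_matrix <- function(eeg, dir) {
  assert_eeg(eeg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_subjects(eeg))
  for (i in seq_len(n_subjects(eeg))) {
    p <- file.path(dir, sprintf("%s_v%s.tsv", eeg$subject_ids[i],
                                as.character(eeg$video_id)))
    utils::write.table(subject_matrix(eeg, i), p, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
      list(fs = eeg$fs, channel_labels = eeg$channel_labels,
           subject_id = eeg$subject_ids[i], group = eeg$group[i],
           video_id = eeg$video_id),
      sidecar_path(p), auto_unbox = TRUE, digits = NA)
    paths[i] <- p
  }
  invisible(paths)
}

read_matrix_file <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing sidecar JSON for ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(mat) <- NULL
  list(data = mat, fs = meta$fs, labels = meta$channel_labels,
       subject_id = meta$subject_id %||% basename(path),
       group = meta$group %||% "healthy", video_id = meta$video_id %||% 1L)
}

#' Read multi-subject EEG files into an aligned tensor
#'
#' Restricts every recording to the configured common montage (erroring, with
#' their names, on channels the montage requires but a file lacks), reorders
#' channels canonically, checks that all files share one sampling rate, and
#' truncates all subjects to the shortest common length.
#'
#' @param paths character vector of files (one subject per file).
#' @param layout `"matrix"` (TSV + JSON sidecar) or `"edf"`.
#' @param montage channel labels to retain, in canonical order.
#' @return A [multisubject_eeg()].
#' @export
read_eeg <- function(paths, layout = c("matrix", "edf"),
                     montage = montage_1020_19()) {
  layout <- match.arg(layout)
  if (length(paths) < 1) stop("no input files")
  recs <- lapply(paths, function(p)
    if (layout == "matrix") read_matrix_file(p) else read_edf(p))
  fss <- vapply(recs, function(r) r$fs, numeric(1))
  if (length(unique(fss)) > 1)
    stop("mixed sampling rates across files: ",
         paste(sprintf("%s (%g Hz)", basename(paths), fss), collapse = ", "))
  sel <- lapply(seq_along(recs), function(i) {
    missing <- setdiff(montage, recs[[i]]$labels)
    if (length(missing))
      stop("file ", basename(paths[i]), " lacks montage channels: ",
           paste(missing, collapse = ", "))
    match(montage, recs[[i]]$labels)
  })
  tmin <- min(vapply(recs, function(r) ncol(r$data), integer(1)))
  n <- length(recs); d <- length(montage)
  arr <- array(0, dim = c(n, d, tmin))
  for (i in seq_len(n))
    arr[i, , ] <- recs[[i]]$data[sel[[i]], seq_len(tmin), drop = FALSE]
  multisubject_eeg(arr, fss[1], montage,
                   vapply(recs, function(r) as.character(r$subject_id),
                          character(1)),
                   vapply(recs, function(r) as.character(r$group),
                          character(1)),
                   video_id = recs[[1]]$video_id)
}

## ---- minimal EDF (16-bit, continuous, 1 s records) ----

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write one subject's recording as an EDF file
#'
#' Continuous EDF with 1-second data records and per-channel physical scaling
#' chosen from the data range; 16-bit quantization limits round-trip accuracy
#' to about 1/65000 of each channel's range. Subject id and group are stored
#' in the patient field, the video id in the recording field.
#'
#' @param eeg a [multisubject_eeg()].
#' @param dir output directory.
#' @return Invisibly, the vector of EDF paths written.
#' @export
write_edf <- function(eeg, dir) {
  assert_eeg(eeg)
  if (abs(eeg$fs - round(eeg$fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_subjects(eeg))
  for (i in seq_len(n_subjects(eeg))) {
    p <- file.path(dir, sprintf("%s_v%s.edf", eeg$subject_ids[i],
                                as.character(eeg$video_id)))
    write_edf_file(subject_matrix(eeg, i), eeg$fs, eeg$channel_labels,
                   patient = paste(eeg$subject_ids[i], eeg$group[i]),
                   recording = paste("video", as.character(eeg$video_id)), p)
    paths[i] <- p
  }
  invisible(paths)
}

write_edf_file <- function(mat, fs, labels, patient, recording, path) {
  d <- nrow(mat); fs <- as.integer(round(fs))
  n_rec <- floor(ncol(mat) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  mat <- mat[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- apply(abs(mat), 1, max)
  pmax_[pmax_ == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_ascii("0", 8), pad_ascii(patient, 80), pad_ascii(recording, 80),
    pad_ascii("01.01.20", 8), pad_ascii("00.00.00", 8),
    pad_ascii(256 + 256 * d, 8), pad_ascii("", 44),
    pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(d, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, pad_ascii, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  fld(labels, 16)
  fld(rep("", d), 80)                       # transducer
  fld(rep("uV", d), 8)                      # physical dimension
  fld(formatC(-pmax_, format = "g", digits = 6), 8)
  fld(formatC(pmax_, format = "g", digits = 6), 8)
  fld(rep(-32767L, d), 8)
  fld(rep(32767L, d), 8)
  fld(rep("", d), 80)                       # prefiltering
  fld(rep(fs, d), 8)
  fld(rep("", d), 32)
  scale <- 32767 / pmax_
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(mat[, idx, drop = FALSE] * scale)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a single EDF file
#'
#' @param path an EDF file written by [write_edf()] or another system using
#'   the plain continuous 16-bit layout.
#' @return list with `data` (channels x samples), `fs`, `labels`,
#'   `subject_id`, `group`, `video_id`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(wi) trimws(readChar(con, wi, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  d <- as.integer(rd(4))
  if (is.na(d) || d < 1) stop("malformed EDF header in ", path)
  rdv <- function(wi) vapply(seq_len(d), function(i) rd(wi), character(1))
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1)
    stop("EDF reader supports a single sampling rate per file")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  offset <- pmin_ - gain * dmin
  mat <- matrix(0, d, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = d * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1])     # samples x channels
    mat[, ((r - 1) * spr[1] + 1):(r * spr[1])] <- t(block) * gain + offset
  }
  parts <- strsplit(patient, " +")[[1]]
  vid <- sub("^video *", "", recording)
  list(data = mat, fs = fs, labels = labels,
       subject_id = if (length(parts)) parts[1] else basename(path),
       group = if (length(parts) > 1 && parts[2] %in% c("healthy", "patient"))
         parts[2] else "healthy",
       video_id = if (grepl("^[0-9]+$", vid)) as.integer(vid) else recording)
}

## ---- OpenPose-style keypoint JSON ----

#' Write a keypoint track as per-frame OpenPose-style JSON files
#'
#' One file per frame, `"people"` holding one entry per detected person with
#' a flat `pose_keypoints_2d` vector of `[x, y, confidence]` triples in
#' BODY_25 order. People with all-zero confidence in a frame are omitted
#' (as a pose estimator that missed them would).
#'
#' @param track a `keypoint_track`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return Invisibly, the paths written.
#' @export
write_keypoints <- function(track, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- dim(track$coords)
  paths <- character(dims[1])
  for (f in seq_len(dims[1])) {
    people <- list()
    for (p in seq_len(dims[2])) {
      kp <- track$coords[f, p, , ]
      if (all(kp[, 3] == 0)) next
      people[[length(people) + 1L]] <-
        list(pose_keypoints_2d = as.numeric(t(kp)))
    }
    paths[f] <- file.path(dir, sprintf("%s_%012d_keypoints.json", prefix,
                                       f - 1L))
    jsonlite::write_json(list(version = 1.3, people = people), paths[f],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a directory of OpenPose-style keypoint JSON files
#'
#' Frames are ordered by the index embedded in the filename. Frames with an
#' empty `"people"` array yield all-missing (confidence 0) keypoints;
#' multi-person frames are preserved up to the maximum person count seen.
#'
#' @param dir directory of `*_keypoints.json` files.
#' @param fps frames per second of the source video (not stored in the JSON).
#' @param frame_size `c(width, height)` in pixels.
#' @return A `keypoint_track`.
#' @export
read_keypoints <- function(dir, fps = 25, frame_size = c(1280, 720)) {
  files <- list.files(dir, pattern = "_keypoints\\.json$", full.names = TRUE)
  if (length(files) == 0) stop("no keypoint JSON files in ", dir)
  idx <- as.integer(sub(".*_(\\d+)_keypoints\\.json$", "\\1", basename(files)))
  files <- files[order(idx)]
  raw <- vector("list", length(files))
  for (f in seq_along(files)) {
    parsed <- tryCatch(jsonlite::read_json(files[f], simplifyVector = FALSE),
                       error = function(e)
                         stop("malformed keypoint JSON at frame index ", f - 1,
                              " (", basename(files[f]), "): ",
                              conditionMessage(e)))
    raw[[f]] <- lapply(parsed$people, function(pp)
      as.numeric(unlist(pp$pose_keypoints_2d)))
  }
  nk <- 25L
  for (f in seq_along(raw))
    for (pp in raw[[f]])
      if (length(pp) %% 3 == 0 && length(pp) > 0) nk <- max(nk, length(pp) %/% 3L)
  maxp <- max(1L, vapply(raw, length, integer(1)))
  coords <- array(0, dim = c(length(files), maxp, nk, 3))
  for (f in seq_along(raw)) {
    for (p in seq_along(raw[[f]])) {
      v <- raw[[f]][[p]]
      if (length(v) %% 3 != 0)
        stop("malformed pose_keypoints_2d at frame index ", f - 1)
      m <- matrix(v, ncol = 3, byrow = TRUE)
      coords[f, p, seq_len(nrow(m)), ] <- m
    }
  }
  keypoint_track(coords, fps, frame_size)
}

## ---- result tables & config ----

#' Write an ISC result table as TSV
#'
#' One row per subject per video per component, with the per-component ISC
#' and that subject/video's top-K component sum.
#'
#' @param result an ISC result data.frame (see [loo_isc_table()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_isc_table <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.table(format_num_df(df), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
  df
}

#' Read back an ISC table written by [write_isc_table()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_isc_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a JSON pipeline configuration file
#' @param path JSON file.
#' @return Nested list.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
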