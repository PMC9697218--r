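# Movement annotation from pose keypoints.
#
# A limb "moves" in a frame transition when the Euclidean displacement of its
# screen coordinates between consecutive frames lies strictly between two
# thresholds: displacements at or below the lower threshold are camera
# jitter, displacements at or above the upper threshold are scene cuts.
# Analysis windows are then labelled by the dominant per-frame limb state.

#' Movement-annotation configuration
#'
#' @param lower,upper displacement thresholds in pixels/frame
#'   (`0 <= lower < upper`); a displacement counts as movement only when it
#'   is strictly between them.
#' @param arm_keypoints,leg_keypoints 0-based BODY_25 keypoint indices per
#'   limb class (defaults: elbows+wrists, knees+ankles); the lists must be
#'   disjoint and non-empty.
#' @param confidence_min minimal detection confidence for a keypoint to
#'   participate (in both frames of a transition).
#' @param dominance_rule window labelling rule; `"modal"` takes the most
#'   frequent per-frame state, ties broken by the fixed priority
#'   both > arm > leg > neither.
#' @return A `movement_config` list.
#' @export
movement_config <- function(lower, upper,
                            arm_keypoints = body25_limbs()$arm,
                            leg_keypoints = body25_limbs()$leg,
                            confidence_min = 0.1,
                            dominance_rule = "modal") {
  if (lower < 0 || upper <= lower) stop("need 0 <= lower < upper")
  if (length(arm_keypoints) == 0 || length(leg_keypoints) == 0 ||
      length(intersect(arm_keypoints, leg_keypoints)))
    stop("limb keypoint lists must be non-empty and disjoint")
  structure(list(lower = lower, upper = upper,
                 arm_keypoints = as.integer(arm_keypoints),
                 leg_keypoints = as.integer(leg_keypoints),
                 confidence_min = confidence_min,
                 dominance_rule = dominance_rule),
            class = "movement_config")
}

limb_distance_one <- function(coords, frames2, idx1, conf_min) {
  # coords: frames x people x keypoints x 3; idx1: 1-based keypoint indices
  a <- coords[frames2 - 1L, , idx1, , drop = FALSE]
  b <- coords[frames2, , idx1, , drop = FALSE]
  valid <- a[, , , 3, drop = FALSE] >= conf_min &
    b[, , , 3, drop = FALSE] >= conf_min
  dd <- sqrt((b[, , , 1, drop = FALSE] - a[, , , 1, drop = FALSE])^2 +
               (b[, , , 2, drop = FALSE] - a[, , , 2, drop = FALSE])^2)
  dd[!valid] <- NA_real_
  dim(dd) <- c(length(frames2), prod(dim(dd)[2:3]))
  out <- apply(dd, 1, function(r) if (all(is.na(r))) NA_real_
               else max(r, na.rm = TRUE))
  out
}

#' Per-transition limb displacement
#'
#' For each consecutive-frame transition and limb class, the displacement is
#' the maximum, over detected people and over the limb's configured
#' keypoints, of the Euclidean displacement of keypoints detected with
#' sufficient confidence in both frames. Transitions with no valid keypoint
#' are `NA`.
#'
#' @param track a `keypoint_track` with at least 2 frames.
#' @param config a [movement_config()].
#' @return data.frame with `frame` (2..F; the transition into that frame),
#'   `arm`, `leg` displacements in pixels.
#' @export
limb_displacement <- function(track, config) {
  nf <- dim(track$coords)[1]
  if (nf < 2) stop("need at least 2 frames")
  frames2 <- 2:nf
  data.frame(
    frame = frames2,
    arm = limb_distance_one(track$coords, frames2,
                            config$arm_keypoints + 1L, config$confidence_min),
    leg = limb_distance_one(track$coords, frames2,
                            config$leg_keypoints + 1L, config$confidence_min))
}

#' Per-frame movement flags from limb displacements
#'
#' A limb moves in a frame iff its displacement is strictly between the
#' thresholds; jitter (at or below `lower`) and scene cuts (at or above
#' `upper`) are not movement, and missing displacements count as no
#' movement. Frame 1 has no incoming transition and is never moving.
#'
#' @param distances output of [limb_displacement()].
#' @param config a [movement_config()].
#' @return data.frame with `frame` (1..F), `arm_moving`, `leg_moving`.
#' @export
detect_movement <- function(distances, config) {
  flag <- function(d) !is.na(d) & d > config$lower & d < config$upper
  nf <- max(distances$frame)
  out <- data.frame(frame = seq_len(nf),
                    arm_moving = FALSE, leg_moving = FALSE)
  out$arm_moving[distances$frame] <- flag(distances$arm)
  out$leg_moving[distances$frame] <- flag(distances$leg)
  out
}

frame_state <- function(flags) {
  ifelse(flags$arm_moving & flags$leg_moving, "both",
         ifelse(flags$arm_moving, "arm",
                ifelse(flags$leg_moving, "leg", "neither")))
}

#' Label analysis windows by their dominant movement
#'
#' Tallies the per-frame joint limb states within each window and assigns
#' the modal state; ties are broken by the deterministic priority
#' both > arm > leg > neither (logged). The four labels are exhaustive and
#' mutually exclusive.
#'
#' @param flags per-frame flags from [detect_movement()].
#' @param grid window grid from [window_grid()] (times in seconds).
#' @param fps video frame rate, mapping frames to window times.
#' @param config a [movement_config()].
#' @return data.frame with `window`, `start_s`, `end_s`, `label` (factor with
#'   levels arm, leg, both, neither).
#' @export
label_windows <- function(flags, grid, fps, config = NULL) {
  states <- frame_state(flags)
  t_frame <- (flags$frame - 1) / fps
  lev <- c("both", "arm", "leg", "neither")   # tie priority order
  lab <- character(nrow(grid))
  n_tie <- 0L
  for (wi in seq_len(nrow(grid))) {
    sel <- t_frame >= grid$start_s[wi] & t_frame < grid$end_s[wi]
    if (!any(sel)) { lab[wi] <- "neither"; next }
    counts <- table(factor(states[sel], levels = lev))
    best <- which(counts == max(counts))
    if (length(best) > 1) n_tie <- n_tie + 1L
    lab[wi] <- lev[min(best)]
  }
  if (n_tie > 0)
    message(n_tie, " window(s) had tied states; resolved by priority ",
            "both > arm > leg > neither")
  data.frame(window = grid$window, start_s = grid$start_s,
             end_s = grid$end_s,
             label = factor(lab, levels = c("arm", "leg", "both", "neither")))
}

#' Align movement annotation, windowed ISC and patient scores
#'
#' Produces the long table the mixed-model stage consumes: one row per
#' patient per window carrying the window's reported ISC (top-K component
#' sum), its movement label and the patient's clinical/cognitive scores
#' (joined on subject code).
#'
#' @param annotation window labels from [label_windows()].
#' @param window_isc result of [time_resolved_isc()] for the patient targets.
#' @param scores the patient scores table ([load_scores_fixture()] schema);
#'   `NULL` to omit the join.
#' @return data.frame with columns `subject`, `window`, `start_s`, `end_s`,
#'   `isc`, `label` and, when scores are given, the score columns.
#' @export
align_annotation_isc <- function(annotation, window_isc, scores = NULL) {
  base <- unique(window_isc[window_isc$component == 1,
                            c("subject", "window", "start_s", "end_s",
                              "topk_sum")])
  names(base)[names(base) == "topk_sum"] <- "isc"
  if (max(base$window) != max(annotation$window))
    stop("window grids of annotation and ISC differ (",
         max(annotation$window), " vs ", max(base$window), " windows)")
  out <- merge(base, annotation[, c("window", "label")], by = "window")
  if (!is.null(scores)) {
    missing <- setdiff(unique(out$subject), scores$Code)
    if (length(missing))
      stop("no scores for subjects: ", paste(missing, collapse = ", "))
    out <- merge(out, scores, by.x = "subject", by.y = "Code")
  }
  if (length(unique(out$label[!is.na(out$isc)])) < 2)
    warning("movement label has a single level; downstream models will ",
            "drop the movement term")
  out[order(out$subject, out$window), ]
}
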