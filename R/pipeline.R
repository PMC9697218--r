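#' Pipeline configuration
#'
#' One object drives an end-to-end run, either from a synthetic cohort
#' (`mode = "synthetic"`, using `cohort`) or from files on disk
#' (`mode = "files"`, using `input_paths`, a list of per-video file vectors,
#' plus `input_layout`). Exactly one mode is populated; a seed is mandatory
#' in synthetic mode.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param cohort a [cohort_spec()] (synthetic mode).
#' @param input_paths list (per video) of file vectors (file mode).
#' @param input_layout `"matrix"` or `"edf"` (file mode).
#' @param preprocess a [preprocess_config()].
#' @param k_report components summed in reported ISC values.
#' @param shrinkage CorrCA shrinkage regularization.
#' @param window_length,window_overlap sliding-window parameters, seconds.
#' @param alpha_band,alpha_broadband spectral bands, Hz (`NULL` broadband
#'   means `[0, fs/2]`).
#' @param movement a [movement_config()] or `NULL` to skip annotation.
#' @param keypoint_dir directory of keypoint JSON (file mode annotation).
#' @param fps video frame rate for annotation.
#' @param output_dir where result tables are written.
#' @param seed RNG seed for generation and ICA.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_spec(),
                            input_paths = NULL, input_layout = "matrix",
                            preprocess = preprocess_config(),
                            k_report = 3, shrinkage = 0.1,
                            window_length = 1.5, window_overlap = 1.2,
                            alpha_band = c(8, 12), alpha_broadband = NULL,
                            movement = NULL, keypoint_dir = NULL, fps = 25,
                            output_dir = tempfile("corrisc_run_"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files" && is.null(input_paths))
    stop("file mode requires input_paths")
  if (mode == "synthetic" && is.null(seed))
    stop("synthetic mode requires a seed")
  step <- window_length - window_overlap
  if (step <= 0) stop("window overlap must be smaller than the window length")
  structure(list(mode = mode, cohort = cohort, input_paths = input_paths,
                 input_layout = input_layout, preprocess = preprocess,
                 k_report = k_report, shrinkage = shrinkage,
                 window_length = window_length, window_step = step,
                 alpha_band = alpha_band, alpha_broadband = alpha_broadband,
                 movement = movement, keypoint_dir = keypoint_dir, fps = fps,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(format_num_df(as.data.frame(df)), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or generate the per-video cohorts; preprocess each
#' video; compute per-video covariances, pool them and fit the correlated
#' components on both groups together (so the optimization favors neither
#' group); leave-one-out ISC of every subject against the healthy reference
#' cohort; within-patient ISC with patient-only components; time-resolved
#' windowed ISC; component alpha power; movement annotation alignment (when
#' configured); group statistics (Welch t with Cohen's d on the top-K ISC
#' sums, ANCOVA adjusting for age when scores are available and for alpha
#' power). Writes TSV tables plus a JSON manifest into `output_dir`.
#'
#' @param config a [pipeline_config()].
#' @param scores optional patient scores table (defaults to the packaged
#'   fixture when patient ids match its codes).
#' @return list with the in-memory results and `manifest` (also written to
#'   `output_dir/manifest.json`).
#' @export
run_pipeline <- function(config, scores = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)

  if (config$mode == "synthetic") {
    spec <- config$cohort
    spec$seed <- config$seed
    gen <- generate_cohort(spec)
    eeg_list <- gen$eeg
    if (sum(unlist(spec$artifact_spec)) > 0)
      eeg_list <- lapply(seq_along(eeg_list), function(v)
        inject_artifacts(eeg_list[[v]], spec,
                         seed = config$seed + 7919L + v))
    truth <- gen$truth
  } else {
    eeg_list <- lapply(config$input_paths, read_eeg,
                       layout = config$input_layout)
    truth <- NULL
  }

  eeg_list <- lapply(seq_along(eeg_list), function(v)
    preprocess(eeg_list[[v]], config$preprocess,
               seed = config$seed + 131L * v))

  pairs <- lapply(eeg_list, compute_covariances)
  pooled <- pool_covariances(pairs)
  model <- fit_corrca(pooled, k = max(config$k_report, 3),
                      shrinkage = config$shrinkage)
  proj <- lapply(eeg_list, project_components, model = model)

  grp <- eeg_list[[1]]$group
  healthy_idx <- which(grp == "healthy")
  patient_idx <- which(grp == "patient")
  isc <- loo_isc_table(proj, reference = healthy_idx,
                       k_report = config$k_report)
  outputs <- c(outputs, write_tsv(isc, file.path(config$output_dir,
                                                 "isc.tsv")))
  outputs <- c(outputs,
               write_tsv(isc_summary(isc),
                         file.path(config$output_dir, "isc_summary.tsv")))
  fm <- as.data.frame(model$A)
  names(fm) <- paste0("comp", seq_len(ncol(model$A)))
  fm <- cbind(channel = eeg_list[[1]]$channel_labels, fm)
  outputs <- c(outputs, write_tsv(fm, file.path(config$output_dir,
                                                "forward_models.tsv")))

  within_pat <- NULL
  if (length(patient_idx) >= 3)
    within_pat <- within_group_isc(eeg_list, "patient",
                                   k_report = config$k_report,
                                   shrinkage = config$shrinkage)
  if (!is.null(within_pat))
    outputs <- c(outputs,
                 write_tsv(isc_summary(within_pat),
                           file.path(config$output_dir,
                                     "within_patient_isc.tsv")))

  wisc <- time_resolved_isc(proj[[1]], reference = healthy_idx,
                            targets = patient_idx,
                            window_length = config$window_length,
                            step = config$window_step,
                            k_report = config$k_report)
  outputs <- c(outputs, write_tsv(wisc, file.path(config$output_dir,
                                                  "window_isc.tsv")))

  alpha <- component_alpha(proj, band = config$alpha_band,
                           broadband = config$alpha_broadband,
                           k_report = config$k_report)
  outputs <- c(outputs, write_tsv(alpha, file.path(config$output_dir,
                                                   "alpha.tsv")))

  aligned <- NULL
  annotation <- NULL
  if (!is.null(config$movement)) {
    track <- if (!is.null(config$keypoint_dir))
      read_keypoints(config$keypoint_dir, fps = config$fps)
    else NULL
    if (!is.null(track)) {
      dist <- limb_displacement(track, config$movement)
      flags <- detect_movement(dist, config$movement)
      annotation <- label_windows(flags, attr(wisc, "grid"), config$fps,
                                  config$movement)
      if (is.null(scores) &&
          all(unique(wisc$subject) %in% load_scores_fixture()$Code))
        scores <- load_scores_fixture()
      aligned <- align_annotation_isc(annotation, wisc, scores)
      outputs <- c(outputs,
                   write_tsv(aligned, file.path(config$output_dir,
                                                "aligned_windows.tsv")))
    }
  }

  summ <- isc_summary(isc)
  stats_rows <- list()
  if (length(healthy_idx) >= 2 && length(patient_idx) >= 2) {
    wt <- welch_t(summ$isc_topk[summ$group == "healthy"],
                  summ$isc_topk[summ$group == "patient"])
    stats_rows$welch <- data.frame(term = "group (healthy - patient)",
                                   test = "welch_t",
                                   statistic = wt$statistic, df = wt$df,
                                   p = wt$p_value, effect_name = "cohens_d",
                                   effect = wt$effect)
    av <- ancova_group_cov(summ$isc_topk, summ$group,
                           merge_alpha_cov(summ, alpha))
    stats_rows$ancova <- data.frame(term = "group | alpha",
                                    test = "ancova_F",
                                    statistic = av$group$statistic,
                                    df = av$group$df[2],
                                    p = av$group$p_value,
                                    effect_name = "ges",
                                    effect = av$group$ges)
  }
  stats_tab <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  if (!is.null(stats_tab))
    outputs <- c(outputs, write_tsv(stats_tab,
                                    file.path(config$output_dir,
                                              "stats.tsv")))

  cfg_path <- file.path(config$output_dir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  manifest <- list(seed = config$seed,
                   config_file = cfg_path,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(model = model, isc = isc, within_patient = within_pat,
       window_isc = wisc, alpha = alpha, annotation = annotation,
       aligned = aligned, stats = stats_tab, truth = truth,
       manifest = manifest)
}

merge_alpha_cov <- function(summ, alpha) {
  alpha$alpha[match(summ$subject, alpha$subject)]
}

config_to_list <- function(config) {
  cl <- unclass(config)
  cl$cohort <- if (!is.null(cl$cohort)) unclass(cl$cohort)
  cl$preprocess <- unclass(cl$preprocess)
  cl$movement <- if (!is.null(cl$movement)) unclass(cl$movement)
  cl
}
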