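# End-to-end pipeline: silhouette extraction -> height -> features ->
# weight model -> identification, both on rendered synthetic cohorts held in
# memory and on frame directories on disk.

#' Per-frame features and height estimates for a rendered session
#'
#' Renders each subject's walking sequence and computes the 13-feature vector
#' and metrology height per frame. With `from_rgb = TRUE` the silhouette is
#' recovered by the full foreground stage (differencing, suppressed Otsu,
#' shadow removal, cleanup); otherwise the generator's ground-truth mask is
#' measured directly, which isolates the measurement stages from segmentation
#' noise and is considerably faster.
#'
#' @param bodies list of [body_params()] (e.g. from [sample_cohort()]).
#' @param camera a [camera_geometry()].
#' @param n_frames frames per subject (1 fps decimation of a walk).
#' @param seed integer seed; sequences and appearance draws derive from it.
#' @param appearance_change emulate a later session: roughly half the
#'   subjects carry a backpack and clothes are dilated by 0-2 px.
#' @param from_rgb run the foreground stage on rendered RGB frames.
#' @param params [shadow_model_params()] for the foreground stage.
#' @return data.frame with `subject_id`, `frame`, `true_height_cm`,
#'   `true_weight_kg`, `est_height_cm`, and the 13 feature columns.
#' @export
session_features <- function(bodies, camera, n_frames = 14, seed = 1,
                             appearance_change = FALSE, from_rgb = FALSE,
                             params = shadow_model_params()) {
  app <- with_seed(seed + 500009L, list(
    backpack = runif(length(bodies)) < 0.5,
    dilation = sample(0:2, length(bodies), replace = TRUE)
  ))
  rows <- vector("list", length(bodies))
  for (i in seq_along(bodies)) {
    body <- bodies[[i]]
    if (appearance_change) {
      body$backpack <- app$backpack[i]
      body$clothes_dilation_px <- app$dilation[i]
    }
    seq <- render_sequence(body, camera, n_frames,
                           seed = seed + 131L * i +
                             if (appearance_change) 70001L else 0L,
                           rgb = from_rgb)
    feats <- lapply(seq$frames, function(fr) {
      mask <- if (from_rgb) {
        extract_silhouette(fr$background, fr$frame, params)
      } else {
        fr$gt_mask
      }
      v <- compute_features(mask, camera)
      data.frame(subject_id = body$subject_id, frame = fr$frame_index,
                 true_height_cm = body$height_cm,
                 true_weight_kg = body$mass_kg,
                 est_height_cm = v[["o_h_cm"]],
                 as.list(v), check.names = FALSE)
    })
    rows[[i]] <- do.call(rbind, feats)
  }
  do.call(rbind, rows)
}

feature_matrix <- function(df) as.matrix(df[, feature_names])

#' Pipeline configuration
#'
#' @param data_dir directory laid out as
#'   `<data_dir>/session<k>/<subject>/frame_*.png` with per-subject
#'   `background.png` and `ground_truth.csv` (as written by
#'   [write_sequence()]), plus a `camera.yaml` in `data_dir`.
#' @param out_dir output directory for masks, CSVs and the summary.
#' @param fps_decimation frame subsampling factor for [load_sequence()].
#' @param params [shadow_model_params()].
#' @param hidden_nodes node count of the weight network.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir, fps_decimation = 1,
                            params = shadow_model_params(),
                            hidden_nodes = 10, seed = 1) {
  structure(list(data_dir = data_dir, out_dir = out_dir,
                 fps_decimation = fps_decimation, params = params,
                 hidden_nodes = as.integer(hidden_nodes),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

process_session_dir <- function(session_dir, camera, config) {
  subjects <- list.dirs(session_dir, recursive = FALSE)
  if (length(subjects) == 0) {
    stopf("stage extract: no subject directories in %s", session_dir)
  }
  rows <- lapply(subjects, function(sd) {
    gt <- read.csv(file.path(sd, "ground_truth.csv"))
    sq <- tryCatch(load_sequence(sd, config$fps_decimation),
                   error = function(e) stopf("stage extract: %s",
                                             conditionMessage(e)))
    per <- lapply(seq_along(sq$frames), function(k) {
      mask <- extract_silhouette(sq$background, sq$frames[[k]], config$params)
      roi <- extract_roi(mask)
      v <- compute_features(mask, camera, roi)
      data.frame(subject_id = gt$subject_id[1], frame = k,
                 x_t = roi$top_row, x_b = roi$bottom_row,
                 true_height_cm = gt$height_cm[1],
                 true_weight_kg = gt$weight_kg[1],
                 est_height_cm = v[["o_h_cm"]], as.list(v),
                 check.names = FALSE)
    })
    do.call(rbind, per)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on a two-session frame-directory dataset
#'
#' Chains extract -> height -> features -> train/evaluate -> identify.
#' Session 1 trains the weight network (normalization fitted there only);
#' session 2 is the test and probe session. Writes per-frame ROI/height and
#' feature CSVs, per-subject report CSVs, the CMC curve and a `summary.yaml`
#' with the four headline metrics to `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return summary list (invisibly written to disk as well): height and
#'   weight MAE/std, CMC rates, stop reason of training.
#' @export
run_pipeline <- function(config) {
  camera <- read_camera(file.path(config$data_dir, "camera.yaml"))
  s1 <- process_session_dir(file.path(config$data_dir, "session1"),
                            camera, config)
  s2 <- process_session_dir(file.path(config$data_dir, "session2"),
                            camera, config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(s1, file.path(config$out_dir, "session1_features.csv"),
            row.names = FALSE)
  write.csv(s2, file.path(config$out_dir, "session2_features.csv"),
            row.names = FALSE)

  # height: per-subject aggregation over session-2 frames
  h_stats <- lapply(split(s2, s2$subject_id), function(d) {
    st <- subject_height_stats(d$est_height_cm, d$true_height_cm[1],
                               d$subject_id[1])
    data.frame(subject_id = st$subject_id, real_height_cm = d$true_height_cm[1],
               mean_est_cm = st$mean_est_cm, mae_cm = st$mae_cm,
               std_cm = st$std_cm)
  })
  h_tab <- do.call(rbind, c(h_stats, list(make.row.names = FALSE)))
  write.csv(h_tab, file.path(config$out_dir, "height_report.csv"),
            row.names = FALSE)
  h_err <- abs(s2$est_height_cm - s2$true_height_cm)

  # weight: train on session 1, test on session 2
  norm <- normalize_features(feature_matrix(s1))
  model <- train_ffnn(norm$features, s1$true_weight_kg, config$hidden_nodes,
                      train_config(seed = config$seed))
  x2 <- normalize_features(feature_matrix(s2), norm$params)$features
  ev <- evaluate_mae(model, x2, s2$true_weight_kg, s2$subject_id)
  write.csv(ev$per_subject, file.path(config$out_dir, "weight_report.csv"),
            row.names = FALSE)

  # identification: session 1 enrolment, session 2 probes
  enrol <- lapply(split(s1, s1$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1],
               height_cm = mean(d$est_height_cm),
               weight_kg = mean(predict(model,
                 normalize_features(feature_matrix(d), norm$params)$features)))
  })
  enrol <- do.call(rbind, c(enrol, list(make.row.names = FALSE)))
  gallery <- make_gallery(enrol$subject_id, enrol$height_cm, enrol$weight_kg)
  probes <- lapply(split(s2, s2$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1],
               height_cm = mean(d$est_height_cm),
               weight_kg = mean(predict(model,
                 normalize_features(feature_matrix(d), norm$params)$features)))
  })
  probes <- do.call(rbind, c(probes, list(make.row.names = FALSE)))
  cmc <- cmc_curve(probes, gallery)
  write.csv(data.frame(rank = seq_along(cmc), rate = as.numeric(cmc)),
            file.path(config$out_dir, "cmc.csv"), row.names = FALSE)

  summary <- list(
    n_subjects = length(unique(s1$subject_id)),
    n_frames = nrow(s1) + nrow(s2),
    height_mae_cm = mean(h_err),
    height_std_cm = if (length(h_err) > 1) sd(h_err) else 0,
    weight_mae_kg = ev$overall_mae,
    weight_std_kg = ev$overall_std,
    rank1_rate = as.numeric(cmc[1]),
    rank5_rate = as.numeric(cmc[min(5, length(cmc))]),
    train_stop_reason = model$stop_reason,
    seed = config$seed
  )
  yaml::write_yaml(summary, file.path(config$out_dir, "summary.yaml"))
  summary
}
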