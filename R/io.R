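# Frame/mask readers and writers, sequence loading with fps decimation,
# camera configuration in YAML.

#' Read an 8-bit RGB frame
#'
#' @param path PNG or JPEG file.
#' @return numeric array rows x cols x 3 with intensities in [0, 255].
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stopf("cannot read frame: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  img * 255
}

#' Write an 8-bit RGB frame or a binary mask as PNG
#'
#' @param img RGB array in [0, 255] or a 0/1 mask matrix.
#' @param path output PNG path.
#' @export
write_frame <- function(img, path) {
  if (is.matrix(img)) {
    png::writePNG(pmin(pmax(img, 0), 1), path)
  } else {
    png::writePNG(img / 255, path)
  }
  invisible(path)
}

#' Write a synthetic sequence to disk
#'
#' Writes numbered frame PNGs, the background PNG, per-frame ground truth as
#' CSV (`subject_id`, `frame`, `height_cm`, `weight_kg`, `gt_top_row`,
#' `gt_bottom_row`) and the camera geometry as YAML.
#'
#' @param seq a `scene_sequence` from [render_sequence()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fr1 <- seq$frames[[1]]
  if (is.null(fr1$frame)) stopf("sequence was rendered without RGB frames")
  write_frame(fr1$background, file.path(dir, "background.png"))
  gt <- lapply(seq$frames, function(fr) {
    write_frame(fr$frame, file.path(dir, sprintf("frame_%03d.png",
                                                 fr$frame_index)))
    data.frame(subject_id = fr$subject_id, frame = fr$frame_index,
               height_cm = seq$body$height_cm,
               weight_kg = if (is.null(seq$body$mass_kg)) NA else
                 seq$body$mass_kg,
               gt_top_row = fr$gt_top_row, gt_bottom_row = fr$gt_bottom_row)
  })
  write.csv(do.call(rbind, gt), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  yaml::write_yaml(unclass(seq$camera), file.path(dir, "camera.yaml"))
  invisible(dir)
}

#' Read camera geometry from YAML
#'
#' @param path YAML file with the [camera_geometry()] fields.
#' @return a `camera_geometry` object.
#' @export
read_camera <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(camera_geometry, cfg[intersect(names(cfg),
                                         names(formals(camera_geometry)))])
}

#' Load a frame sequence from a directory
#'
#' Frames are the PNG files other than the background, ordered by natural
#' (numeric-aware) filename sort, then subsampled by the decimation factor
#' (every `fps_decimation`-th frame is retained).
#'
#' @param path directory of numbered frame PNGs plus `background.png`.
#' @param fps_decimation keep every k-th frame; 50 models 1 fps selection
#'   from 50 fps footage.
#' @param background_file name of the background image within `path`.
#' @return list with `frames` (list of RGB arrays), `background`,
#'   `frame_files`.
#' @export
load_sequence <- function(path, fps_decimation = 1,
                          background_file = "background.png") {
  if (!dir.exists(path)) stopf("no such sequence directory: %s", path)
  bg_path <- file.path(path, background_file)
  if (!file.exists(bg_path)) stopf("missing background frame: %s", bg_path)
  files <- setdiff(list.files(path, pattern = "\\.png$"), background_file)
  if (length(files) == 0) stopf("no frames found in %s", path)
  files <- files[natural_order(files)]
  files <- files[seq(1, length(files), by = max(1, fps_decimation))]
  background <- read_frame(bg_path)
  frames <- lapply(files, function(f) {
    img <- read_frame(file.path(path, f))
    if (!identical(dim(img), dim(background))) {
      stopf("frame dimensions differ from background: %s", f)
    }
    img
  })
  list(frames = frames, background = background, frame_files = files)
}
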