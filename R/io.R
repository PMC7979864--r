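# File formats: CSV tables for detections / trajectories / counts, PNG or
# TIFF frame folders, YAML configuration, and model checkpoints (RDS plus a
# JSON-like YAML sidecar recording the configuration).

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s is missing columns: %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}

validate_detections <- function(df) {
  check_columns(df, c("frame", "t", "x", "y", "b"), "detections table")
  if (nrow(df) && !all(df$b %in% c(1, 2)))
    stop("detections column b must contain only classes 1 and 2")
  if (is.null(df$alpha)) df$alpha <- NA_real_
  df
}

#' Read / write a detections table
#'
#' CSV schema: `frame,t,x,y,b,alpha` (plus optional `area`, `id`); `alpha`
#' may be blank for cell-bees. Floats are written at full precision so
#' write-then-read is the identity on valid tables.
#'
#' @param path CSV file path.
#' @return A validated detections `data.frame`.
#' @export
read_detections <- function(path) {
  validate_detections(utils::read.csv(path))
}

#' @rdname read_detections
#' @param detections Detections `data.frame`.
#' @export
write_detections <- function(detections, path) {
  validate_detections(detections)
  utils::write.csv(detections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a trajectories table
#'
#' CSV schema: `traj_id,frame,t,x,y,b,alpha`.
#'
#' @param path CSV file path.
#' @return A trajectories `data.frame`.
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("traj_id", "frame", "t", "x", "y", "b"),
                "trajectories table")
  df
}

#' @rdname read_trajectories
#' @param trajectories Trajectory `data.frame` or `bee_tracks` object.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- if (inherits(trajectories, "bee_tracks")) trajectories$trajectories
        else trajectories
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a count series table
#'
#' CSV schema: `t` plus one column per count series.
#'
#' @param path CSV file path.
#' @return A `data.frame`.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, "t", "counts table")
  df
}

#' @rdname read_counts
#' @param counts Counts `data.frame` with a `t` column.
#' @export
write_counts <- function(counts, path) {
  check_columns(counts, "t", "counts table")
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_image <- function(path) {
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
    else if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      tiff::readTIFF(path)
    else stop("unsupported image format")
  }, error = function(e)
    stop(sprintf("cannot read frame '%s': %s", path, conditionMessage(e))))
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Read an ordered frame sequence
#'
#' Frames are PNG/TIFF files in a directory (lexicographic order) or the
#' pages of a multi-page TIFF. Timestamps are assigned from the frame rate.
#'
#' @param path Directory of image files, or a multi-page TIFF file.
#' @param fps Frame rate used to assign timestamps.
#' @return List of grayscale matrices with attributes `t` (seconds) and
#'   `files`.
#' @export
read_frames <- function(path, fps = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    frames <- lapply(files, read_image)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    frames <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1]
                                        else p)
    files <- rep(path, length(frames))
  }
  if (length(frames) > 1) {
    shp <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                  character(1))
    if (length(unique(shp)) > 1)
      stop("frames have mixed shapes: ", paste(unique(shp), collapse = ", "))
  }
  attr(frames, "t") <- (seq_along(frames) - 1) / fps
  attr(frames, "files") <- files
  frames
}

#' Write frames as numbered PNG files
#'
#' @param frames List of matrices in `[0, 1]`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames))
    png::writePNG(pmin(pmax(frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%05d.png", i - 1L)))
  invisible(dir)
}

#' Default run configuration
#'
#' Nested list of all pipeline defaults (detector, embedding, tracker,
#' simulator sections plus the pixel scale), suitable for YAML
#' serialisation. Every numeric default matches the constants documented
#' in the component constructors.
#'
#' @return A nested list.
#' @export
run_config <- function() {
  list(px_per_mm = 2.0,
       detector = unclass(detector_config()),
       embedding = unclass(embedding_config()),
       tracker = unclass(tracker_params()),
       simulator = unclass(sim_config()))
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file; missing entries fall back to [run_config()].
#' @return A nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(run_config(), user)
}

merge_lists <- function(base, override) {
  if (is.null(override)) return(base)
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_lists(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The weights are serialised to RDS with a YAML sidecar recording the
#' configuration for inspection.
#'
#' @param model A `bee_detector` or `bee_embedder`.
#' @param path Output `.rds` path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- sub("\\.rds$", ".yaml", path)
  cfg <- unclass(model$config)
  cfg$class <- class(model)[1]
  cfg$n_parameters <- model$n_parameters
  yaml::write_yaml(cfg, side)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
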