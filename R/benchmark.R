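# Desk-scale benchmark scenes: fixed synthetic study conditions under
# which the pipeline's headline properties (detection accuracy after
# tiny-scale training, trajectory recovery with and without appearance
# embeddings) are measured, both by the test suite and by
# scripts/acceptance.R.

#' Build the detector benchmark scene
#'
#' A 256 x 256 px colony of ~15 bees at 10 FPS for 3 s (30 frames: 24 for
#' training, 6 held out), with painter's-order occlusion: bees covered
#' over half their body, which no annotator could label, are rendered
#' underneath but absent from the ground truth. Targets and per-frame
#' weight maps are rendered from the visible ground truth.
#'
#' @param seed Scene seed.
#' @param n_bees,arena,duration Scene parameters.
#' @return List with `config`, `truth`, `frames`, `targets`, `geom`,
#'   `ratio` (background/foreground pixel ratio), `train_idx`, `test_idx`.
#' @export
detector_scene <- function(seed = 11, n_bees = 15, arena = 256,
                           duration = 3) {
  config <- sim_config(n_bees = n_bees, arena = arena, fps = 10,
                       duration = duration, occlusion_threshold = 0.5,
                       seed = seed)
  truth <- simulate_trajectories(config)
  frames <- render_frames(truth)
  geom <- bee_geometry(body_length = config$body_length,
                       body_width = config$body_width)
  shape <- c(arena, arena)
  targets <- lapply(seq_along(frames), function(i) {
    sub <- truth$detections[truth$detections$frame == i - 1L, ]
    ann <- bee_annotations(sub$x, sub$y, sub$b, sub$alpha)
    render_bee_targets(ann, shape, geom)
  })
  ratio <- background_foreground_ratio(lapply(targets, `[[`, "class_map"))
  for (i in seq_along(targets)) {
    sub <- truth$detections[truth$detections$frame == i - 1L, ]
    ann <- bee_annotations(sub$x, sub$y, sub$b, sub$alpha)
    targets[[i]]$weight_map <- render_weight_map(ann, shape, geom, ratio)
  }
  n <- length(frames)
  # midpoints of bee pairs closer than a body length: the crowded spots
  # where predicted blobs are at risk of fusing
  focus <- lapply(seq_len(n), function(i) {
    sub <- truth$detections[truth$detections$frame == i - 1L, ]
    if (nrow(sub) < 2)
      return(data.frame(x = numeric(0), y = numeric(0)))
    d <- as.matrix(stats::dist(cbind(sub$x, sub$y)))
    d[lower.tri(d, diag = TRUE)] <- Inf
    hits <- which(d < config$body_length, arr.ind = TRUE)
    data.frame(x = (sub$x[hits[, 1]] + sub$x[hits[, 2]]) / 2,
               y = (sub$y[hits[, 1]] + sub$y[hits[, 2]]) / 2)
  })
  list(config = config, truth = truth, frames = frames, targets = targets,
       geom = geom, ratio = ratio, focus = focus,
       train_idx = seq_len(n - 6L), test_idx = (n - 5L):n)
}

#' Train a detector on the benchmark scene
#'
#' Two-phase schedule: the class segmentation loss alone first (the
#' orientation regression destabilises early training), then a short
#' joint phase at a lower rate to fit the angle head. Training chains the
#' recurrent prior over the three preceding frames (`prior_depth = 3`),
#' which lets the network carry partially occluded bees, and biases half
#' of the training windows towards close bee pairs. The trained model
#' post-processes with fused-blob splitting enabled.
#'
#' @param scene A [detector_scene()].
#' @param seed Training seed (weight initialisation and crop sampling).
#' @param widths Encoder widths of the trained network.
#' @param iters Iterations of the two phases.
#' @param lrs Learning rates of the two phases.
#' @param crop Training window side in px.
#' @return A trained `bee_detector`.
#' @export
train_scene_detector <- function(scene, seed = 1L, widths = c(16, 32),
                                 iters = c(1500, 500),
                                 lrs = c(2e-3, 5e-4), crop = 48) {
  net <- build_network(detector_config(encoder_widths = widths,
                                       blob_split = TRUE),
                       seed = seed)
  bias <- scene$focus[scene$train_idx]
  net <- train_detector(net, scene$frames[scene$train_idx],
                        scene$targets[scene$train_idx],
                        n_iter = iters[1], lr = lrs[1], crop = crop,
                        angle_weight = 0, seed = seed, crop_bias = bias,
                        prior_depth = 3L)
  train_detector(net, scene$frames[scene$train_idx],
                 scene$targets[scene$train_idx],
                 n_iter = iters[2], lr = lrs[2], crop = crop,
                 angle_weight = 0.3, seed = seed + 1000L,
                 crop_bias = bias, prior_depth = 3L)
}

#' Evaluate a detector over the scene's held-out frames
#'
#' Frames are processed in order with the recurrent prior chained across
#' frames exactly as during training; detections on the held-out frames
#' are scored against the visible ground truth within half a body length.
#' Objects in the frame margin (within half a body length of the border)
#' are discarded from both sides before scoring — partially visible
#' objects at image borders are unreliable, which is the same reason
#' tiled inference discards its window margins.
#'
#' @param net A trained `bee_detector`.
#' @param scene The [detector_scene()] it was trained on.
#' @param test_frames Frame positions (1-based) to score; defaults to the
#'   scene's held-out frames.
#' @return List with mean `tpr`, `fpr` and the per-frame table.
#' @export
evaluate_scene_detector <- function(net, scene,
                                    test_frames = scene$test_idx) {
  prior <- NULL
  rows <- list()
  radius <- scene$geom$body_length / 2
  lo <- radius; hi <- scene$config$arena - 1 - radius
  interior <- function(df) df[df$x >= lo & df$x <= hi &
                              df$y >= lo & df$y <= hi, , drop = FALSE]
  for (i in seq_along(scene$frames)) {
    res <- detect_frame(net, scene$frames[[i]], prior)
    prior <- res$prior
    if (!i %in% test_frames) next
    d <- interior(maps_to_detections(res$class_map, res$angle_map,
                                     net$config))
    tr <- interior(scene$truth$detections[
      scene$truth$detections$frame == i - 1L, ])
    s <- detection_scores(d, tr, radius = radius)
    rows[[length(rows) + 1L]] <- data.frame(frame = i - 1L, tpr = s$tpr,
                                            fpr = s$fpr,
                                            n_detections = nrow(d),
                                            n_truth = nrow(tr))
  }
  per_frame <- do.call(rbind, rows)
  list(tpr = mean(per_frame$tpr), fpr = mean(per_frame$fpr),
       per_frame = per_frame)
}

#' Build the tracking benchmark scene
#'
#' 50 identities in a 512 px arena for 90 s at 10 FPS with occlusions, and
#' oracle appearance embeddings, isolating the matching procedure from
#' detector and embedder quality.
#'
#' @param seed Scene seed.
#' @return List with `truth`, `detections`, `embeddings`.
#' @export
tracking_scene <- function(seed = 7) {
  cfg <- sim_config(n_bees = 50, arena = 512, fps = 10, duration = 90,
                    occlusion_threshold = 0.5, dwell_rate = 0.01,
                    seed = seed)
  truth <- simulate_trajectories(cfg)
  list(truth = truth, detections = truth$detections,
       embeddings = oracle_embeddings(truth))
}
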