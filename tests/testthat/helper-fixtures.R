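# Shared fixtures, built in code. The heavier simulator scenes are
# memoised so several tests can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# brute-force oriented-ellipse membership oracle, independent of the
# renderer's vectorised implementation
ellipse_oracle <- function(x, y, alpha, sa, sb, shape) {
  a <- alpha * pi / 180
  u <- c(sin(a), -cos(a)); v <- c(cos(a), sin(a))
  out <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (cc in seq_len(shape[2])) {
      dx <- (cc - 1) - x; dy <- (r - 1) - y
      al <- dx * u[1] + dy * u[2]
      pe <- dx * v[1] + dy * v[2]
      out[r, cc] <- (al / sa)^2 + (pe / sb)^2 <= 1
    }
  }
  out
}

# a small colony with crossings and occlusions for tracker tests
tracker_scene <- function() {
  memo("tracker_scene", function() {
    cfg <- sim_config(n_bees = 20, arena = 320, fps = 10, duration = 75,
                      occlusion_threshold = 0.5, dwell_rate = 0.01,
                      seed = 5)
    truth <- simulate_trajectories(cfg)
    list(cfg = cfg, truth = truth, emb = oracle_embeddings(truth))
  })
}

# detections table for two well-separated slow bees over a few frames
two_bee_detections <- function(n_frames = 6, sep = 300) {
  fr <- rep(seq_len(n_frames) - 1L, each = 2)
  data.frame(frame = fr, t = fr / 10,
             x = ifelse(seq_along(fr) %% 2 == 1, 10, 10 + sep),
             y = 50, b = 1L, alpha = 0,
             id = rep(c(1L, 2L), n_frames))
}

expect_dataframe_equal <- function(a, b, tol = 1e-9) {
  expect_equal(nrow(a), nrow(b))
  for (nm in names(a)) expect_equal(a[[nm]], b[[nm]], tolerance = tol)
}
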