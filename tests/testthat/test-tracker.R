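test_that("distance cutoff follows the class-dependent rules", {
  p <- tracker_params()
  full <- data.frame(t = seq(0, 0.9, by = 0.1), b = rep(1L, 10))
  expect_equal(distance_cutoff(full, 1.0, p), 40)        # dt = 1 frame
  expect_equal(distance_cutoff(full, 1.3, p), 80)        # dt = 4 frames
  cell <- data.frame(t = seq(0, 0.9, by = 0.1), b = rep(2L, 10))
  expect_equal(distance_cutoff(cell, 1.0, p), 40 / 3)
  expect_equal(distance_cutoff(cell, 5.0, p), 40 / 3)    # dt-independent
  # majority over the last 10 positions decides
  mixed <- data.frame(t = seq(0, 1.1, by = 0.1),
                      b = c(1L, 1L, rep(2L, 4), rep(1L, 6)))
  expect_equal(distance_cutoff(mixed, 1.2, p), 40)
  expect_error(distance_cutoff(full, 0.5, p), "later")
})

test_that("length factor interpolates between A and 0", {
  expect_equal(length_factor(10, 10, 30), 0)
  expect_equal(length_factor(0, 10, 30), 30)
  expect_equal(length_factor(5, 10, 30), 15)
  expect_equal(length_factor(0, 0, 30), 0)
})

test_that("visual similarity is the window minimum of squared distances", {
  M <- matrix(0, 12, 4)
  for (i in 1:12) M[i, 1] <- i          # embeddings drift away
  det <- c(1, 0, 0, 0)                  # equals the oldest embedding
  # full history would give 0, but position n-11 is outside the window
  expect_equal(visual_similarity(M, det, lookback = 10), (3 - 1)^2)
  expect_equal(visual_similarity(M, M[12, ], lookback = 10), 0)
  expect_equal(visual_similarity(M[1, , drop = FALSE], det), 0)
  # brute-force window oracle on random data
  set.seed(4)
  E <- matrix(rnorm(15 * 8), 15, 8)
  v <- rnorm(8)
  oracle <- min(vapply(6:15, function(i) sum((E[i, ] - v)^2), numeric(1)))
  expect_equal(visual_similarity(E, v, lookback = 10), oracle)
})

test_that("pair cost combines terms by mode with the printed constants", {
  p <- tracker_params()
  expect_equal(pair_cost(30, V = 0.5, l = 0, mode = "embedding",
                         params = p), 0.033 * 30 + 0.5)
  expect_equal(pair_cost(10, l = 15, mode = "position", params = p), 25)
  d180 <- beetrackr:::angle_dissimilarity(0, 180)
  expect_equal(pair_cost(0, V = 0, l = 0, mode = "embedding+angle",
                         d_a = d180, params = p), 0.25)
  expect_error(pair_cost(1, V = NULL, mode = "embedding"), "requires V")
})

test_that("greedy matching extends, rejects and seeds correctly", {
  p <- tracker_params()
  tr <- beetrackr:::new_traj(1L, data.frame(frame = 0L, t = 0, x = 50,
                                            y = 50, b = 1L, alpha = 0), 1L)
  near <- data.frame(frame = 1L, t = 0.1, x = 60, y = 50, b = 1L,
                     alpha = 0)
  m <- match_frame(list(tr), near, p)
  expect_equal(m$pairs$traj, 1L)
  expect_equal(length(m$unmatched), 0)
  far <- data.frame(frame = 1L, t = 0.1, x = 200, y = 50, b = 1L,
                    alpha = 0)
  m2 <- match_frame(list(tr), far, p)
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(m2$unmatched, 1L)
})

test_that("embeddings resolve a crossing that fools position-only matching", {
  p <- tracker_params()
  mk <- function(id, x, row) beetrackr:::new_traj(
    id, data.frame(frame = 0L, t = 0, x = x, y = 50, b = 1L, alpha = 0),
    row)
  trajs <- list(mk(1L, 40, 1L), mk(2L, 60, 2L))
  # the bees crossed: detection near 60 belongs to bee 1, near 40 to bee 2
  dets <- data.frame(frame = 1L, t = 0.1, x = c(58, 42), y = 50, b = 1L,
                     alpha = 0)
  emb <- rbind(c(10, 0), c(0, 10),   # trajectory anchors (rows 1, 2)
               c(10, 0), c(0, 10))   # detections: det1 = bee1, det2 = bee2
  pos <- match_frame(trajs, dets, p, mode = "position")
  swap <- merge(pos$pairs, data.frame(traj = c(1, 2), det = c(2, 1)))
  expect_equal(nrow(swap), 2)        # position-only swaps the identities
  embm <- match_frame(trajs, dets, p, mode = "embedding",
                      embeddings = emb, det_rows = c(3L, 4L))
  good <- merge(embm$pairs, data.frame(traj = c(1, 2), det = c(1, 2)))
  expect_equal(nrow(good), 2)        # embeddings keep identities
})

test_that("greedy assignment is optimal on dominant-diagonal instances", {
  set.seed(12)
  perms <- function(n) {
    if (n == 1) return(matrix(1))
    p <- perms(n - 1)
    do.call(rbind, lapply(seq_len(n), function(k)
      cbind(k, matrix(ifelse(p >= k, p + 1, p), nrow(p)))))
  }
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    base <- runif(n, 0, 5)
    pos <- cumsum(runif(n, 60, 90))          # well-separated bees
    trajs <- lapply(seq_len(n), function(i) beetrackr:::new_traj(
      as.integer(i), data.frame(frame = 0L, t = 0, x = pos[i], y = 50,
                                b = 1L, alpha = 0), i))
    dets <- data.frame(frame = 1L, t = 0.1, x = pos + base, y = 50,
                       b = 1L, alpha = 0)
    m <- match_frame(trajs, dets, tracker_params(), mode = "position")
    got <- m$pairs[order(m$pairs$traj), "det"]
    # exhaustive assignment over all permutations of the same cost matrix
    E <- abs(outer(pos, dets$x, "-"))
    cd <- 40 * sqrt(1)
    pm <- perms(n)
    costs <- apply(pm, 1, function(pp) {
      e <- E[cbind(seq_len(n), pp)]
      if (any(e > cd)) Inf else sum(e)
    })
    best <- unname(pm[which.min(costs), ])
    expect_equal(as.integer(got), as.integer(best))
  }
})

test_that("gap cutoffs close trajectories by class and location", {
  p <- tracker_params(entrance = list(shape = "disk", x = 0, y = 0,
                                      r = 20))
  mk <- function(b, t0, t1, x = 100) {
    n <- round((t1 - t0) * 10) + 1
    ts <- seq(t0, t1, length.out = n)
    list(id = 1L, frames = seq_along(ts) - 1L, ts = ts,
         xs = rep(x, n), ys = rep(x, n), bs = rep(b, n),
         alphas = rep(0, n), rows = seq_along(ts))
  }
  # cell-bee trajectory at 8 s gap stays open (10 s rule)
  cell <- mk(2L, 0, 70)
  expect_equal(length(close_stale(list(cell), 78, p)$open), 1)
  # default trajectory: 3.1 s gap, 40 s span -> discarded
  short <- mk(1L, 0, 40)
  res <- close_stale(list(short), 43.2, p)
  expect_equal(length(res$discarded), 1)
  # entrance-adjacent trajectory: 1.1 s gap, 70 s span -> finished
  ent <- mk(1L, 0, 70, x = 5)
  res2 <- close_stale(list(ent), 71.2, p)
  expect_equal(length(res2$finished), 1)
  # default full-bee at 1.1 s gap elsewhere stays open
  mid <- mk(1L, 0, 70)
  expect_equal(length(close_stale(list(mid), 71.2, p)$open), 1)
})

test_that("a single gap-free bee yields one trajectory covering every frame", {
  n <- 3000                                  # 5 min at 10 FPS
  det <- data.frame(frame = 0:(n - 1), t = (0:(n - 1)) / 10,
                    x = 100 + cumsum(rnorm(n, 0, 0.5)), y = 100, b = 1L,
                    alpha = 0)
  tr <- track(det, tracker_params())
  expect_equal(length(unique(tr$trajectories$traj_id)), 1)
  expect_equal(nrow(tr$trajectories), n)
  expect_error(track(det[rev(seq_len(n)), ], tracker_params()), "sorted")
})

test_that("appearance rejections are monotone in the cutoff c_v", {
  sc <- tracker_scene()
  det <- sc$truth$detections
  emb <- sc$emb
  frames <- unique(det$frame)
  f <- frames[30]
  prev <- which(det$frame == f - 1L)
  cur <- which(det$frame == f)
  # pairs admissible by distance; count those rejected for appearance
  rejected <- function(c_v) {
    n <- 0
    for (i in prev) {
      E <- sqrt((det$x[cur] - det$x[i])^2 + (det$y[cur] - det$y[i])^2)
      ok <- cur[E <= 40]
      for (j in ok) {
        V <- sum((emb[i, ] - emb[j, ])^2)
        if (V >= c_v) n <- n + 1
      }
    }
    n
  }
  rej <- vapply(c(0.5, 1, 1.75, 3, 6), rejected, numeric(1))
  expect_true(all(diff(rej) <= 0))
})

test_that("trajectory scoring applies the 80% purity and coverage rules", {
  det <- two_bee_detections(n_frames = 20)
  # perfect split: one trajectory per bee
  perfect <- data.frame(traj_id = det$id, frame = det$frame, t = det$t,
                        x = det$x, y = det$y, b = det$b, alpha = det$alpha,
                        det_row = seq_len(nrow(det)))
  sc <- score_against_truth(perfect, det)
  expect_equal(sc$proportion_correct, 1)
  # 75% majority identity -> incorrect
  mixed_ids <- c(rep(1L, 15), rep(2L, 5))
  rows <- vapply(seq_len(20), function(k)
    which(det$frame == k - 1 & det$id == mixed_ids[k]), integer(1))
  mixed <- data.frame(traj_id = 9L, frame = det$frame[rows],
                      t = det$t[rows], x = det$x[rows], y = det$y[rows],
                      b = det$b[rows], alpha = det$alpha[rows],
                      det_row = rows)
  sc2 <- score_against_truth(mixed, det)
  expect_equal(sc2$n_correct, 0)
  # two half-length fragments of one identity count at most once
  rows1 <- which(det$id == 1L)
  half <- data.frame(traj_id = rep(c(1L, 2L), each = 10),
                     frame = det$frame[rows1], t = det$t[rows1],
                     x = det$x[rows1], y = det$y[rows1], b = det$b[rows1],
                     alpha = det$alpha[rows1], det_row = rows1)
  sc3 <- score_against_truth(half, det, coverage = 0.3)
  expect_lte(sc3$n_correct, 1)
})

test_that("lower frame rates degrade trajectory recovery", {
  sc <- tracker_scene()
  det <- sc$truth$detections
  full <- track(det, tracker_params(), mode = "embedding",
                embeddings = sc$emb)
  s_full <- score_against_truth(full, det)
  keep <- det$frame %% 5 == 0                # 10 -> 2 FPS
  det2 <- det[keep, ]
  emb2 <- sc$emb[keep, , drop = FALSE]
  slow <- track(det2, tracker_params(fps = 2), mode = "embedding",
                embeddings = emb2)
  s_slow <- score_against_truth(slow, det2)
  expect_lt(s_slow$proportion_correct, s_full$proportion_correct)
})

test_that("segment-parallel tracking matches sequential tracking", {
  # single isolated bee: identical output
  n <- 1500
  det <- data.frame(frame = 0:(n - 1), t = (0:(n - 1)) / 10,
                    x = 100, y = 100, b = 1L, alpha = 0)
  seq_tr <- track(det, tracker_params())
  par_tr <- track_parallel(det, tracker_params(), segment = 60)
  expect_equal(nrow(par_tr$trajectories), nrow(seq_tr$trajectories))
  expect_equal(sort(par_tr$trajectories$det_row),
               sort(seq_tr$trajectories$det_row))
  # simulator scene: at least 95% of trajectories identical
  sc <- tracker_scene()
  dets <- sc$truth$detections
  a <- track(dets, tracker_params(), mode = "embedding",
             embeddings = sc$emb)
  b <- track_parallel(dets, tracker_params(), mode = "embedding",
                      embeddings = sc$emb, segment = 60)
  sig <- function(tr) vapply(split(tr$trajectories$det_row,
                                   tr$trajectories$traj_id),
                             function(r) paste(sort(r), collapse = ","),
                             character(1))
  sa <- sig(a); sb <- sig(b)
  expect_gte(mean(sa %in% sb), 0.95)
})
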