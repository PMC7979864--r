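test_that("parameter counting matches an independent layer-by-layer sum", {
  # single 3x3 convolution, 1 -> 16 channels, with bias
  expect_equal(count_parameters(data.frame(name = "c", k = 3, cin = 1,
                                           cout = 16)), 160)
  # original widths: independent spreadsheet-style sum over the layer list
  w <- c(64, 128, 256, 512, 1024)
  conv3 <- function(cin, cout) 9 * cin * cout + cout
  conv1 <- function(cin, cout) cin * cout + cout
  manual <- conv3(1, 64) + conv3(64, 64) +            # enc1
    conv3(64, 128) + conv3(128, 128) +                # enc2
    conv3(128, 256) + conv3(256, 256) +               # enc3
    conv3(256, 512) + conv3(512, 512) +               # enc4
    conv3(512, 1024) + conv3(1024, 1024) +            # bottleneck
    conv3(1024, 512) + conv3(1024, 512) + conv3(512, 512) +   # dec4
    conv3(512, 256) + conv3(512, 256) + conv3(256, 256) +     # dec3
    conv3(256, 128) + conv3(256, 128) + conv3(128, 128) +     # dec2
    conv3(128, 64) + conv3(128, 64) + conv3(64, 64) +         # dec1
    conv1(64, 3) + conv1(64, 1)                               # heads
  cfg <- detector_config(encoder_widths = w, recurrent = FALSE)
  expect_equal(count_parameters(cfg), manual)
})

test_that("the reduced recurrent network keeps under 7% of the original parameters", {
  original <- count_parameters(detector_config(
    encoder_widths = c(64, 128, 256, 512, 1024), recurrent = FALSE))
  reduced <- count_parameters(detector_config())  # 16..256, recurrent
  expect_lte(reduced / original, 0.07)
  expect_equal(1 - reduced / original, 0.94, tolerance = 0.01)
  net <- build_network(detector_config(encoder_widths = c(4, 8),
                                       tile = 16, tile_margin = 2))
  expect_equal(net$n_parameters,
               sum(vapply(net$params, function(p)
                 length(p$W) + length(p$b), numeric(1))))
})

test_that("class loss is weighted cross-entropy averaged over pixels", {
  cm <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  perfect <- array(0, c(2, 2, 3))
  for (i in 1:2) for (j in 1:2) perfect[i, j, cm[i, j] + 1] <- 50
  expect_lt(class_loss(perfect, cm), 1e-10)
  uniform <- array(0, c(2, 2, 3))
  expect_equal(class_loss(uniform, cm), log(3), tolerance = 1e-12)
  w <- matrix(2, 2, 2)
  expect_equal(class_loss(uniform, cm, w), 2 * log(3), tolerance = 1e-12)
  expect_error(class_loss(uniform, matrix(3L, 2, 2)), "0..2")
})

test_that("angle loss is the periodic sin^2 of half the difference", {
  am <- matrix(40, 2, 2)
  expect_equal(angle_loss(matrix(40, 2, 2), am), 0)
  expect_equal(angle_loss(matrix(220, 2, 2), am), 1)
  expect_equal(angle_loss(matrix(130, 2, 2), am), 0.5)
  # period-360 and symmetry
  expect_equal(angle_loss(matrix(40 + 360 + 17, 2, 2), am),
               angle_loss(matrix(40 + 17, 2, 2), am))
  expect_equal(angle_loss(matrix(17, 2, 2), matrix(40, 2, 2)),
               angle_loss(matrix(40, 2, 2), matrix(17, 2, 2)))
  expect_equal(angle_loss(matrix(90, 2, 2), matrix(-1, 2, 2)), 0)
})

test_that("blob post-processing recovers rendered annotations", {
  # too-small blobs are dropped
  cm <- matrix(0L, 32, 32); cm[10:14, 10] <- 1L       # 5 px
  am <- matrix(-1, 32, 32); am[cm == 1L] <- 90
  expect_equal(nrow(maps_to_detections(cm, am)), 0)
  # noiseless render -> detection round trip
  ann <- bee_annotations(c(40, 100, 70), c(40, 60, 110), c(1, 1, 2),
                         c(30, 200, 0))
  tg <- render_bee_targets(ann, c(160, 160))
  det <- maps_to_detections(tg$class_map, tg$angle_map)
  det <- det[order(det$x), ]
  ord <- order(ann$x)
  expect_equal(det$x, ann$x[ord], tolerance = 1)
  expect_equal(det$y, ann$y[ord], tolerance = 1)
  expect_identical(det$b, ann$b[ord])
  full <- det$b == 1
  d <- abs(det$alpha[full] - ann$alpha[ord][full])
  expect_true(all(pmin(d, 360 - d) <= 1))
})

test_that("fused-blob splitting separates touching blobs and spares thin ones", {
  # two elliptical blobs bridged by a 1-px neck fuse into one component;
  # with blob_split they come apart at the eroded core
  ann <- bee_annotations(c(60, 74), c(40, 40), c(1, 1), c(0, 0))
  tg <- render_bee_targets(ann, c(96, 128))
  cm <- tg$class_map
  cm[41, 66:70] <- 1L                    # bridge the gap
  am <- tg$angle_map; am[41, 66:70] <- 0
  plain <- maps_to_detections(cm, am, detector_config())
  expect_equal(nrow(plain), 1)           # contiguous reading: one mark
  split <- maps_to_detections(cm, am, detector_config(blob_split = TRUE))
  expect_equal(nrow(split), 2)
  expect_equal(sort(split$x), c(60, 74), tolerance = 0.05)
  # a thin 2-px-wide blob has no eroded core and is kept whole
  cm2 <- matrix(0L, 40, 40); cm2[10:30, 20:21] <- 1L
  am2 <- matrix(-1, 40, 40); am2[cm2 == 1L] <- 0
  thin <- maps_to_detections(cm2, am2, detector_config(blob_split = TRUE))
  expect_equal(nrow(thin), 1)
  # splitting is a no-op on clean rendered targets
  ann3 <- bee_annotations(c(40, 100), c(40, 60), c(1, 2), c(30, 0))
  tg3 <- render_bee_targets(ann3, c(128, 128))
  a <- maps_to_detections(tg3$class_map, tg3$angle_map, detector_config())
  b <- maps_to_detections(tg3$class_map, tg3$angle_map,
                          detector_config(blob_split = TRUE))
  expect_equal(a, b)
})

test_that("predicted pixel angles disambiguate the principal axis half-turn", {
  # vertical blob whose pixel angles all say 180: the PCA axis (0 mod 180)
  # must be flipped to 180
  cm <- matrix(0L, 40, 40)
  cm[10:30, 20] <- 1L
  cm[10:30, 21] <- 1L
  am <- matrix(-1, 40, 40); am[cm == 1L] <- 180
  det <- maps_to_detections(cm, am)
  expect_equal(det$alpha, 180, tolerance = 1)
})

test_that("round trip holds across random non-overlapping layouts", {
  set.seed(17)
  for (rep in 1:4) {
    repeat {
      n <- 5
      x <- runif(n, 25, 230); y <- runif(n, 25, 230)
      if (min(dist(cbind(x, y))) > 85) break
    }
    bs <- sample(1:2, n, TRUE)
    al <- ifelse(bs == 1, floor(runif(n, 0, 360)), 0)
    ann <- bee_annotations(x, y, bs, al)
    tg <- render_bee_targets(ann, c(256, 256))
    det <- maps_to_detections(tg$class_map, tg$angle_map)
    expect_equal(nrow(det), n)
    for (i in seq_len(n)) {
      j <- which.min((det$x - ann$x[i])^2 + (det$y - ann$y[i])^2)
      expect_lt(abs(det$x[j] - ann$x[i]), 1)
      expect_lt(abs(det$y[j] - ann$y[i]), 1)
      expect_identical(det$b[j], ann$b[i])
      if (ann$b[i] == 1) {
        d <- abs(det$alpha[j] - ann$alpha[i])
        expect_lte(min(d, 360 - d), 1)
      }
    }
  }
})

test_that("tiled inference stitches to the whole-frame result", {
  # oracle predictor: the "image" is the rendered class map itself
  set.seed(3)
  shape <- c(700, 700)
  # one bee centred exactly on the interior tile boundary (row 462 for
  # tile 512 / margin 50), others scattered
  ann <- bee_annotations(c(100, 462, 600, 330), c(462, 330, 100, 600),
                         c(1, 1, 2, 1), c(45, 120, 0, 300))
  tg <- render_bee_targets(ann, shape)
  img <- tg$class_map + 0
  angle_img <- tg$angle_map
  predict_fn <- function(x, prior) {
    list(class_map = round(x),
         angle_map = matrix(-1, nrow(x), ncol(x)), prior = NULL)
  }
  res <- infer_tiled(img, predict_fn, tile = 512, tile_margin = 50)
  expect_identical(res$class_map, round(img))
  whole <- maps_to_detections(tg$class_map, tg$angle_map)
  tiled <- maps_to_detections(res$class_map, angle_img)
  expect_equal(nrow(tiled), nrow(whole))
  expect_equal(tiled[order(tiled$x), c("x", "y", "b")],
               whole[order(whole$x), c("x", "y", "b")],
               tolerance = 1e-9, ignore_attr = TRUE)
  # a frame that fits one tile is returned untouched
  one <- infer_tiled(img[1:512, 1:512], predict_fn)
  expect_identical(one$class_map, round(img[1:512, 1:512]))
  # blank frame yields no detections
  blank <- infer_tiled(matrix(0, 700, 700), predict_fn, 512, 50)
  expect_equal(nrow(maps_to_detections(blank$class_map, blank$angle_map)),
               0)
})

test_that("fine-tuning respects n_iter = 0 and lr = 0 and reduces the loss", {
  set.seed(9)
  cfg <- sim_config(n_bees = 4, arena = 64, duration = 0.5,
                    body_length = 20, body_width = 8, seed = 2)
  truth <- simulate_trajectories(cfg)
  frames <- render_frames(truth)
  geom <- bee_geometry(body_length = 20, body_width = 8)
  targets <- lapply(seq_along(frames), function(i) {
    sub <- truth$detections[truth$detections$frame == i - 1L, ]
    render_bee_targets(bee_annotations(sub$x, sub$y, sub$b, sub$alpha),
                       c(64, 64), geom)
  })
  net <- build_network(detector_config(encoder_widths = c(4, 8)), seed = 1)
  expect_identical(fine_tune(net, frames, targets, n_iter = 0)$params,
                   net$params)
  frozen <- fine_tune(net, frames, targets, n_iter = 2, lr = 0)
  expect_equal(frozen$params, net$params, tolerance = 1e-12)
  expect_error(fine_tune(net, list(), list(), 10), "no labelled frames")
  tuned <- fine_tune(net, frames, targets, n_iter = 10, lr = 1e-3)
  lh <- tuned$loss_history
  k <- length(frames)
  expect_lt(mean(tail(lh, k)), mean(head(lh, k)))
})

test_that("background extraction recovers the static scene", {
  const <- replicate(4, matrix(0.4, 16, 16), simplify = FALSE)
  expect_equal(extract_background(const), matrix(0.4, 16, 16))
  expect_error(extract_background(const[1:2]), ">= 3")
  # moving synthetic bees over a known comb: background within noise
  cfg <- sim_config(n_bees = 3, arena = 96, duration = 4, speed_mean = 6,
                    body_length = 20, body_width = 8, noise_sd = 0.01,
                    seed = 8)
  truth <- simulate_trajectories(cfg)
  frames <- render_frames(truth)
  bg_true <- beetrackr:::comb_background(96)
  bg <- extract_background(frames[seq(1, 40, by = 4)])
  expect_lt(median(abs(bg - bg_true)), 0.02)
  # an always-moving pixel falls back to the plain median
  fr <- lapply(1:5, function(i) matrix(i / 10, 8, 8))
  bg2 <- extract_background(fr, motion_thresh = 0.01)
  expect_equal(bg2, matrix(0.3, 8, 8))
})

test_that("brood centres are recovered from segmentation masks", {
  ann <- data.frame(x = c(30, 80), y = c(40, 20))
  br <- render_brood_targets(ann, c(101, 101))
  cells <- brood_mask_to_cells(br$mask)
  cells <- cells[order(cells$x), ]
  expect_equal(cells$x, ann$x, tolerance = 1)
  expect_equal(cells$y, ann$y, tolerance = 1)
  expect_equal(nrow(brood_mask_to_cells(matrix(FALSE, 50, 50))), 0)
  # two tangent cells merge into one blob with a centre at the midpoint
  tang <- render_brood_targets(data.frame(x = c(40, 60), y = c(50, 50)),
                               c(101, 101))
  merged <- brood_mask_to_cells(tang$mask)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$x, 50, tolerance = 1)
})
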