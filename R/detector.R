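# The segmentation detector: a U-shaped encoder-decoder with an optional
# recurrent component (the penultimate feature map of the previous frame is
# concatenated with the current penultimate features before the output
# heads), a weighted 3-class cross-entropy loss for class segmentation and a
# periodic sin^2 loss for body-orientation regression.

#' Detector configuration
#'
#' @param encoder_widths Filter counts per resolution level, strictly
#'   increasing. The compact default (16/32/64/128/256) is one quarter of
#'   the original encoder-decoder widths (64/128/256/512/1024) at every
#'   level, which together with the recurrent component reduces the
#'   parameter count by roughly 94%.
#' @param n_classes Number of segmentation classes including background.
#' @param recurrent Concatenate the previous frame's penultimate features
#'   before the output heads.
#' @param in_channels Image channels (1 for grayscale).
#' @param tile,tile_margin Tiled-inference window size and overlap margin in
#'   px; objects whose pixels fall in a tile margin are attributed to the
#'   neighbouring tile.
#' @param blob_min,blob_max Connected foreground components with areas
#'   outside this range (px) are discarded as likely errors.
#' @param blob_split Split fused foreground components whose eroded core
#'   falls apart into several parts (nearest-core pixel reassignment).
#'   Off by default: with a sharp model each contiguous region is one
#'   bee; small models benefit from splitting blobs of adjacent bees
#'   whose predictions bleed together.
#' @param lr Base learning rate of the adaptive-moment optimizer.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(encoder_widths = c(16, 32, 64, 128, 256),
                            n_classes = 3, recurrent = TRUE,
                            in_channels = 1,
                            tile = 512, tile_margin = 50,
                            blob_min = 10, blob_max = 1000,
                            blob_split = FALSE,
                            lr = 1e-4) {
  stopifnot(length(encoder_widths) >= 1, all(diff(encoder_widths) > 0),
            tile_margin < tile / 2, blob_min < blob_max, lr >= 0)
  structure(list(encoder_widths = as.integer(encoder_widths),
                 n_classes = as.integer(n_classes),
                 recurrent = isTRUE(recurrent),
                 in_channels = as.integer(in_channels),
                 tile = as.integer(tile), tile_margin = as.integer(tile_margin),
                 blob_min = blob_min, blob_max = blob_max,
                 blob_split = isTRUE(blob_split), lr = lr),
            class = "detector_config")
}

#' Layer table of the segmentation network
#'
#' Enumerates every parameterised layer: two 3x3 convolutions per encoder
#' level with 2x2 max pooling between levels, a decoder mirroring the
#' encoder (2x2 nearest-neighbour upsampling followed by a channel-halving
#' 3x3 convolution, concatenation with the encoder skip, and two 3x3
#' convolutions), and two 1x1 output heads (class logits and orientation
#' angle) reading the penultimate feature map — doubled in channels when the
#' recurrent prior is concatenated.
#'
#' @param config A [detector_config()].
#' @return A `data.frame` with columns `name`, `k`, `cin`, `cout`.
#' @export
network_layers <- function(config) {
  w <- config$encoder_widths
  L <- length(w)
  rows <- list()
  add <- function(name, k, cin, cout)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, k = k,
                                             cin = cin, cout = cout)
  for (i in seq_len(L)) {
    cin <- if (i == 1L) config$in_channels else w[i - 1L]
    add(sprintf("enc%da", i), 3L, cin, w[i])
    add(sprintf("enc%db", i), 3L, w[i], w[i])
  }
  if (L > 1L) for (i in L:2) {
    add(sprintf("up%d", i), 3L, w[i], w[i - 1L])
    add(sprintf("dec%da", i - 1L), 3L, 2L * w[i - 1L], w[i - 1L])
    add(sprintf("dec%db", i - 1L), 3L, w[i - 1L], w[i - 1L])
  }
  head_in <- if (config$recurrent) 2L * w[1L] else w[1L]
  add("head_class", 1L, head_in, config$n_classes)
  add("head_angle", 1L, head_in, 1L)
  do.call(rbind, rows)
}

#' Count trainable parameters of a detector configuration
#'
#' Closed-form sum of `k^2 * cin * cout + cout` over the layer table.
#'
#' @param config A [detector_config()] or the layer table itself.
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  layers <- if (is.data.frame(config)) config else network_layers(config)
  sum(layers$k^2 * layers$cin * layers$cout + layers$cout)
}

#' Build a segmentation network
#'
#' @param config A [detector_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `bee_detector` mapping
#'   `(image, prior state) -> (class logits, angle map, new prior state)`;
#'   `$n_parameters` holds the trainable-parameter count.
#' @export
build_network <- function(config = detector_config(), seed = 1L) {
  spec <- network_layers(config)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- list()
  for (i in seq_len(nrow(spec))) {
    l <- spec[i, ]
    params[[l$name]] <- if (l$k == 3L) init_conv3(l$cin, l$cout)
                        else init_conv1(l$cin, l$cout)
  }
  structure(list(config = config, spec = spec, params = params,
                 n_parameters = count_parameters(spec)),
            class = "bee_detector")
}

# number of 2x downsamplings the input must survive
net_depth_factor <- function(config) 2L^(length(config$encoder_widths) - 1L)

zero_prior <- function(net, h, w) array(0, c(h, w, net$config$encoder_widths[1]))

# Full forward pass. `prior` is the previous frame's penultimate feature map
# (zeros for the first frame). With train = TRUE all intermediates needed
# for backpropagation are cached.
unet_forward <- function(net, x, prior = NULL, train = FALSE) {
  x <- as_tensor(x)
  cfg <- net$config
  p <- net$params
  L <- length(cfg$encoder_widths)
  d <- dim(x)
  f <- net_depth_factor(cfg)
  if (d[1] %% f != 0 || d[2] %% f != 0)
    stop(sprintf("input size %dx%d must be a multiple of %d", d[1], d[2], f))
  enc <- vector("list", L)
  cur <- x
  for (i in seq_len(L)) {
    fa <- conv3_forward(cur, p[[sprintf("enc%da", i)]], cache = train)
    ya <- relu_forward(fa$y)
    fb <- conv3_forward(ya, p[[sprintf("enc%db", i)]], cache = train)
    yb <- relu_forward(fb$y)
    pool <- if (i < L) maxpool2_forward(yb) else NULL
    enc[[i]] <- list(input = if (train) cur else NULL, fa = fa, ya = ya,
                     fb = fb, yb = yb, pool = pool)
    cur <- if (i < L) pool$y else yb
  }
  dec <- vector("list", L)
  if (L > 1L) for (i in L:2) {
    up <- upsample2_forward(cur)
    fu <- conv3_forward(up, p[[sprintf("up%d", i)]], cache = train)
    yu <- relu_forward(fu$y)
    cat_ <- concat_channels(yu, enc[[i - 1L]]$yb)
    fa <- conv3_forward(cat_, p[[sprintf("dec%da", i - 1L)]], cache = train)
    ya <- relu_forward(fa$y)
    fb <- conv3_forward(ya, p[[sprintf("dec%db", i - 1L)]], cache = train)
    yb <- relu_forward(fb$y)
    dec[[i]] <- list(fu = fu, yu = yu, fa = fa, ya = ya, fb = fb, yb = yb)
    cur <- yb
  }
  penult <- cur
  if (cfg$recurrent) {
    if (is.null(prior)) prior <- zero_prior(net, d[1], d[2])
    if (!all(dim(prior) == dim(penult)))
      stop("prior state shape does not match the penultimate layer")
    head_in <- concat_channels(penult, prior)
  } else head_in <- penult
  logits <- conv1_forward(head_in, p$head_class)
  angle <- conv1_forward(head_in, p$head_angle)[, , 1]
  list(logits = logits, angle = angle, prior = penult,
       caches = if (train) list(enc = enc, dec = dec, head_in = head_in,
                                x = x) else NULL)
}

# Backpropagation matching unet_forward. The prior path is treated as a
# constant input (no backpropagation through time).
unet_backward <- function(net, fwd, d_logits, d_angle) {
  cfg <- net$config
  p <- net$params
  L <- length(cfg$encoder_widths)
  cc <- fwd$caches
  grads <- list()
  w1 <- cfg$encoder_widths[1]
  da <- d_angle
  dim(da) <- c(dim(da), 1L)
  g1 <- conv1_backward(cc$head_in, p$head_class, d_logits)
  g2 <- conv1_backward(cc$head_in, p$head_angle, da)
  grads$head_class <- list(W = g1$dW, b = g1$db)
  grads$head_angle <- list(W = g2$dW, b = g2$db)
  d_head_in <- g1$dx + g2$dx
  d_cur <- if (cfg$recurrent) d_head_in[, , seq_len(w1), drop = FALSE]
           else d_head_in
  d_skip <- vector("list", L)
  if (L > 1L) for (i in 2:L) {
    dc <- cc$dec[[i]]
    wlev <- cfg$encoder_widths[i - 1L]
    d_fb <- relu_backward(dc$fb$y, d_cur)
    gb <- conv3_backward(dc$fb, p[[sprintf("dec%db", i - 1L)]], d_fb)
    grads[[sprintf("dec%db", i - 1L)]] <- list(W = gb$dW, b = gb$db)
    d_fa <- relu_backward(dc$fa$y, gb$dx)
    ga <- conv3_backward(dc$fa, p[[sprintf("dec%da", i - 1L)]], d_fa)
    grads[[sprintf("dec%da", i - 1L)]] <- list(W = ga$dW, b = ga$db)
    d_cat <- ga$dx
    d_yu <- d_cat[, , seq_len(wlev), drop = FALSE]
    d_skip[[i - 1L]] <- d_cat[, , wlev + seq_len(wlev), drop = FALSE]
    d_fu <- relu_backward(dc$fu$y, d_yu)
    gu <- conv3_backward(dc$fu, p[[sprintf("up%d", i)]], d_fu)
    grads[[sprintf("up%d", i)]] <- list(W = gu$dW, b = gu$db)
    d_cur <- upsample2_backward(gu$dx)
  }
  for (i in L:1) {
    ec <- cc$enc[[i]]
    d_yb <- if (i == L) d_cur
            else maxpool2_backward(ec$pool, d_cur) + d_skip[[i]]
    d_fb <- relu_backward(ec$fb$y, d_yb)
    gb <- conv3_backward(ec$fb, p[[sprintf("enc%db", i)]], d_fb)
    grads[[sprintf("enc%db", i)]] <- list(W = gb$dW, b = gb$db)
    d_fa <- relu_backward(ec$fa$y, gb$dx)
    ga <- conv3_backward(ec$fa, p[[sprintf("enc%da", i)]], d_fa)
    grads[[sprintf("enc%da", i)]] <- list(W = ga$dW, b = ga$db)
    d_cur <- ga$dx
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Weighted multi-class segmentation loss
#'
#' Per-pixel cross-entropy of the softmax over class logits, multiplied by
#' the pixel weight map and averaged over all pixels.
#'
#' @param logits Array `[H, W, n_classes]` of class scores.
#' @param class_map Integer matrix of true classes in `0:(n_classes - 1)`.
#' @param weight_map Positive matrix of per-pixel loss weights (default 1).
#' @return Non-negative scalar.
#' @export
class_loss <- function(logits, class_map, weight_map = NULL) {
  class_loss_grad(logits, class_map, weight_map, grad = FALSE)$loss
}

class_loss_grad <- function(logits, class_map, weight_map = NULL,
                            grad = TRUE) {
  d <- dim(logits)
  k <- d[3]
  if (any(class_map < 0) || any(class_map > k - 1))
    stop(sprintf("class labels must lie in 0..%d", k - 1))
  n <- d[1] * d[2]
  if (is.null(weight_map)) weight_map <- matrix(1, d[1], d[2])
  z <- matrix(logits, n, k)
  pr <- softmax_rows(z)
  y <- as.integer(class_map) + 1L
  iy <- cbind(seq_len(n), y)
  w <- as.vector(weight_map)
  loss <- sum(w * -log(pmax(pr[iy], 1e-12))) / n
  out <- list(loss = loss)
  if (grad) {
    g <- pr
    g[iy] <- g[iy] - 1
    g <- g * (w / n)
    dim(g) <- d
    out$grad <- g
  }
  out
}

#' Circular orientation loss
#'
#' Mean of `sin((predicted - true) / 2)^2` over foreground pixels (where the
#' angle map is not -1), with the angle difference taken in radians. The
#' loss has period 360 degrees and equals 1 for a 180-degree error. An empty
#' foreground yields 0.
#'
#' @param pred Numeric matrix of predicted angles in degrees.
#' @param angle_map True angle map in degrees, -1 on background.
#' @return Scalar in `[0, 1]`.
#' @export
angle_loss <- function(pred, angle_map) {
  angle_loss_grad(pred, angle_map, grad = FALSE)$loss
}

angle_loss_grad <- function(pred, angle_map, grad = TRUE) {
  fg <- angle_map != -1
  nfg <- sum(fg)
  if (nfg == 0) {
    out <- list(loss = 0)
    if (grad) out$grad <- matrix(0, nrow(pred), ncol(pred))
    return(out)
  }
  dlt <- (pred - angle_map) * pi / 180
  s <- sin(dlt / 2)
  loss <- sum((s^2)[fg]) / nfg
  out <- list(loss = loss)
  if (grad) {
    g <- matrix(0, nrow(pred), ncol(pred))
    g[fg] <- (0.5 * sin(dlt) * pi / 180)[fg] / nfg
    out$grad <- g
  }
  out
}

# ---- training --------------------------------------------------------------

take_crop <- function(m, r0, c0, h, w) m[r0:(r0 + h - 1L), c0:(c0 + w - 1L)]

#' Train a detector on labelled frames
#'
#' Stochastic training on randomly cropped windows. When the network is
#' recurrent and the sampled frame has predecessors, the same window of the
#' `prior_depth` preceding frames is passed through the network first,
#' chaining the penultimate feature map from frame to frame, to produce
#' the prior for the trained step (the chain is treated as constant, i.e.
#' truncated backpropagation). Chained priors are what let the network
#' carry a bee's presence through partial occlusion.
#'
#' @param net A [build_network()] model.
#' @param frames List of grayscale image matrices in `[0, 1]`.
#' @param targets List (parallel to `frames`) of lists with `class_map`,
#'   `angle_map` and optional `weight_map`.
#' @param n_iter Number of optimisation steps.
#' @param lr Learning rate (default from the config).
#' @param crop Window side in px (multiple of the depth factor); `NULL`
#'   trains on full frames.
#' @param angle_weight Weight of the orientation loss in the total loss.
#' @param seed Seed controlling window sampling.
#' @param crop_bias Optional list (parallel to `frames`) of `data.frame`s
#'   with `x`, `y` focus points (e.g. midpoints of close bee pairs): half
#'   of the sampled windows are centred on a random focus point, a simple
#'   curriculum that concentrates gradient on crowded regions where
#'   foreground blobs are hardest to keep separate.
#' @param prior_depth Number of preceding frames chained to build the
#'   recurrent prior of the trained step.
#' @return The updated model, with `$loss_history`.
#' @export
train_detector <- function(net, frames, targets, n_iter, lr = NULL,
                           crop = NULL, angle_weight = 1, seed = 1L,
                           crop_bias = NULL, prior_depth = 1L) {
  if (length(frames) == 0) stop("no labelled frames supplied")
  stopifnot(length(frames) == length(targets))
  if (is.null(lr)) lr <- net$config$lr
  if (n_iter == 0) return(net)
  f <- net_depth_factor(net$config)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  state <- adam_init(net$params)
  losses <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    fi <- sample.int(length(frames), 1L)
    img <- frames[[fi]]
    tgt <- targets[[fi]]
    h <- nrow(img); w <- ncol(img)
    if (!is.null(crop) && (crop < h || crop < w)) {
      ch <- min(crop, h %/% f * f); cw <- min(crop, w %/% f * f)
      focus <- if (is.null(crop_bias)) NULL else crop_bias[[fi]]
      if (!is.null(focus) && nrow(focus) && stats::runif(1) < 0.5) {
        p <- focus[sample.int(nrow(focus), 1L), ]
        r0 <- min(max(1L, round(p$y) + 1L - ch %/% 2L), h - ch + 1L)
        c0 <- min(max(1L, round(p$x) + 1L - cw %/% 2L), w - cw + 1L)
      } else {
        r0 <- sample.int(h - ch + 1L, 1L); c0 <- sample.int(w - cw + 1L, 1L)
      }
    } else {
      ch <- h %/% f * f; cw <- w %/% f * f; r0 <- 1L; c0 <- 1L
    }
    x <- take_crop(img, r0, c0, ch, cw)
    cm <- take_crop(tgt$class_map, r0, c0, ch, cw)
    am <- take_crop(tgt$angle_map, r0, c0, ch, cw)
    wm <- if (is.null(tgt$weight_map)) NULL
          else take_crop(tgt$weight_map, r0, c0, ch, cw)
    prior <- NULL
    if (net$config$recurrent && fi > 1L) {
      first <- max(1L, fi - prior_depth)
      for (pf in first:(fi - 1L)) {
        prev <- take_crop(frames[[pf]], r0, c0, ch, cw)
        prior <- unet_forward(net, prev, prior = prior)$prior
      }
    }
    fwd <- unet_forward(net, x, prior = prior, train = TRUE)
    cl <- class_loss_grad(fwd$logits, cm, wm)
    al <- angle_loss_grad(fwd$angle, am)
    losses[it] <- cl$loss + angle_weight * al$loss
    grads <- unet_backward(net, fwd, cl$grad, angle_weight * al$grad)
    upd <- adam_step(net$params, grads, state, lr)
    net$params <- upd$params
    state <- upd$state
  }
  net$loss_history <- c(net$loss_history, losses)
  net
}

#' Fine-tune a detector on a small set of labelled frames
#'
#' Deterministic full-frame passes over the labelled frames, `n_iter`
#' epochs (default 10) at the configured base learning rate.
#'
#' @inheritParams train_detector
#' @param n_iter Number of epochs over the frames.
#' @return The updated model.
#' @export
fine_tune <- function(net, frames, targets, n_iter = 10, lr = 1e-4,
                      angle_weight = 1) {
  if (length(frames) == 0) stop("no labelled frames supplied")
  stopifnot(length(frames) == length(targets))
  if (n_iter == 0) return(net)
  f <- net_depth_factor(net$config)
  state <- adam_init(net$params)
  losses <- c()
  for (ep in seq_len(n_iter)) {
    prior <- NULL
    for (fi in seq_along(frames)) {
      img <- frames[[fi]]
      ch <- nrow(img) %/% f * f; cw <- ncol(img) %/% f * f
      x <- take_crop(img, 1L, 1L, ch, cw)
      tgt <- targets[[fi]]
      cm <- take_crop(tgt$class_map, 1L, 1L, ch, cw)
      am <- take_crop(tgt$angle_map, 1L, 1L, ch, cw)
      wm <- if (is.null(tgt$weight_map)) NULL
            else take_crop(tgt$weight_map, 1L, 1L, ch, cw)
      fwd <- unet_forward(net, x, prior = prior, train = TRUE)
      cl <- class_loss_grad(fwd$logits, cm, wm)
      al <- angle_loss_grad(fwd$angle, am)
      losses <- c(losses, cl$loss + angle_weight * al$loss)
      grads <- unet_backward(net, fwd, cl$grad, angle_weight * al$grad)
      upd <- adam_step(net$params, grads, state, lr)
      net$params <- upd$params
      state <- upd$state
      prior <- if (net$config$recurrent) fwd$prior else NULL
    }
  }
  net$loss_history <- c(net$loss_history, losses)
  net
}

# ---- inference -------------------------------------------------------------

#' Run the network on one full frame
#'
#' Pads the frame to a multiple of the network's downsampling factor,
#' evaluates it, and crops the maps back.
#'
#' @param net A `bee_detector`.
#' @param image Grayscale matrix in `[0, 1]`.
#' @param prior Previous-frame prior state or `NULL` (zeros).
#' @return List with `class_map` (argmax classes), `angle_map` (predicted
#'   degrees) and `prior` for the next frame.
#' @export
detect_frame <- function(net, image, prior = NULL) {
  f <- net_depth_factor(net$config)
  h <- nrow(image); w <- ncol(image)
  hp <- ceiling(h / f) * f; wp <- ceiling(w / f) * f
  xp <- matrix(0, hp, wp)
  xp[seq_len(h), seq_len(w)] <- image
  if (!is.null(prior) && !all(dim(prior)[1:2] == c(hp, wp))) {
    pp <- zero_prior(net, hp, wp)
    ph <- min(dim(prior)[1], hp); pw <- min(dim(prior)[2], wp)
    pp[seq_len(ph), seq_len(pw), ] <- prior[seq_len(ph), seq_len(pw), ]
    prior <- pp
  }
  fwd <- unet_forward(net, xp, prior = prior)
  k <- dim(fwd$logits)[3]
  cls <- max.col(matrix(fwd$logits, ncol = k)) - 1L
  dim(cls) <- c(hp, wp)
  list(class_map = cls[seq_len(h), seq_len(w), drop = FALSE],
       angle_map = fwd$angle[seq_len(h), seq_len(w), drop = FALSE],
       prior = fwd$prior)
}

tile_starts <- function(extent, tile, margin) {
  if (extent <= tile) return(list(starts = 1L, v0 = 1L, v1 = extent))
  stride <- tile - 2L * margin
  starts <- seq(1L, extent - tile, by = stride)
  if (starts[length(starts)] + tile - 1L < extent)
    starts <- c(starts, extent - tile + 1L)
  n <- length(starts)
  v0 <- pmax(starts + margin, 1L); v0[1] <- 1L
  v1 <- starts + tile - 1L - margin; v1[n] <- extent
  for (k in seq_len(n - 1L)) v0[k + 1L] <- v1[k] + 1L
  list(starts = as.integer(starts), v0 = as.integer(v0), v1 = as.integer(v1))
}

#' Tiled full-frame inference
#'
#' Splits a large frame into overlapping windows (`tile` px wide with a
#' `margin`-px overlap), evaluates `predict_fn` on each, and stitches the
#' interior (non-margin) parts of the per-tile maps back into full-frame
#' maps, so every object is attributed to exactly one tile. Each tile keeps
#' its own prior state across frames.
#'
#' @param image Grayscale matrix.
#' @param predict_fn Function `(image, prior) -> list(class_map, angle_map,
#'   prior)`; e.g. `function(x, p) detect_frame(net, x, p)`.
#' @param tile,tile_margin Window size and overlap margin in px.
#' @param priors Per-tile prior list from the previous call, or `NULL`.
#' @return List with stitched `class_map`, `angle_map`, and `priors`.
#' @export
infer_tiled <- function(image, predict_fn, tile = 512, tile_margin = 50,
                        priors = NULL) {
  h <- nrow(image); w <- ncol(image)
  th <- tile_starts(h, tile, tile_margin)
  tw <- tile_starts(w, tile, tile_margin)
  class_map <- matrix(0L, h, w)
  angle_map <- matrix(-1, h, w)
  new_priors <- list()
  k <- 0L
  for (i in seq_along(th$starts)) {
    for (j in seq_along(tw$starts)) {
      k <- k + 1L
      r0 <- th$starts[i]; c0 <- tw$starts[j]
      r1 <- min(r0 + tile - 1L, h); c1 <- min(c0 + tile - 1L, w)
      sub <- image[r0:r1, c0:c1, drop = FALSE]
      res <- predict_fn(sub, if (is.null(priors)) NULL else priors[[k]])
      rows <- th$v0[i]:th$v1[i]; cols <- tw$v0[j]:tw$v1[j]
      class_map[rows, cols] <- res$class_map[rows - r0 + 1L, cols - c0 + 1L]
      angle_map[rows, cols] <- res$angle_map[rows - r0 + 1L, cols - c0 + 1L]
      new_priors[[k]] <- res$prior
    }
  }
  list(class_map = class_map, angle_map = angle_map, priors = new_priors)
}

# ---- blob post-processing --------------------------------------------------

# 8-connected component labelling of a logical matrix. Returns an integer
# matrix of labels (0 = background).
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- integer(h * w)
  idx <- which(mask)
  if (!length(idx)) return(matrix(labels, h, w))
  infg <- logical(h * w)
  infg[idx] <- TRUE
  lab <- 0L
  stack <- integer(length(idx))
  for (s in idx) {
    if (labels[s]) next
    lab <- lab + 1L
    top <- 1L
    stack[1L] <- s
    labels[s] <- lab
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      r <- (cur - 1L) %% h + 1L
      cl <- (cur - 1L) %/% h + 1L
      for (dc in -1:1) {
        cc <- cl + dc
        if (cc < 1L || cc > w) next
        base <- (cc - 1L) * h
        for (dr in -1:1) {
          rr <- r + dr
          if (rr < 1L || rr > h) next
          nb <- base + rr
          if (infg[nb] && !labels[nb]) {
            labels[nb] <- lab
            top <- top + 1L
            stack[top] <- nb
          }
        }
      }
    }
  }
  matrix(labels, h, w)
}

# 4-neighbour binary erosion
erode4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  shift <- function(dr, dc) {
    m <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    m[rs, cs] <- mask[rs - dr, cs - dc]
    m
  }
  mask & shift(1, 0) & shift(-1, 0) & shift(0, 1) & shift(0, -1)
}

# Split fused components: if a component's eroded core falls apart into
# several pieces, its pixels are re-assigned to the nearest core piece
# (components whose core stays whole, or vanishes — e.g. thin blobs — are
# kept untouched).
split_fused_components <- function(labs, mask) {
  core <- erode4(mask)
  h <- nrow(mask)
  out <- labs
  next_lab <- max(labs)
  for (k in seq_len(max(labs))) {
    idx <- which(labs == k)
    core_k <- matrix(FALSE, h, ncol(mask))
    core_k[idx[core[idx]]] <- TRUE
    sub <- label_components(core_k)
    n_parts <- max(sub)
    if (n_parts <= 1L) next
    core_idx <- which(sub > 0L)
    cr <- (core_idx - 1L) %% h; cc <- (core_idx - 1L) %/% h
    rows <- (idx - 1L) %% h; cols <- (idx - 1L) %/% h
    for (p in seq_along(idx)) {
      d2 <- (cr - rows[p])^2 + (cc - cols[p])^2
      out[idx[p]] <- next_lab + sub[core_idx[which.min(d2)]]
    }
    next_lab <- next_lab + n_parts
  }
  out
}

circular_mean_deg <- function(deg) {
  a <- deg * pi / 180
  m <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  (m + 360) %% 360
}

#' Convert segmentation maps into individual detections
#'
#' Each 8-connected foreground component is one candidate bee. Components
#' with areas outside `[blob_min, blob_max]` px are discarded. The position
#' is the mean of the member pixel coordinates, the class the majority vote
#' of member pixels, and (full-bees only) the body axis is the first
#' principal component of the member coordinates, disambiguated to the
#' half-turn closer, under the circular loss, to the circular mean of the
#' member pixels' predicted angles.
#'
#' @param class_map Integer matrix of per-pixel classes (0 background).
#' @param angle_map Matrix of per-pixel predicted angles in degrees.
#' @param config A [detector_config()] providing the blob area filter.
#' @param frame,t Frame index and time in seconds stored in the output.
#' @return A detections `data.frame` with columns
#'   `frame, t, x, y, b, alpha, area` (`alpha` is `NA` for cell-bees).
#' @export
maps_to_detections <- function(class_map, angle_map,
                               config = detector_config(),
                               frame = 0L, t = 0) {
  stopifnot(all(dim(class_map) == dim(angle_map)))
  mask <- class_map != 0L
  labs <- label_components(mask)
  if (isTRUE(config$blob_split))
    labs <- split_fused_components(labs, mask)
  n <- max(labs)
  out <- vector("list", n)
  h <- nrow(class_map)
  for (k in seq_len(n)) {
    idx <- which(labs == k)
    area <- length(idx)
    if (area < config$blob_min || area > config$blob_max) next
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    x <- mean(cols - 1); y <- mean(rows - 1)
    cls <- as.integer(names(which.max(table(class_map[idx]))))
    alpha <- NA_real_
    if (cls == 1L) {
      mu <- circular_mean_deg(angle_map[idx])
      if (area > 1L && (stats::sd(cols) > 0 || stats::sd(rows) > 0)) {
        cv <- stats::cov(cbind(cols - 1, rows - 1))
        ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
        # axis angle, clockwise from vertical-up, in [0, 180)
        th <- (atan2(ev[1], -ev[2]) * 180 / pi) %% 180
        cand <- c(th, th + 180)
        dloss <- sin((cand - mu) * pi / 360)^2
        alpha <- cand[which.min(dloss)] %% 360
      } else {
        alpha <- mu
      }
    }
    out[[k]] <- data.frame(frame = frame, t = t, x = x, y = y,
                           b = cls, alpha = alpha, area = area)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(frame = integer(0), t = numeric(0), x = numeric(0),
                      y = numeric(0), b = integer(0), alpha = numeric(0),
                      area = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score detections against ground truth
#'
#' Greedy nearest-neighbour matching of detections to true positions within
#' `radius` px, one-to-one. TPR is the fraction of true objects matched;
#' FPR the fraction of detections left unmatched.
#'
#' @param detections Detections `data.frame` (one frame).
#' @param truth `data.frame` with true `x`, `y` (one frame).
#' @param radius Match radius in px.
#' @return List with `tpr`, `fpr`, `n_matched`.
#' @export
detection_scores <- function(detections, truth, radius = 20) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nt == 0) return(list(tpr = NA_real_, fpr = if (nd) 1 else 0,
                           n_matched = 0L))
  if (nd == 0) return(list(tpr = 0, fpr = 0, n_matched = 0L))
  dmat <- outer(detections$x, truth$x, "-")^2 +
    outer(detections$y, truth$y, "-")^2
  dmat <- sqrt(dmat)
  matched_d <- logical(nd); matched_t <- logical(nt)
  ord <- order(dmat)
  for (o in ord) {
    if (dmat[o] > radius) break
    i <- (o - 1L) %% nd + 1L
    j <- (o - 1L) %/% nd + 1L
    if (matched_d[i] || matched_t[j]) next
    matched_d[i] <- TRUE; matched_t[j] <- TRUE
  }
  n <- sum(matched_t)
  list(tpr = n / nt, fpr = sum(!matched_d) / nd, n_matched = n)
}

# ---- background extraction and brood ---------------------------------------

#' Extract a static background image from a frame sample
#'
#' Per-pixel temporal median restricted to samples that are not moving: a
#' sample is kept when the absolute difference to its temporal neighbours
#' stays below a motion threshold (3 times a robust MAD-based noise estimate
#' of the frame-to-frame differences by default). Pixels with no static
#' sample fall back to the plain temporal median.
#'
#' @param frames List of at least 3 grayscale matrices sampled over the
#'   background window (e.g. 12 h of timelapse).
#' @param motion_thresh Absolute-difference threshold; `NULL` for the
#'   MAD-based default.
#' @return A background image matrix.
#' @export
extract_background <- function(frames, motion_thresh = NULL) {
  if (length(frames) < 3) stop("background extraction needs >= 3 frames")
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  T <- length(frames)
  arr <- array(unlist(frames), c(h, w, T))
  d <- abs(arr[, , -1, drop = FALSE] - arr[, , -T, drop = FALSE])
  if (is.null(motion_thresh)) {
    motion_thresh <- 3 * stats::mad(d, center = 0)
    if (motion_thresh == 0) motion_thresh <- 3 * mean(d)
  }
  still <- array(TRUE, c(h, w, T))
  still[, , -1] <- still[, , -1, drop = FALSE] & (d < motion_thresh)
  still[, , -T] <- still[, , -T, drop = FALSE] & (d < motion_thresh)
  vals <- arr
  vals[!still] <- NA
  bg <- apply(vals, c(1, 2), stats::median, na.rm = TRUE)
  fallback <- is.na(bg)
  if (any(fallback)) {
    med <- apply(arr, c(1, 2), stats::median)
    bg[fallback] <- med[fallback]
  }
  bg
}

#' Number of integer lattice points inside a disk of the given radius
#' @param r Radius in px.
#' @return Integer count (317 for r = 10).
#' @export
lattice_disk_count <- function(r) {
  xs <- -floor(r):floor(r)
  sum(outer(xs^2, xs^2, "+") <= r^2)
}

#' Extract brood-cell centres from a binary segmentation mask
#'
#' Connected components of the mask are candidate cells; components smaller
#' than half the area of a brood-radius disk are discarded; centres are the
#' component centroids.
#'
#' @param mask Logical matrix (foreground = brood marker).
#' @param geom A [bee_geometry()] supplying the brood radius.
#' @return `data.frame` with columns `x`, `y` (0-based centres).
#' @export
brood_mask_to_cells <- function(mask, geom = bee_geometry()) {
  min_area <- floor(lattice_disk_count(geom$brood_radius) / 2)
  labs <- label_components(mask)
  h <- nrow(mask)
  cells <- list()
  for (k in seq_len(max(labs))) {
    idx <- which(labs == k)
    if (length(idx) < min_area) next
    rows <- (idx - 1L) %% h + 1L
    cols <- (idx - 1L) %/% h + 1L
    cells[[length(cells) + 1L]] <- data.frame(x = mean(cols - 1),
                                              y = mean(rows - 1))
  }
  if (!length(cells)) return(data.frame(x = numeric(0), y = numeric(0)))
  do.call(rbind, cells)
}

#' Detect capped brood cells on a background image
#'
#' Runs a (non-recurrent) segmentation model trained on circular brood
#' targets over the background image and converts the foreground mask into
#' cell centres.
#'
#' @param background Background image matrix.
#' @param model A `bee_detector` trained for brood segmentation.
#' @param geom A [bee_geometry()].
#' @return `data.frame` with columns `x`, `y`.
#' @export
detect_brood <- function(background, model, geom = bee_geometry()) {
  res <- detect_frame(model, background)
  brood_mask_to_cells(res$class_map != 0L, geom)
}
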