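# Appearance-embedding learning. Crops centred on detections are mapped to
# 64-dimensional vectors by a small convolutional backbone trained with a
# triplet objective: embeddings of the same bee at nearby times are pulled
# together, embeddings of different bees that the matching procedure could
# confuse (same frame, within the distance cutoff of the anchor) are pushed
# apart by a margin.

#' Embedding configuration
#'
#' @param dim Embedding dimensionality.
#' @param margin Triplet-loss margin.
#' @param batch_size Triplets per training batch.
#' @param lr Base learning rate.
#' @param crop_size Side of the square crop centred on a detection, px.
#' @param widths Filter counts of the convolutional backbone.
#' @param augment Apply joint rotation/flip augmentation to triplets.
#' @param mask_background Zero out pixels outside the body ellipse.
#' @return An object of class `embedding_config`.
#' @export
embedding_config <- function(dim = 64, margin = 0.5, batch_size = 32,
                             lr = 1e-4, crop_size = 128,
                             widths = c(8, 16, 32),
                             augment = FALSE, mask_background = FALSE) {
  stopifnot(dim >= 2, margin > 0, batch_size >= 1, crop_size >= 4,
            length(widths) >= 1)
  structure(list(dim = as.integer(dim), margin = margin,
                 batch_size = as.integer(batch_size), lr = lr,
                 crop_size = as.integer(crop_size),
                 widths = as.integer(widths),
                 augment = isTRUE(augment),
                 mask_background = isTRUE(mask_background)),
            class = "embedding_config")
}

#' Triplet loss
#'
#' `max(||f1 - f2||^2 - ||f1 - f3||^2 + margin, 0)` where `f1` is the
#' anchor embedding, `f2` the positive (same bee, later frame) and `f3`
#' the negative (different bee, same frame as the positive).
#'
#' @param f1,f2,f3 Embedding vectors of equal dimension.
#' @param margin Separation margin.
#' @return Non-negative scalar.
#' @export
triplet_loss <- function(f1, f2, f3, margin = 0.5) {
  if (length(f1) != length(f2) || length(f1) != length(f3))
    stop("embeddings must have equal dimension")
  max(sum((f1 - f2)^2) - sum((f1 - f3)^2) + margin, 0)
}

#' Batch triplet loss
#'
#' Sum of the triplet losses divided by the number of correct triplets
#' (those with loss 0), clamped below at 1.
#'
#' @param losses Numeric vector of per-triplet losses (non-empty).
#' @return List with `loss` and `n_violating` (triplets with positive
#'   loss).
#' @export
batch_loss <- function(losses) {
  if (!length(losses)) stop("empty batch")
  n_correct <- sum(losses == 0)
  list(loss = sum(losses) / max(1, n_correct),
       n_violating = sum(losses > 0))
}

#' Retain hard examples for the next batch
#'
#' Triplets with a positive triplet loss are fed back into training; the
#' rest of the next batch is refilled by fresh sampling.
#'
#' @param triplets Triplet table (or list) of the previous batch.
#' @param losses Per-triplet losses aligned with `triplets`.
#' @return The retained subset.
#' @export
hard_example_feedback <- function(triplets, losses) {
  keep <- which(losses > 0)
  if (is.data.frame(triplets)) triplets[keep, , drop = FALSE]
  else triplets[keep]
}

#' Sample matcher-constrained triplets
#'
#' Anchors are drawn from trajectories (a detection table with an `id`
#' column); the positive is the same bee in a later frame; negatives are
#' restricted to detections in the positive's frame that lie within the
#' matching procedure's distance cutoff of the anchor — precisely the
#' candidates a tracker could confuse. Anchors with no admissible negative
#' are skipped.
#'
#' @param detections Detection table with columns `frame, t, x, y, b` and a
#'   trajectory/identity column `id`.
#' @param params A [tracker_params()] supplying the distance cutoff.
#' @param n Number of triplets to draw.
#' @param seed Integer seed.
#' @param dt_frames Frame offset between anchor and positive.
#' @return `data.frame` with columns `anchor`, `positive`, `negative`
#'   holding row indices into `detections`.
#' @export
sample_triplets <- function(detections, params = tracker_params(), n = 100,
                            seed = 1L, dt_frames = 1L) {
  if (is.null(detections$id)) stop("detections need an id column")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  by_frame <- split(seq_len(nrow(detections)), detections$frame)
  frames <- as.integer(names(by_frame))
  out <- matrix(NA_integer_, n, 3)
  got <- 0L
  attempts <- 0L
  max_attempts <- 50L * n
  while (got < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    f <- sample(frames[frames + dt_frames <= max(frames)], 1L)
    rows_a <- by_frame[[as.character(f)]]
    rows_p <- by_frame[[as.character(f + dt_frames)]]
    if (is.null(rows_p)) next
    a <- sample(rows_a, 1L)
    aid <- detections$id[a]
    p <- rows_p[detections$id[rows_p] == aid]
    if (length(p) != 1L) next
    # anchor's trajectory history up to the anchor frame
    hist_rows <- which(detections$id == aid & detections$frame <= f)
    hist <- list(ts = detections$t[hist_rows], bs = detections$b[hist_rows])
    cd <- distance_cutoff(hist, detections$t[p], params)
    negs <- rows_p[detections$id[rows_p] != aid]
    if (length(negs)) {
      E <- sqrt((detections$x[negs] - detections$x[a])^2 +
                (detections$y[negs] - detections$y[a])^2)
      negs <- negs[E <= cd]
    }
    if (!length(negs)) next
    got <- got + 1L
    out[got, ] <- c(a, p, if (length(negs) == 1L) negs
                          else sample(negs, 1L))
  }
  out <- out[seq_len(got), , drop = FALSE]
  data.frame(anchor = out[, 1], positive = out[, 2], negative = out[, 3])
}

#' Extract a square crop centred on a detection
#'
#' @param image Frame matrix.
#' @param x,y 0-based detection coordinates.
#' @param crop_size Side of the square crop; areas outside the frame are
#'   zero-padded.
#' @return A `crop_size` x `crop_size` matrix.
#' @export
extract_crop <- function(image, x, y, crop_size = 128) {
  h <- nrow(image); w <- ncol(image)
  half <- crop_size %/% 2
  out <- matrix(0, crop_size, crop_size)
  r0 <- round(y) - half + 1L; c0 <- round(x) - half + 1L
  rs <- max(1L, r0 + 1L):min(h, r0 + crop_size)
  cs <- max(1L, c0 + 1L):min(w, c0 + crop_size)
  if (length(rs) && length(cs))
    out[rs - r0, cs - c0] <- image[rs, cs]
  out
}

#' Mask the background of a detection crop
#'
#' Pixels outside the oriented full-body ellipse (full `body_length` by
#' `body_width`, not the smaller target region) are set to 0; cell-bees use
#' a disk of diameter `body_width` (only the abdomen is visible).
#'
#' @param crop Square crop with the detection at its centre.
#' @param b Detection class (1 or 2).
#' @param alpha Body orientation in degrees (full-bees).
#' @param geom A [bee_geometry()].
#' @return The masked crop.
#' @export
mask_background <- function(crop, b, alpha = 0, geom = bee_geometry()) {
  if (nrow(crop) != ncol(crop)) stop("crop must be square")
  n <- nrow(crop)
  ctr <- (n - 1) / 2
  idx <- if (b == 1) {
    ellipse_indices(ctr, ctr, alpha, geom$body_length / 2,
                    geom$body_width / 2, c(n, n))
  } else {
    ellipse_indices(ctr, ctr, 0, geom$body_width / 2, geom$body_width / 2,
                    c(n, n))
  }
  out <- matrix(0, n, n)
  out[idx] <- crop[idx]
  out
}

rotate90 <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

apply_crop_transform <- function(crop, k, flip_h, flip_v) {
  m <- rotate90(crop, k)
  if (flip_h) m <- m[, ncol(m):1, drop = FALSE]
  if (flip_v) m <- m[nrow(m):1, , drop = FALSE]
  m
}

#' Jointly augment a triplet of crops
#'
#' One transform — a multiple of 90 degrees rotation plus optional
#' horizontal/vertical flips — is drawn once and applied identically to the
#' anchor, positive and negative crops, preserving their orientation
#' relationship.
#'
#' @param triplet List with `anchor`, `positive`, `negative` square crops.
#' @param seed Integer seed; or pass `transform` explicitly.
#' @param transform Optional list `(k, flip_h, flip_v)`.
#' @return The transformed triplet (with the applied `transform` attached).
#' @export
augment_triplet <- function(triplet, seed = NULL, transform = NULL) {
  for (nm in c("anchor", "positive", "negative"))
    if (nrow(triplet[[nm]]) != ncol(triplet[[nm]]))
      stop("augmentation requires square crops")
  if (is.null(transform)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    if (!is.null(seed)) set.seed(seed)
    transform <- list(k = sample(0:3, 1), flip_h = sample(c(TRUE, FALSE), 1),
                      flip_v = sample(c(TRUE, FALSE), 1))
  }
  out <- lapply(triplet[c("anchor", "positive", "negative")],
                apply_crop_transform, k = transform$k,
                flip_h = transform$flip_h, flip_v = transform$flip_v)
  attr(out, "transform") <- transform
  out
}

# ---- the embedding network -------------------------------------------------

#' Build an appearance-embedding model
#'
#' A small convolutional backbone (3x3 convolution + ReLU + 2x2 max pool
#' per stage) followed by global average pooling and a dense projection to
#' the embedding dimension. The backbone is deliberately compact and
#' swappable; the training objective, not the architecture, is the
#' contract.
#'
#' @param config An [embedding_config()].
#' @param seed Seed for weight initialisation.
#' @return Object of class `bee_embedder`.
#' @export
build_embedder <- function(config = embedding_config(), seed = 1L) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  w <- config$widths
  params <- list()
  cin <- 1L
  for (i in seq_along(w)) {
    params[[sprintf("conv%d", i)]] <- init_conv3(cin, w[i])
    cin <- w[i]
  }
  params$dense <- init_dense(cin, config$dim)
  structure(list(config = config, params = params), class = "bee_embedder")
}

embedder_forward <- function(model, crop, train = FALSE) {
  w <- model$config$widths
  cur <- as_tensor(crop)
  stages <- vector("list", length(w))
  for (i in seq_along(w)) {
    f <- conv3_forward(cur, model$params[[sprintf("conv%d", i)]],
                       cache = train)
    y <- relu_forward(f$y)
    pool <- maxpool2_forward(y)
    stages[[i]] <- list(f = f, y = y, pool = pool)
    cur <- pool$y
  }
  d <- dim(cur)
  gap <- colMeans(matrix(cur, d[1] * d[2], d[3]))
  out <- dense_forward(matrix(gap, 1), model$params$dense)
  list(out = out, gap = gap, gap_dims = d,
       stages = if (train) stages else NULL)
}

embedder_backward <- function(model, fwd, d_out) {
  w <- model$config$widths
  gd <- dense_backward(matrix(fwd$gap, 1), model$params$dense, d_out)
  grads <- list(dense = list(W = gd$dW, b = gd$db))
  d <- fwd$gap_dims
  d_cur <- array(rep(gd$dx / (d[1] * d[2]), each = d[1] * d[2]), d)
  for (i in rev(seq_along(w))) {
    st <- fwd$stages[[i]]
    d_y <- maxpool2_backward(st$pool, d_cur)
    d_f <- relu_backward(st$f$y, d_y)
    g <- conv3_backward(st$f, model$params[[sprintf("conv%d", i)]], d_f)
    grads[[sprintf("conv%d", i)]] <- list(W = g$dW, b = g$db)
    d_cur <- g$dx
  }
  grads
}

#' Embed detection crops
#'
#' @param crops A list of square matrices (side `crop_size`), or a single
#'   matrix.
#' @param model A `bee_embedder`.
#' @return Matrix with one embedding row per crop.
#' @export
embed <- function(crops, model) {
  if (is.matrix(crops)) crops <- list(crops)
  cs <- model$config$crop_size
  bad <- which(vapply(crops, function(x) nrow(x) != cs || ncol(x) != cs,
                      logical(1)))
  if (length(bad))
    stop(sprintf("crop %d is not %dx%d", bad[1], cs, cs))
  t(vapply(crops, function(x) embedder_forward(model, x)$out,
           numeric(model$config$dim)))
}

accumulate_grads <- function(acc, g, scale = 1) {
  if (is.null(acc)) {
    return(lapply(g, function(l) lapply(l, function(v) v * scale)))
  }
  for (ln in names(g)) for (pn in names(g[[ln]]))
    acc[[ln]][[pn]] <- acc[[ln]][[pn]] + g[[ln]][[pn]] * scale
  acc
}

#' Train an embedder on matcher-constrained triplets
#'
#' Each batch draws fresh triplets via `triplet_fn`, prepends the hard
#' examples (positive-loss triplets) retained from the previous batch,
#' optionally applies joint augmentation, and takes one adaptive-moment
#' step on the batch loss.
#'
#' @param model A `bee_embedder`.
#' @param triplet_fn Function `(n) -> list` of triplets, each a list with
#'   square `anchor`, `positive`, `negative` crops.
#' @param n_batches Number of training batches.
#' @param lr Learning rate (default from the config).
#' @param seed Seed for augmentation draws.
#' @return The updated model with `$batch_history` (`data.frame` of batch
#'   loss and violating-triplet count).
#' @export
train_embedder <- function(model, triplet_fn, n_batches, lr = NULL,
                           seed = 1L) {
  cfg <- model$config
  if (is.null(lr)) lr <- cfg$lr
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  state <- adam_init(model$params)
  hist <- list()
  queue <- list()
  for (bi in seq_len(n_batches)) {
    fresh <- triplet_fn(max(0L, cfg$batch_size - length(queue)))
    batch <- c(queue, fresh)
    if (!length(batch)) break
    if (cfg$augment)
      batch <- lapply(batch, function(tp) augment_triplet(tp))
    losses <- numeric(length(batch))
    raw_grads <- vector("list", length(batch))
    for (k in seq_along(batch)) {
      tp <- batch[[k]]
      fa <- embedder_forward(model, tp$anchor, train = TRUE)
      fp <- embedder_forward(model, tp$positive, train = TRUE)
      fn <- embedder_forward(model, tp$negative, train = TRUE)
      L <- triplet_loss(fa$out, fp$out, fn$out, cfg$margin)
      losses[k] <- L
      if (L > 0) {
        g <- embedder_backward(model, fa, 2 * (fn$out - fp$out))
        g <- accumulate_grads(g,
              embedder_backward(model, fp, -2 * (fa$out - fp$out)))
        g <- accumulate_grads(g,
              embedder_backward(model, fn, 2 * (fa$out - fn$out)))
        raw_grads[[k]] <- g
      }
    }
    bl <- batch_loss(losses)
    scale <- 1 / max(1, sum(losses == 0))
    total <- NULL
    for (k in seq_along(batch))
      if (!is.null(raw_grads[[k]]))
        total <- accumulate_grads(total, raw_grads[[k]], scale)
    if (!is.null(total)) {
      upd <- adam_step(model$params, total, state, lr)
      model$params <- upd$params
      state <- upd$state
    }
    queue <- hard_example_feedback(batch, losses)
    if (length(queue) > cfg$batch_size)
      queue <- queue[seq_len(cfg$batch_size)]
    hist[[bi]] <- data.frame(batch = bi, loss = bl$loss,
                             n_violating = bl$n_violating,
                             n_triplets = length(batch))
  }
  new_hist <- do.call(rbind, hist)
  if (!is.null(model$batch_history)) {
    new_hist$batch <- new_hist$batch + max(model$batch_history$batch)
    new_hist <- rbind(model$batch_history, new_hist)
  }
  model$batch_history <- new_hist
  model
}
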