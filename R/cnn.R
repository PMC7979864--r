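# Minimal convolutional-network engine.
#
# Tensors are plain R arrays with dimensions [H, W, C]; convolutions are
# evaluated as im2col matrix products so that all heavy arithmetic goes
# through BLAS. Only what the segmentation and embedding networks need is
# implemented: 3x3 'same' convolutions, 1x1 convolutions, ReLU, 2x2 max
# pooling, 2x2 nearest-neighbour upsampling, channel concatenation, a dense
# layer, and the Adam optimizer.

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

pad_hw <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

# im2col for a 3x3 kernel with 'same' zero padding. Column order matches
# as.vector() of a [3, 3, Cin, Cout] weight array: ki fastest, then kj,
# then cin.
im2col3 <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; cin <- d[3]
  xp <- pad_hw(x, 1L)
  out <- matrix(0, h * w, 9L * cin)
  col <- 0L
  for (ci in seq_len(cin)) {
    for (kj in 1:3) {
      for (ki in 1:3) {
        col <- col + 1L
        out[, col] <- as.vector(xp[ki:(ki + h - 1L), kj:(kj + w - 1L), ci])
      }
    }
  }
  out
}

col2im3 <- function(dX, h, w, cin) {
  dxp <- array(0, c(h + 2L, w + 2L, cin))
  col <- 0L
  for (ci in seq_len(cin)) {
    for (kj in 1:3) {
      for (ki in 1:3) {
        col <- col + 1L
        dxp[ki:(ki + h - 1L), kj:(kj + w - 1L), ci] <-
          dxp[ki:(ki + h - 1L), kj:(kj + w - 1L), ci] + matrix(dX[, col], h, w)
      }
    }
  }
  dxp[2:(h + 1L), 2:(w + 1L), , drop = FALSE]
}

conv3_forward <- function(x, par, cache = FALSE) {
  d <- dim(x)
  X <- im2col3(x)
  Wm <- matrix(par$W, ncol = dim(par$W)[4])
  y <- X %*% Wm
  y <- sweep(y, 2, par$b, "+")
  dim(y) <- c(d[1], d[2], length(par$b))
  list(y = y, X = if (cache) X else NULL, dims = d)
}

conv3_backward <- function(fw, par, dy) {
  cout <- dim(par$W)[4]
  dY <- matrix(dy, ncol = cout)
  dW <- crossprod(fw$X, dY)
  dim(dW) <- dim(par$W)
  db <- colSums(dY)
  Wm <- matrix(par$W, ncol = cout)
  dX <- tcrossprod(dY, Wm)
  dx <- col2im3(dX, fw$dims[1], fw$dims[2], fw$dims[3])
  list(dx = dx, dW = dW, db = db)
}

conv1_forward <- function(x, par) {
  d <- dim(x)
  X <- matrix(x, ncol = d[3])
  y <- sweep(X %*% par$W, 2, par$b, "+")
  dim(y) <- c(d[1], d[2], ncol(par$W))
  y
}

conv1_backward <- function(x, par, dy) {
  d <- dim(x)
  X <- matrix(x, ncol = d[3])
  dY <- matrix(dy, ncol = ncol(par$W))
  dW <- crossprod(X, dY)
  db <- colSums(dY)
  dx <- tcrossprod(dY, par$W)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) pmax(x, 0)

relu_backward <- function(x, dy) dy * (x > 0)

maxpool2_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , drop = FALSE]; b <- x[i2, j1, , drop = FALSE]
  cc <- x[i1, j2, , drop = FALSE]; dd <- x[i2, j2, , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  # route gradient to the first block attaining the max
  m1 <- a == y
  m2 <- (b == y) & !m1
  m3 <- (cc == y) & !m1 & !m2
  m4 <- (dd == y) & !m1 & !m2 & !m3
  list(y = y, masks = list(m1, m2, m3, m4), dims = d)
}

maxpool2_backward <- function(fw, dy) {
  d <- fw$dims
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dx[i1, j1, ] <- dy * fw$masks[[1]]
  dx[i2, j1, ] <- dy * fw$masks[[2]]
  dx[i1, j2, ] <- dy * fw$masks[[3]]
  dx[i2, j2, ] <- dy * fw$masks[[4]]
  dx
}

upsample2_forward <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1], 2L * d[2], d[3]))
  i1 <- seq(1L, 2L * d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, 2L * d[2], 2L); j2 <- j1 + 1L
  y[i1, j1, ] <- x; y[i2, j1, ] <- x; y[i1, j2, ] <- x; y[i2, j2, ] <- x
  y
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

dense_forward <- function(x, par) drop(x %*% par$W) + par$b

dense_backward <- function(x, par, dy) {
  list(dx = drop(tcrossprod(dy, par$W)),
       dW = outer(drop(x), dy), db = dy)
}

# He-style initialisation for a conv/dense layer
init_conv3 <- function(cin, cout, rng_sd = NULL) {
  fan_in <- 9 * cin
  sd <- if (is.null(rng_sd)) sqrt(2 / fan_in) else rng_sd
  list(W = array(stats::rnorm(9 * cin * cout, 0, sd), c(3, 3, cin, cout)),
       b = rep(0, cout))
}

init_conv1 <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

init_dense <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- function(p) lapply(p, function(v) array(0, dim(as.array(v))))
  list(m = lapply(params, zeros), v = lapply(params, zeros), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (ln in names(params)) {
    for (pn in names(params[[ln]])) {
      g <- grads[[ln]][[pn]]
      if (is.null(g)) next
      m <- beta1 * state$m[[ln]][[pn]] + (1 - beta1) * g
      v <- beta2 * state$v[[ln]][[pn]] + (1 - beta2) * g * g
      state$m[[ln]][[pn]] <- m
      state$v[[ln]][[pn]] <- v
      upd <- params[[ln]][[pn]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      dim(upd) <- dim(params[[ln]][[pn]])
      params[[ln]][[pn]] <- upd
    }
  }
  list(params = params, state = state)
}
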