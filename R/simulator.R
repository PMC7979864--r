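# Synthetic colony generator. Produces correlated-random-walk bee
# trajectories with cell-bee dwell episodes, entrance entries/exits and
# occlusions; renders textured elliptical bees on a hexagonal comb-like
# background; provides oracle appearance embeddings with controlled
# identity separation; and generates sociometric count series with ~24 h
# periodicity and bee-brood anticorrelation. Everything is a pure function
# of (config, seed), which makes each analysis stage testable against known
# ground truth.

#' Simulator configuration
#'
#' @param n_bees Number of identities.
#' @param arena Arena side in px (square).
#' @param fps Frames per second.
#' @param duration Duration in seconds.
#' @param speed_mean Mean per-frame step length of a moving full-bee, px.
#' @param speed_shape Gamma shape of the step-length distribution.
#' @param turn_sd Standard deviation of the per-frame heading change,
#'   radians (correlated random walk).
#' @param collision_radius Minimum centre separation between bees, px
#'   (bodies cannot interpenetrate); `NULL` defaults to the body width,
#'   0 disables collisions.
#' @param dwell_rate Rate (per second) at which a bee enters a comb cell.
#' @param dwell_duration Mean duration of a cell-bee episode, seconds.
#' @param exit_rate Rate (per second) at which a bee near the entrance
#'   leaves the hive.
#' @param away_duration Mean time outside the hive, seconds.
#' @param entrance Entrance region (`list(shape, ...)` as in
#'   [tracker_params()]); defaults to a disk at the bottom centre.
#' @param occlusion_threshold A bee whose body is covered by bees drawn
#'   above it (painter's order by id) over more than this fraction is
#'   hidden: it is still rendered underneath but absent from the ground
#'   truth, as a heavily occluded bee is for a human annotator. `1`
#'   disables occlusions.
#' @param body_length,body_width Rendered bee dimensions, px.
#' @param bee_intensity Mean body intensity of a bee in `[0, 1]` (the comb
#'   background is brighter).
#' @param identity_contrast Half-range of the per-identity intensity
#'   offset (the appearance signature visible to an embedder).
#' @param stripe_contrast Amplitude of the abdomen stripe texture.
#' @param noise_sd Gaussian sensor noise, intensity units.
#' @param embed_dim Oracle embedding dimensionality.
#' @param embed_separation Pairwise distance between identity embedding
#'   centres.
#' @param embed_noise Expected norm of the per-frame embedding noise.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_bees = 15, arena = 256, fps = 10, duration = 3,
                       speed_mean = 3, speed_shape = 2, turn_sd = 0.3,
                       collision_radius = NULL,
                       dwell_rate = 0.02, dwell_duration = 5,
                       exit_rate = 0, away_duration = 10,
                       entrance = NULL, occlusion_threshold = 1,
                       body_length = 40, body_width = 14,
                       bee_intensity = 0.25, identity_contrast = 0.12,
                       stripe_contrast = 0.1, noise_sd = 0.02,
                       embed_dim = 64, embed_separation = 2,
                       embed_noise = 0.2, seed = 1L) {
  stopifnot(n_bees >= 0, arena > 0, fps > 0, duration > 0,
            speed_mean >= 0, dwell_rate >= 0, exit_rate >= 0,
            embed_separation >= 0, embed_noise >= 0)
  if (is.null(entrance))
    entrance <- list(shape = "disk", x = arena / 2, y = arena - 1,
                     r = arena / 8)
  if (is.null(collision_radius)) collision_radius <- body_width
  structure(list(n_bees = as.integer(n_bees), arena = as.integer(arena),
                 fps = fps, duration = duration, speed_mean = speed_mean,
                 speed_shape = speed_shape, turn_sd = turn_sd,
                 collision_radius = collision_radius,
                 dwell_rate = dwell_rate, dwell_duration = dwell_duration,
                 exit_rate = exit_rate, away_duration = away_duration,
                 entrance = entrance,
                 occlusion_threshold = occlusion_threshold,
                 body_length = body_length, body_width = body_width,
                 bee_intensity = bee_intensity,
                 identity_contrast = identity_contrast,
                 stripe_contrast = stripe_contrast, noise_sd = noise_sd,
                 embed_dim = as.integer(embed_dim),
                 embed_separation = embed_separation,
                 embed_noise = embed_noise, seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate ground-truth colony trajectories
#'
#' Each bee performs a correlated random walk (gamma step lengths, wrapped
#' normal turning) with reflecting arena walls. Cell-bee episodes freeze
#' the position and set the class to 2; exits (only through the entrance
#' region, when enabled) remove the bee until it re-enters there. Bees
#' whose body is mostly covered by bees drawn above them (painter's order)
#' are marked not visible: they stay rendered underneath but are absent
#' from the ground-truth detections, as for a human annotator.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_truth`: list with `detections` (a
#'   `data.frame` of the visible ground truth: `frame, t, x, y, b, alpha,
#'   id`), `all` (every bee-frame row, with `present` and `visible`
#'   flags), and `config`.
#' @export
simulate_trajectories <- function(config = sim_config()) {
  n_frames <- round(config$duration * config$fps)
  nb <- config$n_bees
  if (nb == 0)
    return(structure(list(detections = data.frame(), all = data.frame(),
                          config = config), class = "sim_truth"))
  with_seed(config$seed, {
    margin <- config$body_length / 2
    x <- stats::runif(nb, margin, config$arena - 1 - margin)
    y <- stats::runif(nb, margin, config$arena - 1 - margin)
    heading <- stats::runif(nb, 0, 2 * pi)
    state <- rep("walk", nb)        # walk | cell | away
    state_left <- rep(0, nb)
    rows <- vector("list", n_frames)
    dt <- 1 / config$fps
    for (fr in seq_len(n_frames) - 1L) {
      # state transitions
      for (i in seq_len(nb)) {
        if (state[i] == "walk") {
          if (stats::runif(1) < config$dwell_rate * dt) {
            state[i] <- "cell"
            state_left[i] <- stats::rexp(1, 1 / config$dwell_duration)
          } else if (config$exit_rate > 0 &&
                     in_entrance(x[i], y[i], config$entrance) &&
                     stats::runif(1) < config$exit_rate * dt) {
            state[i] <- "away"
            state_left[i] <- stats::rexp(1, 1 / config$away_duration)
          }
        } else {
          state_left[i] <- state_left[i] - dt
          if (state_left[i] <= 0) {
            if (state[i] == "away") {
              # re-enter at the entrance
              x[i] <- config$entrance$x + stats::rnorm(1, 0, 2)
              y[i] <- config$entrance$y - abs(stats::rnorm(1, 0, 2))
              heading[i] <- stats::runif(1, 0, 2 * pi)
            }
            state[i] <- "walk"
          }
        }
      }
      moving <- state == "walk"
      nm <- sum(moving)
      if (nm) {
        step <- stats::rgamma(nm, shape = config$speed_shape,
                              scale = config$speed_mean / config$speed_shape)
        heading[moving] <- heading[moving] + stats::rnorm(nm, 0, config$turn_sd)
        x[moving] <- x[moving] + step * sin(heading[moving])
        y[moving] <- y[moving] - step * cos(heading[moving])
        # reflect at walls
        lo <- 0; hi <- config$arena - 1
        for (i in which(moving)) {
          if (x[i] < lo) { x[i] <- lo + (lo - x[i]); heading[i] <- -heading[i] }
          if (x[i] > hi) { x[i] <- hi - (x[i] - hi); heading[i] <- -heading[i] }
          if (y[i] < lo) { y[i] <- lo + (lo - y[i]); heading[i] <- pi - heading[i] }
          if (y[i] > hi) { y[i] <- hi - (y[i] - hi); heading[i] <- pi - heading[i] }
          x[i] <- min(max(x[i], lo), hi)
          y[i] <- min(max(y[i], lo), hi)
        }
      }
      present <- state != "away"
      if (config$collision_radius > 0 && nb > 1) {
        res <- resolve_collisions(x, y, present, frozen = state == "cell",
                                  config$collision_radius,
                                  config$arena - 1)
        x <- res$x; y <- res$y
      }
      alpha <- ifelse(state == "cell", 0, (heading * 180 / pi) %% 360)
      b <- ifelse(state == "cell", 2L, 1L)
      visible <- present
      if (config$occlusion_threshold < 1 && nb > 1) {
        cover <- body_coverage(x, y, b, alpha, present, config)
        visible <- present & cover <= config$occlusion_threshold
      }
      rows[[fr + 1L]] <- data.frame(
        frame = fr, t = fr * dt, x = x, y = y, b = b,
        alpha = alpha, id = seq_len(nb), present = present,
        visible = visible)
    }
    all <- do.call(rbind, rows)
    det <- all[all$visible, c("frame", "t", "x", "y", "b", "alpha", "id")]
    rownames(det) <- NULL
    structure(list(detections = det, all = all, config = config),
              class = "sim_truth")
  })
}

# Soft-core collision resolution: pairs of present bees closer than
# min_sep are pushed apart along their centre line (frozen cell-bees do
# not move; their partner takes the full shift). A few relaxation passes
# suffice since per-frame moves are small.
resolve_collisions <- function(x, y, present, frozen, min_sep, hi,
                               passes = 3L) {
  for (p in seq_len(passes)) {
    dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
    d2 <- dx^2 + dy^2
    d2[!present, ] <- Inf; d2[, !present] <- Inf
    d2[lower.tri(d2, diag = TRUE)] <- Inf
    hits <- which(d2 < min_sep^2, arr.ind = TRUE)
    if (!nrow(hits)) break
    for (k in seq_len(nrow(hits))) {
      i <- hits[k, 1]; j <- hits[k, 2]
      d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
      if (d < 1e-9) { ux <- 1; uy <- 0; d <- 1e-9 }
      else { ux <- (x[j] - x[i]) / d; uy <- (y[j] - y[i]) / d }
      push <- (min_sep - d)
      wi <- if (frozen[i]) 0 else if (frozen[j]) 1 else 0.5
      wj <- if (frozen[j]) 0 else if (frozen[i]) 1 else 0.5
      x[i] <- min(max(x[i] - wi * push * ux, 0), hi)
      y[i] <- min(max(y[i] - wi * push * uy, 0), hi)
      x[j] <- min(max(x[j] + wj * push * ux, 0), hi)
      y[j] <- min(max(y[j] + wj * push * uy, 0), hi)
    }
  }
  list(x = x, y = y)
}

body_pixels <- function(x, y, b, alpha, config) {
  if (b == 1L) {
    ellipse_indices(x, y, alpha, config$body_length / 2,
                    config$body_width / 2,
                    c(config$arena, config$arena))
  } else {
    ellipse_indices(x, y, 0, config$body_width / 2, config$body_width / 2,
                    c(config$arena, config$arena))
  }
}

# Fraction of each bee's body pixels covered by bees drawn above it
# (painter's order: higher id on top). Only pairs closer than one body
# length are rasterised.
body_coverage <- function(x, y, b, alpha, present, config) {
  nb <- length(x)
  cover <- numeric(nb)
  if (nb < 2) return(cover)
  close_r2 <- config$body_length^2
  px <- vector("list", nb)
  get_px <- function(i) {
    if (is.null(px[[i]]))
      px[[i]] <<- body_pixels(x[i], y[i], b[i], alpha[i], config)
    px[[i]]
  }
  for (i in seq_len(nb - 1L)) {
    if (!present[i]) next
    js <- (i + 1L):nb
    js <- js[present[js] &
             (x[js] - x[i])^2 + (y[js] - y[i])^2 < close_r2]
    if (!length(js)) next
    own <- get_px(i)
    if (!length(own)) next
    covered <- rep(FALSE, length(own))
    for (j in js) covered <- covered | own %in% get_px(j)
    cover[i] <- mean(covered)
  }
  cover
}

# hexagonal comb-like interference pattern in [0, 1]
comb_background <- function(arena, cell_pitch = 12) {
  xs <- 0:(arena - 1)
  X <- outer(rep(1, arena), xs)
  Y <- outer(xs, rep(1, arena))
  k <- 2 * pi / cell_pitch
  p <- cos(k * X) + cos(k * (X / 2 + Y * sqrt(3) / 2)) +
    cos(k * (X / 2 - Y * sqrt(3) / 2))
  0.5 + 0.12 * p / 3
}

#' Render synthetic frames from ground truth
#'
#' Bees are textured oriented ellipses (full body for full-bees, an
#' abdomen-only disk for cell-bees) drawn in identity order on a hexagonal
#' comb-like background, plus Gaussian sensor noise. Each identity carries
#' a fixed intensity offset — the appearance signature that embedding
#' models can learn.
#'
#' @param truth A `sim_truth` from [simulate_trajectories()].
#' @param frames Optional subset of frame indices (0-based) to render.
#' @return List of image matrices in `[0, 1]`, named by frame index.
#' @export
render_frames <- function(truth, frames = NULL) {
  config <- truth$config
  arena <- config$arena
  bg <- comb_background(arena)
  if (is.null(frames))
    frames <- seq_len(round(config$duration * config$fps)) - 1L
  signatures <- identity_signatures(config)
  with_seed(config$seed + 1L, {
    out <- vector("list", length(frames))
    for (k in seq_along(frames)) {
      fr <- frames[k]
      img <- bg
      sub <- truth$all[truth$all$frame == fr & truth$all$present, ,
                       drop = FALSE]
      if (nrow(sub)) for (i in order(sub$id)) {
        r <- sub[i, ]
        base <- config$bee_intensity + signatures$offset[r$id]
        if (r$b == 1L) {
          idx <- ellipse_indices(r$x, r$y, r$alpha, config$body_length / 2,
                                 config$body_width / 2, c(arena, arena))
          if (length(idx)) {
            rows_px <- (idx - 1L) %% arena
            cols_px <- (idx - 1L) %/% arena
            ax <- body_axes(r$alpha)
            along <- (cols_px - r$x) * ax$major[1] +
              (rows_px - r$y) * ax$major[2]
            img[idx] <- base + config$stripe_contrast *
              sin(2 * pi * along / signatures$stripe_period[r$id])
          }
        } else {
          idx <- ellipse_indices(r$x, r$y, 0, config$body_width / 2,
                                 config$body_width / 2, c(arena, arena))
          img[idx] <- base
        }
      }
      if (config$noise_sd > 0)
        img <- img + matrix(stats::rnorm(arena * arena, 0, config$noise_sd),
                            arena, arena)
      out[[k]] <- pmin(pmax(img, 0), 1)
    }
    names(out) <- frames
    out
  })
}

# Per-identity appearance signatures: evenly spaced intensity offsets
# (shuffled) so every pair of identities is separated by at least
# 2 * identity_contrast / (n - 1), plus a per-identity stripe period.
# This is the oracle-separable appearance model an embedder can learn.
identity_signatures <- function(config) {
  nb <- config$n_bees
  with_seed(config$seed + 2L, {
    off <- if (nb == 1) 0 else
      seq(-config$identity_contrast, config$identity_contrast,
          length.out = nb)[sample(nb)]
    period <- config$body_length / 3 * stats::runif(nb, 0.7, 1.3)
    list(offset = off, stripe_period = period)
  })
}

#' Oracle appearance embeddings
#'
#' Identity-specific fixed centres with exactly controlled pairwise
#' distance (`embed_separation`, via a scaled orthonormal construction)
#' plus isotropic per-frame noise whose expected norm is `embed_noise`.
#' These stand in for a trained embedder in tracker tests, isolating the
#' matching procedure from embedding quality.
#'
#' @param truth A `sim_truth`.
#' @param config A [sim_config()]; defaults to the truth's config.
#' @return Matrix with one embedding row per row of `truth$detections`.
#' @export
oracle_embeddings <- function(truth, config = truth$config) {
  det <- truth$detections
  nb <- config$n_bees
  if (nb > config$embed_dim)
    stop("oracle embeddings require n_bees <= embed_dim")
  centers <- diag(nb) * config$embed_separation / sqrt(2)
  centers <- cbind(centers, matrix(0, nb, config$embed_dim - nb))
  with_seed(config$seed + 3L, {
    noise <- matrix(stats::rnorm(nrow(det) * config$embed_dim, 0,
                                 config$embed_noise / sqrt(config$embed_dim)),
                    nrow(det), config$embed_dim)
    centers[det$id, , drop = FALSE] + noise
  })
}

#' Per-frame ground-truth counts
#'
#' @param truth A `sim_truth`.
#' @return `data.frame` with `frame, t, full_bees, cell_bees, visible`.
#' @export
truth_counts <- function(truth) {
  det <- truth$detections
  frames <- sort(unique(truth$all$frame))
  t <- vapply(frames, function(f) truth$all$t[truth$all$frame == f][1],
              numeric(1))
  full <- vapply(frames, function(f) sum(det$frame == f & det$b == 1L),
                 numeric(1))
  cell <- vapply(frames, function(f) sum(det$frame == f & det$b == 2L),
                 numeric(1))
  data.frame(frame = frames, t = t, full_bees = full, cell_bees = cell,
             visible = full + cell)
}

#' Simulate sociometric count series
#'
#' Visible-bee counts follow a sinusoid with the given period plus trend
#' and noise; brood counts are a baseline minus `coupling` times the
#' window-averaged bee count (bee-brood anticorrelation); cell-bee counts
#' carry a nightly excess peaking at `peak_hour`.
#'
#' @param days Number of days (>= 2).
#' @param interval Sampling interval in seconds (60 or 120 typical).
#' @param period Oscillation period in hours.
#' @param phase_hour Hour of day at which the bee count peaks.
#' @param mean_bees,amplitude Mean level and oscillation amplitude of the
#'   visible-bee count.
#' @param trend Linear drift in bees per day.
#' @param coupling Brood response per (window-averaged) bee.
#' @param mean_brood Brood baseline.
#' @param noise_sd Count noise standard deviation.
#' @param cell_fraction Mean fraction of visible bees inside cells.
#' @param peak_hour Hour of the nightly cell-bee peak.
#' @param seed Integer seed.
#' @return List of `data.frame`s `bees` (`t, full_bees, cell_bees,
#'   visible`) and `brood` (`t, brood`), each sampled every `interval`
#'   seconds.
#' @export
simulate_count_series <- function(days = 14, interval = 120, period = 24,
                                  phase_hour = 14, mean_bees = 1000,
                                  amplitude = 150, trend = 0,
                                  coupling = 0.8, mean_brood = 800,
                                  noise_sd = 20, cell_fraction = 0.25,
                                  peak_hour = 2, seed = 1L) {
  stopifnot(days >= 2)
  with_seed(seed, {
    t <- seq(0, days * 86400 - interval, by = interval)
    hours <- (t / 3600) %% 24
    osc <- cos(2 * pi * (t / 3600 - phase_hour) / period)
    bees <- mean_bees + amplitude * osc + trend * t / 86400 +
      stats::rnorm(length(t), 0, noise_sd)
    bees <- pmax(0, round(bees))
    cell_osc <- cos(2 * pi * (hours - peak_hour) / 24)
    cell <- cell_fraction * bees * (1 + 0.5 * cell_osc) +
      stats::rnorm(length(t), 0, noise_sd / 4)
    cell <- pmin(pmax(0, round(cell)), bees)
    # 12 h window average of the bee series drives the brood level
    win <- max(1L, round(12 * 3600 / interval))
    kern <- rep(1 / win, win)
    smooth <- stats::filter(bees - mean(bees), kern, sides = 2)
    smooth[is.na(smooth)] <- 0
    brood <- mean_brood - coupling * as.numeric(smooth) +
      stats::rnorm(length(t), 0, noise_sd / 10)
    brood <- pmax(0, round(brood))
    list(bees = data.frame(t = t, full_bees = bees - cell,
                           cell_bees = cell, visible = bees),
         brood = data.frame(t = t, brood = brood),
         interval = interval)
  })
}
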