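# Colony-level sociometric statistics and per-trajectory motion metrics.

#' Periodogram of a count series
#'
#' Discrete Fourier periodogram of the mean-subtracted series, one-sided
#' and scaled so the total power equals the series' (population) variance.
#' The dominant period is the power maximum over periods between 2 and
#' 48 hours.
#'
#' @param counts Numeric vector, uniformly sampled.
#' @param interval Sampling interval in seconds.
#' @param period_range Period window (hours) searched for the dominant
#'   peak.
#' @return List with `period_hours`, `power`, `dominant_period_hours`,
#'   `total_power`.
#' @export
periodogram <- function(counts, interval, period_range = c(2, 48)) {
  n <- length(counts)
  if (n * interval < 2 * 86400)
    stop("periodogram needs at least 2 days of data")
  x <- counts - mean(counts)
  X <- stats::fft(x)
  pw <- Mod(X)^2 / n^2
  half <- seq(2L, floor(n / 2) + 1L)
  power <- 2 * pw[half]
  if (n %% 2 == 0) power[length(power)] <- pw[half[length(half)]]
  freq <- (half - 1) / (n * interval)      # Hz
  period_hours <- 1 / freq / 3600
  sel <- period_hours >= period_range[1] & period_hours <= period_range[2]
  dom <- if (any(sel)) period_hours[sel][which.max(power[sel])] else NA_real_
  list(period_hours = period_hours, power = power,
       dominant_period_hours = dom, total_power = sum(power))
}

# vectorised Rayleigh p approximation (standard large-n form with the
# finite-n correction)
rayleigh_p <- function(n, rbar) {
  R <- n * rbar
  Z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  pmin(pmax(p, 0), 1)
}

#' Rayleigh test of circular uniformity
#'
#' Hours of the day are mapped to angles on the 24 h circle; the test
#' statistic is the mean resultant length. The p-value uses the standard
#' exponential approximation with finite-sample correction,
#' `exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * rbar`,
#' monotone decreasing in the concentration.
#'
#' @param hours Numeric vector of hours in `[0, 24)` (n >= 5).
#' @return List with `rbar`, `statistic` (`Z = n * rbar^2`), `p.value`,
#'   `n`.
#' @export
rayleigh_test <- function(hours) {
  n <- length(hours)
  if (n < 5) stop("Rayleigh test needs at least 5 angles")
  a <- 2 * pi * hours / 24
  rbar <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  list(rbar = rbar, statistic = n * rbar^2,
       p.value = rayleigh_p(n, rbar), n = n)
}

#' Hours at which cell-bee counts exceed the daily median
#'
#' For each calendar day the daily median count is computed (days with less
#' than 50% sample coverage are excluded); samples strictly above their
#' day's median are binned into 24 one-hour bins, and the circular mean
#' hour of the above-median samples is reported.
#'
#' @param t Sample times in seconds.
#' @param counts Cell-bee counts aligned with `t`.
#' @param interval Sampling interval in seconds.
#' @return List with `histogram` (24 bins), `mean_hour` (circular, in
#'   `[0, 24)`), `hours` (raw above-median hours) and the Rayleigh test of
#'   the above-median hours.
#' @export
nightly_high_counts <- function(t, counts, interval) {
  day <- floor(t / 86400)
  per_day <- split(seq_along(t), day)
  full <- 86400 / interval
  hours <- c()
  for (ix in per_day) {
    if (length(ix) < 0.5 * full) next
    med <- stats::median(counts[ix])
    above <- ix[counts[ix] > med]
    hours <- c(hours, (t[above] / 3600) %% 24)
  }
  hist24 <- tabulate(floor(hours) + 1L, nbins = 24L)
  names(hist24) <- 0:23
  a <- 2 * pi * hours / 24
  mean_hour <- if (length(hours))
    (atan2(mean(sin(a)), mean(cos(a))) * 24 / (2 * pi)) %% 24 else NA_real_
  ray <- if (length(hours) >= 5) rayleigh_test(hours) else NULL
  list(histogram = hist24, mean_hour = mean_hour, hours = hours,
       rayleigh = ray)
}

#' Windowed bee-brood correlation
#'
#' Both series are averaged over consecutive windows (12 h by default) on
#' their common time range, each windowed series has its mean subtracted,
#' and the Pearson correlation with its two-sided p-value is computed.
#'
#' @param bee_t,bee_counts Bee series (times in seconds, counts).
#' @param brood_t,brood_counts Brood series.
#' @param window Window length in seconds.
#' @return List with `r`, `p.value`, `n_windows` and the paired window
#'   means.
#' @export
windowed_correlation <- function(bee_t, bee_counts, brood_t, brood_counts,
                                 window = 12 * 3600) {
  t0 <- max(min(bee_t), min(brood_t))
  t1 <- min(max(bee_t), max(brood_t))
  if (t1 <= t0) stop("series do not overlap in time")
  wb <- floor((bee_t - t0) / window)
  wr <- floor((brood_t - t0) / window)
  keep_b <- bee_t >= t0 & bee_t <= t1
  keep_r <- brood_t >= t0 & brood_t <= t1
  mb <- tapply(bee_counts[keep_b], wb[keep_b], mean)
  mr <- tapply(brood_counts[keep_r], wr[keep_r], mean)
  common <- intersect(names(mb), names(mr))
  if (length(common) < 3) stop("need at least 3 overlapping windows")
  xb <- mb[common] - mean(mb[common])
  xr <- mr[common] - mean(mr[common])
  ct <- stats::cor.test(xb, xr, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value,
       n_windows = length(common),
       windows = data.frame(window = as.integer(common), bees = xb,
                            brood = xr))
}

#' Distance of each detection class to the nearest brood cell
#'
#' @param detections Detections `data.frame` with `x, y, b`.
#' @param brood Brood cell centres `data.frame` with `x, y`.
#' @param px_per_mm Pixels per millimetre.
#' @return List with per-class mean distances (mm), their difference
#'   (full-bee minus cell-bee), and a two-sided Wilcoxon rank-sum test.
#' @export
brood_distance_stats <- function(detections, brood, px_per_mm = 1) {
  if (!nrow(brood)) stop("brood set is empty")
  nearest <- function(xs, ys) {
    out <- numeric(length(xs))
    chunk <- 2000L
    for (s in seq(1L, length(xs), by = chunk)) {
      ix <- s:min(length(xs), s + chunk - 1L)
      d2 <- outer(xs[ix], brood$x, "-")^2 + outer(ys[ix], brood$y, "-")^2
      out[ix] <- sqrt(apply(d2, 1, min))
    }
    out
  }
  d_mm <- nearest(detections$x, detections$y) / px_per_mm
  full <- d_mm[detections$b == 1]
  cell <- d_mm[detections$b == 2]
  if (length(full) < 2 || length(cell) < 2)
    stop("each class needs at least 2 detections for the rank-sum test")
  wt <- suppressWarnings(stats::wilcox.test(full, cell))
  p <- wt$p.value
  if (is.nan(p)) p <- 1          # fully tied samples carry no evidence
  list(mean_full_mm = mean(full), mean_cell_mm = mean(cell),
       difference_mm = mean(full) - mean(cell),
       p.value = p, distances_mm = d_mm)
}

wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Motion metrics of one trajectory
#'
#' Speed from successive displacements; angular speed from successive
#' displacement-heading changes (wrapped to `(-pi, pi]`); path length as
#' the displacement sum; motion span as the diagonal of the minimal
#' axis-aligned rectangle containing the trajectory; diffusion coefficient
#' as slope/4 of a linear fit (with intercept) to the mean squared
#' displacement over lags up to `max_lag` seconds; comb-cell visits as the
#' number of full-bee to cell-bee class transitions.
#'
#' @param traj Trajectory `data.frame` with `t, x, y` (and `b` for cell
#'   visits), at least 2 rows.
#' @param max_lag Maximum MSD lag in seconds.
#' @return List of class `motion_summary` with `speed` (px/s),
#'   `angular_speed` (rad/s), `path_length` (px), `span` (px),
#'   `diffusion` (px^2/s), `cell_visits`.
#' @export
motion_summary <- function(traj, max_lag = 10) {
  n <- nrow(traj)
  if (n < 2) stop("trajectory needs at least 2 detections")
  dx <- diff(traj$x); dy <- diff(traj$y); dt <- diff(traj$t)
  disp <- sqrt(dx^2 + dy^2)
  speed <- mean(disp / dt)
  heading <- atan2(dx, -dy)
  moving <- disp > 0
  ang <- NA_real_
  if (sum(moving) >= 2) {
    hm <- heading[moving]
    dth <- abs(wrap_angle(diff(hm)))
    tm <- traj$t[-n][moving]
    ang <- mean(dth / diff(tm))
  } else ang <- 0
  span <- sqrt(diff(range(traj$x))^2 + diff(range(traj$y))^2)
  # MSD linear fit
  dt0 <- stats::median(dt)
  max_k <- max(1L, floor(max_lag / dt0))
  ks <- seq_len(min(max_k, n - 1L))
  msd <- vapply(ks, function(k) {
    mean((traj$x[-seq_len(k)] - traj$x[seq_len(n - k)])^2 +
         (traj$y[-seq_len(k)] - traj$y[seq_len(n - k)])^2)
  }, numeric(1))
  lag_s <- ks * dt0
  D <- if (length(ks) >= 2)
    unname(stats::coef(stats::lm(msd ~ lag_s))[2] / 4) else msd[1] / (4 * lag_s[1])
  visits <- if (!is.null(traj$b)) sum(diff(traj$b) == 1) else NA_integer_
  structure(list(speed = speed, angular_speed = ang,
                 path_length = sum(disp), span = span,
                 diffusion = D, cell_visits = visits),
            class = "motion_summary")
}

#' Motion summaries for every trajectory in a track set
#'
#' @param tracks A `bee_tracks` object or trajectory `data.frame`.
#' @return `data.frame` with one row per trajectory.
#' @export
motion_summaries <- function(tracks) {
  df <- if (inherits(tracks, "bee_tracks")) tracks$trajectories else tracks
  out <- lapply(split(df, df$traj_id), function(tr) {
    m <- motion_summary(tr)
    data.frame(traj_id = tr$traj_id[1], speed = m$speed,
               angular_speed = m$angular_speed,
               path_length = m$path_length, span = m$span,
               diffusion = m$diffusion, cell_visits = m$cell_visits)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Entrance enrichment of top-ranked trajectories
#'
#' The fraction of positions of the `k` top-ranked trajectories (by the
#' supplied per-trajectory metric) falling inside the entrance region is
#' compared with the same fraction for random trajectory subsets of size
#' `k`. Enrichment is observed / mean permuted fraction; the permutation
#' p-value is `(1 + #permutations >= observed) / (1 + n_perm)`.
#'
#' @param tracks A `bee_tracks` object or trajectory `data.frame`.
#' @param metric Named numeric vector (names = trajectory ids) used to
#'   rank trajectories.
#' @param k Number of top trajectories.
#' @param region Entrance region (as in [tracker_params()]).
#' @param n_perm Number of permutations (>= 999).
#' @param seed Integer seed.
#' @return List with `enrichment`, `p.value`, `observed_fraction`,
#'   `background_fraction`.
#' @export
entrance_enrichment <- function(tracks, metric, k = 100, region,
                                n_perm = 999, seed = 1L) {
  if (is.null(region)) stop("entrance region must be supplied")
  df <- if (inherits(tracks, "bee_tracks")) tracks$trajectories else tracks
  ids <- unique(df$traj_id)
  if (k > length(ids)) stop("k exceeds the number of trajectories")
  if (n_perm < 999) stop("use at least 999 permutations")
  frac_inside <- function(sel_ids) {
    sub <- df[df$traj_id %in% sel_ids, ]
    mean(in_entrance(sub$x, sub$y, region))
  }
  metric <- metric[as.character(ids)]
  top <- ids[order(-metric)][seq_len(k)]
  obs <- frac_inside(top)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm),
                   function(i) frac_inside(sample(ids, k)), numeric(1))
    bg <- mean(perm)
    list(enrichment = if (bg > 0) obs / bg else Inf,
         p.value = (1 + sum(perm >= obs)) / (1 + n_perm),
         observed_fraction = obs, background_fraction = bg)
  })
}
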