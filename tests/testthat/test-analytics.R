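test_that("the periodogram finds a 24 h peak and conserves variance", {
  interval <- 120
  t <- seq(0, 14 * 86400 - interval, by = interval)
  x <- 1000 + 150 * sin(2 * pi * t / (24 * 3600))
  ps <- periodogram(x, interval)
  expect_equal(ps$dominant_period_hours, 24, tolerance = 0.05)
  # constant series: zero power everywhere
  expect_lt(periodogram(rep(5, length(t)), interval)$total_power, 1e-12)
  # Parseval: total one-sided power equals the population variance
  set.seed(6)
  y <- rnorm(length(t))
  psy <- periodogram(y, interval)
  expect_equal(psy$total_power, mean((y - mean(y))^2), tolerance = 1e-8)
  expect_error(periodogram(rnorm(100), 60), "2 days")
})

test_that("white noise concentrates no dominant power", {
  set.seed(8)
  interval <- 600
  n <- 4 * 86400 / interval
  for (rep in 1:5) {
    ps <- periodogram(rnorm(n), interval)
    expect_lt(max(ps$power) / ps$total_power, 0.2)
  }
})

test_that("the Rayleigh test behaves at the concentration extremes", {
  conc <- rayleigh_test(rep(3, 100))
  expect_lt(conc$p.value, 1e-4)
  anti <- rayleigh_test(rep(c(0, 12), 50))   # balanced antipodal pairs
  expect_lt(anti$rbar, 1e-10)
  expect_gt(anti$p.value, 0.99)
  expect_error(rayleigh_test(1:4), "at least 5")
  # p monotone decreasing in the resultant length at fixed n
  rbars <- seq(0.05, 0.6, by = 0.05)
  ps <- beetrackr:::rayleigh_p(50, rbars)
  expect_true(all(diff(ps) < 0))
})

test_that("the Rayleigh test rejects concentrated circular samples", {
  # von Mises sample via Best-Fisher rejection sampling (test-side oracle)
  rvm <- function(n, mu, kappa) {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(n); i <- 0
    while (i < n) {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        i <- i + 1
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      }
    }
    out
  }
  set.seed(13)
  rej <- vapply(1:50, function(s) {
    hours <- rvm(200, pi, 2) * 24 / (2 * pi)
    rayleigh_test(hours)$p.value < 1e-4
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("nightly high counts locate the cell-bee peak hour", {
  interval <- 600
  t <- seq(0, 6 * 86400 - interval, by = interval)
  hours <- (t / 3600) %% 24
  x <- 100 + 30 * cos(2 * pi * (hours - 2) / 24)
  nh <- nightly_high_counts(t, x, interval)
  expect_lt(min(abs(nh$mean_hour - 2), 24 - abs(nh$mean_hour - 2)), 0.75)
  expect_equal(sum(nh$histogram), length(nh$hours))
  # constant series: nothing is strictly above the median
  nh0 <- nightly_high_counts(t, rep(7, length(t)), interval)
  expect_equal(sum(nh0$histogram), 0)
})

test_that("windowed correlation recovers constructed dependence", {
  set.seed(10)
  interval <- 600
  t <- seq(0, 7 * 86400 - interval, by = interval)
  bees <- 1000 + 150 * sin(2 * pi * t / 86400) + rnorm(length(t), 0, 5)
  wc <- windowed_correlation(t, bees, t, -bees + rnorm(length(t), 0, 1))
  expect_lt(wc$r, -0.99)
  wc_same <- windowed_correlation(t, bees, t, bees)
  expect_equal(wc_same$r, 1, tolerance = 1e-9)
  # independent series: small mean |r| across seeds
  rs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    windowed_correlation(t, rnorm(length(t)), t, rnorm(length(t)))$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.5)
  expect_error(windowed_correlation(1:10, 1:10, 1:10, 1:10,
                                    window = 1000), "3 overlapping")
})

test_that("brood distances separate constructed classes", {
  brood <- data.frame(x = 0, y = 0)
  eq <- data.frame(x = c(10, -10, 10, -10), y = 0, b = c(1, 1, 2, 2))
  res <- suppressWarnings(brood_distance_stats(eq, brood, px_per_mm = 1))
  expect_equal(res$difference_mm, 0)
  expect_equal(res$p.value, 1)
  # cell-bees 10 mm closer by construction (2 px/mm)
  set.seed(3)
  n <- 200
  det <- data.frame(
    x = c(40 + rnorm(n), 20 + rnorm(n)), y = 0,
    b = rep(c(1L, 2L), each = n))
  r2 <- brood_distance_stats(det, brood, px_per_mm = 2)
  expect_equal(r2$difference_mm, 10, tolerance = 1)
  expect_lt(r2$p.value, 1e-4)
  one <- data.frame(x = c(1, 2), y = 0, b = c(1, 2))
  expect_error(brood_distance_stats(one, brood), "at least 2")
  expect_error(brood_distance_stats(det, brood[0, ]), "empty")
})

test_that("motion metrics match closed forms on constructed trajectories", {
  # stationary trajectory: every metric zero
  still <- data.frame(t = (0:99) / 10, x = 5, y = 5, b = 1L)
  ms <- motion_summary(still)
  expect_equal(ms$speed, 0)
  expect_equal(ms$path_length, 0)
  expect_equal(ms$span, 0)
  expect_equal(ms$diffusion, 0, tolerance = 1e-12)
  # uniform straight motion
  v <- 3                                   # px per frame at 10 FPS
  straight <- data.frame(t = (0:199) / 10, x = v * (0:199), y = 7, b = 1L)
  m2 <- motion_summary(straight)
  expect_equal(m2$speed, v * 10)
  expect_equal(m2$angular_speed, 0)
  expect_equal(m2$path_length, m2$span, tolerance = 1e-9)
  expect_error(motion_summary(still[1, ]), "at least 2")
  # translation invariance
  shifted <- straight; shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 50
  m3 <- motion_summary(shifted)
  expect_equal(m3$speed, m2$speed)
  expect_equal(m3$span, m2$span)
  # cell visits count 1 -> 2 transitions
  tv <- data.frame(t = (0:5) / 10, x = 1:6, y = 0,
                   b = c(1L, 2L, 2L, 1L, 2L, 1L))
  expect_equal(motion_summary(tv)$cell_visits, 2)
})

test_that("diffusion estimates recover sigma^2 * fps / 4 for a random walk", {
  set.seed(15)
  n <- 10000; fps <- 10; sigma <- 2
  steps_x <- rnorm(n, 0, sigma / sqrt(2))
  steps_y <- rnorm(n, 0, sigma / sqrt(2))
  traj <- data.frame(t = (0:n) / fps, x = c(0, cumsum(steps_x)),
                     y = c(0, cumsum(steps_y)), b = 1L)
  D <- motion_summary(traj)$diffusion
  expect_equal(D, sigma^2 * fps / 4, tolerance = 0.2)
})

test_that("entrance enrichment detects entrance-bound dancers", {
  region <- list(shape = "disk", x = 0, y = 0, r = 10)
  mk_traj <- function(id, cx, cy) data.frame(
    traj_id = id, frame = 0:19, t = (0:19) / 10,
    x = cx + rnorm(20, 0, 2), y = cy + rnorm(20, 0, 2), b = 1L,
    alpha = 0, det_row = 1L)
  set.seed(20)
  inside <- do.call(rbind, lapply(1:5, function(i) mk_traj(i, 0, 0)))
  outside <- do.call(rbind, lapply(6:40, function(i)
    mk_traj(i, 200, 200)))
  df <- rbind(inside, outside)
  metric <- stats::setNames(c(rep(10, 5), rep(1, 35)), 1:40)
  res <- entrance_enrichment(df, metric, k = 5, region, n_perm = 999,
                             seed = 1)
  expect_equal(res$p.value, 1 / 1000)
  expect_gt(res$enrichment, 2)
  # uniform metric: no enrichment
  unif <- stats::setNames(rnorm(40), 1:40)
  shuffled <- df
  res2 <- entrance_enrichment(shuffled, unif, k = 20, region,
                              n_perm = 999, seed = 2)
  expect_gt(res2$p.value, 0.05)
  expect_error(entrance_enrichment(df, metric, k = 100, region), "exceeds")
  expect_error(entrance_enrichment(df, metric, k = 5, NULL), "region")
})
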