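test_that("volume-weighted average matches hand and brute-force values", {
  expect_equal(volume_weighted_average(c(0, 4), c(1, 3)), 3)
  expect_equal(volume_weighted_average(rep(2.5, 10), runif(10) + 0.1), 2.5)
  set.seed(5)
  c <- matrix(runif(200), 20, 10); v <- matrix(runif(200) + 0.01, 20, 10)
  acc <- 0
  for (q in seq_along(c)) acc <- acc + v[q] * c[q]
  expect_equal(volume_weighted_average(c, v), acc / sum(v))
  expect_error(volume_weighted_average(c(1, 2), c(0, 0)), "positive")
  expect_error(volume_weighted_average(1:3, 1:2), "shape")
})

test_that("strip averages cover the right nodes and match closed forms", {
  g <- tiny_geometry()
  # a 1-um strip at dx = 0.1 covers 10 node rows
  marker <- matrix(0, g$nx, g$ny)
  marker[, 11:20] <- 1
  expect_equal(strip_average(marker, g, axis = "y", center = 1.55, width = 1),
               1)
  # full-width strip equals the volume-weighted whole-field average
  f <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  expect_equal(strip_average(f, g, axis = "y", center = 2, width = 100),
               volume_weighted_average(f, g$v_i))
  # field linear in y: strip trace equals the analytic strip mean
  # (uniform volume fractions make the weighted mean the arithmetic mean)
  g2 <- g; g2$v_i[] <- 0.9
  y <- (col(f) - 0.5) * g$dy
  lin <- y
  got <- strip_average(lin, g2, axis = "y", center = 2, width = 0.5)
  pos <- ((1:g$ny) - 0.5) * g$dy
  rows <- which(pos >= 1.75 - 1e-9 & pos < 2.25 - 1e-9)  # half-open strip
  expect_equal(got, mean(pos[rows]))
  expect_error(strip_average(f, g, axis = "y", center = 50, width = 0.2),
               "no nodes")
})

make_movie <- function(discs, nx = 120, ny = 80, nt = 8, base = 0.1) {
  # discs: list of (x, y, r, amp, t0, t1) in node units
  mv <- array(base, dim = c(nx, ny, nt))
  for (d in discs) {
    sel <- outer((1:nx) - d$x, (1:ny) - d$y,
                 function(a, b) sqrt(a^2 + b^2) <= d$r)
    for (t in d$t0:d$t1) mv[, , t][sel] <- d$amp
  }
  mv
}

test_that("spark detector counts constructed fixtures exactly", {
  dx <- 0.1
  times <- (1:8) * 2
  # empty movie: nothing above threshold
  mv0 <- make_movie(list())
  expect_equal(nrow(detect_sparks(mv0, dx, times, amplitude_threshold = 0.3)),
               0)
  # one immobile disc of radius 2 um for 5 frames: exactly one event
  mv1 <- make_movie(list(list(x = 60, y = 40, r = 20, amp = 2, t0 = 2, t1 = 6)))
  ev1 <- detect_sparks(mv1, dx, times, amplitude_threshold = 0.3)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$max_radius_um, 2, tolerance = 0.05)
  expect_equal(ev1$t_start_ms, 4)
  expect_equal(ev1$t_end_ms, 12)
  expect_equal(ev1$x_um, 60 * dx - 0.05, tolerance = 0.05)
  # two discs 10 um apart: two events; overlapping discs: one event
  mv2 <- make_movie(list(list(x = 30, y = 40, r = 18, amp = 2, t0 = 2, t1 = 5),
                         list(x = 100, y = 40, r = 18, amp = 2, t0 = 3, t1 = 6)))
  expect_equal(nrow(detect_sparks(mv2, dx, times, amplitude_threshold = 0.3)),
               2)
  mv3 <- make_movie(list(list(x = 55, y = 40, r = 18, amp = 2, t0 = 2, t1 = 5),
                         list(x = 70, y = 40, r = 18, amp = 2, t0 = 2, t1 = 5)))
  expect_equal(nrow(detect_sparks(mv3, dx, times, amplitude_threshold = 0.3)),
               1)
})

test_that("spark detection is monotone in both thresholds", {
  set.seed(9)
  mv <- array(0.1 + 0.05 * runif(60 * 40 * 10), dim = c(60, 40, 10))
  for (q in 1:6)
    mv[sample(10:50, 1) + (-8:8), sample(10:30, 1) + (-6:6), sample(2:9, 1)] <- 1.5
  times <- (1:10) * 2
  n <- function(amp, r) nrow(detect_sparks(mv, 0.1, times,
                                           amplitude_threshold = amp,
                                           radius_threshold = r))
  expect_gte(n(0.5, 0.4), n(1.0, 0.4))
  expect_gte(n(1.0, 0.4), n(1.0, 0.8))
  expect_gte(n(0.5, 0.4), n(0.5, 0.8))
})

test_that("spark frequency counts events per unit time within a region", {
  ev <- data.frame(t_start_ms = 1:6, t_end_ms = 2:7,
                   x_um = c(1, 1, 1, 9, 9, 9), y_um = rep(2, 6),
                   max_radius_um = 2, peak_amplitude_uM = 1)
  expect_equal(spark_frequency(ev, 2000), 3)
  expect_equal(spark_frequency(ev[0, ], 500), 0)
  expect_equal(spark_frequency(ev, 1000, region = c(0, 5, 0, 4)), 3)
})

test_that("front tracking recovers a constructed constant speed", {
  # front moving at exactly 200 um/s = 0.2 um/ms on a 1D ladder
  nx <- 150; dx <- 0.1
  times <- seq(0, 50, by = 1)
  prof <- sapply(times, function(t) {
    x <- ((1:nx) - 0.5) * dx
    ifelse(x <= 1 + 0.2 * t, 1, 0.1)
  })
  tr <- track_front(prof, times, dx, threshold = 0.5)
  expect_false(tr$stalled)
  expect_equal(tr$fitted_speed_um_s, 200, tolerance = 0.01)
  # stationary field: stalled, undefined speed
  tr0 <- track_front(matrix(0.1, nx, length(times)), times, dx, threshold = 0.5)
  expect_true(tr0$stalled)
  expect_true(is.na(tr0$fitted_speed_um_s))
  # jittered front: slope within the regression standard error
  set.seed(21)
  pos <- 1 + 0.15 * times + rnorm(length(times), 0, 0.05)
  prof2 <- sapply(seq_along(times), function(q) {
    ifelse(((1:nx) - 0.5) * dx <= pos[q], 1, 0.1) })
  tr2 <- track_front(prof2, times, dx, threshold = 0.5)
  fit <- lm(pos ~ times)
  se <- summary(fit)$coefficients[2, 2] * 1000
  expect_lt(abs(tr2$fitted_speed_um_s - 150), 4 * se + 10)
})

test_that("front tracking is invariant under uniform amplitude scaling", {
  nx <- 100; dx <- 0.1
  times <- seq(0, 30, by = 1)
  prof <- sapply(times, function(t)
    ifelse(((1:nx) - 0.5) * dx <= 1 + 0.18 * t, 0.8, 0.05))
  a <- track_front(prof, times, dx, threshold = 0.4)
  b <- track_front(5 * prof, times, dx, threshold = 2)
  expect_equal(a$fitted_speed_um_s, b$fitted_speed_um_s)
})

test_that("transient features recover analytic beat shapes", {
  t <- seq(0, 799, by = 1)
  expect_equal(transient_features(rep(0.3, 800), t, 800)$peak, 0.3)
  expect_equal(transient_features(rep(0.3, 800), t, 800)$diastolic, 0.3)
  # triangular pulse: peak 1.0 at t = 100
  tri <- ifelse(t <= 100, 0.1 + 0.9 * t / 100,
                pmax(0.1, 1 - (t - 100) / 200 * 0.9))
  f <- transient_features(tri, t, 800)
  expect_equal(f$peak, 1.0, tolerance = 1e-9)
  expect_equal(f$time_to_peak_ms, 100)
  # two identical beats average to the single-beat features
  f2 <- transient_features(c(tri, tri), seq(0, 1599, by = 1), 800)
  expect_equal(f2$peak, f$peak)
  expect_equal(nrow(f2$per_beat), 2)
})

test_that("analysis operators do not mutate their inputs", {
  g <- tiny_geometry()
  f <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  f0 <- f + 0
  invisible(strip_average(f, g, axis = "y", center = 2, width = 1))
  invisible(volume_weighted_average(f, g$v_i))
  expect_identical(f, f0)
})
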