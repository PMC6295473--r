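test_that("RyR transition rates follow the configured calcium dependence", {
  p <- sim_params(ryr_h = 2, ryr_ki_ca = 0, ryr_ki = 0.01)
  r0 <- ryr_transition_rates(c(9L, 0L, 0L, 0L), 0, p)
  expect_equal(unname(r0["C_O"]), 0)
  r1 <- ryr_transition_rates(c(9L, 0L, 0L, 0L), 1, p)
  r2 <- ryr_transition_rates(c(9L, 0L, 0L, 0L), 2, p)
  expect_equal(unname(r2["C_O"] / r1["C_O"]), 4)  # h = 2 power law
  expect_equal(unname(r1["C_I2"]), 9 * 0.01)      # constant inactivation mode
  expect_error(ryr_transition_rates(c(9L, 0L, 0L, 0L), -1, p), ">= 0")
})

test_that("LCC rates activate with depolarization, occupancy sums conserved", {
  p <- sim_params()
  r_rest <- lcc_transition_rates(c(5L, 0L, 0L, 0L, 0L), -80, 0.1, p)
  r_dep <- lcc_transition_rates(c(5L, 0L, 0L, 0L, 0L), 0, 0.1, p)
  expect_gt(r_dep["C1_C2"], r_rest["C1_C2"] * 100)
  # calcium-dependent inactivation grows with local calcium
  rI <- lcc_transition_rates(c(0L, 0L, 5L, 0L, 0L), 0, 10, p)["O_I1"]
  rI0 <- lcc_transition_rates(c(0L, 0L, 5L, 0L, 0L), 0, 0.1, p)["O_I1"]
  expect_gt(rI, rI0)
  expect_error(lcc_transition_rates(c(5L, 0L, 0L, 0L, 0L), NaN, 0.1, p),
               "finite")
})

test_that("channel counts are conserved under arbitrary gating sequences", {
  p <- sim_params()
  g <- tiny_geometry()
  ch <- init_channels(g)
  set.seed(99)
  for (q in 1:30) {
    ci <- runif(ncol(ch$ryr), 0, 20)
    cl <- runif(ncol(ch$lcc), 0, 20)
    ch <- gillespie_advance(ch, ci, cl, runif(1, -80, 20), 2, p)
    expect_true(all(colSums(ch$ryr) == g$ryr_count[ch$ryr_nodes]))
    expect_true(all(colSums(ch$lcc) == 5L))
    expect_true(all(ch$ryr >= 0L), all(ch$lcc >= 0L))
  }
})

test_that("gating trajectories are bit-identical under a fixed seed", {
  p <- sim_params()
  g <- tiny_geometry()
  run <- function(seed) {
    set.seed(seed)
    ch <- init_channels(g)
    for (q in 1:10)
      ch <- gillespie_advance(ch, rep(5, ncol(ch$ryr)),
                              rep(5, ncol(ch$lcc)), 0, 1, p)
    ch
  }
  expect_identical(run(5)$ryr, run(5)$ryr)
  expect_identical(run(5)$lcc, run(5)$lcc)
  expect_false(identical(run(5)$ryr, run(6)$ryr))
})

test_that("two-state reduction recovers the analytic stationary occupancy", {
  # ki = 0 collapses the square scheme to C <-> O with rates
  # a = ka c^h (open), b = km (close)
  p <- sim_params(ryr_ka = 0.02, ryr_h = 2, ryr_km = 0.4, ryr_ki = 0,
                  ryr_ki_ca = 0)
  cfix <- 4
  a <- 0.02 * cfix^2; b <- 0.4
  p_open <- a / (a + b)
  n_ch <- 50L
  ch <- list(ryr_nodes = 1:n_ch,
             ryr = rbind(rep(1L, n_ch), 0L, 0L, 0L),
             lcc_nodes = integer(0), lcc = matrix(0L, 5, 0))
  class(ch) <- "channel_states"
  set.seed(31)
  # burn-in, then time-average the open fraction
  ch <- gillespie_advance(ch, rep(cfix, n_ch), numeric(0), -80, 50, p)
  tot <- 0; n_windows <- 200L
  for (q in seq_len(n_windows)) {
    ch <- gillespie_advance(ch, rep(cfix, n_ch), numeric(0), -80, 5, p)
    tot <- tot + sum(ch$ryr[2, ])
  }
  phat <- tot / (n_windows * n_ch)
  # 3 standard errors with an effective sample size that accounts for the
  # exponential autocorrelation of the chain across 5 ms windows
  tau <- 1 / (a + b)
  n_eff <- n_windows * n_ch / max(1, 2 * tau / 5)
  se <- sqrt(p_open * (1 - p_open) / n_eff)
  expect_lt(abs(phat - p_open), 3 * se + 1e-3)
})

test_that("first-transition waiting times are exponential (KS test)", {
  p <- sim_params(ryr_ka = 0.05, ryr_h = 2, ryr_km = 0.3, ryr_ki = 0,
                  ryr_ki_ca = 0)
  cfix <- 2
  rate <- 0.05 * cfix^2  # single closed channel: total propensity = ka c^2
  set.seed(17)
  wt <- ryr_first_event_time(10000, c(1L, 0L, 0L, 0L), cfix, Inf, p)
  ks <- suppressWarnings(ks.test(wt, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean open time equals the reciprocal total exit rate from O", {
  p <- sim_params(ryr_km = 0.25, ryr_ki = 0.004, ryr_ki_ca = 0)
  cfix <- 1  # activation does not matter when starting from O
  exit <- 0.25 + 0.004
  set.seed(23)
  wt <- ryr_first_event_time(8000, c(0L, 1L, 0L, 0L), cfix, Inf, p)
  se <- (1 / exit) / sqrt(8000)
  expect_lt(abs(mean(wt) - 1 / exit), 4 * se)
})

test_that("LCC stationary open probability at rest is negligible", {
  p <- sim_params()
  # single-channel generator assembled from the exported transition rates
  states <- diag(5)
  storage.mode(states) <- "integer"
  arrows <- list(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3),
                 c(3, 5), c(5, 3))
  Q <- matrix(0, 5, 5)
  for (s in 1:5) {
    r <- lcc_transition_rates(states[s, ], -80, 0.1, p)
    for (q in seq_along(arrows)) {
      if (arrows[[q]][1] == s && r[q] > 0) Q[s, arrows[[q]][2]] <- r[q]
    }
  }
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 5))
  pi_st <- qr.solve(A, c(rep(0, 5), 1))
  expect_lt(pi_st[3], 1e-3)  # open-state occupancy
  expect_gt(pi_st[1], 0.99)  # essentially all channels deep-closed
})
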