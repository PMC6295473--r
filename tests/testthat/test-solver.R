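test_that("divergence-form operator reduces to the 5-point stencil", {
  set.seed(3)
  c <- matrix(runif(30 * 20), 30, 20)
  D <- matrix(0.25, 30, 20)
  L <- laplacian_divergence_form(c, D, 0.1)
  expect_equal(max(abs(laplacian_divergence_form(matrix(1, 30, 20), D, 0.1))),
               0)
  # interior stencil oracle
  i <- 11; j <- 9
  want <- 0.25 * (c[i + 1, j] + c[i - 1, j] + c[i, j + 1] + c[i, j - 1] -
                    4 * c[i, j]) / 0.01
  expect_equal(L[i, j], want, tolerance = 1e-12)
  expect_error(laplacian_divergence_form(c, D[1:10, ], 0.1), "shape")
  expect_error(laplacian_divergence_form(c, -D, 0.1), "positive")
})

test_that("Gaussian variance grows as 2 D t under pure diffusion", {
  nx <- 100; dx <- 0.1; D <- 0.25
  x <- ((1:nx) - 0.5) * dx
  s0 <- 0.6
  c <- outer(exp(-(x - 5)^2 / (2 * s0^2)), exp(-(x - 5)^2 / (2 * s0^2)))
  Df <- matrix(D, nx, nx)
  dt <- 0.008; nsteps <- 250
  for (q in seq_len(nsteps)) c <- c + dt * laplacian_divergence_form(c, Df, dx)
  t_end <- dt * nsteps
  marg <- rowSums(c)
  mu <- sum(x * marg) / sum(marg)
  v <- sum((x - mu)^2 * marg) / sum(marg)
  expect_equal(v, s0^2 + 2 * D * t_end, tolerance = 0.01)
})

test_that("total calcium diagnostic matches a brute-force summation", {
  g <- tiny_geometry()
  p <- quiet_params()
  st <- init_state(g, p)
  expect_equal(total_calcium(
    structure(list(c_i = 0 * st$c_i, c_sr = 0 * st$c_sr, b_tnc = 0 * st$b_tnc,
                   b_cam = 0 * st$b_cam, b_srb = 0 * st$b_srb, t = 0),
              class = "field_state"), g), 0)
  set.seed(8)
  st$c_i[] <- runif(length(st$c_i)); st$c_sr[] <- runif(length(st$c_sr), 0, 900)
  tot <- 0
  for (j in 1:g$nx) for (k in 1:g$ny) {
    tot <- tot + g$v_i[j, k] * (st$c_i[j, k] + st$b_tnc[j, k] +
                                  st$b_cam[j, k] + st$b_srb[j, k]) +
      g$v_sr[j, k] * st$c_sr[j, k]
  }
  expect_equal(total_calcium(st, g), tot * g$dx * g$dy, tolerance = 1e-12)
})

test_that("uniform equilibrium state is a fixed point of the stepper", {
  g <- channel_free(tiny_geometry())
  p <- quiet_params()
  st <- init_state(g, p)
  ch <- init_channels(g)
  res <- run_steps(st, g, ch, p, solver_config(record_ms = 1), n_steps = 100)
  expect_equal(res$state$c_i, st$c_i, tolerance = 1e-14)
  expect_equal(res$state$c_sr, st$c_sr, tolerance = 1e-14)
  expect_equal(res$state$b_srb, st$b_srb, tolerance = 1e-14)
})

test_that("closed cell conserves total calcium despite release activity", {
  g <- build_geometry(geometry_config(Lx = 5, Ly = 4, seed = 6))
  p <- sim_params(g_cal = 0, k_ncx = 0)  # closed-cell configuration
  st <- init_state(g, p)
  ch <- init_channels(g)
  # force release activity: open all channels at a few nodes
  ch$ryr[1, 1:5] <- 0L
  ch$ryr[2, 1:5] <- 9L
  tot0 <- total_calcium(st, g)
  set.seed(12)
  res <- run_steps(st, g, ch, p, solver_config(record_ms = 5),
                   n_steps = 2000)
  tot1 <- total_calcium(res$state, g)
  expect_gt(res$gating_events, 0)
  expect_lt(abs(tot1 - tot0) / tot0, 1e-6)
})

test_that("no-flux boundaries conserve a point release near the edge", {
  g <- channel_free(tiny_geometry())
  p <- quiet_params()
  st <- init_state(g, p)
  st$c_i[2, 2] <- 50  # near-corner point elevation
  tot0 <- total_calcium(st, g)
  ch <- init_channels(g)
  res <- run_steps(st, g, ch, p, solver_config(), n_steps = 500)
  expect_lt(abs(total_calcium(res$state, g) - tot0) / tot0, 1e-10)
})

test_that("immobile SR field: with D_sr = 0 and SR fluxes off, c_sr is frozen", {
  g <- channel_free(tiny_geometry())
  g$D_sr[] <- 0
  p <- quiet_params()
  st <- init_state(g, p)
  set.seed(4)
  st$c_sr[] <- runif(length(st$c_sr), 100, 900)
  ch <- init_channels(g)
  res <- run_steps(st, g, ch, p, solver_config(), n_steps = 300)
  expect_equal(res$state$c_sr, st$c_sr, tolerance = 1e-14)
})

test_that("stepper is deterministic and respects the stability bound", {
  g <- tiny_geometry()
  p <- sim_params()
  st <- init_state(g, p)
  ch <- init_channels(g)
  run <- function() {
    set.seed(44)
    run_steps(st, g, ch, p, solver_config(record_ms = 1), n_steps = 500)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$state$c_i, r2$state$c_i)
  expect_identical(r1$records$ci_avg, r2$records$ci_avg)
  expect_error(run_steps(st, g, ch, p,
                         solver_config(dt = 10 * dt_max(g)), n_steps = 1),
               "stability")
})

test_that("concentrations stay non-negative and buffers bounded", {
  g <- tiny_geometry()
  p <- sim_params()
  st <- init_state(g, p)
  ch <- init_channels(g)
  ch$ryr[1, ] <- 0L; ch$ryr[2, ] <- g$ryr_count[ch$ryr_nodes]  # all open
  set.seed(2)
  res <- run_steps(st, g, ch, p, solver_config(), n_steps = 2000)
  expect_true(all(res$state$c_i >= 0), all(res$state$c_sr >= 0))
  expect_true(all(res$state$b_tnc <= p$tnc_B + 1e-9))
  expect_true(all(res$state$b_cam <= p$cam_B + 1e-9))
  expect_true(all(res$state$b_srb <= p$srb_B + 1e-9))
})

test_that("halving dt self-converges (first-order splitting)", {
  g <- channel_free(tiny_geometry())
  p <- quiet_params(v_up = 0.3, g_leak = 5e-5)  # smooth deterministic terms
  st <- init_state(g, p)
  st$c_i <- st$c_i + 2 * exp(-((row(st$c_i) - 30)^2 + (col(st$c_i) - 20)^2) / 50)
  ch <- init_channels(g)
  dt0 <- 0.8 * dt_max(g)
  out <- lapply(c(1, 2, 4), function(f) {
    run_steps(st, g, ch, p, solver_config(dt = dt0 / f),
              n_steps = round(10 / (dt0 / f)))$state$c_i
  })
  e1 <- max(abs(out[[1]] - out[[3]]))
  e2 <- max(abs(out[[2]] - out[[3]]))
  expect_lt(e2, e1)           # refinement reduces the error
  expect_lt(e1, 1e-3)         # and the error is already small
})

test_that("single step advances the clock by dt and preserves shapes", {
  g <- tiny_geometry()
  p <- sim_params()
  st <- init_state(g, p)
  ch <- init_channels(g)
  sv <- solver_config(dt = 0.005)
  set.seed(1)
  res <- step(st, g, ch, p, sv)
  expect_equal(res$state$t, 0.005)
  expect_equal(dim(res$state$c_i), c(g$nx, g$ny))
})
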