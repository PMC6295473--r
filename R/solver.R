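#' Solver configuration
#'
#' Time step and output control for the explicit finite-volume integrator.
#' The time step must satisfy a monotonicity/stability bound derived from
#' the volume-fraction-weighted face conductances; by default it is set to
#' `safety` times that bound.
#'
#' @param dt Time step (ms); `NULL` picks `safety * dt_max(geom)`.
#' @param safety Safety factor in (0, 1] applied to the stability bound.
#' @param record_ms Stride (ms) for recorded traces and profiles.
#' @param snap_ms Stride (ms) for full-field snapshots (0 = off).
#' @return A `solver_config` list.
#' @export
solver_config <- function(dt = NULL, safety = 0.9, record_ms = 1,
                          snap_ms = 0) {
  stopifnot(is.null(dt) || dt > 0, safety > 0, safety <= 1, record_ms > 0,
            snap_ms >= 0)
  structure(list(dt = dt, safety = safety, record_ms = record_ms,
                 snap_ms = snap_ms), class = "solver_config")
}

# Face conductances for the conservative diffusion operator: harmonic mean
# of v*D on the two sides of each face, divided by dx^2.  gx[j, k] is the
# face between nodes (j, k) and (j+1, k) (last row zero); gy likewise in y.
# Each face value is shared by its two nodes and the update is scaled by
# 1/(v dx^2) locally, so the discrete scheme conserves sum(v * c) exactly
# with zero-flux outer boundaries.
face_conductances <- function(v, D, dx) {
  nx <- nrow(v); ny <- ncol(v)
  vD <- v * D
  hm <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  gx <- matrix(0, nx, ny); gy <- matrix(0, nx, ny)
  gx[-nx, ] <- hm(vD[-nx, , drop = FALSE], vD[-1, , drop = FALSE]) / dx^2
  gy[, -ny] <- hm(vD[, -ny, drop = FALSE], vD[, -1, drop = FALSE]) / dx^2
  list(gx = gx, gy = gy)
}

# Per-node relaxation rate of the explicit diffusion update (1/ms).
relax_rate <- function(v, D, dx) {
  f <- face_conductances(v, D, dx)
  nx <- nrow(v); ny <- ncol(v)
  gW <- matrix(0, nx, ny); gS <- matrix(0, nx, ny)
  gW[-1, ] <- f$gx[-nx, ]; gS[, -1] <- f$gy[, -ny]
  (f$gx + gW + f$gy + gS) / v
}

# Assemble the geometry-derived arrays consumed by the C++ stepper.
core_geometry <- function(geom, params) {
  fi <- face_conductances(geom$v_i, geom$D_i, geom$dx)
  fs <- face_conductances(geom$v_sr, geom$D_sr, geom$dx)
  tnc_B <- matrix(0, geom$nx, geom$ny)
  tnc_B[geom$domain == SARCOMERE] <- params$tnc_B
  list(nx = geom$nx, ny = geom$ny,
       v_i = geom$v_i, v_sr = geom$v_sr,
       ratio = geom$v_i / geom$v_sr,
       tnc_B = tnc_B,
       gx_i = fi$gx, gy_i = fi$gy, gx_s = fs$gx, gy_s = fs$gy,
       inv_vi = 1 / geom$v_i, inv_vsr = 1 / geom$v_sr,
       membrane = which(geom$domain == MEMBRANE))
}

#' Maximal stable time step for a geometry
#'
#' The explicit update at node p relaxes at rate
#' `sum_faces g / (v_p dx^2)`; monotonicity (and hence positivity) of the
#' diffusion update requires `dt * rate <= 1` everywhere.
#'
#' @param geom A `cell_geometry`.
#' @return Bound on dt (ms).
#' @export
dt_max <- function(geom) {
  1 / max(max(relax_rate(geom$v_i, geom$D_i, geom$dx)),
          max(relax_rate(geom$v_sr, geom$D_sr, geom$dx)))
}

#' Initialize the dynamic field state
#'
#' Uniform diastolic fields with every buffer at its binding equilibrium
#' for the initial cytosolic calcium.
#'
#' @param geom A `cell_geometry`.
#' @param params A [sim_params()].
#' @param c_i0,c_sr0 Initial concentrations (uM); default from `params`.
#' @return A `field_state` list (`c_i`, `c_sr`, `b_tnc`, `b_cam`, `b_srb`,
#'   `t`).
#' @export
init_state <- function(geom, params, c_i0 = params$c_i0,
                       c_sr0 = params$c_sr0) {
  eq <- function(B, kon, koff) B * kon * c_i0 / (kon * c_i0 + koff)
  b_tnc <- matrix(0, geom$nx, geom$ny)
  b_tnc[geom$domain == SARCOMERE] <- eq(params$tnc_B, params$tnc_kon,
                                        params$tnc_koff)
  structure(list(
    c_i = matrix(c_i0, geom$nx, geom$ny),
    c_sr = matrix(c_sr0, geom$nx, geom$ny),
    b_tnc = b_tnc,
    b_cam = matrix(eq(params$cam_B, params$cam_kon, params$cam_koff),
                   geom$nx, geom$ny),
    b_srb = matrix(eq(params$srb_B, params$srb_kon, params$srb_koff),
                   geom$nx, geom$ny),
    t = 0), class = "field_state")
}

#' Divergence-form diffusion operator
#'
#' Finite-volume discretization of `div(D grad c)` with harmonic-mean face
#' diffusivities and zero-flux (reflecting) outer boundaries.  For uniform
#' D it reduces to the standard 5-point stencil
#' `D (c_E + c_W + c_N + c_S - 4 c)/dx^2` at interior nodes.
#'
#' @param c Concentration field (matrix).
#' @param D Diffusion-coefficient field (matrix, same shape, > 0).
#' @param dx Grid spacing (um).
#' @return Matrix of the same shape.
#' @export
laplacian_divergence_form <- function(c, D, dx) {
  if (!all(dim(c) == dim(D))) stop("c and D must have the same shape")
  if (any(D <= 0)) stop("D must be positive")
  nx <- nrow(c); ny <- ncol(c)
  hm <- function(a, b) 2 * a * b / (a + b)
  L <- matrix(0, nx, ny)
  gx <- hm(D[-nx, , drop = FALSE], D[-1, , drop = FALSE])
  fx <- gx * (c[-1, , drop = FALSE] - c[-nx, , drop = FALSE])
  L[-nx, ] <- L[-nx, ] + fx
  L[-1, ] <- L[-1, ] - fx
  gy <- hm(D[, -ny, drop = FALSE], D[, -1, drop = FALSE])
  fy <- gy * (c[, -1, drop = FALSE] - c[, -ny, drop = FALSE])
  L[, -ny] <- L[, -ny] + fy
  L[, -1] <- L[, -1] - fy
  L / dx^2
}

#' Advance the coupled model
#'
#' Runs `n_steps` explicit steps of the operator-split scheme: (1) exact
#' stochastic gating over dt with fields frozen at step start;
#' (2) conservative diffusion of `c_i` and `c_sr` (monotone at the enforced
#' step bound); (3) reaction update of all fluxes on the diffused values,
#' with the `v_i/v_sr` factor on the SR source and the stiff release
#' exchange integrated exactly as a pairwise relaxation.  Buffers are
#' immobile and updated by an unconditionally bounded implicit rule.  Each
#' sub-update is positivity-preserving, so the closed-cell configuration
#' conserves total calcium to machine precision; a residual guard still
#' clips (and counts in `clips`) any negative value.
#'
#' @param state A `field_state`.
#' @param geom A `cell_geometry`.
#' @param channels A `channel_states`.
#' @param params A [sim_params()].
#' @param solver A [solver_config()].
#' @param n_steps Number of steps.
#' @param clamp Voltage-clamp spec `c(V_rest, V_pulse, pulse_dur, period,
#'   t_offset)`; `period <= 0` holds `V_rest` constant.  Default: constant
#'   resting potential.
#' @param strips Optional integer matrix (one row per strip,
#'   `j0, j1, k0, k1` 1-based node ranges) of rectangles whose
#'   volume-weighted mean trace is recorded.
#' @return A list with updated `state`, `channels`, a `records` data
#'   context (traces, whole-cell fluxes, transversal/longitudinal
#'   profiles, strip traces), optional snapshots, and clip counters.
#' @export
run_steps <- function(state, geom, channels, params, solver, n_steps,
                      clamp = NULL, strips = NULL) {
  dt <- solver$dt
  bound <- dt_max(geom)
  if (is.null(dt)) dt <- solver$safety * bound
  if (dt > bound * (1 + 1e-9))
    stop(sprintf("dt = %g ms violates the stability bound %g ms", dt, bound))
  if (is.null(clamp)) clamp <- c(params$v_rest, params$v_rest, 0, 0, 0)
  if (is.null(strips)) strips <- matrix(0L, 0, 4)
  storage.mode(strips) <- "integer"
  strips0 <- strips
  if (nrow(strips0) > 0) strips0 <- strips0 - 1L  # 0-based for C++
  record_stride <- max(1L, as.integer(round(solver$record_ms / dt)))
  snap_stride <- if (solver$snap_ms > 0)
    max(1L, as.integer(round(solver$snap_ms / dt))) else 0L

  geo <- core_geometry(geom, params)
  res <- .core_run_cpp(geo, unclass(state), channels$ryr, channels$ryr_nodes,
                       channels$lcc, channels$lcc_nodes, unclass(params),
                       as.integer(n_steps), dt, state$t, as.numeric(clamp),
                       record_stride, snap_stride, strips0)

  new_state <- structure(list(c_i = res$c_i, c_sr = res$c_sr,
                              b_tnc = res$b_tnc, b_cam = res$b_cam,
                              b_srb = res$b_srb, t = res$t_end),
                         class = "field_state")
  new_channels <- channels
  new_channels$ryr <- res$ryr
  dimnames(new_channels$ryr) <- dimnames(channels$ryr)
  new_channels$lcc <- res$lcc
  dimnames(new_channels$lcc) <- dimnames(channels$lcc)

  snaps <- NULL
  if (snap_stride > 0 && res$snap_dim[3] > 0)
    snaps <- array(res$snapshots, dim = res$snap_dim)

  list(state = new_state, channels = new_channels, records = res$records,
       snapshots = snaps, snapshot_t = res$snapshot_t, dt = dt,
       clips = c(c_i = res$clip_ci, c_sr = res$clip_csr),
       gating_events = res$gating_events)
}

#' Single solver step
#'
#' One operator-split step of [run_steps()] (gating, reaction, diffusion);
#' the clock advances by `dt`.
#'
#' @inheritParams run_steps
#' @param V Membrane potential held over the step (mV).
#' @return List with updated `state` and `channels`.
#' @export
step <- function(state, geom, channels, params, solver, V = params$v_rest) {
  res <- run_steps(state, geom, channels, params, solver, n_steps = 1L,
                   clamp = c(V, V, 0, 0, 0))
  res$records <- NULL
  res
}

#' Total calcium content of the cell
#'
#' Volume-fraction-weighted sum over all nodes of free cytosolic, bound and
#' SR calcium: `sum(v_i (c_i + sum_b c_b) + v_sr c_sr) dx dy` (uM um^2).
#' Conserved by the closed-cell configuration (no L-type or exchanger
#' flux); used as the solver correctness diagnostic.
#'
#' @param state A `field_state`.
#' @param geom A `cell_geometry`.
#' @return Scalar amount (uM um^2).
#' @export
total_calcium <- function(state, geom) {
  if (!all(dim(state$c_i) == c(geom$nx, geom$ny)))
    stop("state and geometry shapes do not match")
  bound <- state$b_tnc + state$b_cam + state$b_srb
  sum(geom$v_i * (state$c_i + bound) + geom$v_sr * state$c_sr) *
    geom$dx * geom$dy
}
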