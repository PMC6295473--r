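#' Pacing protocol
#'
#' Square voltage-clamp waveform applied periodically: the membrane is held
#' at `v_rest` and stepped to `v_pulse` for `pulse_ms` at the start of each
#' period.  No voltage dynamics are solved (voltage clamp).
#'
#' @param Ts Pacing period (ms).
#' @param prepace_ms Pre-pacing duration before recording starts (ms).
#' @param n_beats Number of recorded beats.
#' @param v_rest,v_pulse Clamp levels (mV).
#' @param pulse_ms Pulse duration (ms); must satisfy `Ts > pulse_ms > 0`.
#' @return A `pacing_protocol` list.
#' @export
pacing_protocol <- function(Ts = 800, prepace_ms = 400, n_beats = 5,
                            v_rest = -80, v_pulse = 0, pulse_ms = 100) {
  if (!(Ts > pulse_ms && pulse_ms > 0))
    stop("need Ts > pulse_ms > 0", call. = FALSE)
  stopifnot(prepace_ms >= 0, n_beats >= 1)
  structure(list(Ts = Ts, prepace_ms = prepace_ms,
                 n_beats = as.integer(n_beats), v_rest = v_rest,
                 v_pulse = v_pulse, pulse_ms = pulse_ms),
            class = "pacing_protocol")
}

#' RyR cluster configuration variants
#'
#' The four microstructure configurations compared in the resting-spark
#' experiment: the control (sigma = 0.4 um dispersion, 36-RyR CaRUs on 2x2
#' node blocks), two larger-dispersion variants (sigma = 2 and 3.6 um), and
#' the large-cluster "structure" variant (54-RyR CaRUs on 2x3 node blocks)
#' with the same total RyR count as control.
#'
#' @param label One of `"control"`, `"sigma2.0"`, `"sigma3.6"`,
#'   `"structure54"`.
#' @param base A [geometry_config()] supplying the cell dimensions.
#' @return A `geometry_config` for the variant (with `total_ryr_target` set
#'   so all variants share the control RyR budget).
#' @export
ryr_variant <- function(label = c("control", "sigma2.0", "sigma3.6",
                                  "structure54"),
                        base = geometry_config()) {
  label <- match.arg(label)
  cfg <- base
  # the control budget: number of interior candidate positions times 36
  ctrl <- build_geometry(modifyList_cfg(base, list(sigma = 0)))
  budget <- 36L * ctrl$log$n_interior_carus
  upd <- switch(label,
    control = list(sigma = 0.4, nodes_per_caru = 4L),
    "sigma2.0" = list(sigma = 2.0, nodes_per_caru = 4L),
    "sigma3.6" = list(sigma = 3.6, nodes_per_caru = 4L),
    structure54 = list(sigma = 0.4, nodes_per_caru = 6L,
                       total_ryr_target = budget))
  out <- modifyList_cfg(cfg, upd)
  attr(out, "variant") <- label
  out
}

modifyList_cfg <- function(cfg, upd) {
  x <- unclass(cfg)
  for (nm in names(upd)) x[[nm]] <- upd[[nm]]
  do.call(geometry_config, x)
}

# Shared driver: build channels/state, optionally pre-pace, then record.
run_clamped <- function(geom, params, solver, clamp, prepace_ms, record_ms_total,
                        seed, strips = NULL, snap = FALSE, state = NULL,
                        channels = NULL) {
  with_stream(stream_seed(seed, "gating"), {
    if (is.null(state)) state <- init_state(geom, params)
    if (is.null(channels)) channels <- init_channels(geom)
    sv <- solver
    dt <- if (is.null(sv$dt)) sv$safety * dt_max(geom) else sv$dt
    if (prepace_ms > 0) {
      pre_sv <- solver_config(dt = sv$dt, safety = sv$safety,
                              record_ms = max(1, prepace_ms / 4), snap_ms = 0)
      pre <- run_steps(state, geom, channels, params, pre_sv,
                       n_steps = round(prepace_ms / dt), clamp = clamp,
                       strips = strips)
      state <- pre$state; channels <- pre$channels
    }
    res <- run_steps(state, geom, channels, params, sv,
                     n_steps = round(record_ms_total / dt), clamp = clamp,
                     strips = strips)
    res
  })
}

# Default analysis strips: 1-um longitudinal strips at the periphery
# (subsarcolemmal, bottom edge) and the cell centre.
default_strips <- function(geom, width_um = 1) {
  w <- max(1L, round(width_um / geom$dy))
  mid <- round(geom$ny / 2)
  rbind(periphery = c(1L, geom$nx, 2L, 1L + w),
        center = c(1L, geom$nx, mid - floor(w / 2), mid - floor(w / 2) + w - 1L))
}

#' Run a paced voltage-clamp experiment
#'
#' Pre-paces the cell, then records `n_beats` beats of whole-cell
#' volume-weighted averages, per-flux traces, peripheral/central strip
#' traces and transversal/longitudinal line-scan profiles.
#'
#' @param geom A `cell_geometry`.
#' @param params A [sim_params()].
#' @param protocol A [pacing_protocol()].
#' @param seed Integer seed (expanded into a private gating stream).
#' @param solver A [solver_config()].
#' @param snap_ms Snapshot stride in ms (0 = none).
#' @return A `pacing_recording` list: `time`, `ci_avg`, `csr_avg`, `V`,
#'   `fluxes` (data.frame), `strips`, `tprofile` (ny x nt transversal line
#'   scan), `lprofile`, `snapshots`, the protocol, seed and final state.
#' @export
run_paced <- function(geom, params, protocol = pacing_protocol(), seed = 1,
                      solver = solver_config(), snap_ms = 0) {
  clamp <- c(protocol$v_rest, protocol$v_pulse, protocol$pulse_ms,
             protocol$Ts, 0)
  solver$snap_ms <- snap_ms
  strips <- default_strips(geom)
  res <- run_clamped(geom, params, solver, clamp,
                     prepace_ms = protocol$prepace_ms,
                     record_ms_total = protocol$n_beats * protocol$Ts,
                     seed = seed, strips = strips)
  rec <- res$records
  out <- list(time = rec$t, ci_avg = rec$ci_avg, csr_avg = rec$csr_avg,
              V = rec$V,
              fluxes = data.frame(time_ms = rec$t, J_NaCa = rec$j_ncx,
                                  J_CaL = rec$j_cal, J_rel = rec$j_rel,
                                  J_up = rec$j_up),
              strips = stats::setNames(
                as.data.frame(t(rec$strips)), rownames(strips)),
              tprofile = rec$tprofile, lprofile = rec$lprofile,
              snapshots = res$snapshots, snapshot_t = res$snapshot_t,
              protocol = protocol, seed = seed, dt = res$dt,
              clips = res$clips, state = res$state, channels = res$channels,
              geom_dims = c(geom$nx, geom$ny, geom$dx, geom$dy))
  class(out) <- "pacing_recording"
  out
}

#' Restitution: transient features versus pacing period
#'
#' Runs [run_paced()] at each pacing period and extracts per-beat peak and
#' diastolic levels of the whole-cell cytosolic and SR averages.
#'
#' @param geom A `cell_geometry`.
#' @param params A [sim_params()].
#' @param Ts_list Pacing periods (ms), non-empty.
#' @param seed Integer seed.
#' @param protocol Template [pacing_protocol()] (its `Ts` is overridden).
#' @param solver A [solver_config()].
#' @return Data frame with one row per period: `Ts`, `ci_peak`, `ci_diast`,
#'   `csr_peak`, `csr_diast` (uM), plus the per-run recordings as
#'   `attr(, "recordings")`.
#' @export
run_restitution <- function(geom, params, Ts_list, seed = 1,
                            protocol = pacing_protocol(),
                            solver = solver_config()) {
  stopifnot(length(Ts_list) >= 1)
  recs <- lapply(seq_along(Ts_list), function(q) {
    pr <- protocol; pr$Ts <- Ts_list[q]
    run_paced(geom, params, pr, seed = seed + (q - 1L) * 1000L,
              solver = solver)
  })
  rows <- lapply(recs, function(r) {
    fi <- transient_features(r$ci_avg, r$time, r$protocol$Ts)
    fs <- transient_features(r$csr_avg, r$time, r$protocol$Ts)
    data.frame(Ts = r$protocol$Ts, ci_peak = fi$peak, ci_diast = fi$diastolic,
               csr_peak = fs$peak, csr_diast = fs$diastolic)
  })
  out <- do.call(rbind, rows)
  attr(out, "recordings") <- recs
  out
}

#' Run the longitudinal wave-speed assay
#'
#' On the 10-z-line geometry: sets the SR load uniformly, elevates
#' cytosolic calcium on the first z-line strip, lets the system evolve
#' unforced at the resting potential, tracks the longitudinal front from
#' the initiation side and fits its speed.
#'
#' @param geom A wave-assay `cell_geometry` (see
#'   [build_wave_assay_geometry()]).
#' @param params A [sim_params()].
#' @param sr_load Uniform initial SR calcium (uM).
#' @param D_i,D_sr Optional overrides of the reference diffusion
#'   coefficients (um^2/ms); the geometry is rescaled accordingly.
#' @param elevation Multiple of diastolic calcium applied around the first
#'   z-line (default 50; the stripe must overcome fast local buffering and
#'   diffusion to ignite the first clusters).
#' @param elevation_width Width of the elevated stripe (um, default 1).
#' @param duration_ms Simulated time (ms).
#' @param seed Integer seed.
#' @param solver A [solver_config()]; profile recording should be fine
#'   (default 0.5 ms).
#' @param threshold Front-tracking threshold (uM); default 2x diastolic.
#' @return A `wave_trace` (see [track_front()]) with the recording attached
#'   as attributes.
#' @export
run_wave_assay <- function(geom, params, sr_load = params$sr_load_wave,
                           D_i = NULL, D_sr = NULL, elevation = 50,
                           elevation_width = 1, duration_ms = 120, seed = 1,
                           solver = solver_config(record_ms = 0.5),
                           threshold = NULL) {
  if (!is.null(D_i)) geom$D_i <- geom$D_i * (D_i / geom$config$D_i_ref)
  if (!is.null(D_sr)) geom$D_sr <- geom$D_sr * (D_sr / geom$config$D_sr_ref)
  state <- init_state(geom, params, c_sr0 = sr_load)
  # elevate cytosolic calcium on a stripe centred on the first z-line
  first_z <- geom$zline_centers[1]
  cols <- which(abs(((seq_len(geom$nx)) - 0.5) * geom$dx - first_z) <=
                  elevation_width / 2)
  c_el <- params$c_i0 * elevation
  state$c_i[cols, ] <- c_el
  # the stripe's buffers are loaded to equilibrium with the elevated level,
  # so the initial condition elevates total (free + bound) calcium
  eq <- function(B, kon, koff) B * kon * c_el / (kon * c_el + koff)
  state$b_tnc[cols, ] <- ifelse(geom$domain[cols, ] == SARCOMERE,
                                eq(params$tnc_B, params$tnc_kon,
                                   params$tnc_koff), 0)
  state$b_cam[cols, ] <- eq(params$cam_B, params$cam_kon, params$cam_koff)
  state$b_srb[cols, ] <- eq(params$srb_B, params$srb_kon, params$srb_koff)
  clamp <- c(params$v_rest, params$v_rest, 0, 0, 0)
  solver$snap_ms <- solver$record_ms  # interior profile built from snapshots
  res <- run_clamped(geom, params, solver, clamp, prepace_ms = 0,
                     record_ms_total = duration_ms, seed = seed,
                     state = state)
  if (is.null(threshold)) threshold <- 2 * params$c_i0
  # longitudinal profile over interior rows only: the membrane ring hosts
  # perimeter clusters whose spontaneous sparks would fake front jumps
  margin <- max(2L, round(0.5 / geom$dy))
  rows <- (margin + 1):(geom$ny - margin)
  vsub <- geom$v_i[, rows]
  prof <- apply(res$snapshots[, rows, , drop = FALSE], 3,
                function(m) rowSums(vsub * m) / rowSums(vsub))
  # likewise cap tracking 1 um short of the far edge (edge clusters)
  xmax <- geom$nx - round(1 / geom$dx)
  tr <- track_front(prof[1:xmax, , drop = FALSE], res$snapshot_t, geom$dx,
                    threshold = threshold)
  # a wave either traverses the z-line ladder or has failed to propagate:
  # the fitted speed is meaningful only for traversing fronts
  goal <- geom$zline_centers[length(geom$zline_centers)] - 0.75
  tr$propagated <- !tr$stalled &&
    any(tr$front_positions >= goal, na.rm = TRUE)
  if (!tr$propagated) {
    tr$stalled <- TRUE
    tr$fitted_speed_um_s <- NA_real_
  } else if (length(geom$zline_centers) >= 3) {
    # refit over the ladder traversal (second z-line to goal): excludes the
    # initiation transient from the slope
    z2 <- geom$zline_centers[2]
    sel <- which(!is.na(tr$front_positions) & tr$front_positions >= z2 &
                   tr$front_positions <= goal)
    sel <- sel[sel <= which.max(tr$front_positions)]
    if (length(sel) >= 3) {
      fit <- lm(tr$front_positions[sel] ~ tr$times[sel])
      tr$fitted_speed_um_s <- unname(coef(fit)[2]) * 1000
      tr$fit_residual <- sqrt(mean(stats::residuals(fit)^2))
    }
  }
  attr(tr, "records") <- res$records
  attr(tr, "sr_load") <- sr_load
  tr
}

#' Resting (unpaced) run with spark detection
#'
#' Holds the membrane at rest (L-type channels essentially closed), records
#' full-field snapshots and detects spontaneous calcium sparks.
#'
#' @param geom A `cell_geometry`.
#' @param params A [sim_params()].
#' @param duration_ms Simulated time (ms, > 0).
#' @param seed Integer seed.
#' @param snap_ms Snapshot stride for spark detection (ms).
#' @param solver A [solver_config()].
#' @param radius_threshold Spark radial criterion (um, default 1.6).
#' @param amplitude_threshold Spark amplitude level (uM); `NULL` uses the
#'   robust default of [detect_sparks()].
#' @return A list: `sparks` (data.frame), `frequency_hz`, `duration_ms`,
#'   `records`, and the snapshot movie dimensions.
#' @export
run_rest <- function(geom, params, duration_ms = 1000, seed = 1, snap_ms = 2,
                     solver = solver_config(record_ms = 5),
                     radius_threshold = 1.6, amplitude_threshold = NULL) {
  stopifnot(duration_ms > 0)
  clamp <- c(params$v_rest, params$v_rest, 0, 0, 0)
  solver$snap_ms <- snap_ms
  res <- run_clamped(geom, params, solver, clamp, prepace_ms = 0,
                     record_ms_total = duration_ms, seed = seed, snap = TRUE)
  sparks <- detect_sparks(res$snapshots, dx = geom$dx,
                          frame_times = res$snapshot_t,
                          amplitude_threshold = amplitude_threshold,
                          radius_threshold = radius_threshold)
  list(sparks = sparks, frequency_hz = nrow(sparks) / (duration_ms / 1000),
       duration_ms = duration_ms, records = res$records,
       snapshot_t = res$snapshot_t, clips = res$clips, seed = seed)
}
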