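#' Initialize channel-state containers for a geometry
#'
#' RyR-bearing nodes start with all channels closed; L-type sites start in
#' the deep closed state.  States are stored as occupancy counts per node
#' (channels within a node share the same local field, so identities are
#' not tracked).
#'
#' @param geom A `cell_geometry`.
#' @return A `channel_states` list: `ryr_nodes` (linear indices),
#'   `ryr` (4 x n matrix of C/O/I1/I2 counts), `lcc_nodes`, `lcc`
#'   (5 x n matrix of C1/C2/O/I1/I2 counts).
#' @export
init_channels <- function(geom) {
  ryr_nodes <- which(geom$ryr_count > 0L)
  ryr <- matrix(0L, 4, length(ryr_nodes),
                dimnames = list(c("C", "O", "I1", "I2"), NULL))
  ryr[1, ] <- geom$ryr_count[ryr_nodes]
  lcc_nodes <- which(geom$lcc_count > 0L)
  lcc <- matrix(0L, 5, length(lcc_nodes),
                dimnames = list(c("C1", "C2", "O", "I1", "I2"), NULL))
  lcc[1, ] <- geom$lcc_count[lcc_nodes]
  structure(list(ryr_nodes = ryr_nodes, ryr = ryr,
                 lcc_nodes = lcc_nodes, lcc = lcc),
            class = "channel_states")
}

#' RyR transition rates for one node
#'
#' Total (count-weighted) rates for the eight arrows of the 4-state square
#' scheme C <-> O, O <-> I1, C <-> I2, I2 <-> I1.  The activating arrows
#' C->O and I2->I1 carry the calcium-dependent per-channel rate
#' `ka * c^h`; the inactivating arrows O->I1 and C->I2 are calcium
#' dependent by default (`ki * c^2`, constant when `ryr_ki_ca = 0`);
#' closing (O->C, I1->I2) and recovery rates are constant.
#'
#' @param counts Length-4 integer vector (C, O, I1, I2 occupancy).
#' @param c_i_local Local cytosolic calcium (uM, >= 0).
#' @param params A [sim_params()].
#' @return Named numeric vector of total rates (1/ms) per transition.
#' @export
ryr_transition_rates <- function(counts, c_i_local, params) {
  if (c_i_local < 0) stop("concentration must be >= 0")
  stopifnot(length(counts) == 4, all(counts >= 0))
  act <- if (c_i_local > 0) params$ryr_ka * c_i_local^params$ryr_h else 0
  inact <- if (params$ryr_ki_ca != 0) params$ryr_ki * c_i_local^2
           else params$ryr_ki
  c(C_O  = counts[1] * act,
    O_C  = counts[2] * params$ryr_km,
    O_I1 = counts[2] * inact,
    I1_O = counts[3] * params$ryr_kir,
    C_I2 = counts[1] * inact,
    I2_C = counts[4] * params$ryr_kir,
    I2_I1 = counts[4] * act,
    I1_I2 = counts[3] * params$ryr_km)
}

#' L-type channel transition rates for one site
#'
#' Total rates for the 5-state scheme C1 <-> C2 <-> O with calcium-dependent
#' inactivation O <-> I1 and voltage-dependent inactivation O <-> I2.
#' Activation (C1->C2) increases with depolarization; the O->I1 rate
#' increases with local calcium.
#'
#' @param counts Length-5 integer vector (C1, C2, O, I1, I2 occupancy).
#' @param V Membrane potential (mV, finite).
#' @param c_i_local Local cytosolic calcium (uM, >= 0).
#' @param params A [sim_params()].
#' @return Named numeric vector of total rates (1/ms) per transition.
#' @export
lcc_transition_rates <- function(counts, V, c_i_local, params) {
  if (!is.finite(V)) stop("membrane potential must be finite")
  if (c_i_local < 0) stop("concentration must be >= 0")
  stopifnot(length(counts) == 5, all(counts >= 0))
  alpha <- params$lcc_a_max / (1 + exp(-(V - params$lcc_Va) / params$lcc_ka_slope))
  beta  <- params$lcc_b_max / (1 + exp((V - params$lcc_Vb) / params$lcc_kb_slope))
  s1 <- params$lcc_s1max * c_i_local^2 / (c_i_local^2 + params$lcc_Ks^2)
  s2 <- params$lcc_s2max / (1 + exp(-(V - params$lcc_Vs2) / params$lcc_ks2_slope))
  c(C1_C2 = counts[1] * alpha,
    C2_C1 = counts[2] * beta,
    C2_O  = counts[2] * params$lcc_ko,
    O_C2  = counts[3] * params$lcc_kc,
    O_I1  = counts[3] * s1,
    I1_O  = counts[4] * params$lcc_r1,
    O_I2  = counts[3] * s2,
    I2_O  = counts[5] * params$lcc_r2)
}

#' Advance all channel states over a time window
#'
#' Exact stochastic simulation (Gillespie) of every RyR node and L-type
#' site across `[t, t + dt]`, with the local calcium concentration and
#' voltage frozen at window start.  Propensities are recomputed after every
#' transition (they depend on the occupancy counts); per-node/site state
#' sums are conserved.  Reproducible under `set.seed()`.
#'
#' @param channels A `channel_states` from [init_channels()].
#' @param ci_ryr Local cytosolic calcium at each RyR node (uM).
#' @param ci_lcc Local cytosolic calcium at each L-type site (uM).
#' @param V Membrane potential (mV).
#' @param dt Window length (ms, > 0).
#' @param params A [sim_params()].
#' @return The updated `channel_states` (with `n_events` attribute).
#' @export
gillespie_advance <- function(channels, ci_ryr, ci_lcc, V, dt, params) {
  stopifnot(dt > 0, length(ci_ryr) == ncol(channels$ryr),
            length(ci_lcc) == ncol(channels$lcc))
  if (!is.finite(V)) stop("membrane potential must be finite")
  res <- .gating_advance_cpp(channels$ryr, as.numeric(ci_ryr),
                             channels$lcc, as.numeric(ci_lcc),
                             V, dt, unclass(params))
  out <- channels
  out$ryr <- res$ryr
  dimnames(out$ryr) <- dimnames(channels$ryr)
  out$lcc <- res$lcc
  dimnames(out$lcc) <- dimnames(channels$lcc)
  attr(out, "n_events") <- res$n_events
  out
}

#' Waiting time to the first RyR transition
#'
#' Draws `n` waiting times to the first transition of a single RyR node
#' with occupancy `counts` at fixed local calcium, capped at `t_max`.
#' The waiting time is exponential with rate equal to the summed
#' propensity.
#'
#' @param n Number of samples.
#' @param counts Length-4 occupancy (C, O, I1, I2).
#' @param c_i_local Local calcium (uM).
#' @param t_max Cap (ms).
#' @param params A [sim_params()].
#' @return Numeric vector of waiting times (ms).
#' @export
ryr_first_event_time <- function(n, counts, c_i_local, t_max, params) {
  .ryr_first_event_cpp(as.integer(n), as.integer(counts), c_i_local,
                       t_max, unclass(params))
}
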