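#' Model parameters: fluxes, buffers and channel gating
#'
#' One flat, validated parameter list covering every calcium source/sink
#' term and the Markov gating constants.  Defaults are calibrated so that a
#' resting cell sits near a diastolic state of ~0.1 uM cytosolic and
#' several hundred uM SR free calcium with rare spontaneous sparks, and a
#' 100 ms voltage-clamp pulse to 0 mV triggers subsarcolemmal release.
#' Every constant is a configuration knob, not code.
#'
#' Flux forms:
#' * Release through open RyRs: `J_rel = g_rel * n_open * (c_sr - c_i)`.
#' * L-type current: GHK driving force
#'   `I = g_cal * n_open * 4 z_m (c_i e^{2z} - ca_o) / (e^{2z} - 1)` with
#'   `z = V F / R T` and `z_m = 0.341 z F`; converted to a cytosolic flux by
#'   `J = -I / (2 F v_myo)` (inward current gives a positive flux).
#' * SERCA: unidirectional Hill pump `v_up c^2 / (K_up^2 + c^2)` acting at
#'   every node, paired with a passive SR leak `g_leak (c_sr - c_i)` that
#'   balances uptake at the diastolic set point.
#' * Na/Ca exchange: Luo-Rudy-type electrogenic form with fixed Na,
#'   evaluated on the membrane ring only.
#' * Immobile buffers: troponin (sarcomere domain only), calmodulin and SR
#'   binding sites (everywhere); mass-action on/off kinetics.
#'
#' @param ... Named overrides of any default listed below.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(...) {
  p <- list(
    # release
    g_rel = 4,          # 1/ms per open RyR (local SR-cytosol equilibration)
    # RyR 4-state gating (C <-> O Ca-activated; inactivation Ca-dependent
    # by default: per-channel rate ryr_ki * c^2, or constant if ryr_ki_ca = 0)
    ryr_ka = 1e-3,      # 1/(uM^h ms) opening rate scale
    ryr_h = 3,          # cytosolic activation exponent
    ryr_km = 0.1,       # 1/ms closing rate
    ryr_ki = 2e-3,      # 1/(uM^2 ms) inactivation rate scale (or 1/ms if constant)
    ryr_ki_ca = 1,      # 1 = quadratic Ca-dependence, 0 = constant rate
    ryr_kir = 1e-3,     # 1/ms recovery rate
    # LCC current + 5-state gating
    g_cal = 0.045,      # um^3/ms conductance scale
    v_myo = 1.0,        # um^3 effective cytosolic volume for conversion
    ca_o = 1800,        # uM extracellular calcium
    f_const = 96.485,   # C/mmol Faraday constant
    rt_over_f = 26.71,  # mV at 310 K
    lcc_a_max = 1.0, lcc_Va = -15, lcc_ka_slope = 6.5,   # C1->C2 activation
    lcc_b_max = 0.8, lcc_Vb = -25, lcc_kb_slope = 6.5,   # C2->C1
    lcc_ko = 0.35, lcc_kc = 0.5,                         # C2<->O
    lcc_s1max = 0.05, lcc_Ks = 4, lcc_r1 = 0.002,        # O<->I1 (Ca)
    lcc_s2max = 0.012, lcc_Vs2 = -20, lcc_ks2_slope = 6, # O<->I2 (V)
    lcc_r2 = 0.0015,
    # NCX (Luo-Rudy form; Na in mM)
    k_ncx = 8000,       # uM/ms scale
    na_i = 13.5, na_o = 140, km_na = 87.5, km_ca = 1.38,
    k_sat = 0.1, eta = 0.35,
    # SERCA + leak
    v_up = 0.3,         # uM/ms max uptake
    K_up = 0.3,         # uM half-saturation
    hill_up = 2,        # Hill coefficient (fixed quadratic form in the core)
    g_leak = 5e-5,      # 1/ms passive SR leak conductance
    # immobile buffers (B in uM, kon in 1/(uM ms), koff in 1/ms)
    tnc_B = 30,  tnc_kon = 0.0327, tnc_koff = 0.0196,
    cam_B = 12,  cam_kon = 0.034,  cam_koff = 0.238,
    srb_B = 20,  srb_kon = 0.115,  srb_koff = 0.1,
    # wave-assay standard SR load (uM; the assay sweeps this)
    sr_load_wave = 1600,
    # initial/resting levels
    c_i0 = 0.1,         # uM diastolic cytosolic calcium
    c_sr0 = 600,        # uM initial SR load
    v_rest = -80        # mV resting clamp potential
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(over)] <- over
  }
  stopifnot(p$g_rel >= 0, p$ryr_ka >= 0, p$ryr_km >= 0, p$ryr_ki >= 0,
            p$ryr_kir >= 0, p$g_cal >= 0, p$v_myo > 0, p$ca_o > 0,
            p$v_up >= 0, p$K_up > 0, p$hill_up >= 1, p$g_leak >= 0,
            p$tnc_B >= 0, p$cam_B >= 0, p$srb_B >= 0, p$k_ncx >= 0)
  if (p$hill_up != 2)
    stop("only hill_up = 2 is supported by the solver core", call. = FALSE)
  class(p) <- "sim_params"
  p
}

#' SR release flux through open RyRs
#'
#' `J_rel = g_rel * n_open * (c_sr - c_i)`, proportional to the SR-cytosol
#' concentration difference and the number of open channels.
#'
#' @param n_open Number of open RyRs.
#' @param c_sr,c_i SR and cytosolic free calcium (uM), non-negative.
#' @param params A [sim_params()].
#' @return Flux in uM/ms (positive into the cytosol when `c_sr > c_i`).
#' @export
release_flux <- function(n_open, c_sr, c_i, params) {
  if (any(c_sr < 0) || any(c_i < 0)) stop("concentrations must be >= 0")
  params$g_rel * n_open * (c_sr - c_i)
}

#' L-type calcium current (GHK form)
#'
#' `I = g_cal * n_open * 4 z_m (c_i e^{2z} - ca_o)/(e^{2z} - 1)` with
#' `z = V F/(R T)`, `z_m = 0.341 z F`.  The analytic limit is substituted
#' when |z| < 1e-8, making the current continuous through V = 0.  Negative
#' values are inward (calcium-entering) currents.
#'
#' @param n_open Open L-type channels.
#' @param V Membrane potential (mV, finite).
#' @param c_i Local cytosolic calcium (uM).
#' @param params A [sim_params()].
#' @return Current (model units; see [current_to_flux()]).
#' @export
lcc_current <- function(n_open, V, c_i, params) {
  if (any(!is.finite(V))) stop("membrane potential must be finite")
  if (any(c_i < 0)) stop("concentrations must be >= 0")
  mapply(function(n, v, c)
    .lcc_current_cpp(n, v, c, params$g_cal, params$ca_o, params$f_const,
                     params$rt_over_f),
    n_open, V, c_i)
}

#' Convert L-type current to a cytosolic flux
#'
#' `J = -I / (2 F v_myo)` in uM/ms; the Faraday constant cancels against the
#' `z_m = 0.341 z F` factor of [lcc_current()], so the unit bookkeeping
#' closes with `g_cal` in um^3/ms and `v_myo` in um^3.  The sign flip makes
#' an inward (negative, calcium-entering) current a positive cytosolic flux.
#'
#' @param I Current from [lcc_current()].
#' @param params A [sim_params()].
#' @return Flux in uM/ms.
#' @export
current_to_flux <- function(I, params) {
  -I / (2 * params$f_const * params$v_myo)
}

#' SERCA uptake flux
#'
#' Unidirectional Hill pump `v_up c^2/(K_up^2 + c^2)`; monotone in `c_i`,
#' saturating at `v_up`, acting at every node of the cell.
#'
#' @param c_i Cytosolic calcium (uM).
#' @param params A [sim_params()].
#' @return Uptake flux in uM/ms (cytosol to SR).
#' @export
serca_flux <- function(c_i, params) {
  if (any(c_i < 0)) stop("concentrations must be >= 0")
  params$v_up * c_i^2 / (params$K_up^2 + c_i^2)
}

#' Na/Ca exchanger flux
#'
#' Luo-Rudy-type electrogenic exchange with fixed intra/extracellular
#' sodium, evaluated only on membrane nodes by the solver.  Positive values
#' extrude calcium; the flux vanishes at the exchanger's thermodynamic
#' equilibrium `c_i = ca_o (na_i/na_o)^3 e^{V F/RT}`.
#'
#' @param c_i Cytosolic calcium (uM).
#' @param V Membrane potential (mV, finite).
#' @param params A [sim_params()].
#' @return Extrusion flux in uM/ms.
#' @export
ncx_flux <- function(c_i, V, params) {
  if (any(!is.finite(V))) stop("membrane potential must be finite")
  if (any(c_i < 0)) stop("concentrations must be >= 0")
  mapply(function(c, v)
    .ncx_flux_cpp(c, v, params$k_ncx, params$na_i, params$na_o,
                  params$ca_o / 1000, params$km_na, params$km_ca,
                  params$k_sat, params$eta, params$rt_over_f),
    c_i, V)
}

#' Buffer binding flux
#'
#' Mass-action binding to an immobile buffer:
#' `J_b = kon * c_i * (B_T - c_b) - koff * c_b`.  The solver applies
#' troponin only in the sarcomere domain and calmodulin/SR sites everywhere.
#'
#' @param c_i Free cytosolic calcium (uM).
#' @param c_b Bound calcium (uM), in `[0, B_T]`.
#' @param B_T Total buffer concentration (uM).
#' @param kon,koff On/off rate constants (1/(uM ms), 1/ms).
#' @return Net binding flux in uM/ms.
#' @export
buffer_flux <- function(c_i, c_b, B_T, kon, koff) {
  if (any(c_b > B_T + 1e-12) || any(c_b < 0))
    stop("bound calcium must lie in [0, B_T]")
  kon * c_i * (B_T - c_b) - koff * c_b
}
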