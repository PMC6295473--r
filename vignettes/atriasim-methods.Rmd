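---
title: "atriasim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{atriasim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`atriasim` simulates calcium-induced calcium release (CICR) in a
two-dimensional atrial myocyte at submicron resolution.  Atrial cells
largely lack transverse tubules, so the depolarization-triggered calcium
signal enters at the outer membrane and must propagate inward as a
regenerative wave; how far it penetrates, and how the spatial organization
of ryanodine-receptor (RyR) clusters shapes spontaneous release, are the
questions the package is built to study.

The cell is a homogenized two-concentration-field ("bidomain") continuum:
cytosol and sarcoplasmic reticulum (SR) coexist at every grid node with
volume fractions `v_i + v_sr = 1`.  Three coupled fields evolve:

* `c_i(r, t)` — free cytosolic calcium (uM),
* `c_sr(r, t)` — free SR calcium (uM),
* `c_b(r, t)` — calcium bound to each immobile buffer (uM).

with

```
dc_i/dt  = J_i + div(D_i grad c_i) - sum_b J_b
dc_sr/dt = (v_i/v_sr) J_sr + div(D_sr grad c_sr)
dc_b/dt  = J_b
```

The `v_i/v_sr` factor converts fluxes expressed per cytosolic volume into
SR-concentration changes; it is evaluated node-wise with the local volume
fractions.  Both effective diffusion coefficients scale linearly with the
local volume fraction of their compartment and are normalized so that the
values between z-lines equal the reference coefficients
(`D_i = 0.25 um^2/ms`, `D_sr = 0.09 um^2/ms`).

### Microstructure

The standard cell is `100 x 15 um` at `dx = dy = 0.1 um`.  Z-lines are
0.3-um-wide transversal strips repeating every 1.6 um; together with the
one-node membrane ring they form the SR-rich domain (default SR fraction
0.06 there, 0.02 in the sarcomere between z-lines).  The SR fraction
defaults are deliberately modest — they put the whole-cell SR volume near
3%, in the physiological range — and are ordinary configuration knobs.

Calcium release units (CaRUs) are blocks of RyR-bearing nodes, 9 RyRs per
node (a node holds at most 10): `2 x 2` blocks of 36 RyRs by default, or
`2 x 3` blocks of 54 RyRs in the large-cluster ("structure") variant.
Interior CaRUs sit on z-lines at 0.5 um transversal spacing, with
longitudinal positions drawn from a Gaussian of standard deviation `sigma`
(0.4 um by default) about the z-line.  Perimeter CaRUs are exactly
periodic at 0.5 um along the membrane and each carries a 5-channel L-type
(LCC) site.  Colliding placements are re-sampled up to 20 times and then
shifted deterministically to the nearest free slot; every retry, shift,
clip and drop is counted in the geometry's `log`.

Functional CaRUs for the spatial statistics are obtained by merging
RyR-bearing nodes closer than 0.15 um *edge to edge* (transitive closure);
node squares of side `dx` are used for the edge distance, and cluster
centres are RyR-count-weighted centroids.

### Channel gating

RyRs follow a 4-state square scheme (closed C, open O, inactivated I1 and
I2): C->O and I2->I1 activate with cytosolic calcium at per-channel rate
`ka * c^h`; O->I1 and C->I2 inactivate with rate `ki * c^2` (a constant
rate is available via `ryr_ki_ca = 0`); O->C and I1->I2 close at `km`;
recovery I1->O and I2->C at `kir`.  Two defaults deserve comment:

* **Activation exponent `h = 3`.**  With the homogenized 0.1-um voxels a
  releasing node reaches only a few uM of free calcium (not the hundreds
  of uM of a true dyadic cleft).  A quadratic law cannot simultaneously
  keep the diastolic cell quiet and let a single opening recruit its
  cluster across that narrow concentration range; the cubic law gives the
  separation with a realistic resting open rate.
* **Calcium-dependent inactivation.**  A constant closed-state
  inactivation rate strong enough to terminate release would also park
  most channels in I2 at rest and silence the cell.  Making both
  inactivating arrows proportional to `c^2` confines inactivation to
  actively releasing regions.

LCCs follow a 5-state scheme (C1, C2, O, I1, I2) with voltage-dependent
activation C1<->C2, opening C2<->O, calcium-dependent inactivation O<->I1
and voltage-dependent inactivation O<->I2.  At the resting potential the
stationary open probability is below 1e-3 (checked against the generator
matrix in the test suite).

All channel states are advanced per node/site by an exact stochastic
simulation algorithm over each time step, with the local fields frozen at
step start; propensities are recomputed after every transition because
they depend on the occupancy counts.  All draws come from R's RNG, so a
`set.seed()` (or a protocol seed) reproduces trajectories bit-exactly on a
given platform.

### Fluxes

* Release: `J_rel = g_rel * n_open * (c_sr - c_i)` at RyR nodes.  The
  default `g_rel` is large enough that a releasing node equilibrates
  locally with its SR within a step; the solver therefore integrates this
  stiff exchange *exactly* as a pairwise relaxation, which is
  unconditionally stable and conserves mass to machine precision.
* L-type current: GHK form
  `I = g_cal n 4 z_m (c_i e^{2z} - ca_o)/(e^{2z} - 1)`, `z = VF/RT`,
  `z_m = 0.341 z F`, with the analytic limit substituted for |z| < 1e-8.
  Conversion `J = -I/(2 F v_myo)` makes inward current a positive
  cytosolic flux; the Faraday constant cancels, closing the units.
* SERCA: unidirectional Hill pump `v_up c^2/(K_up^2 + c^2)` at every
  node, paired with a passive SR leak `g_leak (c_sr - c_i)` chosen so that
  leak balances uptake at the diastolic set point (`c_i ~ 0.1 uM`,
  `c_sr ~ 600 uM`).  Without the leak the unidirectional pump would load
  the SR without bound at rest.
* Na/Ca exchange: Luo-Rudy-type electrogenic form with fixed sodium, on
  the membrane ring only.  Its thermodynamic equilibrium at -80 mV
  (~0.08 uM) pins the diastolic cytosolic level.
* Buffers: troponin (sarcomere domain only), calmodulin and SR binding
  sites (everywhere), all immobile, updated by an unconditionally bounded
  implicit rule that keeps occupancy in `[0, B_T]` for any step size.

### Numerics

Explicit first-order operator splitting per step: (1) gating, (2)
conservative finite-volume diffusion, (3) reaction on the diffused values
(with the exact release relaxation).  Diffusion is monotone at the
enforced step bound and every reaction term is individually
positivity-safe, so no sub-update can overdraw a node.  Face conductances are harmonic means of `v * D` divided by
`dx^2`; the update is scaled by `1/v` locally, so the scheme conserves
`sum(v c)` exactly with zero-flux boundaries.  The step size defaults to
90% of the monotonicity bound `dt * max_rate <= 1` (about 0.008 ms for the
standard microstructure).  Any node a step would drive negative is clipped
to zero and counted; counts are reported with every run.  Self-convergence
under step halving and closed-cell mass conservation (drift < 0.01% over
10^4 steps) are enforced in the test suite.

## Experiments and measurements

* `run_paced()`: square voltage clamp (-80 to 0 mV, 100 ms) at a given
  period; records whole-cell volume-weighted averages, per-flux traces,
  peripheral/central 1-um strip traces and line-scan profiles.
* `run_restitution()`: peak and pre-stimulus diastolic levels versus
  pacing period.
* `run_wave_assay()`: 10 equidistant z-lines 1.5 um apart; the SR is set
  to a uniform load, a 1-um stripe around the first z-line is elevated
  (free calcium times 50, with the stripe's buffers equilibrated to that
  level — otherwise local buffering absorbs the stimulus within a
  fraction of a millisecond), and the system evolves unforced at rest.
  The front is tracked on an interior-row longitudinal profile (the
  membrane ring is excluded because spontaneous perimeter sparks would
  fake front jumps), and a run either traverses the ladder of z-lines or
  is flagged as not propagated; the speed is fitted on the traversal.
* `run_rest()`: unpaced run with snapshot recording and spark detection.
  Sparks are 4-connected components above an amplitude threshold
  (default: movie median plus twice its median absolute deviation) whose
  equivalent radius `sqrt(area/pi)` reaches 1.6 um, merged across
  consecutive frames (one missing frame tolerated).  The 1.6 um criterion
  is interpreted as a radius.

## Calibration and the synthetic study conditions

The microstructural constants (cell size, grid, z-line period and width,
CaRU spacing and sizes, dispersion values 0.4/2.0/3.6 um, the 36- and
54-RyR cluster variants at fixed total RyR budget, merge distance 0.15 um,
diffusion references) are fixed study conditions.  The kinetic constants
(channel rates, `g_rel`, `g_cal`, pump/exchanger scales, buffer totals)
are *calibrated*, not transcribed: they were tuned once so that the
resting cell sits near 0.1 uM with rare sparks, a paced beat produces a
subsarcolemmal transient above 1 uM with a whole-cell peak near 0.7-0.9
uM and limited inward penetration, the wave assay propagates at a few
hundred um/s at elevated SR load, and the spark-frequency ordering across
cluster configurations is reproduced.  They are defaults of
`sim_params()`, all overridable.

Two compromises are worth knowing about:

* The buffer totals (30/12/20 uM for TnC/CaM/SR sites) are below common
  literature values.  With full literature buffering the trigger calcium
  decays over ~0.2 um, an order of magnitude below the 0.5-1.5 um
  cluster spacing, and no fire-diffuse-fire propagation of any kind
  occurs at this discretization; the reduced totals restore a coupling
  length that supports marginal propagation.
* Inter-cluster propagation sits deliberately close to threshold: paced
  beats penetrate a few um and stall, and wave-assay runs fail to
  propagate in a substantial fraction of seeds.  This is the intended
  marginal ("diffuse and fire") regime, but it makes wave-speed
  estimates strongly seed-dependent; ensemble means over the propagated
  subset are reported.

## Scaled problem sizes

Simulations in the test-suite and acceptance script use length-reduced
cells (16 x 15 um for paced beats, 16 x 6-10 um for wave and rest assays),
pre-pacing of 0.3-0.8 s instead of tens of seconds, ensembles of 5-10
seeds, and rest runs of 0.5-0.6 s.  These sizes were chosen as the
smallest at which the measured quantities are intensive and the trends
resolvable; whole-cell extensive quantities are never compared across
scales.  What passes on the scaled runs demonstrates internal consistency
and trend reproduction, not quantitative agreement with any particular
full-scale cell.

## Known limitations

* Two-dimensional geometry, isotropic diffusion, immobile buffers, no
  calsequestrin, fixed sodium, voltage clamp only (no membrane dynamics),
  no t-tubules, IP3 receptors or mitochondria.
* The homogenized 0.1-um voxel caps local free calcium far below dyadic
  concentrations; channel kinetics were re-calibrated for that range and
  are not transferable to cleft-resolving models.
* The synthetic generator produces idealized microstructure (exact
  periodic z-lines and perimeter sites, Gaussian longitudinal scatter
  only); real RyR maps show transversal jitter, cluster-size
  distributions and membrane invaginations that are not emulated, so
  passing tests do not certify behavior on experimentally imaged
  geometries.
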