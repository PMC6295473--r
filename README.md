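# atriasim

Stochastic, spatially resolved simulation of calcium handling in an atrial
cardiac myocyte.

Atrial cells largely lack transverse tubules, so the calcium transient that
couples electrical excitation to contraction is born at the cell membrane:
L-type channels admit a small trigger flux, subsarcolemmal ryanodine
receptor (RyR) clusters amplify it by calcium-induced calcium release
(CICR), and the signal then has to travel inward as a regenerative
fire-diffuse-fire wave.  How deep it penetrates, how fast calcium waves
move, and how the spatial layout and size of RyR clusters shape spontaneous
calcium sparks are questions at the heart of atrial arrhythmia research —
and the questions this package is built to explore.

The model is a homogenized two-concentration-field continuum on a 2D
submicron grid (dx = 0.1 um): cytosol and sarcoplasmic reticulum (SR)
coexist at every node with volume fractions `v_i + v_sr = 1`,

    dc_i/dt  = J_i  + div(D_i(r)  grad c_i)  - sum_b J_b
    dc_sr/dt = (v_i/v_sr) J_sr + div(D_sr(r) grad c_sr)
    dc_b/dt  = J_b

with effective diffusion coefficients that scale with the local volume
fractions (reference values 0.25 and 0.09 um^2/ms between z-lines).  The
source terms are stochastic RyR release (4-state Markov clusters, exact
Gillespie simulation), a GHK-form L-type current at perimeter sites
(5-state Markov channels), a Hill-type SERCA pump with a balancing passive
leak, an electrogenic Na/Ca exchanger on the membrane, and three immobile
buffers.  The microstructure — z-lines every 1.6 um, calcium release units
(CaRUs) of 36 RyRs placed with Gaussian longitudinal scatter, exactly
periodic perimeter sites — is generated by the package and fully
configurable, including the cluster-configuration variants (dispersion
0.4/2.0/3.6 um; 54-RyR clusters at fixed total RyR count).

The stepping core is C++ (via Rcpp); everything else is plain R.  See the
methods vignette (`vignettes/atriasim-methods.Rmd`) for the full model
description, parameter meanings and the design decisions.

## A worked example

A length-reduced cell (16 x 15 um, full transversal structure) paced at
800 ms under a square voltage clamp:

```r
library(atriasim)

geom <- build_geometry(geometry_config(Lx = 16, Ly = 15))
params <- sim_params()
rec <- run_paced(geom, params,
                 pacing_protocol(Ts = 800, prepace_ms = 400, n_beats = 2),
                 seed = 1)
f <- transient_features(rec$ci_avg, rec$time, 800)
sprintf("peak %.2f uM, diastolic %.3f uM, periphery strip peak %.2f uM",
        f$peak, f$diastolic, max(rec$strips$periphery))
#> "peak 0.73 uM, diastolic 0.117 uM, periphery strip peak 2.24 uM"
```

The whole-cell volume-weighted transient peaks at ~0.73 uM over a ~0.12 uM
diastolic level, while the 1-um subsarcolemmal strip rises several-fold
higher — the hallmark of peripherally confined release in a cell without
t-tubules.  `rec$tprofile` holds the transversal line scan (the inward
wave), `rec$fluxes` the whole-cell release/uptake/L-type/exchanger fluxes,
and `run_rest()` / `run_wave_assay()` / `run_restitution()` drive the
spark-statistics, wave-speed and pacing-dependence experiments.  A thin
command-line driver with one subcommand per experiment lives in
`inst/cli/atriasim.R`.

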