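# Example configuration: a length-reduced cell paced at 800 ms.
# Units are fixed package-wide: um, ms, uM, mV.
geometry:
  Lx: 16.0
  Ly: 15.0
  sigma: 0.4
  seed: 1
params:
  c_sr0: 600
protocol:
  Ts: 800
  prepace_ms: 400
  n_beats: 3
solver:
  record_ms: 1
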