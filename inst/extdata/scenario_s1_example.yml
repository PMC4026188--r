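name: S1_example
druse:
  position: A
  shape: b
geometry_mm: []
beam:
  energy_eV: 2.0
  fwhm_um: 350.0
  origin_mm:
  - 0.0
  - 0.0
  - 2.0
  axis_direction:
  - 0.0
  - 0.0
  - -1.0
  n_photons: 100000
  scan_step_um: 50.0
  n_runs: 5
detectors:
- D1
- D5
seed: 1.0
max_scatters: 100000.0
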