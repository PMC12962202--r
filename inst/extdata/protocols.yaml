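# Named acquisition protocol presets.
# Pulseq-FAM 2D presets per field strength, plus the constant-flip 3D-CSE
# protocol used as the steady-state comparator at 3T.
# b0_label carries the nominal field label; b0_t the value used for
# ppm -> Hz conversion (declared-3T systems at 2.89 T keep their own configs).
"0.55T":
  b0_t: 0.55
  b0_label: "0.55T"
  tr_ms: 15.8
  te1_ms: 2.38
  dte_ms: 2.22
  n_echoes: 6
  matrix: [108, 108]
  fov_cm: [39, 39]
  slice_thickness_mm: 8.0
  n_slices: 32
  readout: monopolar
  flip_mode: fam
"1.5T":
  b0_t: 1.5
  b0_label: "1.5T"
  tr_ms: 12.6
  te1_ms: 1.67
  dte_ms: 1.82
  n_echoes: 6
  matrix: [144, 144]
  fov_cm: [44, 44]
  slice_thickness_mm: 8.0
  n_slices: 32
  readout: monopolar
  flip_mode: fam
"3T":
  b0_t: 3.0
  b0_label: "3T"
  tr_ms: 9.3
  te1_ms: 1.21
  dte_ms: 1.22
  n_echoes: 6
  matrix: [144, 144]
  fov_cm: [44, 44]
  slice_thickness_mm: 8.0
  n_slices: 32
  readout: monopolar
  flip_mode: fam
"3T-3D-CSE":
  b0_t: 3.0
  b0_label: "3T"
  tr_ms: 6.4
  te1_ms: 0.97
  dte_ms: 0.77
  n_echoes: 6
  matrix: [192, 128]
  fov_cm: [40, 32]
  slice_thickness_mm: 8.0
  n_slices: 32
  readout: monopolar
  flip_mode: constant
  alpha_deg: 3
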