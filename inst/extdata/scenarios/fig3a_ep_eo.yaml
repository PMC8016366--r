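name: fig3a_ep_eo
notes: >
  Electrophoresis vs electroosmosis baseline: charged sphere captured by a
  small cylindrical solid-state pore in 1 M KCl.  The wall charge of
  0.012 C/m^2 is the smallest positive value of the worked example
  (competition regime, b_eo/ep ~ 0.16).
electrolyte:
  conductivity: {value: 11.1, unit: "S/m", note: "1 M KCl"}
  debye_length: {value: 0.3, unit: "nm", note: "1 M monovalent salt"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s", note: "water"}
  density: {value: 1000.0, unit: "kg/m^3", note: "water"}
  temperature: {value: 298.0, unit: "K", note: "room temperature"}
particle:
  radius: {value: 1.5, unit: "nm", note: "worked-example sphere"}
  charge: {value: 4, unit: "e"}
  dipole: {value: 0, unit: "e*nm"}
pore:
  radius: {value: 2, unit: "nm"}
  length: {value: 10, unit: "nm"}
  entrance_radius: {value: 2, unit: "nm", note: "r_e taken equal to r_p"}
  surface_charge: {value: 0.012, unit: "C/m^2", note: "smallest positive q_w of the sweep"}
  access_model: hemispherical
drive:
  voltage: {value: 100, unit: "mV"}
  concentration: {value: 40, unit: "uM"}
entrance:
  model: perfect
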