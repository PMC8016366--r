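name: fig3b_dep_eo
notes: >
  Dielectrophoresis vs electroosmosis: neutral sphere with a permanent
  dipole of 12 e nm (~600 D, typical protein range), same pore and
  electrolyte as fig3a_ep_eo.  Smallest wall charge of the sweep
  (b_eo/di ~ 0.02: electroosmosis barely perturbs the capture).
electrolyte:
  conductivity: {value: 11.1, unit: "S/m", note: "1 M KCl"}
  debye_length: {value: 0.3, unit: "nm"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s"}
  density: {value: 1000.0, unit: "kg/m^3"}
  temperature: {value: 298.0, unit: "K"}
particle:
  radius: {value: 1.5, unit: "nm"}
  charge: {value: 0, unit: "e", note: "neutral dipolar particle"}
  dipole: {value: 12, unit: "e*nm", note: "~600 D"}
pore:
  radius: {value: 2, unit: "nm"}
  length: {value: 10, unit: "nm"}
  entrance_radius: {value: 2, unit: "nm"}
  surface_charge: {value: 0.006, unit: "C/m^2", note: "smallest q_w of the sweep"}
  access_model: hemispherical
drive:
  voltage: {value: 100, unit: "mV"}
  concentration: {value: 40, unit: "uM"}
entrance:
  model: perfect
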