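name: larkin_rnase
notes: >
  Transport-limited capture of RNase A by the same HfO2 pore as
  larkin_prok.  Charge 5e is the protonation-aware value; radius and
  dipole are literature-typical estimates.
electrolyte:
  conductivity: {value: 11.1, unit: "S/m", note: "1 M KCl, pH 8.1"}
  debye_length: {value: 0.3, unit: "nm"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s"}
  density: {value: 1000.0, unit: "kg/m^3"}
  temperature: {value: 298.0, unit: "K"}
particle:
  radius: {value: 1.9, unit: "nm", note: "hydrodynamic radius estimate"}
  charge: {value: 5, unit: "e", note: "protonation-aware estimate"}
  dipole: {value: 350, unit: "D", note: "typical protein dipole; contribution negligible"}
pore:
  radius: {value: 2.6, unit: "nm"}
  length: {value: 7, unit: "nm"}
  entrance_radius: {value: 2.6, unit: "nm"}
  surface_charge: {value: -0.025, unit: "C/m^2"}
  conductance: {value: 20, unit: "nS", note: "measured"}
  eo_conductance: {value: 15.0e-18, unit: "m^3/(s*V)", note: "published estimate"}
  access_model: hemispherical
drive:
  voltage: {value: 100, unit: "mV"}
  concentration: {value: 1, unit: "nM"}
entrance:
  model: perfect
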