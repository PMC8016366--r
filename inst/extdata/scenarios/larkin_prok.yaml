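name: larkin_prok
notes: >
  Transport-limited capture of Proteinase K by a solid-state HfO2 pore
  (Larkin et al. setup): pore slightly larger than the rigid protein, so
  the entrance barrier is taken negligible (perfect absorption, f = f_a).
  The eo_conductance override stores the published estimate
  15e-18 m^3 s^-1 V^-1 (positive: the negative wall pumps fluid into the
  pore at positive voltage, cooperating with electrophoresis); the
  thin-double-layer model value from q_w = -0.025 C/m^2 would be
  ~23e-18.  Protein radius and dipole are literature-typical estimates
  (not printed in the source data); the charge 3e is the
  protonation-aware value.
electrolyte:
  conductivity: {value: 11.1, unit: "S/m", note: "1 M KCl, pH 8.1"}
  debye_length: {value: 0.3, unit: "nm"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s"}
  density: {value: 1000.0, unit: "kg/m^3"}
  temperature: {value: 298.0, unit: "K"}
particle:
  radius: {value: 2.4, unit: "nm", note: "hydrodynamic radius estimate"}
  charge: {value: 3, unit: "e", note: "protonation-aware estimate"}
  dipole: {value: 250, unit: "D", note: "typical protein dipole; contribution negligible"}
pore:
  radius: {value: 2.6, unit: "nm"}
  length: {value: 7, unit: "nm"}
  entrance_radius: {value: 2.6, unit: "nm"}
  surface_charge: {value: -0.025, unit: "C/m^2", note: "HfO2 at pH 8.1, 0.1 M NaCl data"}
  conductance: {value: 20, unit: "nS", note: "measured"}
  eo_conductance: {value: 15.0e-18, unit: "m^3/(s*V)", note: "published estimate; model value ~23e-18"}
  access_model: hemispherical
drive:
  voltage: {value: 100, unit: "mV"}
  concentration: {value: 1, unit: "nM"}
entrance:
  model: perfect
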