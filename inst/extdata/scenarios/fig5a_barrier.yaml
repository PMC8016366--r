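name: fig5a_barrier
notes: >
  Entrance-barrier effect, electrophoretic case: the fig3a_ep_eo system
  without electroosmosis, with an Arrhenius docking barrier.  The worked
  example sweeps dG0 over 5-20 kBT; 15 kBT is stored as the default.
electrolyte:
  conductivity: {value: 11.1, unit: "S/m"}
  debye_length: {value: 0.3, unit: "nm"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s"}
  density: {value: 1000.0, unit: "kg/m^3"}
  temperature: {value: 298.0, unit: "K"}
particle:
  radius: {value: 1.5, unit: "nm"}
  charge: {value: 4, unit: "e"}
  dipole: {value: 0, unit: "e*nm"}
pore:
  radius: {value: 2, unit: "nm"}
  length: {value: 10, unit: "nm"}
  entrance_radius: {value: 2, unit: "nm"}
  surface_charge: {value: 0, unit: "C/m^2", note: "no electroosmosis"}
  access_model: hemispherical
drive:
  voltage: {value: 100, unit: "mV"}
  concentration: {value: 40, unit: "uM"}
entrance:
  model: barrier
  dG0: {value: 15, unit: "kBT", note: "sweep value; worked example uses 5-20"}
  barrier_coupling: phi_at_entrance
  s: 1
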