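name: sv28_dumbbell
notes: >
  Dielectrophoretic capture of the rigid beta-hairpin peptide SV28 by
  alpha-hemolysin in a droplet bilayer.  The 28-residue peptide is neutral
  at pH 7 and modeled as a dumbbell of +-2e end charges 4 nm apart, i.e. a
  permanent dipole of 8 e nm.  Entrance model: dG0 = 22 kBT with docking
  field-enhancement s = 10 multiplying the dielectrophoretic coefficient
  in the barrier-reduction term.  Capture occurs at both voltage
  polarities (V-shaped f vs voltage).
electrolyte:
  conductivity: {value: 11.1, unit: "S/m", note: "1 M KCl"}
  debye_length: {value: 0.3, unit: "nm"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s"}
  density: {value: 1000.0, unit: "kg/m^3"}
  temperature: {value: 298.0, unit: "K"}
particle:
  radius: {value: 0.4, unit: "nm", note: "per-residue hydrodynamic radius"}
  n_residues: 28
  charge: {value: 0, unit: "e", note: "neutral at pH 7"}
  dipole: {value: 8, unit: "e*nm", note: "dumbbell +-2e x 4 nm"}
pore:
  radius: {value: 1, unit: "nm", note: "alpha-hemolysin entrance"}
  length: {value: 10, unit: "nm"}
  entrance_radius: {value: 1, unit: "nm"}
  surface_charge: {value: 0, unit: "C/m^2", note: "electroosmosis neglected"}
  conductance: {value: 2, unit: "nS", note: "measured"}
  access_model: hemispherical
drive:
  voltage: {value: 150, unit: "mV", note: "recordings at +-80..180 mV"}
  concentration: {value: 50, unit: "nM"}
entrance:
  model: barrier
  dG0: {value: 22, unit: "kBT"}
  barrier_coupling: phi_at_entrance
  s: 10
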