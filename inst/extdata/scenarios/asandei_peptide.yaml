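name: asandei_peptide
notes: >
  Electroosmotic capture of a positively charged 20-residue peptide by an
  alpha-hemolysin pore made anion-selective at pH 2.8 (Asandei et al.
  setup).  The electroosmotic conductance magnitude comes from MD at
  pH 2.8; its printed units are garbled in the source, the stored value
  1.6e-18 m^3 s^-1 V^-1 is a best guess and is marked unverified.  Its
  sign is negative in this package's convention (flow out of the pore at
  positive voltage: the positively charged wall makes anions the
  counterions, so electroosmosis competes with electrophoretic capture of
  the positive peptide).  dG0 = 21 kBT is chosen so that the computed mean
  capture time reproduces the observed ~1 s; the regime classification is
  then a model output.
electrolyte:
  conductivity: {value: 20, unit: "S/m"}
  debye_length: {value: 0.3, unit: "nm"}
  kinematic_viscosity: {value: 1.0e-6, unit: "m^2/s"}
  density: {value: 1000.0, unit: "kg/m^3"}
  temperature: {value: 298.0, unit: "K"}
particle:
  radius: {value: 0.4, unit: "nm", note: "per-residue hydrodynamic radius"}
  n_residues: 20
  charge: {value: 8, unit: "e", note: "peptide net charge at pH 2.8"}
  dipole: {value: 0, unit: "e*nm", note: "negligible dipole"}
pore:
  radius: {value: 1, unit: "nm", note: "alpha-hemolysin entrance"}
  length: {value: 10, unit: "nm", note: "alpha-hemolysin channel length"}
  entrance_radius: {value: 1, unit: "nm", note: "from the crystal structure"}
  surface_charge: {value: 0, unit: "C/m^2", note: "superseded by the G_eo override"}
  conductance: {value: 2.2, unit: "nS", note: "measured"}
  eo_conductance: {value: -1.6e-18, unit: "m^3/(s*V)", note: "MD estimate, magnitude unverified (garbled units in source)"}
  access_model: hemispherical
drive:
  voltage: {value: -100, unit: "mV", note: "polarity at which electroosmotic capture wins"}
  concentration: {value: 30, unit: "uM"}
entrance:
  model: barrier
  dG0: {value: 21, unit: "kBT", note: "calibrated to the observed tau ~ 1 s"}
  barrier_coupling: phi_at_entrance
  s: 1
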