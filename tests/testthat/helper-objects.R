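# Shared fixtures built in code: the worked-example pore/particle system
# (2 nm cylindrical pore in 1 M KCl, 1.5 nm sphere) used across tests.

kcl_1M <- function(temperature = 298) {
  electrolyte(conductivity = 11.1, debye_length = 0.3e-9,
              kinematic_viscosity = 1e-6, density = 1000,
              temperature = temperature)
}

sphere_4e <- function(q_e = 4, p_enm = 0) {
  particle(radius = 1.5e-9, charge = q_e * pc_constants$e,
           dipole = e_nm_to_SI(p_enm))
}

pore_2nm <- function(q_w = 0, ...) {
  pore(radius = 2e-9, length = 10e-9, surface_charge = q_w, ...)
}

drive_100mV <- function(voltage = 0.1, c_molar = 40e-6) {
  drive_conditions(voltage, molarity_to_density(c_molar))
}

# Reference diffusion coefficient of the 1.5 nm sphere at 298 K.
D_ref <- function() {
  einstein_diffusion(stokes_mobility(1.5e-9, 1e-3), 298)
}

make_scenario <- function(q_e = 4, p_enm = 0, q_w = 0, voltage = 0.1,
                          entrance = entrance_model(model = "perfect"),
                          c_molar = 40e-6) {
  scenario(kcl_1M(), sphere_4e(q_e, p_enm), pore_2nm(q_w),
           drive_100mV(voltage, c_molar), entrance, name = "test")
}
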