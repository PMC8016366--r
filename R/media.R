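# Physical parameterization: electrolyte, particle, pore, drive conditions,
# and the derived transport quantities (mobility, diffusion, conductances,
# fields, the a2/a3 coefficients and the dimensionless competition numbers).

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Electrolyte description
#'
#' Either the dynamic viscosity `viscosity` or the pair
#' (`kinematic_viscosity`, `density`) must be given; when all three are
#' present they must satisfy eta = nu * rho.
#'
#' @param conductivity Bulk ionic conductivity sigma, S/m.
#' @param debye_length Debye screening length lambda_D, m.
#' @param viscosity Dynamic viscosity eta, Pa s.
#' @param kinematic_viscosity Kinematic viscosity nu, m^2/s.
#' @param density Mass density rho, kg/m^3.
#' @param temperature Absolute temperature, K.
#' @return An object of class `"electrolyte"`.
#' @examples
#' kcl_1M <- electrolyte(conductivity = 11.1, debye_length = 0.3e-9,
#'                       kinematic_viscosity = 1e-6, density = 1000)
#' @export
electrolyte <- function(conductivity, debye_length,
                        viscosity = NULL,
                        kinematic_viscosity = NULL, density = NULL,
                        temperature = pc_constants$default_temperature) {
  stopifnot_positive(conductivity, "conductivity")
  stopifnot_positive(debye_length, "debye_length")
  stopifnot_positive(temperature, "temperature")
  if (is.null(viscosity)) {
    if (is.null(kinematic_viscosity) || is.null(density)) {
      stop("give either 'viscosity' or both 'kinematic_viscosity' and 'density'",
           call. = FALSE)
    }
    stopifnot_positive(kinematic_viscosity, "kinematic_viscosity")
    stopifnot_positive(density, "density")
    viscosity <- kinematic_viscosity * density
  } else {
    stopifnot_positive(viscosity, "viscosity")
    if (!is.null(kinematic_viscosity) && !is.null(density)) {
      if (abs(viscosity - kinematic_viscosity * density) >
            1e-6 * viscosity) {
        stop("inconsistent viscosity: eta != nu * rho", call. = FALSE)
      }
    }
  }
  structure(
    list(conductivity = conductivity, debye_length = debye_length,
         viscosity = viscosity, temperature = temperature),
    class = "electrolyte"
  )
}

#' Particle description
#'
#' A rigid particle with hydrodynamic radius `radius`, net charge `charge`
#' and permanent dipole `dipole`.  Mobility and diffusion coefficient are
#' derived from Stokes drag and the Einstein relation unless overridden.
#' When `n_residues` is given the particle is treated as a peptide chain and
#' `radius` is read as the per-residue hydrodynamic radius, so that
#' mu = 1/(6 pi N eta a).
#'
#' @param radius Hydrodynamic radius a (or per-residue radius when
#'   `n_residues` is given), m.
#' @param charge Net charge q, C (signed).
#' @param dipole Permanent dipole magnitude p, C m (>= 0).
#' @param n_residues Optional residue count N for peptide-chain mobility.
#' @param mobility Optional mobility override, m N^-1 s^-1.
#' @param diffusion Optional diffusion-coefficient override, m^2/s.
#' @return An object of class `"particle"`.
#' @export
particle <- function(radius, charge = 0, dipole = 0, n_residues = NULL,
                     mobility = NULL, diffusion = NULL) {
  stopifnot_positive(radius, "radius")
  if (dipole < 0) stop("'dipole' must be >= 0", call. = FALSE)
  if (!is.null(n_residues) && n_residues < 1) {
    stop("'n_residues' must be >= 1", call. = FALSE)
  }
  structure(
    list(radius = radius, charge = charge, dipole = dipole,
         n_residues = n_residues, mobility = mobility, diffusion = diffusion),
    class = "particle"
  )
}

#' Pore description
#'
#' @param radius Pore radius r_p, m.
#' @param length Pore length L, m.
#' @param entrance_radius Capture radius r_e, m; defaults to the pore radius.
#' @param surface_charge Wall surface charge density q_w, C/m^2 (signed).
#' @param conductance Optional measured ionic conductance override G, S.
#' @param eo_conductance Optional electroosmotic conductance override G_eo,
#'   m^3 s^-1 V^-1 (signed; positive means flow into the pore at positive
#'   voltage).
#' @param access_model `"hemispherical"` adds two hemispherical access
#'   resistances to the pore resistance; `"none"` uses the bare cylinder.
#' @return An object of class `"pore"`.
#' @export
pore <- function(radius, length, entrance_radius = radius,
                 surface_charge = 0, conductance = NULL,
                 eo_conductance = NULL,
                 access_model = c("hemispherical", "none")) {
  stopifnot_positive(radius, "radius")
  stopifnot_positive(length, "length")
  stopifnot_positive(entrance_radius, "entrance_radius")
  access_model <- match.arg(access_model)
  structure(
    list(radius = radius, length = length,
         entrance_radius = entrance_radius,
         surface_charge = surface_charge,
         conductance = conductance, eo_conductance = eo_conductance,
         access_model = access_model),
    class = "pore"
  )
}

#' Drive conditions
#'
#' @param voltage Applied voltage Delta V, V (signed; positive drives a
#'   positive ionic current and a field pointing toward the pore on the
#'   particle side).
#' @param concentration Bulk particle number density C0, 1/m^3 (use
#'   [molarity_to_density()] for molar inputs).
#' @return An object of class `"drive_conditions"`.
#' @export
drive_conditions <- function(voltage, concentration) {
  if (concentration < 0) stop("'concentration' must be >= 0", call. = FALSE)
  structure(list(voltage = voltage, concentration = concentration),
            class = "drive_conditions")
}

# --- elementary transport operations ----------------------------------------

#' Stokes mobility of a sphere
#'
#' mu = 1/(6 pi eta a).
#'
#' @param a Particle radius, m.
#' @param eta Dynamic viscosity, Pa s.
#' @return Mobility in m N^-1 s^-1.
#' @export
stokes_mobility <- function(a, eta) {
  stopifnot_positive(a, "a")
  stopifnot_positive(eta, "eta")
  1 / (6 * pi * eta * a)
}

#' Peptide-chain mobility
#'
#' Free-draining-chain estimate mu = 1/(6 pi N eta a) with N residues of
#' hydrodynamic radius a each; reduces to [stokes_mobility()] at N = 1.
#'
#' @param n_residues Number of residues N (>= 1).
#' @param a_res Per-residue hydrodynamic radius, m.
#' @param eta Dynamic viscosity, Pa s.
#' @return Mobility in m N^-1 s^-1.
#' @export
chain_mobility <- function(n_residues, a_res, eta) {
  if (n_residues < 1) stop("'n_residues' must be >= 1", call. = FALSE)
  stokes_mobility(a_res, eta) / n_residues
}

#' Einstein diffusion coefficient
#'
#' Fluctuation-dissipation relation D = kB T mu.
#'
#' @param mu Mobility, m N^-1 s^-1.
#' @param temperature Absolute temperature, K.
#' @return Diffusion coefficient, m^2/s.
#' @export
einstein_diffusion <- function(mu,
                               temperature = pc_constants$default_temperature) {
  stopifnot_positive(mu, "mu")
  stopifnot_positive(temperature, "temperature")
  pc_constants$kB * temperature * mu
}

# Resolve mobility/diffusion for a particle in an electrolyte.
particle_transport <- function(particle, electrolyte) {
  mu <- particle$mobility
  if (is.null(mu)) {
    mu <- if (is.null(particle$n_residues)) {
      stokes_mobility(particle$radius, electrolyte$viscosity)
    } else {
      chain_mobility(particle$n_residues, particle$radius,
                     electrolyte$viscosity)
    }
  }
  D <- particle$diffusion
  if (is.null(D)) D <- einstein_diffusion(mu, electrolyte$temperature)
  list(mobility = mu, diffusion = D)
}

#' Pore resistance and conductance
#'
#' Cylinder resistance R_p = L/(pi r_p^2 sigma) plus, in the hemispherical
#' access model, two access resistances R_a = 1/(2 sigma r_p), one per pore
#' mouth.  A `conductance` override on the pore wins over the model.
#'
#' @param pore A [pore()].
#' @param electrolyte An [electrolyte()].
#' @return A tibble with columns `R_p`, `R_a`, `R_tot` (Ohm) and `G` (S).
#' @examples
#' p <- pore(radius = 2e-9, length = 10e-9)
#' el <- electrolyte(11.1, 0.3e-9, viscosity = 1e-3)
#' pore_resistance(p, el)  # R_tot ~ 0.117 GOhm
#' @export
pore_resistance <- function(pore, electrolyte) {
  sigma <- electrolyte$conductivity
  R_p <- pore$length / (pi * pore$radius^2 * sigma)
  R_a <- 1 / (2 * sigma * pore$radius)
  R_tot <- if (pore$access_model == "hemispherical") R_p + 2 * R_a else R_p
  G <- if (!is.null(pore$conductance)) pore$conductance else 1 / R_tot
  tibble::tibble(R_p = R_p, R_a = R_a, R_tot = R_tot, G = G)
}

#' Electroosmotic conductance of a charged cylindrical pore
#'
#' Thin-double-layer (Helmholtz-Smoluchowski) estimate for a no-slip charged
#' cylinder, |G_eo| = pi r_p^2 |q_w| lambda_D / (eta L), with
#' sign(G_eo) = -sign(q_w): the counterion excess moves with the field, so a
#' negatively charged wall pumps fluid into the pore at positive voltage.
#' Valid for r_p >> lambda_D; a warning is issued when r_p < 5 lambda_D.
#' An `eo_conductance` override on the pore wins over the model.
#'
#' @inheritParams pore_resistance
#' @return Signed electroosmotic conductance, m^3 s^-1 V^-1
#'   (Q_f = G_eo * Delta V).
#' @export
electroosmotic_conductance <- function(pore, electrolyte) {
  if (!is.null(pore$eo_conductance)) return(pore$eo_conductance)
  if (pore$surface_charge == 0) return(0)
  if (pore$radius < 5 * electrolyte$debye_length) {
    warning("thin-double-layer estimate unreliable: r_p < 5 lambda_D",
            call. = FALSE)
  }
  mag <- pi * pore$radius^2 * abs(pore$surface_charge) *
    electrolyte$debye_length / (electrolyte$viscosity * pore$length)
  -sign(pore$surface_charge) * mag
}

#' Radial electric field of the hemispherical entrance model
#'
#' E_r(r) = -I / (2 pi sigma r^2): a positive current gives a field pointing
#' toward the pore (negative radial component).
#'
#' @param I Ionic current, A (signed).
#' @param sigma Electrolyte conductivity, S/m.
#' @param r Distance from the pore entrance, m (> 0).
#' @return Radial field component, V/m.
#' @export
field_at <- function(I, sigma, r) {
  if (any(r <= 0)) stop("'r' must be > 0", call. = FALSE)
  stopifnot_positive(sigma, "sigma")
  -I / (2 * pi * sigma * r^2)
}

#' Transport coefficients a2 and a3 of the effective potential
#'
#' The radial drift toward the pore collects an r^-2 term (electrophoresis
#' plus advection) with coefficient a2 and an r^-3 dielectrophoretic term
#' with coefficient a3:
#' a2 = (mu q I / sigma + Q_f) / (2 pi)   (m^3/s, positive = attraction),
#' a3 = mu p |I| / (pi sigma)             (m^4/s, always >= 0 because the
#' dipole stays aligned with the field and is attracted at either polarity).
#'
#' @param particle A [particle()].
#' @param pore A [pore()].
#' @param electrolyte An [electrolyte()].
#' @param drive A [drive_conditions()].
#' @return A tibble with columns `a2`, `a2_ep`, `a2_eo`, `a3`, `I`, `Q_f`,
#'   `mobility`, `diffusion`.
#' @export
transport_coefficients <- function(particle, pore, electrolyte, drive) {
  tr <- particle_transport(particle, electrolyte)
  G <- pore_resistance(pore, electrolyte)$G
  G_eo <- electroosmotic_conductance(pore, electrolyte)
  I <- G * drive$voltage
  Q_f <- G_eo * drive$voltage
  a2_ep <- tr$mobility * particle$charge * I /
    (2 * pi * electrolyte$conductivity)
  a2_eo <- Q_f / (2 * pi)
  a3 <- tr$mobility * particle$dipole * abs(I) /
    (pi * electrolyte$conductivity)
  tibble::tibble(a2 = a2_ep + a2_eo, a2_ep = a2_ep, a2_eo = a2_eo, a3 = a3,
                 I = I, Q_f = Q_f,
                 mobility = tr$mobility, diffusion = tr$diffusion)
}

#' Electroosmosis/electrophoresis competition number
#'
#' Ratio of the electroosmotic to the electrophoretic drift amplitude.
#' Under the thin-double-layer conductance model, Stokes mobility, and a
#' pore-only ionic conductance (no access resistance) it reduces to the
#' closed form 6 pi a q_w lambda_D / q.  Positive values mean competition
#' (magnitude > 1: electroosmosis wins), negative values cooperation.
#'
#' @inheritParams transport_coefficients
#' @param closed_form Use the reduced closed form (default) instead of the
#'   general conductance ratio.  Both agree to machine precision when no
#'   overrides are present.
#' @return Dimensionless ratio b_eo/ep; `NA` for a neutral particle.
#' @export
b_eo_ep <- function(particle, pore, electrolyte, closed_form = TRUE) {
  q <- particle$charge
  if (q == 0) return(NA_real_)
  if (closed_form && is.null(pore$eo_conductance) &&
        is.null(particle$mobility)) {
    tr_mu <- particle_transport(particle, electrolyte)$mobility
    # closed form assumes Stokes drag on the bare radius; for chains use the
    # general route below
    if (is.null(particle$n_residues)) {
      return(6 * pi * particle$radius * pore$surface_charge *
               electrolyte$debye_length / q)
    }
    G_pore <- pi * pore$radius^2 * electrolyte$conductivity / pore$length
    G_eo <- electroosmotic_conductance(pore, electrolyte)
    return(abs(G_eo) * electrolyte$conductivity *
             sign(pore$surface_charge * q) / (tr_mu * abs(q) * G_pore))
  }
  mu <- particle_transport(particle, electrolyte)$mobility
  G_eo <- electroosmotic_conductance(pore, electrolyte)
  if (G_eo == 0) return(0)
  G <- if (!is.null(pore$conductance)) {
    pore$conductance
  } else {
    pi * pore$radius^2 * electrolyte$conductivity / pore$length
  }
  sgn <- if (pore$surface_charge != 0) sign(pore$surface_charge * q) else
    -sign(G_eo * q)
  abs(G_eo) * electrolyte$conductivity * sgn / (mu * abs(q) * G)
}

#' Electroosmosis/dielectrophoresis competition number
#'
#' Ratio of the r^-2 electroosmotic force term to the r^-3 dielectrophoretic
#' term evaluated at the pore entrance r_e: b_eo/di = |a2_eo| r_e / a3.
#' The ratio is independent of the applied voltage.  Following the pore-only
#' conductance convention used for [b_eo_ep()], the ionic current entering
#' a3 is computed without access resistance unless a conductance override is
#' present.
#'
#' @inheritParams transport_coefficients
#' @param drive Optional; only used for its sign conventions, the ratio does
#'   not depend on the voltage magnitude.
#' @return Dimensionless ratio b_eo/di; `NA` for a particle without dipole.
#' @export
b_eo_di <- function(particle, pore, electrolyte, drive = NULL) {
  p <- particle$dipole
  if (p <= 0) return(NA_real_)
  G_eo <- electroosmotic_conductance(pore, electrolyte)
  if (G_eo == 0) return(0)
  mu <- particle_transport(particle, electrolyte)$mobility
  G <- if (!is.null(pore$conductance)) {
    pore$conductance
  } else {
    pi * pore$radius^2 * electrolyte$conductivity / pore$length
  }
  # |a2_eo| r_e / a3 at unit voltage
  (abs(G_eo) / (2 * pi)) * pore$entrance_radius /
    (mu * p * G / (pi * electrolyte$conductivity))
}
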