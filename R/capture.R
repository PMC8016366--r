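# Capture theory: approach frequency (closed form and quadrature), entrance
# model, combination into the total capture frequency, concentration
# profiles and voltage sweeps.

#' Approach frequency by adaptive quadrature
#'
#' The stationary solution of the radial advection-diffusion problem gives
#' f_a = 2 pi D C0 / Int, with Int = the integral of exp(-phi(r))/r^2 from
#' r_e to infinity.  After the substitution u = 1/r the integrand becomes
#' exp(-(alpha u + beta u^2)) on (0, 1/r_e], integrated adaptively in the
#' log domain so that barriers of hundreds of kB T do not overflow.
#'
#' @param pot An [effective_potential()].
#' @param C0 Bulk number density, 1/m^3.
#' @param r_e Entrance (capture) radius, m.
#' @return Approach frequency f_a, 1/s.
#' @examples
#' pot0 <- effective_potential(0, 0, 1.45e-10)
#' approach_frequency_quadrature(pot0, molarity_to_density(40e-6), 2e-9)
#' # == 2 pi D C0 r_e, the diffusion-limited value
#' @export
approach_frequency_quadrature <- function(pot, C0, r_e) {
  if (r_e <= 0) stop("'r_e' must be > 0", call. = FALSE)
  alpha <- pot$a2 / pot$D
  beta <- pot$a3 / (2 * pot$D)
  logI <- log_phi_integral_quad(0, 1 / r_e, alpha, beta)
  2 * pi * pot$D * C0 * exp(-logI)
}

#' Approach frequency, closed form
#'
#' Completing the square in the u = 1/r integral yields an error-function
#' expression with g = (2 D a3)^(-1/2); the a3 -> 0 limit reduces to
#' f_a = 2 pi C0 a2 / (1 - exp(-a2/(D r_e))) and a2 = a3 = 0 to the
#' diffusion-limited 2 pi D C0 r_e.  Evaluated through the scaled
#' complementary error function so that strong attraction or repulsion does
#' not overflow; if the closed form cannot guarantee accuracy it falls back
#' to [approach_frequency_quadrature()] with a message.
#'
#' @inheritParams approach_frequency_quadrature
#' @return Approach frequency f_a, 1/s.
#' @export
approach_frequency_closed <- function(pot, C0, r_e) {
  if (r_e <= 0) stop("'r_e' must be > 0", call. = FALSE)
  alpha <- pot$a2 / pot$D
  beta <- pot$a3 / (2 * pot$D)
  logI <- log_phi_integral_closed(1 / r_e, alpha, beta)
  if (is.null(logI)) {
    message("closed form declined (precision guard); using quadrature")
    return(approach_frequency_quadrature(pot, C0, r_e))
  }
  2 * pi * pot$D * C0 * exp(-logI)
}

#' @rdname approach_frequency_closed
#' @param method `"closed"` (default) or `"quadrature"`.
#' @export
approach_frequency <- function(pot, C0, r_e,
                               method = c("closed", "quadrature")) {
  method <- match.arg(method)
  switch(method,
         closed = approach_frequency_closed(pot, C0, r_e),
         quadrature = approach_frequency_quadrature(pot, C0, r_e))
}

#' Entrance (pore-docking) model
#'
#' Arrhenius/Eyring model for the Robin rate constant at the pore mouth:
#' k = kappa0 exp(-DeltaG0 + U/kBT), with kappa0 = (kB T / h) l0 using a
#' jump length l0 (default: the entrance radius) to give k its m/s
#' dimension.  With `barrier_coupling = "phi_at_entrance"` the barrier is
#' lowered by the local effective potential, U/kBT = phi_s(r_e), where
#' phi_s is evaluated with the dielectrophoretic coefficient a3 multiplied
#' by the docking field-enhancement factor `s` (>= 1).  `model = "perfect"`
#' is the k -> infinity limit (no barrier, transport-limited capture).
#'
#' @param dG0 Equilibrium free-energy barrier, in units of kB T (>= 0).
#' @param barrier_coupling `"phi_at_entrance"` or `"none"`.
#' @param s Field-enhancement factor applied to a3 in the docking stage
#'   only (dimensionless, >= 1).
#' @param jump_length Jump length l0 of the Eyring prefactor, m; `NULL`
#'   defaults to the entrance radius at compute time.
#' @param rate Optional direct override of k, m/s (`Inf` = perfect
#'   absorption).
#' @param model `"barrier"` (default) or `"perfect"`.
#' @return An object of class `"entrance_model"`.
#' @export
entrance_model <- function(dG0 = 0,
                           barrier_coupling = c("phi_at_entrance", "none"),
                           s = 1, jump_length = NULL, rate = NULL,
                           model = c("barrier", "perfect")) {
  model <- match.arg(model)
  barrier_coupling <- match.arg(barrier_coupling)
  if (dG0 < 0) stop("'dG0' must be >= 0 (units of kB T)", call. = FALSE)
  if (s < 1) stop("'s' must be >= 1", call. = FALSE)
  if (model == "perfect") rate <- Inf
  structure(
    list(model = model, dG0 = dG0, barrier_coupling = barrier_coupling,
         s = s, jump_length = jump_length, rate = rate),
    class = "entrance_model"
  )
}

#' Robin rate constant of the entrance model
#'
#' @param em An [entrance_model()].
#' @param phi_e_s Effective potential at the entrance with the
#'   field-enhanced a3 (dimensionless); enters only when
#'   `barrier_coupling = "phi_at_entrance"`.
#' @param r_e Entrance radius, m (default jump length).
#' @param temperature Absolute temperature, K.
#' @return Rate k, m/s.
#' @export
entrance_rate <- function(em, phi_e_s, r_e,
                          temperature = pc_constants$default_temperature) {
  if (!is.null(em$rate)) return(em$rate)
  l0 <- if (is.null(em$jump_length)) r_e else em$jump_length
  kappa0 <- pc_constants$kB * temperature / pc_constants$h * l0
  U_over_kBT <- if (em$barrier_coupling == "phi_at_entrance") phi_e_s else 0
  kappa0 * exp(-em$dG0 + U_over_kBT)
}

#' Entrance frequency
#'
#' f_e = 2 pi r_e^2 k C0 exp(phi(r_e)).  The exp(phi(r_e)) factor is the
#' unique choice that makes 1/f = 1/f_a + 1/f_e identical to the direct
#' Robin-boundary stationary solution; `phi_e` here is the transport-stage
#' potential (no field enhancement).
#'
#' @param k Robin rate constant, m/s (>= 0; `Inf` gives `Inf`).
#' @param r_e Entrance radius, m.
#' @param C0 Bulk number density, 1/m^3.
#' @param phi_e Effective potential at the entrance (dimensionless).
#' @return Entrance frequency f_e, 1/s.
#' @export
entrance_frequency <- function(k, r_e, C0, phi_e) {
  if (k < 0) stop("'k' must be >= 0", call. = FALSE)
  2 * pi * r_e^2 * k * C0 * exp(phi_e)
}

#' Combine approach and entrance frequencies
#'
#' The mean capture time is the sum of the approach and entrance times:
#' tau = tau_a + tau_e, i.e. 1/f = 1/f_a + 1/f_e.  The regime label uses
#' the tau_a/tau_e ratio: transport-limited when tau_a/tau_e >
#' `ratio_threshold`, entrance-limited when below its reciprocal.
#'
#' @param f_a Approach frequency, 1/s (> 0).
#' @param f_e Entrance frequency, 1/s (>= 0; `Inf` = perfect absorption).
#' @param ratio_threshold Regime threshold on tau_a/tau_e (default 10).
#' @return A tibble with columns `f`, `tau`, `tau_a`, `tau_e`, `regime`.
#' @export
combine_frequencies <- function(f_a, f_e, ratio_threshold = 10) {
  if (!is.finite(f_a) || f_a <= 0) stop("'f_a' must be > 0", call. = FALSE)
  if (f_e < 0) stop("'f_e' must be >= 0", call. = FALSE)
  tau_a <- 1 / f_a
  tau_e <- 1 / f_e                     # 0 when f_e = Inf
  tau <- tau_a + tau_e
  f <- 1 / tau
  ratio <- tau_a / tau_e               # Inf when tau_e = 0
  regime <- if (f_e == 0) {
    "entrance_limited"
  } else if (ratio > ratio_threshold) {
    "transport_limited"
  } else if (ratio < 1 / ratio_threshold) {
    "entrance_limited"
  } else {
    "mixed"
  }
  tibble::tibble(f = f, tau = tau, tau_a = tau_a, tau_e = tau_e,
                 regime = regime)
}

#' Capture frequency of a scenario
#'
#' Resolves a [scenario()] into SI transport quantities, evaluates the
#' approach frequency (closed form), the entrance model and their
#' combination, and returns everything as a `"capture_result"`.
#'
#' @param scenario A [scenario()].
#' @param method Approach-frequency method, `"closed"` or `"quadrature"`.
#' @param ratio_threshold Regime threshold passed to
#'   [combine_frequencies()].
#' @return An object of class `"capture_result"`: a list with the
#'   frequencies (`f_a`, `f_e`, `f`), times (`tau_a`, `tau_e`, `tau`),
#'   `phi_e`, `regime`, transport coefficients, diagnostics `b_eo_ep` and
#'   `b_eo_di`, and the resolved parameters.
#' @examples
#' sc <- load_scenario("fig3a_ep_eo")
#' res <- capture_frequency(sc)
#' glance(res)
#' @export
capture_frequency <- function(scenario, method = c("closed", "quadrature"),
                              ratio_threshold = 10) {
  method <- match.arg(method)
  stopifnot(inherits(scenario, "pc_scenario"))
  el <- scenario$electrolyte
  pa <- scenario$particle
  po <- scenario$pore
  dr <- scenario$drive
  em <- scenario$entrance
  tc <- transport_coefficients(pa, po, el, dr)
  r_e <- po$entrance_radius
  C0 <- dr$concentration
  pot <- effective_potential(tc$a2, tc$a3, tc$diffusion)
  f_a <- approach_frequency(pot, C0, r_e, method = method)
  phi_e <- phi_potential(r_e, pot)
  if (!is.null(em$rate) && is.infinite(em$rate)) {
    k <- Inf
    f_e <- Inf
  } else {
    pot_s <- effective_potential(tc$a2, em$s * tc$a3, tc$diffusion)
    phi_e_s <- phi_potential(r_e, pot_s)
    k <- entrance_rate(em, phi_e_s, r_e, el$temperature)
    f_e <- entrance_frequency(k, r_e, C0, phi_e)
  }
  comb <- combine_frequencies(f_a, f_e, ratio_threshold)
  structure(
    list(
      f_a = f_a, f_e = f_e, f = comb$f,
      tau_a = comb$tau_a, tau_e = comb$tau_e, tau = comb$tau,
      phi_e = phi_e, regime = comb$regime, k = k,
      a2 = tc$a2, a2_ep = tc$a2_ep, a2_eo = tc$a2_eo, a3 = tc$a3,
      I = tc$I, Q_f = tc$Q_f,
      mobility = tc$mobility, diffusion = tc$diffusion,
      b_eo_ep = b_eo_ep(pa, po, el),
      b_eo_di = b_eo_di(pa, po, el),
      r_e = r_e, C0 = C0, voltage = dr$voltage,
      scenario_name = scenario$name
    ),
    class = "capture_result"
  )
}

#' Stationary concentration profile with Robin boundary
#'
#' C(r) = exp(phi(r)) (C0 - (A/D) W(r)) with W(r) the tail integral of
#' exp(-phi)/r'^2 from r to infinity and the flux constant A fixed by the
#' Robin condition D dC/dr - C D phi' = k C at r_e; the capture frequency
#' is f = 2 pi A.  k = 0 returns the zero-flux equilibrium profile
#' C0 exp(phi); k = Inf the perfectly absorbing one (C(r_e) = 0).
#'
#' @inheritParams approach_frequency_quadrature
#' @param k Robin rate constant, m/s (0, finite, or `Inf`).
#' @param r Radial grid, m (all >= r_e).
#' @return A tibble with columns `r`, `C`, `phi`; attributes `A` (flux
#'   constant, so that f = 2 pi A) and `f`.
#' @export
concentration_profile <- function(pot, C0, r_e, k, r) {
  if (any(r < r_e * (1 - 1e-12))) {
    stop("grid must satisfy r >= r_e", call. = FALSE)
  }
  r <- pmax(r, r_e)
  alpha <- pot$a2 / pot$D
  beta <- pot$a3 / (2 * pot$D)
  W <- function(rr) exp(log_phi_integral_quad(0, 1 / rr, alpha, beta))
  W_e <- W(r_e)
  phi_e <- phi_potential(r_e, pot)
  A <- if (k == 0) {
    0
  } else if (is.infinite(k)) {
    pot$D * C0 / W_e
  } else {
    k * C0 / (exp(-phi_e) / r_e^2 + k * W_e / pot$D)
  }
  phi_r <- phi_potential(r, pot)
  Cr <- vapply(seq_along(r), function(i) {
    exp(phi_r[i]) * (C0 - (A / pot$D) * W(r[i]))
  }, numeric(1))
  out <- tibble::tibble(r = r, C = Cr, phi = phi_r)
  attr(out, "A") <- A
  attr(out, "f") <- 2 * pi * A
  class(out) <- c("concentration_profile", class(out))
  out
}

#' Voltage sweep of a scenario
#'
#' Recomputes the capture result of a scenario at each voltage in
#' `voltages`.  Per-voltage failures are reported as warnings and leave an
#' NA row; the sweep continues.
#'
#' @param scenario A [scenario()].
#' @param voltages Voltages to evaluate, V.
#' @param ... Passed to [capture_frequency()].
#' @return A tibble of class `"capture_sweep"` with one row per voltage and
#'   columns `voltage`, `a2`, `a3`, `f_a`, `f_e`, `f`, `tau_a`, `tau_e`,
#'   `tau`, `regime`, `b_eo_ep`, `b_eo_di`.
#' @examples
#' sw <- voltage_sweep(load_scenario("fig3b_dep_eo"),
#'                     seq(-0.2, 0.2, by = 0.05))
#' @export
voltage_sweep <- function(scenario, voltages, ...) {
  rows <- purrr::map(voltages, function(v) {
    sc <- scenario
    sc$drive$voltage <- v
    res <- tryCatch(capture_frequency(sc, ...), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("voltage %g V failed: %s", v, conditionMessage(res)),
              call. = FALSE)
      return(tibble::tibble(
        voltage = v, a2 = NA_real_, a3 = NA_real_, f_a = NA_real_,
        f_e = NA_real_, f = NA_real_, tau_a = NA_real_, tau_e = NA_real_,
        tau = NA_real_, regime = NA_character_, b_eo_ep = NA_real_,
        b_eo_di = NA_real_
      ))
    }
    tibble::tibble(
      voltage = v, a2 = res$a2, a3 = res$a3, f_a = res$f_a, f_e = res$f_e,
      f = res$f, tau_a = res$tau_a, tau_e = res$tau_e, tau = res$tau,
      regime = res$regime, b_eo_ep = res$b_eo_ep, b_eo_di = res$b_eo_di
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "scenario_name") <- scenario$name
  class(out) <- c("capture_sweep", class(out))
  out
}
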