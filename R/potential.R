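# Effective potential phi(r) and the radial Boltzmann-weighted integrals
# that every stationary result (approach frequency, concentration profile,
# splitting probabilities) is built from.

#' Effective potential of the capture problem
#'
#' The combined electrophoretic/advective (r^-2) and dielectrophoretic
#' (r^-3) drift toward the pore derives from the dimensionless potential
#' phi(r) = (a2/r + a3/(2 r^2)) / D, with phi -> 0 far from the pore.
#' Positive a2/a3 mean attraction; the radial drift velocity is
#' v_r(r) = D phi'(r) = -(a2/r^2 + a3/r^3).
#'
#' @param a2 Coefficient of the r^-2 drift term, m^3/s (signed).
#' @param a3 Coefficient of the r^-3 drift term, m^4/s (>= 0).
#' @param D Diffusion coefficient, m^2/s (> 0).
#' @return An object of class `"effective_potential"`.
#' @export
effective_potential <- function(a2, a3, D) {
  if (!is.finite(D) || D <= 0) stop("'D' must be > 0", call. = FALSE)
  if (a3 < 0) stop("'a3' must be >= 0", call. = FALSE)
  structure(list(a2 = a2, a3 = a3, D = D), class = "effective_potential")
}

#' Evaluate the effective potential and its derivative
#'
#' @param r Radial distance(s), m (> 0).
#' @param pot An [effective_potential()].
#' @return `phi_potential()`: phi(r) (dimensionless);
#'   `dphi_potential()`: phi'(r) in 1/m.
#' @export
phi_potential <- function(r, pot) {
  if (any(r <= 0)) stop("'r' must be > 0", call. = FALSE)
  (pot$a2 / r + pot$a3 / (2 * r^2)) / pot$D
}

#' @rdname phi_potential
#' @export
dphi_potential <- function(r, pot) {
  if (any(r <= 0)) stop("'r' must be > 0", call. = FALSE)
  -(pot$a2 / r^2 + pot$a3 / r^3) / pot$D
}

# --- scaled complementary error function ------------------------------------

# erfcx(x) = exp(x^2) erfc(x), stable for large positive x where the naive
# product overflows.  Asymptotic series beyond the range where
# pracma::erfcx is reliable.
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    xx <- x[!small]
    # 1/(x sqrt(pi)) * sum_k (-1)^k (2k-1)!! / (2 x^2)^k
    inv2x2 <- 1 / (2 * xx^2)
    term <- rep(1, length(xx))
    s <- rep(1, length(xx))
    for (k in 1:9) {
      term <- term * -(2 * k - 1) * inv2x2
      s <- s + term
    }
    out[!small] <- s / (xx * sqrt(pi))
  }
  out
}

# --- the u = 1/r integral ---------------------------------------------------

# All stationary quantities reduce to
#   I(u0, u1) = int_{u0}^{u1} exp(-(alpha u + beta u^2)) du,
# with alpha = a2/D, beta = a3/(2D), after the substitution u = 1/r.
# Returned on the log scale to survive |phi| of hundreds.

log_phi_integral_quad <- function(u0, u1, alpha, beta, rel_tol = 1e-10) {
  if (u1 <= u0) return(-Inf)
  g <- function(u) -(alpha * u + beta * u^2)
  cand <- c(g(u0), g(u1))
  if (beta > 0) {
    ustar <- -alpha / (2 * beta)
    if (ustar > u0 && ustar < u1) cand <- c(cand, g(ustar))
  }
  M <- max(cand)
  val <- stats::integrate(function(u) exp(g(u) - M), u0, u1,
                          rel.tol = rel_tol, subdivisions = 400L)$value
  M + log(val)
}

# int_0^1 t^m exp(-z t) dt, stable for all z (series for small |z|,
# recursion on the closed form otherwise).
phi_m <- function(m, z) {
  if (abs(z) < 30) {
    # sum_k (-z)^k / (k! (m + k + 1)); alternating, converges fast
    s <- 0
    term <- 1
    for (k in 0:80) {
      s <- s + term / (m + k + 1)
      term <- term * (-z) / (k + 1)
      if (abs(term) < 1e-20 * abs(s) && k > 5) break
    }
    return(s)
  }
  ez <- exp(-z)
  f <- (1 - ez) / z
  if (m == 0) return(f)
  for (j in 1:m) f <- (j * f - ez) / z
  f
}

# Closed-form log of I(0, u_e); NULL when the closed form declines and the
# caller should fall back to quadrature.
log_phi_integral_closed <- function(u_e, alpha, beta) {
  if (beta * u_e^2 < 1e-6) {
    # dielectrophoretic term perturbative: expand exp(-beta u^2) to 2nd order
    z <- alpha * u_e
    if (!is.finite(exp(-z))) return(NULL)   # extreme repulsion: quadrature
    I0 <- u_e * phi_m(0, z)
    I2 <- u_e^3 * phi_m(2, z)
    I4 <- u_e^5 * phi_m(4, z)
    val <- I0 - beta * I2 + beta^2 / 2 * I4
    if (!is.finite(val) || val <= 0) return(NULL)
    return(log(val))
  }
  sb <- sqrt(beta)
  cc <- sb * u_e
  s0 <- alpha / (2 * sb)
  pref <- log(sqrt(pi) / (2 * sb))
  if (s0 >= 0) {
    bracket <- erfcx_stable(s0) -
      erfcx_stable(s0 + cc) * exp(-cc * (cc + 2 * s0))
    if (!is.finite(bracket) || bracket <= 0) return(NULL)
    return(pref + log(bracket))
  }
  if (s0 + cc <= 0) {
    t1 <- -s0 - cc
    t2 <- -s0
    bracket <- erfcx_stable(t1) - erfcx_stable(t2) * exp(-(t2^2 - t1^2))
    if (!is.finite(bracket) || bracket <= 0) return(NULL)
    return(pref + (s0^2 - t1^2) + log(bracket))
  }
  # mixed: erf(s0 + cc) + erf(-s0), both positive, no cancellation
  delta <- pracma::erf(s0 + cc) + pracma::erf(-s0)
  if (!is.finite(delta) || delta <= 0) return(NULL)
  pref + s0^2 + log(delta)
}
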