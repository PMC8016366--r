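# Brownian-dynamics oracle: stochastic validation of the stationary theory
# by first-passage simulation of walkers in the radial drift field with a
# partially absorbing inner boundary.

#' Brownian-dynamics configuration
#'
#' @param dt Base time step, s.  Must keep the per-contact absorption
#'   probability below 0.1 and the drift displacement per step below
#'   0.1 r_e (checked against the potential at simulation time).
#' @param n_walkers Number of independent walkers.
#' @param seed RNG seed (integer) for reproducibility; `NULL` leaves the
#'   RNG state alone.
#' @param r_start Start radius for splitting runs, m (r_e < r_start <
#'   r_out).
#' @param r_out Outer boundary radius, m.
#' @param absorption `"perfect"` or `"robin"`; `"robin"` uses the rate `k`.
#' @param k Robin rate constant, m/s (used when `absorption = "robin"`).
#' @param max_steps Per-walker step budget before erroring out.
#' @return An object of class `"bd_config"`.
#' @export
bd_config <- function(dt, n_walkers, seed = NULL, r_start = NULL,
                      r_out = NULL, absorption = c("perfect", "robin"),
                      k = Inf, max_steps = 1e8) {
  absorption <- match.arg(absorption)
  stopifnot_positive(dt, "dt")
  if (n_walkers < 1) stop("'n_walkers' must be >= 1", call. = FALSE)
  structure(
    list(dt = dt, n_walkers = as.integer(n_walkers), seed = seed,
         r_start = r_start, r_out = r_out, absorption = absorption, k = k,
         max_steps = max_steps),
    class = "bd_config"
  )
}

# Per-contact absorption probability of the partially reflecting scheme.
bd_pabs <- function(k, dt, D) {
  if (is.infinite(k)) return(1)
  k * sqrt(pi * dt / D)
}

# Validate the dt invariants before any sampling.
bd_validate <- function(pot, r_e, config) {
  if (is.null(config$r_out)) stop("'r_out' must be set", call. = FALSE)
  if (config$r_out <= r_e) stop("need r_out > r_e", call. = FALSE)
  v_e <- abs(pot$a2 / r_e^2 + pot$a3 / r_e^3)
  if (v_e * config$dt >= 0.1 * r_e) {
    stop("dt too large: drift displacement per step exceeds 0.1 r_e",
         call. = FALSE)
  }
  k <- if (config$absorption == "perfect") Inf else config$k
  if (is.finite(k) && bd_pabs(k, config$dt, pot$D) >= 0.1) {
    stop("dt too large: per-contact absorption probability exceeds 0.1",
         call. = FALSE)
  }
  invisible(TRUE)
}

bd_result <- function(kind, captured, n, estimate, se, config, extra = list()) {
  structure(
    c(list(kind = kind, captured = captured, escaped = n - captured, n = n,
           p_capture = captured / n,
           p_se = sqrt(captured / n * (1 - captured / n) / n),
           estimate = estimate, se = se,
           dt = config$dt, seed = config$seed),
      extra),
    class = "bd_result"
  )
}

with_bd_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

#' Analytic splitting probability
#'
#' Probability that a walker started at `r_start` reaches the (partially
#' absorbing) inner boundary r_e before the outer boundary r_out, for the
#' drift field of `pot`.  For a perfectly absorbing inner boundary and
#' phi = 0 this is the classic (1/r_s - 1/r_out)/(1/r_e - 1/r_out).
#'
#' @param pot An [effective_potential()].
#' @param r_start Start radius, m.
#' @param r_e Inner boundary, m.
#' @param r_out Outer boundary, m.
#' @param k Robin rate at r_e, m/s (`Inf` = perfect absorption).
#' @return Capture probability in `[0, 1]`.
#' @export
splitting_probability <- function(pot, r_start, r_e, r_out, k = Inf) {
  stopifnot(r_e < r_start, r_start < r_out)
  alpha <- pot$a2 / pot$D
  beta <- pot$a3 / (2 * pot$D)
  W <- function(rr) exp(log_phi_integral_quad(1 / r_out, 1 / rr, alpha, beta))
  if (k == 0) return(0)
  if (is.infinite(k)) return(W(r_start) / W(r_e))
  phi_e <- phi_potential(r_e, pot)
  k * W(r_start) / (k * W(r_e) + pot$D * exp(-phi_e) / r_e^2)
}

#' Brownian-dynamics splitting probability
#'
#' Euler-Maruyama simulation in 3D of `n_walkers` walkers started at
#' `config$r_start`, absorbed at r_e (perfectly, or with the partially
#' reflecting rule P_abs = k sqrt(pi dt / D)) or removed at r_out.
#' Compare with [splitting_probability()].
#'
#' @param pot An [effective_potential()].
#' @param r_e Inner (pore) boundary radius, m.
#' @param config A [bd_config()] with `r_start` and `r_out` set.
#' @return A `"bd_result"` with the capture-probability estimate and its
#'   binomial standard error.
#' @export
simulate_splitting <- function(pot, r_e, config) {
  bd_validate(pot, r_e, config)
  if (is.null(config$r_start)) stop("'r_start' must be set", call. = FALSE)
  stopifnot(config$r_start > r_e, config$r_start < config$r_out)
  k <- if (config$absorption == "perfect") Inf else config$k
  if (k == 0) {
    return(bd_result("splitting", 0L, config$n_walkers, 0, 0, config))
  }
  pabs <- bd_pabs(k, config$dt, pot$D)
  res <- with_bd_seed(config$seed,
    .bd_splitting_cpp(pot$a2, pot$a3, pot$D, r_e, config$r_out,
                      config$r_start, config$dt, pabs, config$n_walkers,
                      config$max_steps))
  p <- res$captured / res$n
  se <- sqrt(p * (1 - p) / res$n)
  bd_result("splitting", res$captured, res$n, p, se, config,
            list(analytic = splitting_probability(pot, config$r_start, r_e,
                                                  config$r_out, k)))
}

#' Brownian-dynamics capture-rate estimate
#'
#' Flux-injection estimator of the stationary capture frequency: walkers
#' are injected at r_out and followed until capture at r_e or escape to
#' infinity (outer excursions beyond 2 r_out are resolved analytically by
#' re-injection with the exact return probability).  The estimate
#' f_hat = f_arr(r_out) * P_capture is exact in expectation, with
#' f_arr(r_out) = 2 pi D C0 / W(r_out) the first-arrival rate at r_out
#' under the same potential.
#'
#' @param pot An [effective_potential()].
#' @param r_e Inner (pore) boundary radius, m.
#' @param k Robin rate constant at r_e, m/s (`Inf` = perfect absorption).
#' @param C0 Bulk number density, 1/m^3.
#' @param config A [bd_config()] with `r_out` set (default 20 r_e when
#'   `NULL`).
#' @return A `"bd_result"` with the capture-frequency estimate (1/s), its
#'   standard error, and the analytic value from the stationary theory.
#' @export
simulate_capture_rate <- function(pot, r_e, k, C0, config) {
  if (is.null(config$r_out)) config$r_out <- 20 * r_e
  bd_validate(pot, r_e, config)
  alpha <- pot$a2 / pot$D
  beta <- pot$a3 / (2 * pot$D)
  r_far <- 2 * config$r_out
  W_out <- exp(log_phi_integral_quad(0, 1 / config$r_out, alpha, beta))
  W_far <- exp(log_phi_integral_quad(0, 1 / r_far, alpha, beta))
  p_return <- W_far / W_out
  f_arr <- 2 * pi * pot$D * C0 / W_out
  pabs <- bd_pabs(k, config$dt, pot$D)
  res <- with_bd_seed(config$seed,
    .bd_capture_cpp(pot$a2, pot$a3, pot$D, r_e, config$r_out, r_far,
                    p_return, config$dt, pabs, config$n_walkers,
                    config$max_steps))
  p <- res$captured / res$n
  se_p <- sqrt(p * (1 - p) / res$n)
  f_a <- approach_frequency_quadrature(pot, C0, r_e)
  f_e <- entrance_frequency(k, r_e, C0, phi_potential(r_e, pot))
  f_theory <- combine_frequencies(f_a, f_e)$f
  bd_result("capture_rate", res$captured, res$n,
            f_arr * p, f_arr * se_p, config,
            list(f_arr = f_arr, analytic = f_theory))
}

#' @export
print.bd_result <- function(x, ...) {
  cat(sprintf("<bd_result: %s>\n", x$kind))
  cat(sprintf("  walkers: %d  captured: %d  escaped: %d\n",
              x$n, x$captured, x$escaped))
  cat(sprintf("  estimate: %.6g +- %.3g", x$estimate, x$se))
  if (!is.null(x$analytic)) cat(sprintf("  (analytic %.6g)", x$analytic))
  cat("\n")
  invisible(x)
}
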