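test_that("effective potential and its derivative are consistent", {
  D <- D_ref()
  expect_identical(phi_potential(2e-9, effective_potential(0, 0, D)), 0)
  # no dielectrophoresis: phi(r_e) = a2/(D r_e)
  pot <- effective_potential(2e-19, 0, D)
  expect_equal(phi_potential(2e-9, pot), 2e-19 / (D * 2e-9),
               tolerance = 1e-14)
  # finite-difference check of the analytic derivative over mixed terms
  pot2 <- effective_potential(-1.3e-19, 8e-28, D)
  for (r in c(0.7e-9, 2e-9, 9e-9)) {
    h <- r * 1e-6
    num <- (phi_potential(r + h, pot2) - phi_potential(r - h, pot2)) / (2 * h)
    expect_equal(dphi_potential(r, pot2), num, tolerance = 1e-6)
  }
  expect_error(phi_potential(0, pot), "> 0")
  expect_error(effective_potential(0, -1e-30, D), ">= 0")
  expect_error(effective_potential(0, 0, 0), "> 0")
})

test_that("closed-form approach frequency equals quadrature across regimes", {
  D <- 1.45e-10
  C0 <- molarity_to_density(40e-6)
  # the perturbative grid (weak drift) ...
  a2_grid <- c(-10^seq(-30, -25, length.out = 5), 0,
               10^seq(-30, -25, length.out = 5))
  a3_grid <- c(0, 1e-40, 1e-39, 1e-38)
  re_grid <- c(0.5e-9, 1e-9, 2e-9, 5e-9)
  # ... plus physically strong drift (|phi(r_e)| up to tens)
  a2_strong <- c(-3e-19, -1e-19, 1e-19, 3e-19)
  a3_strong <- c(0, 1e-28, 2e-27)
  cases <- rbind(
    expand.grid(a2 = a2_grid, a3 = a3_grid, re = re_grid),
    expand.grid(a2 = a2_strong, a3 = a3_strong, re = c(1e-9, 2e-9))
  )
  for (i in seq_len(nrow(cases))) {
    pot <- effective_potential(cases$a2[i], cases$a3[i], D)
    fc <- approach_frequency_closed(pot, C0, cases$re[i])
    fq <- approach_frequency_quadrature(pot, C0, cases$re[i])
    expect_lt(abs(fc - fq) / fq, 1e-8,
              label = sprintf("case %d (a2=%g a3=%g re=%g): rel err", i,
                              cases$a2[i], cases$a3[i], cases$re[i]))
  }
})

test_that("approach frequency recovers the diffusion-limited value and the a3 = 0 form", {
  D <- D_ref()
  C0 <- molarity_to_density(40e-6)
  r_e <- 2e-9
  pot0 <- effective_potential(0, 0, D)
  smol <- 2 * pi * D * C0 * r_e
  expect_equal(approach_frequency_closed(pot0, C0, r_e), smol,
               tolerance = 1e-12)
  expect_equal(approach_frequency_quadrature(pot0, C0, r_e), smol,
               tolerance = 1e-9)
  # ~4.4e4 1/s for the worked 40 uM / 2 nm system
  expect_equal(smol, 4.4e4, tolerance = 0.02)
  # pure electrophoresis: f_a = 2 pi C0 a2 / (1 - exp(-a2/(D r_e)))
  for (a2 in c(-2e-19, 1e-25, 2.5e-19)) {
    pot <- effective_potential(a2, 0, D)
    f_exact <- 2 * pi * C0 * a2 / (1 - exp(-a2 / (D * r_e)))
    expect_equal(approach_frequency_closed(pot, C0, r_e), f_exact,
                 tolerance = 1e-10)
  }
})

test_that("approach frequency is even in voltage for pure dielectrophoresis and monotone in a2", {
  D <- D_ref()
  C0 <- molarity_to_density(40e-6)
  # evenness via a full scenario sweep (a2 identically 0)
  sc <- make_scenario(q_e = 0, p_enm = 12, q_w = 0)
  sw <- voltage_sweep(sc, c(-0.15, -0.05, 0.05, 0.15))
  expect_identical(sw$a2, rep(0, 4))
  expect_equal(sw$f_a[1], sw$f_a[4], tolerance = 1e-12)
  expect_equal(sw$f_a[2], sw$f_a[3], tolerance = 1e-12)
  # dielectrophoresis always beats pure diffusion
  expect_true(all(sw$f_a > approach_frequency_closed(
    effective_potential(0, 0, D), C0, 2e-9)))
  # strict monotonicity of f_a in a2 at fixed a3
  a2s <- seq(-3e-19, 3e-19, length.out = 13)
  fa <- vapply(a2s, function(a2) approach_frequency_closed(
    effective_potential(a2, 5e-28, D), C0, 2e-9), numeric(1))
  expect_true(all(diff(fa) > 0))
})

test_that("entrance rate follows the Arrhenius form with Eyring prefactor", {
  r_e <- 2e-9
  em0 <- entrance_model(dG0 = 0, barrier_coupling = "none")
  kappa0 <- pc_constants$kB * 298 / pc_constants$h * r_e
  expect_equal(entrance_rate(em0, 0, r_e, 298), kappa0, tolerance = 1e-12)
  # one kB T more divides the rate by e
  em5 <- entrance_model(dG0 = 5, barrier_coupling = "none")
  em6 <- entrance_model(dG0 = 6, barrier_coupling = "none")
  expect_equal(entrance_rate(em5, 0, r_e, 298) /
                 entrance_rate(em6, 0, r_e, 298), exp(1), tolerance = 1e-12)
  # huge barrier: reflective limit
  em_big <- entrance_model(dG0 = 800, barrier_coupling = "none")
  expect_equal(entrance_rate(em_big, 0, r_e, 298), 0, tolerance = 1e-300)
  # barrier coupling lowers the barrier by phi at the entrance
  em_c <- entrance_model(dG0 = 5, barrier_coupling = "phi_at_entrance")
  expect_equal(entrance_rate(em_c, 2, r_e, 298) /
                 entrance_rate(em_c, 0, r_e, 298), exp(2), tolerance = 1e-12)
  # direct rate override
  expect_identical(entrance_rate(entrance_model(rate = 3e-4), 1, r_e, 298),
                   3e-4)
  expect_error(entrance_model(dG0 = -1), ">= 0")
  expect_error(entrance_model(s = 0.5), ">= 1")
})

test_that("entrance frequency and combination behave in the limiting cases", {
  C0 <- molarity_to_density(40e-6)
  r_e <- 2e-9
  expect_equal(entrance_frequency(1e-3, r_e, C0, 0),
               2 * pi * r_e^2 * 1e-3 * C0, tolerance = 1e-12)
  expect_identical(entrance_frequency(0, r_e, C0, 1), 0)
  expect_identical(entrance_frequency(Inf, r_e, C0, 0), Inf)
  # combination: harmonic sum of times
  cb <- combine_frequencies(100, 100)
  expect_equal(cb$f, 50, tolerance = 1e-14)
  cb2 <- combine_frequencies(100, Inf)
  expect_equal(cb2$f, 100, tolerance = 1e-14)
  expect_identical(cb2$regime, "transport_limited")
  cb3 <- combine_frequencies(100, 0)
  expect_identical(cb3$f, 0)
  expect_identical(cb3$regime, "entrance_limited")
  # identity 1/f = 1/f_a + 1/f_e at machine precision
  for (fe in c(0.01, 1, 1e4)) {
    cbx <- combine_frequencies(3097, fe)
    expect_equal(1 / cbx$f, 1 / 3097 + 1 / fe, tolerance = 1e-14)
    expect_equal(cbx$tau, cbx$tau_a + cbx$tau_e, tolerance = 1e-14)
  }
  # the observed tau ~ 1 s against tau_a = 3e-4 s is entrance-limited
  expect_identical(combine_frequencies(1 / 3e-4, 1 / 1)$regime,
                   "entrance_limited")
  expect_error(combine_frequencies(0, 1), "> 0")
  # f strictly increasing in k (through f_e)
  fa <- 5e4
  fs <- vapply(10^seq(-6, 2, by = 1), function(k) {
    combine_frequencies(fa, entrance_frequency(k, r_e, C0, 0.5))$f
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("capture frequency of a scenario equals the direct Robin solution (consistency anchor)", {
  C0 <- molarity_to_density(40e-6)
  r_e <- 2e-9
  D <- D_ref()
  grid <- expand.grid(a2 = c(-2e-19, 0, 2e-19), a3 = c(0, 1e-27),
                      k = c(1e-5, 1e-3, 1))
  for (i in seq_len(nrow(grid))) {
    pot <- effective_potential(grid$a2[i], grid$a3[i], D)
    f_a <- approach_frequency_quadrature(pot, C0, r_e)
    f_e <- entrance_frequency(grid$k[i], r_e, C0, phi_potential(r_e, pot))
    f_comb <- combine_frequencies(f_a, f_e)$f
    prof <- concentration_profile(pot, C0, r_e, grid$k[i],
                                  c(r_e, 3e-9, 1e-8))
    expect_equal(f_comb, attr(prof, "f"), tolerance = 1e-10,
                 label = sprintf("case %d f", i))
  }
})

test_that("concentration profile satisfies the stationary equation and boundary conditions", {
  C0 <- molarity_to_density(40e-6)
  r_e <- 2e-9
  D <- D_ref()
  pot <- effective_potential(1.5e-19, 8e-28, D)

  # classic perfectly absorbing, force-free profile: C0 (1 - r_e/r)
  pot0 <- effective_potential(0, 0, D)
  r <- c(2e-9, 4e-9, 1e-8, 1e-7)
  prof0 <- concentration_profile(pot0, C0, r_e, Inf, r)
  expect_equal(prof0$C, C0 * (1 - r_e / r), tolerance = 1e-8)

  # far field recovers the bulk concentration
  prof_far <- concentration_profile(pot, C0, r_e, 1e-3, 1e-4)
  expect_equal(prof_far$C, C0, tolerance = 1e-4)

  # reflecting pore: equilibrium Boltzmann-like profile, zero flux
  prof_eq <- concentration_profile(pot, C0, r_e, 0, r)
  expect_identical(attr(prof_eq, "A"), 0)
  expect_equal(prof_eq$C, C0 * exp(phi_potential(r, pot)), tolerance = 1e-10)

  # scaled ODE residual (r_e/C0)(C' - C phi') - (A/(C0 D)) / r^2 * r_e < 1e-8
  k <- 1e-3
  rr <- exp(seq(log(r_e * 1.01), log(3e-8), length.out = 12))
  prof <- concentration_profile(pot, C0, r_e, k, rr)
  A <- attr(prof, "A")
  for (i in seq_along(rr)) {
    h <- rr[i] * 1e-5
    Cpm <- concentration_profile(pot, C0, r_e, k,
                                 c(rr[i] - h, rr[i], rr[i] + h))$C
    dC <- (Cpm[3] - Cpm[1]) / (2 * h)
    lhs <- D * (dC - Cpm[2] * dphi_potential(rr[i], pot))
    rhs <- A / rr[i]^2
    resid_scaled <- (lhs - rhs) * r_e / (D * C0 / r_e)
    expect_lt(abs(resid_scaled), 1e-8,
              label = sprintf("ODE residual at r = %g", rr[i]))
  }
  # Robin boundary residual: D (C' - C phi')|_{r_e} = k C(r_e).
  # One-sided second-order differences with Richardson extrapolation
  # (the profile lives on r >= r_e only).
  kR <- 0.1
  h <- r_e * 1e-4
  Cb <- concentration_profile(pot, C0, r_e, kR,
                              c(r_e, r_e + h / 2, r_e + h, r_e + 2 * h))$C
  d_h <- (-3 * Cb[1] + 4 * Cb[3] - Cb[4]) / (2 * h)
  d_h2 <- (-3 * Cb[1] + 4 * Cb[2] - Cb[3]) / h
  dC <- (4 * d_h2 - d_h) / 3
  lhs <- D * (dC - Cb[1] * dphi_potential(r_e, pot))
  expect_lt(abs(lhs - kR * Cb[1]) / (kR * C0), 1e-8)
  # grid below r_e is rejected
  expect_error(concentration_profile(pot, C0, r_e, k, 1e-9), "r >= r_e")
})

test_that("voltage sweep is deterministic, tabular, and handles empty input", {
  sc <- make_scenario(q_e = 4, q_w = 0.012)
  sw1 <- voltage_sweep(sc, c(-0.1, 0, 0.1))
  sw2 <- voltage_sweep(sc, c(-0.1, 0, 0.1))
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  expect_s3_class(sw1, "tbl_df")
  expect_named(sw1, c("voltage", "a2", "a3", "f_a", "f_e", "f", "tau_a",
                      "tau_e", "tau", "regime", "b_eo_ep", "b_eo_di"))
  expect_equal(nrow(voltage_sweep(sc, numeric(0))), 0)
  # at zero voltage the drift vanishes and f_a is the diffusive value
  expect_equal(sw1$f_a[2],
               2 * pi * D_ref() * molarity_to_density(40e-6) * 2e-9,
               tolerance = 1e-10)
})

test_that("tidy and glance expose the capture result as tibbles", {
  res <- capture_frequency(make_scenario())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("f_a", "f_e", "f", "tau", "a2", "a3") %in% td$quantity))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$regime, res$regime)
  expect_equal(gl$f, res$f)
})
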