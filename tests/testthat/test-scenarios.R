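# Scenario schema, packaged fixtures, and the run layer.

test_that("every packaged fixture loads, validates and computes", {
  fixtures <- list_scenarios()
  expect_setequal(fixtures,
                  c("fig3a_ep_eo", "fig3b_dep_eo", "fig5a_barrier",
                    "fig5b_barrier", "asandei_peptide", "larkin_prok",
                    "larkin_rnase", "sv28_dumbbell"))
  for (fx in fixtures) {
    sc <- load_scenario(fx)
    expect_s3_class(sc, "pc_scenario")
    res <- capture_frequency(sc)
    expect_true(is.finite(res$f) && res$f >= 0, label = fx)
    expect_true(is.finite(res$f_a) && res$f_a > 0, label = fx)
  }
})

test_that("fixture parameters match their documented values", {
  sc <- load_scenario("fig3b_dep_eo")
  expect_identical(sc$particle$charge, 0)
  expect_equal(sc$particle$dipole, e_nm_to_SI(12), tolerance = 1e-12)
  sv <- load_scenario("sv28_dumbbell")
  expect_equal(sv$particle$dipole, e_nm_to_SI(8), tolerance = 1e-12)
  expect_equal(sv$entrance$dG0, 22)
  expect_equal(sv$entrance$s, 10)
  expect_equal(sv$pore$entrance_radius, 1e-9)
  expect_equal(sv$pore$conductance, 2e-9)
  expect_equal(sv$drive$concentration, molarity_to_density(50e-9),
               tolerance = 1e-12)
  la <- load_scenario("larkin_prok")
  expect_equal(la$pore$radius, 2.6e-9)
  expect_equal(la$pore$conductance, 20e-9)
  expect_equal(la$pore$eo_conductance, 15e-18)
  expect_equal(la$particle$charge, 3 * pc_constants$e, tolerance = 1e-12)
  as_ <- load_scenario("asandei_peptide")
  expect_identical(as_$particle$n_residues, 20L)
  expect_equal(as_$particle$charge, 8 * pc_constants$e, tolerance = 1e-12)
  expect_equal(as_$pore$eo_conductance, -1.6e-18)
})

test_that("schema violations are rejected with informative errors", {
  bad1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: x", "electrolyte: {conductivity: {value: 1, unit: 'S/m'},",
               "  debye_length: {value: 1, unit: 'nm'},",
               "  viscosity: {value: 1e-3, unit: 'Pa*s'},",
               "  frobnicate: 3}",
               "particle: {radius: {value: 1, unit: 'nm'}}",
               "pore: {radius: {value: 1, unit: 'nm'}, length: {value: 5, unit: 'nm'}}",
               "drive: {voltage: {value: 0.1, unit: 'V'}, concentration: {value: 1, unit: 'uM'}}"),
             bad1)
  expect_error(load_scenario(bad1), "frobnicate")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: x", "gizmo: 1",
               "electrolyte: {conductivity: {value: 1, unit: 'S/m'}}"),
             bad2)
  expect_error(load_scenario(bad2), "gizmo")
  bad3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: x",
               "electrolyte: {conductivity: {value: 1, unit: 'nm'},",
               "  debye_length: {value: 1, unit: 'nm'},",
               "  viscosity: {value: 1e-3, unit: 'Pa*s'}}",
               "particle: {radius: {value: 1, unit: 'nm'}}",
               "pore: {radius: {value: 1, unit: 'nm'}, length: {value: 5, unit: 'nm'}}",
               "drive: {voltage: {value: 0.1, unit: 'V'}, concentration: {value: 1, unit: 'uM'}}"),
             bad3)
  expect_error(load_scenario(bad3), "dimension")
  # missing mandatory section
  bad4 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("name: x", bad4)
  expect_error(load_scenario(bad4), "missing section")
  expect_error(load_scenario("no_such_fixture_xyz"), "no such scenario")
})

test_that("scenarios round-trip through normalized SI YAML", {
  sc <- load_scenario("sv28_dumbbell")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- load_scenario(path)
  p1 <- scenario_parameters(sc)
  p2 <- scenario_parameters(sc2)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
  # and the computed physics is identical
  expect_equal(glance(capture_frequency(sc))$f,
               glance(capture_frequency(sc2))$f, tolerance = 1e-12)
})

test_that("the resolved parameter log is complete enough to re-run", {
  sc <- load_scenario("fig3a_ep_eo")
  pars <- scenario_parameters(sc)
  expect_true(all(c("conductivity", "mobility", "diffusion", "conductance",
                    "eo_conductance", "voltage", "concentration") %in%
                    pars$parameter))
  # rebuild from the logged SI values and compare
  el <- electrolyte(pars$value[pars$parameter == "conductivity"],
                    pars$value[pars$parameter == "debye_length"],
                    viscosity = pars$value[pars$parameter == "viscosity"],
                    temperature = pars$value[pars$parameter == "temperature"])
  pa <- particle(pars$value[pars$parameter == "particle_radius"],
                 charge = pars$value[pars$parameter == "particle_charge"],
                 dipole = pars$value[pars$parameter == "particle_dipole"])
  po <- pore(pars$value[pars$parameter == "pore_radius"],
             pars$value[pars$parameter == "pore_length"],
             surface_charge = pars$value[pars$parameter == "surface_charge"])
  dr <- drive_conditions(pars$value[pars$parameter == "voltage"],
                         pars$value[pars$parameter == "concentration"])
  sc2 <- scenario(el, pa, po, dr, name = "rebuilt")
  expect_equal(capture_frequency(sc2)$f, capture_frequency(sc)$f,
               tolerance = 1e-12)
})

test_that("the peptide-against-electrophoresis scenario is entrance limited with dominant electroosmosis", {
  res <- run_compute("asandei_peptide")
  expect_identical(res$regime, "entrance_limited")
  expect_gt(res$tau_e / res$tau_a, 100)
  # electroosmosis dominates electrophoresis in magnitude
  sc <- load_scenario("asandei_peptide")
  b <- b_eo_ep(sc$particle, sc$pore, sc$electrolyte, closed_form = FALSE)
  expect_gt(b, 1)
})

test_that("the dipolar dumbbell scenario captures at both polarities", {
  sc <- load_scenario("sv28_dumbbell")
  for (v in c(-0.1, 0.1)) {
    sc$drive$voltage <- v
    res <- capture_frequency(sc)
    expect_gt(res$f, 0)
  }
})

test_that("run_* write deterministic artifacts", {
  out <- withr::local_tempdir()
  res <- run_compute("fig3a_ep_eo", out_dir = out)
  expect_true(file.exists(file.path(out, "result.json")))
  expect_true(file.exists(file.path(out, "parameters.csv")))
  expect_true(file.exists(file.path(out, "run.log")))
  js <- jsonlite::read_json(file.path(out, "result.json"))
  expect_equal(js$f, res$f, tolerance = 1e-12)
  sw <- run_sweep("fig3a_ep_eo", c(-0.1, 0.1), out_dir = out)
  tab <- utils::read.csv(file.path(out, "sweep.csv"))
  expect_equal(tab$f, sw$f, tolerance = 1e-12)
  prof <- run_profile("fig3a_ep_eo", out_dir = out)
  expect_true(file.exists(file.path(out, "profile.csv")))
  expect_gt(nrow(prof), 100)
})

test_that("the command-line wrapper computes a fixture end to end", {
  cli <- system.file("cli", "porecapture", package = "porecapture")
  expect_true(nzchar(cli))
  out <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  status <- system2(rscript, c(cli, "compute", "fig3b_dep_eo",
                               "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "result.json")))
  # config errors exit nonzero
  bad <- system2(rscript, c(cli, "compute", "no_such_fixture_xyz",
                            "--out", out), stdout = NULL, stderr = NULL)
  expect_true(bad != 0)
})

test_that("plot methods return ggplot objects", {
  sw <- voltage_sweep(load_scenario("fig3b_dep_eo"),
                      seq(-0.15, 0.15, by = 0.05))
  expect_s3_class(autoplot(sw), "ggplot")
  tr <- synth_trace(0.2, 2, duration = 60, sampling_rate = 20, seed = 4)
  ev <- detect_events(tr, min_duration = 0.2)
  expect_s3_class(autoplot(tr, events = ev), "ggplot")
  prof <- run_profile("fig3a_ep_eo")
  expect_s3_class(autoplot(prof), "ggplot")
})
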