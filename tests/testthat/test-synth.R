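test_that("library generation is byte-deterministic per seed", {
  m <- default_dvl1_model()
  sp <- library_spec(n_molecules = 8, n_conformers = 3, frac_active = 0.5,
                     seed = 42)
  f1 <- withr::local_tempfile(fileext = ".sdf")
  f2 <- withr::local_tempfile(fileext = ".sdf")
  g1 <- generate_library(sp, m, f1)
  g2 <- generate_library(sp, m, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g1$truth, g2$truth)
  sp2 <- library_spec(n_molecules = 8, n_conformers = 3, frac_active = 0.5,
                      seed = 43)
  f3 <- withr::local_tempfile(fileext = ".sdf")
  generate_library(sp2, m, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("every decoy mode fails screening for its recorded reason", {
  m <- default_dvl1_model()
  req_id <- m$queries$id[m$queries$required]
  modes <- c("missing_required", "too_few_features",
             "displaced_beyond_tolerance", "kind_mismatch")
  for (mode in modes) {
    sdf <- withr::local_tempfile(fileext = ".sdf")
    g <- generate_library(
      library_spec(n_molecules = 6, n_conformers = 2, frac_active = 0,
                   seed = 17, decoy_modes = mode), m, sdf)
    expect_true(all(g$truth$decoy_mode == mode))
    for (mol in Filter(function(x) x$conf_id == 0L, read_sdf_library(sdf))) {
      r <- match_pose(perceive_features(mol), m)
      expect_false(r$accepted)
      if (mode == "missing_required") {
        expect_gte(r$n_matched, m$min_match)  # fails only the must-have
        expect_false(req_id %in% r$assignment$query_id)
      } else if (mode == "too_few_features") {
        expect_equal(r$n_matched, m$min_match - 1L)
        expect_true(req_id %in% r$assignment$query_id)
      } else {
        expect_equal(r$n_matched, 0L)
      }
    }
  }
})

test_that("actives are guaranteed acceptable at zero and nonzero jitter", {
  m <- default_dvl1_model()
  for (js in c(0, 0.3)) {
    sdf <- withr::local_tempfile(fileext = ".sdf")
    g <- generate_library(
      library_spec(n_molecules = 10, n_conformers = 2, frac_active = 1,
                   seed = 23, jitter_sd = js), m, sdf)
    rec <- screen_library(sdf, m, screen_config(n_conformers_expected = 2))
    expect_true(all(rec$accepted))
  }
  expect_error(
    generate_library(library_spec(n_molecules = 2, jitter_sd = 1.2),
                     m, tempfile()),
    "too large")
})

test_that("zero-noise generated curves satisfy their equations pointwise", {
  cc <- seq(2, 38, length.out = 10)
  bc <- generate_binding_curve(Kd = 11.5, concentrations = cc)
  expect_equal(bc$signal, cc / (11.5 + cc), tolerance = 1e-12)
  # competitive shift moves half-saturation right of Kd
  bc_i <- generate_binding_curve(Kd = 11.5, Ki = 0.5, inhibitor_conc = 5,
                                 concentrations = cc)
  expect_true(all(bc_i$signal < bc$signal))
  kd_app <- apparent_kd(11.5, 0.5, 5)
  expect_equal(bc_i$signal, cc / (kd_app + cc), tolerance = 1e-12)
  d <- exp(seq(log(0.01 * 0.74), log(100 * 0.74), length.out = 8))
  dr <- generate_dose_response(EC50 = 0.74, doses = d)
  expect_equal(dr$response, 100 / (1 + d / 0.74), tolerance = 1e-10)
  # doses far below EC50 sit at the top plateau
  low <- generate_dose_response(EC50 = 50, doses = c(1e-4, 2e-4, 5e-4,
                                                     1e-3, 2e-3))
  expect_true(all(low$response > 99.99))
})

test_that("curve generators are seed-deterministic", {
  b1 <- generate_binding_curve(11.5, noise_sd_frac = 0.02, seed = 31)
  b2 <- generate_binding_curve(11.5, noise_sd_frac = 0.02, seed = 31)
  b3 <- generate_binding_curve(11.5, noise_sd_frac = 0.02, seed = 32)
  expect_identical(b1$signal, b2$signal)
  expect_false(identical(b1$signal, b3$signal))
  d1 <- generate_dose_response(0.49, noise_sd_frac = 0.02, seed = 31)
  d2 <- generate_dose_response(0.49, noise_sd_frac = 0.02, seed = 31)
  expect_identical(d1$response, d2$response)
})

test_that("frac_active = 0 yields no accepted molecules downstream", {
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(library_spec(n_molecules = 8, n_conformers = 2,
                                frac_active = 0, seed = 2), m, sdf)
  rec <- screen_library(sdf, m, screen_config(n_conformers_expected = 2))
  expect_equal(sum(rec$accepted), 0L)
  expect_equal(nrow(shortlist(rec, 500)), 0L)
})

test_that("SDF round-trip preserves structure and identity", {
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(library_spec(n_molecules = 4, n_conformers = 2,
                                frac_active = 0.5, seed = 11), m, sdf)
  mols <- read_sdf_library(sdf)
  expect_length(mols, 8L)
  out <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_library(mols, out)
  back <- read_sdf_library(out)
  for (k in seq_along(mols)) {
    expect_equal(back[[k]]$mol_id, mols[[k]]$mol_id)
    expect_equal(back[[k]]$conf_id, mols[[k]]$conf_id)
    expect_equal(back[[k]]$atoms, mols[[k]]$atoms)
    expect_equal(back[[k]]$bonds, mols[[k]]$bonds)
    expect_equal(back[[k]]$coords, mols[[k]]$coords, tolerance = 1e-3)
  }
})
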