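test_that("a planted library screens to exactly its ground truth", {
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  g <- generate_library(library_spec(n_molecules = 20, n_conformers = 5,
                                     frac_active = 0.25, seed = 7),
                        m, sdf)
  rec <- screen_library(sdf, m, screen_config(n_conformers_expected = 5))
  expect_s3_class(rec, "screen_records")
  cmp <- merge(as.data.frame(rec), g$truth, by = "mol_id")
  expect_equal(nrow(cmp), 20L)
  expect_identical(cmp$accepted, cmp$is_active)
  expect_equal(sum(rec$accepted), 5L)
  # the planted conformer wins for every active
  act <- cmp[cmp$is_active, ]
  expect_equal(act$best_conf_id, act$planted_conf_id)
  s <- attr(rec, "summary")
  expect_equal(s$n_molecules, 20L)
  expect_equal(s$n_conformers, 100L)
  expect_equal(s$n_accepted, 5L)
})

test_that("a perfect conformer among displaced ones is selected with full fitness", {
  m <- default_dvl1_model()
  f <- perfect_features(m)
  mols <- lapply(0:9, function(k) {
    frags <- lapply(seq_len(nrow(f)), function(i) {
      pharmscreen:::fragment_for(f$kind[i],
                                 as.numeric(f[i, c("x", "y", "z")]),
                                 diag(3))
    })
    mol <- pharmscreen:::assemble_molecule("probe", k, frags)
    if (k != 3L) mol$coords <- sweep(mol$coords, 2, -c(25, 0, 0))
    mol
  })
  rec <- screen_library(mols, m, screen_config())
  expect_equal(rec$best_conf_id, 3L)
  expect_equal(rec$fitness, 7.0, tolerance = 1e-9)
  expect_true(rec$accepted)
})

test_that("ranking is dense over accepted molecules and capped by top_n", {
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(library_spec(n_molecules = 24, n_conformers = 2,
                                frac_active = 0.5, seed = 31), m, sdf)
  rec <- screen_library(sdf, m, screen_config(n_conformers_expected = 2,
                                              top_n = 4))
  expect_equal(sum(!is.na(rec$rank)), 4L)
  expect_equal(sort(rec$rank[!is.na(rec$rank)]), 1:4)
  ranked <- rec[!is.na(rec$rank), ]
  expect_true(all(diff(ranked$fitness[order(ranked$rank)]) <= 0))
  expect_true(all(ranked$accepted))
  # shortlist caps at the accepted count, not top_n
  sl <- shortlist(rec, top_n = 500)
  expect_equal(nrow(sl), sum(rec$accepted))
  expect_true(all(diff(sl$fitness) <= 0))
  expect_equal(nrow(shortlist(rec, top_n = 1)), 1L)
  expect_equal(sl$mol_id[1], rec$mol_id[which.max(rec$fitness)])
  expect_error(shortlist(rec, top_n = 0), "top_n")
  # zero accepted -> empty shortlist
  none <- rec[!rec$accepted, ]
  expect_equal(nrow(shortlist(none, 10)), 0L)
})

test_that("shuffling the library leaves records and shortlist unchanged", {
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(library_spec(n_molecules = 12, n_conformers = 3,
                                frac_active = 0.5, seed = 13), m, sdf)
  mols <- read_sdf_library(sdf)
  cfg <- screen_config(n_conformers_expected = 3, top_n = 3)
  rec1 <- screen_library(mols, m, cfg)
  set.seed(99)
  rec2 <- screen_library(sample(mols), m, cfg)
  expect_equal(as.data.frame(rec1), as.data.frame(rec2))
})

test_that("shortlisted molecules independently satisfy the acceptance rule", {
  # re-check n_matched >= min_match and required-query membership without
  # trusting the accepted flag
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(library_spec(n_molecules = 16, n_conformers = 3,
                                frac_active = 0.5, seed = 5), m, sdf)
  mols <- read_sdf_library(sdf)
  rec <- screen_library(mols, m, screen_config(n_conformers_expected = 3))
  req_id <- m$queries$id[m$queries$required]
  for (i in which(!is.na(rec$rank))) {
    mol <- Filter(function(x) x$mol_id == rec$mol_id[i] &&
                    x$conf_id == rec$best_conf_id[i], mols)[[1]]
    r <- match_pose(perceive_features(mol), m)
    expect_gte(r$n_matched, m$min_match)
    expect_true(all(req_id %in% r$assignment$query_id))
  }
})

test_that("under-populated molecules are screened with a warning", {
  m <- default_dvl1_model()
  sdf <- withr::local_tempfile(fileext = ".sdf")
  generate_library(library_spec(n_molecules = 4, n_conformers = 2,
                                frac_active = 0.5, seed = 3), m, sdf)
  expect_warning(
    rec <- screen_library(sdf, m, screen_config(n_conformers_expected = 10)),
    "fewer than 10")
  expect_equal(nrow(rec), 4L)
  expect_error(screen_library(list(), m, screen_config()), "no conformers")
})
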