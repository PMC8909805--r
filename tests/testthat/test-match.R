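test_that("Kabsch superposition recovers exact rigid relations", {
  set.seed(11)
  P <- matrix(rnorm(15), 5, 3)
  # identity case
  s <- kabsch_superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  # exact rigid relation: 90 degrees about z plus translation
  R90 <- rotation_z(pi / 2)
  Q <- sweep(P %*% t(R90), 2, -c(1, 2, 3))
  s2 <- kabsch_superpose(P, Q)
  expect_lt(s2$rmsd, 1e-9)
  expect_equal(s2$rotation, R90, tolerance = 1e-9)
  expect_equal(s2$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch on mismatched segments gives the closed-form residual", {
  # 1-D closed form: optimal translation centers both segments, residuals
  # are +/-1 on the two points, so rmsd = 1
  P <- rbind(c(0, 0, 0), c(2, 0, 0))
  Q <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(kabsch_superpose(P, Q)$rmsd, 1.0, tolerance = 1e-9)
  expect_error(kabsch_superpose(P, Q[1, , drop = FALSE]), "equal size")
  expect_error(kabsch_superpose(matrix(numeric(), ncol = 3),
                                matrix(numeric(), ncol = 3)), "non-empty")
})

test_that("a perfect pose matches all queries with zero residual", {
  m <- default_dvl1_model()
  r <- match_pose(perfect_features(m), m)
  expect_equal(r$n_matched, 7L)
  expect_equal(r$rmsd_matched, 0, tolerance = 1e-12)
  expect_equal(r$fitness, 7.0, tolerance = 1e-12)
  expect_true(r$accepted)
})

test_that("the must-have query vetoes acceptance regardless of count", {
  m <- default_dvl1_model()
  f <- perfect_features(m)
  req_id <- m$queries$id[m$queries$required]
  f_missing <- f[-which(m$queries$required), ]
  r <- match_pose(f_missing, m)
  expect_equal(r$n_matched, 6L)
  expect_false(r$accepted)
  expect_false(req_id %in% r$assignment$query_id)
})

test_that("tolerance spheres discriminate polar from hydrophobic offsets", {
  # one donor query and one hydrophobic query, a feature 2.2 A from each:
  # 2.2 > 2.0 rejects the donor pair, 2.2 <= 2.5 keeps the hydrophobic one
  m <- pharmacophore_model(
    "tol", data.frame(id = c("d", "h"), kind = c("donor", "hydrophobic"),
                      x = c(0, 10), y = 0, z = 0), min_match = 1)
  f <- data.frame(kind = c("donor", "hydrophobic"),
                  x = c(2.2, 12.2), y = 0, z = 0)
  r <- match_pose(f, m)
  expect_equal(r$assignment$query_id, "h")
  expect_equal(r$n_matched, 1L)
})

test_that("matcher agrees with the brute-force assignment oracle", {
  set.seed(303)
  for (k in 1:60) {
    inst <- random_instance(nq = sample(2:5, 1), nf = sample(2:7, 1))
    r <- match_pose(inst$features, inst$model)
    expect_equal(r$n_matched, oracle_max_matched(inst$features, inst$model))
    expect_identical(r$accepted, r$n_matched >= inst$model$min_match)
  }
})

test_that("fitness follows the normalized-residual form and its orderings", {
  # 5 matches each at exactly half tolerance: 5 - 0.5 = 4.5
  m <- pharmacophore_model(
    "five", data.frame(id = paste0("q", 1:5), kind = "aromatic",
                       x = seq(0, 40, 10), y = 0, z = 0), min_match = 5)
  f <- data.frame(kind = "aromatic", x = seq(0, 40, 10) + 1.25, y = 0, z = 0)
  r <- match_pose(f, m)
  expect_equal(r$n_matched, 5L)
  expect_equal(r$fitness, 4.5, tolerance = 1e-12)
  # any 6-match outscores any 5-match: bounds (n-1, n]
  m6 <- pharmacophore_model(
    "six", data.frame(id = paste0("q", 1:6), kind = "aromatic",
                      x = seq(0, 50, 10), y = 0, z = 0), min_match = 5)
  worst6 <- data.frame(kind = "aromatic", x = seq(0, 50, 10) + 2.49,
                       y = 0, z = 0)
  best5 <- data.frame(kind = "aromatic", x = seq(0, 40, 10), y = 0, z = 0)
  expect_gt(match_pose(worst6, m6)$fitness, match_pose(best5, m6)$fitness)
})

test_that("enlarging tolerances never decreases the match count", {
  set.seed(77)
  for (k in 1:20) {
    inst <- random_instance(nq = 4, nf = 6)
    r1 <- match_pose(inst$features, inst$model)
    grown <- inst$model
    grown$queries$tolerance <- grown$queries$tolerance + runif(4, 0, 2)
    r2 <- match_pose(inst$features, grown)
    expect_gte(r2$n_matched, r1$n_matched)
  }
})

test_that("acceptance is monotone in the min_match threshold", {
  # a pose accepted at min_match = 5 is accepted at min_match = 4
  m <- default_dvl1_model()
  f <- perfect_features(m)[1:5, ]  # required query is among the first 5
  m5 <- m; m5$min_match <- 5L
  m4 <- m; m4$min_match <- 4L
  expect_true(match_pose(f, m5)$accepted)
  expect_true(match_pose(f, m4)$accepted)
  # and the implication holds across random instances
  set.seed(88)
  for (k in 1:20) {
    inst <- random_instance(nq = 5, nf = 6)
    mm5 <- inst$model; mm5$min_match <- 5L
    mm4 <- inst$model; mm4$min_match <- 4L
    acc5 <- match_pose(inst$features, mm5)$accepted
    acc4 <- match_pose(inst$features, mm4)$accepted
    expect_true(!acc5 || acc4)
  }
})

test_that("align-mode results are invariant under rigid transforms of the pose", {
  m <- pharmacophore_model(
    "ali", data.frame(id = c("a1", "a2", "h1", "d1"),
                      kind = c("aromatic", "aromatic", "hydrophobic",
                               "donor"),
                      x = c(0, 6, 3, -3), y = c(0, 0, 5, 4),
                      z = c(0, 0, 2, 1)), min_match = 3)
  f <- data.frame(kind = c("aromatic", "aromatic", "hydrophobic", "donor"),
                  x = c(0.3, 6.2, 3.1, -2.8), y = c(0.2, -0.3, 5.4, 3.9),
                  z = c(0.1, 0.2, 1.8, 1.2))
  base <- match_pose(f, m, mode = "align")
  expect_equal(base$n_matched, 4L)
  set.seed(5)
  for (k in 1:3) {
    R <- random_rotation_matrix()
    tr <- rnorm(3, 0, 15)
    fx <- sweep(as.matrix(f[, c("x", "y", "z")]) %*% t(R), 2, -tr)
    f2 <- data.frame(kind = f$kind, x = fx[, 1], y = fx[, 2], z = fx[, 3])
    r <- match_pose(f2, m, mode = "align")
    expect_equal(r$n_matched, base$n_matched)
    expect_equal(r$fitness, base$fitness, tolerance = 1e-6)
  }
  # prealigned fitness is frame-dependent: the same moved pose scores lower
  fx <- sweep(as.matrix(f[, c("x", "y", "z")]), 2, -c(30, 0, 0))
  f3 <- data.frame(kind = f$kind, x = fx[, 1], y = fx[, 2], z = fx[, 3])
  expect_lt(match_pose(f3, m, mode = "prealigned")$fitness, base$fitness)
})

test_that("featureless poses and empty models are handled explicitly", {
  m <- default_dvl1_model()
  r <- match_pose(data.frame(kind = character(), x = numeric(),
                             y = numeric(), z = numeric()), m)
  expect_equal(r$n_matched, 0L)
  expect_equal(r$fitness, 0)
  expect_false(r$accepted)
  expect_error(
    pharmacophore_model("empty",
                        data.frame(id = character(), kind = character(),
                                   x = numeric(), y = numeric(),
                                   z = numeric()), 1),
    "zero queries")
})
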