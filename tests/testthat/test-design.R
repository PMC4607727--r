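test_that("first-level design holds raw powers of centred age in subject blocks", {
  # one subject, one scan at the reference age
  d1 <- traj_data(make_scans(list(50), list(1)), ref_age = 50)
  X1 <- suppressWarnings(build_first_level_design(d1, traj_spec(1)))
  expect_equal(as.matrix(X1), matrix(c(1, 0), 1, 2), ignore_attr = TRUE)

  # two subjects at centred ages -1, +1: exact block-diagonal form
  d2 <- traj_data(make_scans(list(c(49, 51), c(49, 51)), list(c(1, 1), c(2, 2))),
                  ref_age = 50)
  X1 <- build_first_level_design(d2, traj_spec(1))
  blk <- matrix(c(1, -1, 1, 1), 2, 2, byrow = TRUE)
  expected <- rbind(cbind(blk, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), blk))
  expect_equal(as.matrix(X1), expected, ignore_attr = TRUE)

  # quadratic powers
  d3 <- traj_data(make_scans(list(52), list(1)), ref_age = 50)
  X1 <- suppressWarnings(build_first_level_design(d3, traj_spec(2)))
  expect_equal(as.matrix(X1), matrix(c(1, 2, 4), 1, 3), ignore_attr = TRUE)
})

test_that("cross-subject entries of the random-effect block are exactly zero", {
  sim <- simulate_ensemble(sim_config(n_subjects = 7, n_scans = 3, seed = 1,
                                      design = "unbalanced"))
  X1 <- as.matrix(build_first_level_design(sim, traj_spec(1)))
  si <- sim$scans$subject_index
  for (i in seq_len(sim$n_subjects)) {
    cols <- (i - 1) * 2 + 1:2
    expect_true(all(X1[si != i, cols] == 0))
  }
})

test_that("second-level design takes the Kronecker and multi-group block forms", {
  # N=2, no covariates, D=1, one group: [1_N] x I_2 stacked
  d <- traj_data(make_scans(list(c(49, 51), c(49, 51)), list(c(1, 1), c(2, 2))),
                 ref_age = 50)
  X2 <- build_second_level_design(d, traj_spec(1))
  expect_equal(as.matrix(X2), rbind(diag(2), diag(2)), ignore_attr = TRUE)

  # one centred covariate z = (-1, 1), D=0
  sc <- make_scans(list(c(49, 51), c(49, 51)), list(c(1, 1), c(2, 2)))
  sc$z <- rep(c(-1, 1), each = 2)
  dz <- traj_data(sc, covariates = "z", ref_age = 50)
  X2 <- build_second_level_design(dz, traj_spec(0))
  expect_equal(as.matrix(X2), matrix(c(1, -1, 1, 1), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)

  # two groups of one subject each, D=0: per-group ones columns
  dg <- traj_data(make_scans(list(50, 50), list(1, 2), groups = c("a", "b")),
                  group = "group", ref_age = 50)
  X2 <- build_second_level_design(dg, traj_spec(0))
  expect_equal(as.matrix(X2), diag(2), ignore_attr = TRUE)
})

test_that("covariance bases select one coefficient per group and partition the slots", {
  d <- traj_data(make_scans(list(c(49, 51), c(49, 51)), list(c(1, 1), c(2, 2))),
                 ref_age = 50)
  b <- build_covariance_bases(traj_spec(1), d)
  expect_equal(b$first_level$indices, 1:4)  # I_M on the data rows
  expect_equal(length(b$second_level), 2)
  expect_equal(b$second_level[[1]]$indices, c(1, 3))  # diag(1,0,1,0)
  expect_equal(b$second_level[[2]]$indices, c(2, 4))  # diag(0,1,0,1)
  expect_equal(b$n_hyper, 3)

  # two groups, D=1: G(D+1) = 4 second-level bases, 5 hyperparameters
  dg <- traj_data(make_scans(list(50, 50, 50), list(1, 2, 3),
                             groups = c("a", "a", "b")),
                  group = "group", ref_age = 50)
  bg <- build_covariance_bases(traj_spec(1), dg)
  expect_equal(length(bg$second_level), 4)
  expect_equal(bg$n_hyper, 5)

  # partition property over a range of specs
  for (spec in list(traj_spec(0), traj_spec(1), traj_spec(2))) {
    sim <- simulate_ensemble(sim_config(
      n_subjects = 6, n_scans = 4, seed = 2,
      mean_params = rep(1, spec$degree + 1),
      var_params = rep(1e-3, spec$degree + 1)))
    bb <- build_covariance_bases(spec, sim)
    all_idx <- sort(unlist(lapply(bb$second_level, `[[`, "indices")))
    expect_equal(all_idx, seq_len(sim$n_subjects * (spec$degree + 1)))
  }
})

test_that("augmentation stacks data, zero and prior rows exactly", {
  # minimal model: N=1, m=1, D=0 -> Xbar rows [X1, X1X2], [I, 0], [0, I]
  d <- traj_data(make_scans(list(50), list(5)), ref_age = 50)
  design <- build_design(d, traj_spec(0))
  aug <- augment_system(design, data = d)
  expect_equal(as.matrix(aug$Xbar),
               rbind(c(1, 1), c(1, 0), c(0, 1)), ignore_attr = TRUE)
  expect_equal(aug$ybar, c(5, 0, 0))

  # row count is always M + P1 + P2
  sim <- simulate_ensemble(sim_config(n_subjects = 5, n_scans = 3, seed = 3))
  for (spec in list(traj_spec(0), traj_spec(1), traj_spec(1, 2))) {
    design <- build_design(sim, spec)
    aug <- augment_system(design, data = sim)
    expect_equal(nrow(aug$Xbar),
                 design$dims$M + design$dims$P1 + design$dims$P2)
    expect_equal(length(aug$ybar), nrow(aug$Xbar))
  }
})

test_that("design dimensions follow the fixed/random degree bookkeeping", {
  sim <- simulate_ensemble(sim_config(n_subjects = 8, n_scans = 4, seed = 4))
  design <- build_design(sim, traj_spec(1, fixed_degree = 2))
  expect_equal(design$dims$P1, 8 * 2 + 1)
  expect_equal(design$dims$P2, 2 + 1)
  expect_equal(design$bases$clamped, 8 * 2 + 1)
  expect_equal(design$bases$n_hyper, 3)  # fixed slot is clamped, not free
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(traj_spec(1, fixed_degree = 0), "fixed_degree")
  sc <- make_scans(list(c(49, NA)), list(c(1, 2)))
  expect_error(traj_data(sc), "non-finite age")
  d <- traj_data(make_scans(list(c(49, 51)), list(c(1, 2))), ref_age = 50)
  # uncentered covariates rejected when bypassing the constructor
  d2 <- d
  d2$covariate_names <- "z"
  d2$Z <- matrix(c(1, 2), 1)  # wrong on purpose
  sc2 <- make_scans(list(c(49, 51), c(49, 51)), list(c(1, 2), c(2, 3)))
  sc2$z <- c(5, 5, 7, 7)
  dz <- traj_data(sc2, covariates = "z")
  dz$Z <- dz$Z + 1  # uncentre behind the constructor's back
  expect_error(build_second_level_design(dz, traj_spec(1)), "centred|centre")
  # dimension mismatch names both shapes
  design <- build_design(d, traj_spec(1))
  expect_error(augment_system(design, y = c(1, 2, 3)), "3.*2|does not match")
})

test_that("subjects with fewer scans than coefficients are accepted with a warning", {
  sc <- make_scans(list(50, c(49, 51)), list(3, c(1, 2)))
  d <- traj_data(sc, ref_age = 50)
  expect_warning(build_first_level_design(d, traj_spec(1)), "fewer than")
  fit <- suppressWarnings(fit_trajectories(d, traj_spec(1)))
  expect_s3_class(fit, "traj_fit")
})

test_that("noise-free data is reproduced exactly by the first-level design", {
  sim <- simulate_ensemble(sim_config(n_subjects = 6, n_scans = 4,
                                      noise_sd = 0, seed = 5,
                                      design = "unbalanced"))
  truth <- attr(sim, "truth")
  X1 <- build_first_level_design(sim, traj_spec(1))
  theta1_vec <- as.vector(t(truth$theta1))
  n_random <- attr(X1, "n_random")
  recon <- as.numeric(X1[, seq_len(n_random)] %*% theta1_vec)
  expect_equal(recon, sim$scans$value, tolerance = 1e-12)
})

test_that("design construction is invariant to subject relabeling", {
  sc <- make_scans(list(c(48, 50), c(49, 51, 53), c(50, 52)),
                   list(c(1, 1.1), c(2, 2.1, 2.2), c(3, 3.1)))
  d <- traj_data(sc, ref_age = 50.5)
  perm <- c(3, 1, 2)
  sc_perm <- do.call(rbind, lapply(perm, function(i) sc[sc$subject == paste0("s", i), ]))
  d_perm <- traj_data(sc_perm, ref_age = 50.5)

  # X1 blocks of the permuted data are the original subject blocks
  X1 <- as.matrix(build_first_level_design(d, traj_spec(1)))
  X1p <- as.matrix(build_first_level_design(d_perm, traj_spec(1)))
  rows_of <- function(data, i) which(data$scans$subject_index == i)
  for (j in seq_along(perm)) {
    expect_equal(X1p[rows_of(d_perm, j), (j - 1) * 2 + 1:2],
                 X1[rows_of(d, perm[j]), (perm[j] - 1) * 2 + 1:2],
                 ignore_attr = TRUE)
  }

  # posterior and evidence at fixed hyperparameters are exactly invariant
  lam <- c(-9, -4, -8)
  f1 <- fit_trajectories(d, traj_spec(1), lambda = lam)
  f2 <- fit_trajectories(d_perm, traj_spec(1), lambda = lam)
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-10)
  expect_equal(f1$posterior$theta2, f2$posterior$theta2, tolerance = 1e-9)
})
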