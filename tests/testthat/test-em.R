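test_that("flat-prior E-step reduces to the sample mean for a single intercept", {
  d <- traj_data(make_scans(list(c(49, 51)), list(c(2, 4))), ref_age = 50)
  design <- build_design(d, traj_spec(0))
  aug <- augment_system(design, data = d)
  for (lam in list(c(-2, -1), c(0, 0), c(-5, 2))) {
    post <- e_step(aug, lam)
    theta2 <- post$eta[aug$dims$P1 + 1]
    expect_equal(theta2, 3, tolerance = 1e-6)
  }
})

test_that("zero-noise limit interpolates the observations", {
  d <- traj_data(make_scans(list(c(49, 51)), list(c(1.0, 1.4))), ref_age = 50)
  design <- build_design(d, traj_spec(1))
  aug <- augment_system(design, data = d)
  post <- e_step(aug, c(-30, 0, 0))
  fitted <- as.numeric(aug$Xbar[1:2, ] %*% post$eta)
  expect_lt(max(abs(fitted - c(1.0, 1.4))), 1e-6)
})

test_that("E-step matches the dense Gauss-Markov oracle", {
  set.seed(101)
  sim <- simulate_ensemble(sim_config(n_subjects = 4, n_scans = 3, seed = 6,
                                      design = "unbalanced"))
  for (spec in list(traj_spec(1), traj_spec(1, fixed_degree = 2))) {
    design <- build_design(sim, spec)
    aug <- augment_system(design, data = sim)
    lam <- c(-8, -3, -7)
    post <- e_step(aug, lam)
    oracle <- dense_posterior_oracle(aug, lam)
    expect_equal(post$eta, oracle$eta, tolerance = 1e-8)
    expect_equal(post$C, oracle$C, tolerance = 1e-8)
  }
})

test_that("free energy equals the closed-form Gaussian log marginal under a proper prior", {
  sim <- simulate_ensemble(sim_config(n_subjects = 2, n_scans = 2, seed = 7))
  design <- build_design(sim, traj_spec(0))
  prior <- traj_prior(mean = 1, variance = 0.5)
  aug <- augment_system(design, data = sim, prior = prior)
  lam <- c(-9, -4)
  F <- free_energy(aug, lam)
  F_or <- closed_form_marginal_oracle(design, aug, sim$scans$value, lam,
                                      prior_mean = 1, prior_var = 0.5)
  expect_equal(F, F_or, tolerance = 1e-8)

  # also with fixed effects and a larger model
  sim2 <- simulate_ensemble(sim_config(n_subjects = 5, n_scans = 3, seed = 8))
  design2 <- build_design(sim2, traj_spec(1, fixed_degree = 2))
  aug2 <- augment_system(design2, data = sim2, prior = traj_prior(0, 2))
  lam2 <- c(-8, -3, -6)
  expect_equal(free_energy(aug2, lam2),
               closed_form_marginal_oracle(design2, aug2, sim2$scans$value,
                                           lam2, 0, 2),
               tolerance = 1e-8)
})

test_that("free energy is invariant under subject relabeling", {
  sim <- simulate_ensemble(sim_config(n_subjects = 5, n_scans = 3, seed = 9,
                                      design = "unbalanced"))
  sc <- as.data.frame(sim$scans[, c("subject", "age", "value")])
  perm <- sample(unique(sc$subject))
  sc_perm <- do.call(rbind, lapply(perm, function(s) sc[sc$subject == s, ]))
  f1 <- fit_trajectories(traj_data(sc, ref_age = sim$ref_age), traj_spec(1),
                         lambda = c(-9, -4, -8))
  f2 <- fit_trajectories(traj_data(sc_perm, ref_age = sim$ref_age),
                         traj_spec(1), lambda = c(-9, -4, -8))
  expect_equal(f1$free_energy, f2$free_energy, tolerance = 1e-10)
})

test_that("moving the noise variance off its optimum lowers the free energy", {
  sim <- simulate_ensemble(sim_config(n_subjects = 30, seed = 10))
  fit <- fit_trajectories(sim)
  design <- fit$design
  aug <- fit$aug
  F_opt <- fit$free_energy
  for (shift in c(log(2), -log(2))) {
    lam <- fit$lambda
    lam[1] <- lam[1] + shift
    expect_lt(free_energy(aug, lam), F_opt)
  }
})

test_that("analytic gradients match central finite differences of the free energy", {
  sim <- simulate_ensemble(sim_config(n_subjects = 6, n_scans = 4, seed = 11,
                                      design = "unbalanced"))
  design <- build_design(sim, traj_spec(1))
  aug <- augment_system(design, data = sim)
  for (lam in list(c(-8, -3, -7), c(-6, -5, -9))) {
    post <- e_step(aug, lam)
    ms <- m_step(aug, lam, post)
    g_fd <- vapply(seq_along(lam), function(k) {
      h <- 1e-5
      lp <- lam; lp[k] <- lp[k] + h
      lm <- lam; lm[k] <- lm[k] - h
      (free_energy(aug, lp) - free_energy(aug, lm)) / (2 * h)
    }, 0)
    expect_equal(ms$g, g_fd, tolerance = 1e-4)
    # Fisher information is symmetric positive semidefinite
    expect_equal(ms$H, t(ms$H))
    expect_gt(min(eigen(ms$H, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("the Fisher update is stationary at a converged optimum", {
  sim <- simulate_ensemble(sim_config(n_subjects = 40, seed = 12))
  fit <- fit_trajectories(sim, control = traj_control(tol_f = 1e-10,
                                                      tol_lambda = 1e-6,
                                                      max_iter = 200))
  post <- e_step(fit$aug, fit$lambda)
  ms <- m_step(fit$aug, fit$lambda, post)
  expect_lt(max(abs(ms$lambda - fit$lambda)), 1e-3)
})

test_that("free energy never decreases across accepted EM iterations", {
  for (s in 1:3) {
    sim <- simulate_ensemble(sim_config(n_subjects = 25, seed = 100 + s,
                                        design = if (s == 2) "unbalanced" else "balanced"))
    fit <- fit_trajectories(sim)
    dF <- diff(fit$trace)
    expect_true(all(dF >= -1e-6 * pmax(1, abs(fit$trace[-1]))))
    expect_true(fit$converged)
  }
})

test_that("balanced designs reproduce averaged per-subject least squares", {
  sim <- simulate_ensemble(sim_config(n_subjects = 50, seed = 13))
  fit <- fit_trajectories(sim)
  ols_mean <- colMeans(subject_ols(sim, 1))
  expect_equal(unname(fit$posterior$theta2), ols_mean, tolerance = 1e-3)
})

test_that("degenerate ensembles drive the between-subject variances to zero", {
  sim <- simulate_ensemble(sim_config(n_subjects = 30, var_params = c(0, 0),
                                      noise_sd = 0.01, seed = 14))
  fit <- suppressWarnings(fit_trajectories(sim))
  expect_lt(fit$hyper$variance[2], 1e-6)
  expect_lt(fit$hyper$variance[3], 1e-6)
  dF <- diff(fit$trace)
  expect_true(all(dF >= -1e-6 * pmax(1, abs(fit$trace[-1]))))
})

test_that("refitting at fixed hyperparameters is idempotent on the posterior", {
  sim <- simulate_ensemble(sim_config(n_subjects = 20, seed = 15))
  fit <- fit_trajectories(sim)
  refit <- fit_trajectories(sim, lambda = fit$lambda)
  expect_equal(refit$posterior$theta2, fit$posterior$theta2, tolerance = 1e-10)
  expect_equal(refit$posterior$C_theta2, fit$posterior$C_theta2,
               tolerance = 1e-10)
  refit2 <- fit_trajectories(sim, lambda = fit$lambda)
  expect_identical(refit$posterior$eta, refit2$posterior$eta)
})

test_that("posterior collapses to the marginalized model computed by brute force", {
  # theta2 posterior from the augmented model equals the GLS posterior of the
  # collapsed model y ~ N(X1 X2 theta2, Ce1 + X1 Ce2 X1') under the same
  # (near-flat, but proper) top-level prior
  sim <- simulate_ensemble(sim_config(n_subjects = 4, n_scans = 3, seed = 16))
  design <- build_design(sim, traj_spec(1))
  aug <- augment_system(design, data = sim)
  lam <- c(-9, -4, -8)
  post <- e_step(aug, lam)
  X1 <- as.matrix(design$X1); X2 <- as.matrix(design$X2)
  M <- aug$dims$M; P1 <- aug$dims$P1; P2 <- aug$dims$P2
  v2 <- numeric(P1)
  for (k in seq_along(aug$sets)[-1]) v2[aug$sets[[k]]$indices - M] <- exp(lam[k])
  V <- diag(rep(exp(lam[1]), M)) + X1 %*% diag(v2) %*% t(X1)
  Xc <- X1 %*% X2
  A2 <- t(Xc) %*% solve(V, Xc) + diag(exp(-32), P2)
  C2_or <- solve(A2)
  eta2_or <- drop(C2_or %*% t(Xc) %*% solve(V, sim$scans$value))
  expect_equal(unname(post$eta[P1 + seq_len(P2)]), eta2_or, tolerance = 1e-8)
  expect_equal(unname(post$C[P1 + seq_len(P2), P1 + seq_len(P2)]), C2_or,
               tolerance = 1e-6)
})

test_that("numerical failures carry the offending hyperparameters", {
  d <- traj_data(make_scans(list(c(49, 51)), list(c(1, 2))), ref_age = 50)
  design <- build_design(d, traj_spec(1))
  aug <- augment_system(design, data = d)
  err <- tryCatch(e_step(aug, c(NaN, 0, 0)), condition = function(e) e)
  expect_s3_class(err, "traj_numerical_failure")
})

test_that("per-unit fits are fast enough for mass-univariate use", {
  sim <- simulate_ensemble(sim_config(n_subjects = 200, seed = 17))
  elapsed <- system.time(fit <- fit_trajectories(sim))["elapsed"]
  expect_true(fit$converged)
  expect_lt(elapsed, 2)
})
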