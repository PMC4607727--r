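# independent oracles and small fixture builders used across the suite

# dense Gauss-Markov evaluation of the augmented model posterior, without any
# of the package's factorization shortcuts
dense_posterior_oracle <- function(aug, lambda) {
  Xb <- as.matrix(aug$Xbar)
  v <- numeric(aug$dims$n)
  for (k in seq_along(aug$sets)) v[aug$sets[[k]]$indices] <- exp(lambda[k])
  if (length(aug$clamped_rows) > 0) v[aug$clamped_rows] <- aug$clamped_var
  v[aug$prior_rows] <- aug$prior_var
  W <- diag(1 / v)
  C <- solve(t(Xb) %*% W %*% Xb)
  eta <- drop(C %*% t(Xb) %*% W %*% aug$ybar)
  list(eta = eta, C = C)
}

# closed-form Gaussian log marginal of the collapsed two-level model:
# ln N(y; X1 X2 eta2, Ce1 + X1 (Ce2 + X2 Ctheta2 X2') X1')
closed_form_marginal_oracle <- function(design, aug, y, lambda,
                                        prior_mean, prior_var) {
  X1 <- as.matrix(design$X1)
  X2 <- as.matrix(design$X2)
  M <- aug$dims$M
  P1 <- aug$dims$P1
  P2 <- aug$dims$P2
  Ce1 <- diag(rep(exp(lambda[1]), M))
  v2 <- numeric(P1)
  for (k in seq_along(aug$sets)[-1]) {
    v2[aug$sets[[k]]$indices - M] <- exp(lambda[k])
  }
  if (length(aug$clamped_rows) > 0) v2[aug$clamped_rows - M] <- aug$clamped_var
  Ce2 <- diag(v2, P1)
  Cq <- diag(rep_len(prior_var, P2), P2)
  V <- Ce1 + X1 %*% (Ce2 + X2 %*% Cq %*% t(X2)) %*% t(X1)
  mu <- drop(X1 %*% X2 %*% rep_len(prior_mean, P2))
  ld <- determinant(V, logarithm = TRUE)$modulus
  -0.5 * M * log(2 * pi) - 0.5 * as.numeric(ld) -
    0.5 * drop(t(y - mu) %*% solve(V, y - mu))
}

# per-subject OLS coefficients (summary-statistic first stage)
subject_ols <- function(data, degree = 1) {
  si <- data$scans$subject_index
  t(vapply(seq_len(data$n_subjects), function(i) {
    rows <- which(si == i)
    Xi <- outer(data$scans$age_c[rows], 0:degree, `^`)
    qr.solve(Xi, data$scans$value[rows])
  }, numeric(degree + 1)))
}

sample_moments <- function(x) {
  m <- mean(x)
  s <- sd(x)
  list(mean = m, var = var(x),
       skew = mean((x - m)^3) / s^3,
       exkurt = mean((x - m)^4) / s^4 - 3)
}

# a small deterministic scans table with explicit ages/values
make_scans <- function(ages_by_subject, values_by_subject,
                       groups = NULL) {
  n <- length(ages_by_subject)
  data.frame(
    subject = rep(paste0("s", seq_len(n)), lengths(ages_by_subject)),
    age = unlist(ages_by_subject),
    value = unlist(values_by_subject),
    group = if (is.null(groups)) "all" else rep(groups, lengths(ages_by_subject))
  )
}
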