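# EM engine for the augmented two-level trajectory model.
#
# All error covariances here are diagonal (isotropic noise, per-coefficient
# between-subject variances, clamped fixed-effect variance, diagonal top-level
# prior), so the assembled C_eps is diagonal and its inverse is a weight
# vector. The posterior precision A = Xbar' W Xbar is factorized by Cholesky
# after symmetric Jacobi scaling, which keeps the solve accurate despite the
# exp(32)/exp(-32) spread introduced by the flat prior and the fixed-effect
# clamp.

assemble_weights <- function(aug, lambda) {
  n <- aug$dims$n
  v <- numeric(n)
  for (k in seq_along(aug$sets)) {
    v[aug$sets[[k]]$indices] <- exp(lambda[k])
  }
  if (length(aug$clamped_rows) > 0) v[aug$clamped_rows] <- aug$clamped_var
  v[aug$prior_rows] <- aug$prior_var
  1 / v
}

# scaled Cholesky of a symmetric positive definite matrix; returns the
# inverse, log determinant and the (scaled) factor
chol_inverse <- function(A, lambda = NULL) {
  dsc <- sqrt(diag(A))
  if (any(!is.finite(dsc)) || any(dsc <= 0)) {
    traj_numerical_failure(lambda, "non-positive diagonal in posterior precision")
  }
  As <- A / tcrossprod(dsc)
  R <- tryCatch(chol(As), error = function(e) {
    traj_numerical_failure(lambda, conditionMessage(e))
  })
  Cs <- chol2inv(R)
  C <- Cs / tcrossprod(dsc)
  ldetA <- 2 * sum(log(diag(R))) + 2 * sum(log(dsc))
  list(C = C, ldetA = ldetA)
}

traj_numerical_failure <- function(lambda, msg) {
  abort(
    paste0("indefinite or singular posterior precision (", msg, ")"),
    class = "traj_numerical_failure",
    lambda = lambda
  )
}

estep_core <- function(aug, lambda) {
  w <- assemble_weights(aug, lambda)
  if (any(!is.finite(w))) traj_numerical_failure(lambda, "non-finite weights")
  Xw <- aug$Xbar * w
  A <- as.matrix(crossprod(aug$Xbar, Xw))
  b <- as.numeric(crossprod(Xw, aug$ybar))
  ci <- chol_inverse(A, lambda)
  eta <- drop(ci$C %*% b)
  # two steps of iterative refinement: the normal equations square the
  # conditioning, and near-interpolation limits (noise variance -> 0) need
  # the extra forward accuracy
  for (it in 1:2) {
    resid <- aug$ybar - as.numeric(aug$Xbar %*% eta)
    eta <- eta + drop(ci$C %*% as.numeric(crossprod(aug$Xbar, w * resid)))
  }
  r <- aug$ybar - as.numeric(aug$Xbar %*% eta)
  M <- aug$dims$M
  # after the exact E-step the free-energy bound is tight:
  # F = ln p(y | lambda) for the marginalized two-level model
  F <- 0.5 * sum(log(w)) - 0.5 * sum(w * r * r) - 0.5 * ci$ldetA -
    0.5 * M * log(2 * pi)
  list(eta = eta, C = ci$C, r = r, w = w, ldetA = ci$ldetA, F = F,
       lambda = lambda)
}

# gradient and Fisher information of F in the log-variance hyperparameters,
# exploiting that every basis is a diagonal indicator with disjoint support:
#   P = W - W Xbar C Xbar' W   (W diagonal)
#   tr(P Q_k)        = sum_{i in S_k} w_i - w_i^2 E_ii
#   ybar' P Q_k P ybar = sum_{i in S_k} (w_i r_i)^2
#   tr(P Q_k P Q_l)  = ||A_k A_l'||_F^2 (+ diagonal corrections when k = l)
# with E = Xbar C Xbar' and A_k = diag(w)[S_k] U[S_k,], U = Xbar chol(C).
mstep_grad_fisher <- function(aug, es) {
  sets <- aug$sets
  K <- length(sets)
  lambda <- es$lambda
  w <- es$w
  r <- es$r
  L <- t(chol_psd(es$C))
  U <- as.matrix(aug$Xbar %*% L)
  Eii <- rowSums(U * U)
  wr2 <- (w * r)^2

  g <- numeric(K)
  Gk <- vector("list", K)
  trPQ <- numeric(K)
  for (k in seq_len(K)) {
    S <- sets[[k]]$indices
    wS <- w[S]
    trPQ[k] <- sum(wS) - sum(wS^2 * Eii[S])
    g[k] <- 0.5 * exp(lambda[k]) * (sum(wr2[S]) - trPQ[k])
    Gk[[k]] <- crossprod(U[S, , drop = FALSE] * wS)
  }
  H <- matrix(0, K, K)
  for (k in seq_len(K)) {
    for (l in k:K) {
      tr_kl <- sum(Gk[[k]] * Gk[[l]])
      if (l == k) {
        S <- sets[[k]]$indices
        wS <- w[S]
        tr_kl <- tr_kl + sum(wS^2) - 2 * sum(wS^3 * Eii[S])
      }
      H[k, l] <- H[l, k] <- 0.5 * exp(lambda[k] + lambda[l]) * tr_kl
    }
  }
  list(g = g, H = H, trPQ = trPQ)
}

# Cholesky for a PSD matrix that may be numerically semi-definite
chol_psd <- function(C) {
  tryCatch(chol(C), error = function(e) {
    eps <- max(diag(C)) * 1e-12
    chol(C + diag(eps, nrow(C)))
  })
}

fisher_step <- function(g, H) {
  sol <- tryCatch(solve(H, g), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(sol) || !all(is.finite(sol))) {
    ridged <- TRUE
    ridge <- max(diag(H), 1e-12) * 1e-6
    sol <- solve(H + diag(ridge, nrow(H)), g)
  }
  list(delta = sol, ridged = ridged)
}

#' Exact Gaussian E-step
#'
#' Computes the joint posterior over all trajectory parameters (second-level
#' errors and group-level parameters) of the augmented model at fixed
#' hyperparameters: posterior covariance
#' \eqn{C_{\theta|y} = (\bar X' C_\epsilon^{-1} \bar X)^{-1}} and mean
#' \eqn{\eta_{\theta|y} = C_{\theta|y} \bar X' C_\epsilon^{-1} \bar y},
#' via symmetric factorization of the assembled precision.
#'
#' @param aug An [augment_system()] result.
#' @param lambda Log-variance hyperparameter vector (first element: log noise
#'   variance; then one log variance per trajectory coefficient per group).
#' @return A list of class `traj_posterior`: posterior mean `eta` over
#'   `[eps2; theta2]`, posterior covariance `C`, augmented residual `r`,
#'   the free energy `F` (equal to the log marginal likelihood at `lambda`),
#'   and bookkeeping.
#' @export
e_step <- function(aug, lambda) {
  stopifnot(inherits(aug, "traj_augmented"))
  if (length(lambda) != aug$dims$n_hyper) {
    abort(paste0("lambda has length ", length(lambda), "; expected ",
                 aug$dims$n_hyper))
  }
  es <- estep_core(aug, lambda)
  structure(es, class = "traj_posterior")
}

#' Variational free energy
#'
#' Evaluates the free-energy bound on the log model evidence, including every
#' hyperparameter-independent constant (Gaussian normalizers and the
#' posterior entropy), so that differences between models with different
#' parameter counts are meaningful log Bayes factors. After an exact E-step
#' at the same hyperparameters the bound is tight and equals the log marginal
#' likelihood \eqn{\ln p(y|\lambda)}.
#'
#' @inheritParams e_step
#' @param post Optionally, a posterior from [e_step()] (possibly computed at
#'   other hyperparameters); when omitted the E-step is run at `lambda`.
#' @return Scalar free energy.
#' @export
free_energy <- function(aug, lambda, post = NULL) {
  stopifnot(inherits(aug, "traj_augmented"))
  if (is.null(post)) {
    return(estep_core(aug, lambda)$F)
  }
  # general bound with q(theta) fixed at `post`
  w <- assemble_weights(aug, lambda)
  Xw <- aug$Xbar * w
  A <- as.matrix(crossprod(aug$Xbar, Xw))
  M <- aug$dims$M
  p <- aug$dims$p
  0.5 * sum(log(w)) - 0.5 * sum(w * post$r^2) - 0.5 * sum(post$C * A) -
    0.5 * post$ldetA - 0.5 * M * log(2 * pi) + 0.5 * p
}

#' Fisher-scoring M-step
#'
#' One safeguarded Fisher-scoring update of the log-variance hyperparameters,
#' using the analytic gradient and Fisher information of the free energy with
#' the posterior fixed at the preceding E-step. Steps are capped in magnitude
#' and halved while the free energy decreases, so accepted updates never
#' reduce the free energy. Clamped fixed-effect variances and the top-level
#' prior are never updated.
#'
#' @inheritParams e_step
#' @param post The posterior from the E-step at `lambda`.
#' @param control A [traj_control()].
#' @return A list with the updated `lambda`, the posterior `post` and free
#'   energy `F` at the update, the gradient `g` and Fisher information `H`
#'   at the starting point, and the number of step `halvings`.
#' @export
m_step <- function(aug, lambda, post, control = traj_control()) {
  stopifnot(inherits(aug, "traj_augmented"))
  es <- post
  gf <- mstep_grad_fisher(aug, es)
  fs <- fisher_step(gf$g, gf$H)
  delta <- pmin(pmax(fs$delta, -control$max_step), control$max_step)

  F0 <- es$F
  halvings <- 0L
  accepted <- FALSE
  es_new <- es
  lam_new <- lambda
  while (halvings <= control$max_halvings) {
    lam_try <- pmin(pmax(lambda + delta, control$lambda_floor),
                    control$lambda_ceiling)
    es_try <- tryCatch(estep_core(aug, lam_try),
                       traj_numerical_failure = function(e) NULL)
    if (!is.null(es_try) && is.finite(es_try$F) &&
        es_try$F >= F0 - 1e-12 * max(1, abs(F0))) {
      lam_new <- lam_try
      es_new <- es_try
      accepted <- TRUE
      break
    }
    delta <- delta / 2
    halvings <- halvings + 1L
  }
  list(lambda = lam_new, post = es_new, F = es_new$F, g = gf$g, H = gf$H,
       halvings = halvings, accepted = accepted, ridged = fs$ridged)
}

#' Initial hyperparameters from per-subject least squares
#'
#' The noise log-variance is initialized from the pooled within-subject
#' residual variance of per-subject ordinary least-squares fits; each
#' between-subject log variance from the sample variance of the per-subject
#' coefficients in that group (floored at `exp(-8)`). Subjects with too few
#' scans are skipped; if nothing can be estimated the fallback is -4
#' everywhere.
#'
#' @param data A [traj_data] object.
#' @param spec A [traj_spec].
#' @param y Optional response vector overriding the `value` column.
#' @return Named log-variance vector of length `1 + G(D+1)`.
#' @export
init_hyperparameters <- function(data, spec, y = NULL) {
  data <- traj_data(data)
  D <- spec$degree
  K <- D + 1L
  N <- data$n_subjects
  G <- data$n_groups
  tc <- data$scans$age_c
  yy <- y %||% data$scans$value
  si <- data$scans$subject_index

  coefs <- matrix(NA_real_, N, K)
  rss <- 0; df <- 0
  for (i in seq_len(N)) {
    rows <- which(si == i)
    if (length(rows) < K) next
    Xi <- outer(tc[rows], 0:D, `^`)
    fit <- tryCatch(.lm.fit(Xi, yy[rows]), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) next
    coefs[i, ] <- fit$coefficients
    if (length(rows) > K) {
      rss <- rss + sum(fit$residuals^2)
      df <- df + length(rows) - K
    }
  }
  log_sigma2 <- if (df > 0 && rss > 0) log(rss / df) else -4
  lam <- numeric(G * K)
  labels <- character(G * K)
  idx <- 0L
  for (g in seq_len(G)) {
    subj_g <- which(data$group_of == g)
    for (d in seq_len(K)) {
      idx <- idx + 1L
      v <- coefs[subj_g, d]
      v <- v[is.finite(v)]
      lam[idx] <- if (length(v) >= 2) log(max(var(v), exp(-8))) else -4
      labels[idx] <- paste0(if (G > 1) paste0(data$group_levels[g], ":"),
                            coef_label(d - 1L))
    }
  }
  out <- c(log_sigma2, lam)
  names(out) <- c("noise", labels)
  pmin(pmax(out, -32), 32)
}

#' Fit a Bayesian mixed-effects trajectory model
#'
#' Inverts the two-level trajectory model by Expectation Maximization:
#' alternating the exact Gaussian E-step ([e_step()]) with one safeguarded
#' Fisher-scoring update of the log-variance hyperparameters ([m_step()])
#' until the free energy and the hyperparameters stop changing. The
#' optimizer is deterministic given its inputs.
#'
#' @param data A data frame of scans or a [traj_data] object. Data-frame
#'   inputs are passed to [traj_data()] together with `...`.
#' @param spec A [traj_spec]; default linear random effects (`D = 1`).
#' @param prior A [traj_prior]; flat by default.
#' @param control A [traj_control].
#' @param lambda Optional fixed log-variance hyperparameters: when given, no
#'   EM iterations are run and the posterior is the exact E-step at `lambda`.
#' @param ... Passed to [traj_data()] when `data` is a raw data frame.
#' @return An object of class `traj_fit` with the posterior over all
#'   trajectory parameters, the hyperparameters, the free-energy trace and
#'   convergence information. See [tidy.traj_fit()], [glance.traj_fit()],
#'   [fitted_trajectories()], [ppm()].
#' @examples
#' sim <- simulate_ensemble(sim_config(n_subjects = 30, seed = 1))
#' fit <- fit_trajectories(sim)
#' tidy(fit)
#' glance(fit)
#' @export
fit_trajectories <- function(data, spec = traj_spec(1), prior = traj_prior(),
                             control = traj_control(), lambda = NULL, ...) {
  data <- traj_data(data, ...)
  design <- build_design(data, spec)
  aug <- augment_system(design, data = data, prior = prior)
  fit <- em_fit(aug, data, init = lambda, fixed_lambda = !is.null(lambda),
                control = control)
  fit$call <- match.call()
  fit
}

# core EM loop on an augmented system; `data` only used for labelling and
# initialization
em_fit <- function(aug, data, init = NULL, fixed_lambda = FALSE,
                   control = traj_control()) {
  design <- aug$design
  spec <- design$spec
  lambda <- init %||% init_hyperparameters(data, spec, y = aug$ybar[seq_len(aug$dims$M)])
  if (length(lambda) != aug$dims$n_hyper) {
    abort(paste0("initial lambda has length ", length(lambda),
                 "; expected ", aug$dims$n_hyper))
  }
  names(lambda) <- vapply(aug$sets, `[[`, "", "label")

  es <- estep_core(aug, lambda)
  trace <- es$F
  converged <- FALSE
  iter <- 0L
  any_ridged <- FALSE
  g_last <- rep(NA_real_, length(lambda))
  if (!fixed_lambda) {
    while (iter < control$max_iter) {
      iter <- iter + 1L
      ms <- m_step(aug, lambda, es, control)
      d_lam <- max(abs(ms$lambda - lambda))
      d_f <- ms$F - es$F
      lambda <- ms$lambda
      es <- ms$post
      g_last <- ms$g
      any_ridged <- any_ridged || ms$ridged
      trace <- c(trace, es$F)
      if (control$verbose) {
        inform(sprintf("iter %d: F = %.6f (dF = %.2e, dlambda = %.2e)",
                       iter, es$F, d_f, d_lam))
      }
      if (d_f < control$tol_f * max(1, abs(es$F)) &&
          d_lam < control$tol_lambda) {
        converged <- TRUE
        break
      }
    }
    if (any_ridged) {
      warn("singular Fisher information in at least one M-step; ridge-regularized solve used (a variance component is likely degenerate)")
    }
  } else {
    converged <- TRUE
  }

  P1 <- aug$dims$P1
  P2 <- aug$dims$P2
  theta2 <- es$eta[P1 + seq_len(P2)]
  names(theta2) <- design$theta2_names
  C22 <- es$C[P1 + seq_len(P2), P1 + seq_len(P2), drop = FALSE]
  dimnames(C22) <- list(design$theta2_names, design$theta2_names)

  hyper <- tibble(
    component = names(lambda),
    level = vapply(aug$sets, `[[`, 0L, "level"),
    lambda = unname(lambda),
    variance = exp(unname(lambda))
  )

  structure(
    list(
      data = data, spec = spec, design = design, aug = aug,
      lambda = lambda, hyper = hyper,
      posterior = list(eta = es$eta, C = es$C,
                       theta2 = theta2, C_theta2 = C22,
                       theta2_se = sqrt(pmax(diag(C22), 0))),
      free_energy = es$F, trace = trace,
      iterations = iter, converged = converged,
      gradient = g_last,
      gradient_norm = if (all(is.finite(g_last))) max(abs(g_last)) else NA_real_
    ),
    class = "traj_fit"
  )
}

#' @export
print.traj_fit <- function(x, ...) {
  d <- x$design$dims
  cat("<traj_fit> ", x$spec$label, ": ", d$M, " scans, ", d$N, " subjects",
      if (d$G > 1) paste0(", ", d$G, " groups"), "\n", sep = "")
  cat("  free energy ", format(x$free_energy, digits = 8), " after ",
      x$iterations, " EM iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  cat("  noise sd ", signif(sqrt(x$hyper$variance[1]), 4),
      "; between-subject sds ",
      paste(signif(sqrt(x$hyper$variance[-1]), 3), collapse = ", "),
      "\n", sep = "")
  est <- tidy(x)
  cat("  group parameters:\n")
  print(as.data.frame(est), digits = 4, row.names = FALSE)
  invisible(x)
}
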