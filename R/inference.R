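# Contrast-based Bayesian inference (posterior probability maps) and
# evidence-based model comparison.

resolve_contrast <- function(fit, contrast, level = 2) {
  d <- fit$design$dims
  if (level == 2) {
    nm <- names(fit$posterior$theta2)
    len <- d$P2
  } else if (level == 1) {
    nm <- NULL
    len <- d$P1
  } else {
    abort("level must be 1 (subject parameters) or 2 (group parameters)")
  }
  if (is.character(contrast)) {
    if (level != 2) abort("named contrasts address second-level parameters")
    w <- setNames(rep(0, len), nm)
    miss <- setdiff(contrast, nm)
    if (length(miss) > 0) {
      abort(paste0("unknown term(s): ", paste(miss, collapse = ", "),
                   "; available: ", paste(nm, collapse = ", ")))
    }
    w[contrast] <- 1
    contrast <- w
  }
  contrast <- as.numeric(unlist(resolve_named(contrast, nm, len)))
  if (length(contrast) != len) {
    abort(paste0("contrast has length ", length(contrast),
                 "; expected ", len))
  }
  if (all(contrast == 0)) abort("contrast vector is identically zero")
  contrast
}

resolve_named <- function(contrast, nm, len) {
  if (!is.null(names(contrast)) && !is.null(nm) &&
      length(contrast) != len) {
    w <- setNames(rep(0, len), nm)
    miss <- setdiff(names(contrast), nm)
    if (length(miss) > 0) {
      abort(paste0("unknown term(s): ", paste(miss, collapse = ", ")))
    }
    w[names(contrast)] <- contrast
    return(w)
  }
  contrast
}

contrast_moments <- function(fit, contrast, level = 2) {
  cvec <- resolve_contrast(fit, contrast, level)
  if (level == 2) {
    mu <- sum(cvec * fit$posterior$theta2)
    v <- drop(crossprod(cvec, fit$posterior$C_theta2 %*% cvec))
  } else {
    d <- fit$design$dims
    # theta1 = [I, X2] [eps2; theta2]
    cfull <- c(cvec, as.numeric(Matrix::crossprod(fit$design$X2, cvec)))
    mu <- sum(cfull * fit$posterior$eta)
    v <- drop(crossprod(cfull, fit$posterior$C %*% cfull))
  }
  list(mu = mu, var = max(v, 0))
}

#' Posterior probability of a trajectory contrast exceeding a threshold
#'
#' Evaluates the exceedance probability
#' \eqn{p(c^T\theta > \gamma \mid y) = 1 - \Phi\big((\gamma - c^T\eta_{\theta|y}) / \sqrt{c^T C_{\theta|y} c}\big)}
#' for a linear contrast of second-level (default) or first-level trajectory
#' parameters — the per-unit quantity behind a posterior probability map.
#'
#' @param fit A [traj_fit].
#' @param contrast A contrast over the targeted parameter block: a term name
#'   (e.g. `"slope"`), a named numeric vector (e.g.
#'   `c("pMCI:slope" = 1, "sMCI:slope" = -1)`), or a full-length weight
#'   vector.
#' @param gamma Threshold \eqn{\gamma} in the units of \eqn{c^T\theta}
#'   (default 0).
#' @param p_t Probability threshold used for the suprathreshold flag
#'   (default 0.95).
#' @param level 2 for group-level parameters (default), 1 for subject-level.
#' @return A one-row tibble: `estimate` (\eqn{c^T\eta}), `std.error`,
#'   `gamma`, `prob` (exceedance probability) and `suprathreshold`
#'   (`prob > p_t`).
#' @examples
#' sim <- simulate_ensemble(sim_config(n_subjects = 40, seed = 2))
#' fit <- fit_trajectories(sim)
#' ppm(fit, c(slope = -1))   # evidence for decline
#' @export
ppm <- function(fit, contrast, gamma = 0, p_t = 0.95, level = 2) {
  stopifnot(inherits(fit, "traj_fit"))
  if (p_t <= 0 || p_t >= 1) abort("p_t must lie in (0, 1)")
  cm <- contrast_moments(fit, contrast, level)
  sdv <- sqrt(cm$var)
  prob <- if (sdv > 0) {
    1 - pnorm((gamma - cm$mu) / sdv)
  } else {
    as.numeric(cm$mu > gamma)  # degenerate posterior
  }
  tibble(
    estimate = cm$mu,
    std.error = sdv,
    gamma = gamma,
    prob = prob,
    p_t = p_t,
    suprathreshold = prob > p_t
  )
}

#' Joint posterior of a compound contrast
#'
#' Stacks several contrast vectors into a matrix \eqn{C} and returns the
#' multivariate posterior of \eqn{C\theta^{(2)}}. As a scalar summary it also
#' reports the squared Mahalanobis distance of the null point \eqn{\gamma}
#' from the posterior mean and the corresponding chi-squared posterior mass
#' outside the ellipsoid through \eqn{\gamma} — an extension of the one-sided
#' exceedance probability to compound hypotheses.
#'
#' @param fit A [traj_fit].
#' @param contrasts A matrix with one contrast per row, or a list of contrast
#'   specifications as in [ppm()]. Rows must be linearly independent.
#' @param gamma Null value(s) for \eqn{C\theta}; scalar or vector.
#' @return A list of class `traj_compound`: posterior `mean` and
#'   `covariance` of \eqn{C\theta}, the `statistic` (squared standardized
#'   distance of `gamma`), its degrees of freedom `df`, and
#'   `prob_outside_null` (`pchisq(statistic, df)`).
#' @export
compound_contrast <- function(fit, contrasts, gamma = 0) {
  stopifnot(inherits(fit, "traj_fit"))
  if (is.list(contrasts) && !is.matrix(contrasts)) {
    rows <- lapply(contrasts, function(cc) resolve_contrast(fit, cc, 2))
    Cmat <- do.call(rbind, rows)
  } else {
    Cmat <- as.matrix(contrasts)
    if (ncol(Cmat) != fit$design$dims$P2) {
      abort(paste0("contrast matrix has ", ncol(Cmat),
                   " columns; expected ", fit$design$dims$P2))
    }
  }
  q <- nrow(Cmat)
  if (qr(Cmat)$rank < q) abort("contrast rows are rank deficient")
  gamma <- rep_len(gamma, q)
  mu <- as.numeric(Cmat %*% fit$posterior$theta2)
  V <- Cmat %*% fit$posterior$C_theta2 %*% t(Cmat)
  V <- (V + t(V)) / 2
  stat <- drop(crossprod(mu - gamma, solve(V, mu - gamma)))
  structure(
    list(mean = mu, covariance = V, gamma = gamma,
         statistic = stat, df = q,
         prob_outside_null = pchisq(stat, df = q)),
    class = "traj_compound"
  )
}

#' @export
print.traj_compound <- function(x, ...) {
  cat("<traj_compound> ", x$df, " contrast(s)\n", sep = "")
  cat("  posterior mean: ", paste(signif(x$mean, 4), collapse = ", "), "\n",
      sep = "")
  cat("  chi^2 statistic ", signif(x$statistic, 5), " on ", x$df,
      " df; posterior mass outside null ellipsoid ",
      signif(x$prob_outside_null, 4), "\n", sep = "")
  invisible(x)
}

#' Log Bayes factor from two free energies
#'
#' The difference of free energies of two models fitted to identical data
#' approximates the log ratio of their model evidences.
#'
#' @param fit_i,fit_j [traj_fit] objects or scalar free energies.
#' @return `F_i - F_j` (log Bayes factor; `exp()` of it is the Bayes factor).
#' @export
log_bayes_factor <- function(fit_i, fit_j) {
  f <- function(x) if (inherits(x, "traj_fit")) x$free_energy else as.numeric(x)
  f(fit_i) - f(fit_j)
}

#' Compare trajectory models by model evidence
#'
#' Fits each candidate model specification to the same data by an independent
#' EM optimization and tabulates free energies and pairwise log Bayes
#' factors. Non-converged fits are excluded from the winner selection and
#' reported.
#'
#' @param data A data frame or [traj_data].
#' @param specs A list of [traj_spec] objects (at least 2).
#' @param prior,control See [fit_trajectories()].
#' @param keep_fits Keep the individual [traj_fit] objects (default `FALSE`).
#' @param ... Passed to [traj_data()] for raw data frames.
#' @return A list of class `traj_comparison`: a `table` tibble (model label,
#'   degrees, free energy, delta to the best model, convergence), the
#'   pairwise `log_bf` matrix, and the `winner` label.
#' @examples
#' sim <- simulate_ensemble(sim_config(n_subjects = 30, seed = 3))
#' cmp <- compare_trajectory_models(sim, list(traj_spec(0), traj_spec(1)))
#' tidy(cmp)
#' @export
compare_trajectory_models <- function(data, specs, prior = traj_prior(),
                                      control = traj_control(),
                                      keep_fits = FALSE, ...) {
  data <- traj_data(data, ...)
  if (length(specs) < 2) abort("supply at least two model specifications")
  labels <- vapply(specs, `[[`, "", "label")
  labels <- make.unique(labels)
  fits <- lapply(specs, function(sp) {
    fit_trajectories(data, spec = sp, prior = prior, control = control)
  })
  F_all <- vapply(fits, `[[`, 0, "free_energy")
  conv <- vapply(fits, `[[`, TRUE, "converged")
  if (any(!conv)) {
    warn(paste0("model(s) not converged and excluded from winner selection: ",
                paste(labels[!conv], collapse = ", ")))
  }
  log_bf <- outer(F_all, F_all, `-`)
  dimnames(log_bf) <- list(labels, labels)
  F_ok <- ifelse(conv, F_all, -Inf)
  winner <- labels[which.max(F_ok)]
  table <- tibble(
    model = labels,
    degree = vapply(specs, `[[`, 0L, "degree"),
    fixed_degree = vapply(specs, `[[`, 0L, "fixed_degree"),
    free_energy = F_all,
    delta_f = F_all - max(F_ok),
    converged = conv,
    winner = labels == winner
  )
  structure(
    list(table = table, log_bf = log_bf, winner = winner,
         fits = if (keep_fits) setNames(fits, labels)),
    class = "traj_comparison"
  )
}

#' @method tidy traj_comparison
#' @export
tidy.traj_comparison <- function(x, ...) x$table

#' @export
print.traj_comparison <- function(x, ...) {
  cat("<traj_comparison> winner: ", x$winner, "\n", sep = "")
  print(as.data.frame(x$table), digits = 6, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison table to delimited text
#'
#' @param x A `traj_comparison`.
#' @param file Output path.
#' @param sep Field separator (default tab).
#' @export
write_comparison <- function(x, file, sep = "\t") {
  stopifnot(inherits(x, "traj_comparison"))
  write.table(as.data.frame(x$table), file, sep = sep, quote = FALSE,
              row.names = FALSE)
  invisible(file)
}
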