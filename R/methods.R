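#' Tidy the group-level parameters of a trajectory fit
#'
#' @param x A [traj_fit].
#' @param ... Unused.
#' @return A tibble with one row per second-level parameter: `term`,
#'   `estimate` (posterior mean), `std.error` (posterior standard deviation).
#' @method tidy traj_fit
#' @export
tidy.traj_fit <- function(x, ...) {
  tibble(
    term = names(x$posterior$theta2),
    estimate = unname(x$posterior$theta2),
    std.error = unname(x$posterior$theta2_se)
  )
}

#' One-row summary of a trajectory fit
#'
#' @param x A [traj_fit].
#' @param ... Unused.
#' @return A tibble with the free energy (log model evidence), iteration
#'   count, convergence flag, noise standard deviation and problem size.
#' @method glance traj_fit
#' @export
glance.traj_fit <- function(x, ...) {
  tibble(
    free_energy = x$free_energy,
    iterations = x$iterations,
    converged = x$converged,
    gradient_norm = x$gradient_norm,
    noise_sd = sqrt(x$hyper$variance[1]),
    n_subjects = x$design$dims$N,
    n_scans = x$design$dims$M,
    n_hyper = nrow(x$hyper)
  )
}

#' Posterior subject-level trajectory coefficients
#'
#' The first-level coefficients are derived from the joint posterior as
#' \eqn{\theta^{(1)} = X^{(2)}\theta^{(2)} + \epsilon^{(2)}}; their posterior
#' standard deviations propagate the full joint covariance.
#'
#' @param fit A [traj_fit].
#' @return A tibble with one row per subject and coefficient: `subject`,
#'   `group`, `coef`, `estimate`, `std.error`.
#' @export
fitted_trajectories <- function(fit) {
  stopifnot(inherits(fit, "traj_fit"))
  d <- fit$design$dims
  P1 <- d$P1; P2 <- d$P2
  X2 <- fit$design$X2
  Tm <- cbind(Diagonal(P1), X2)  # theta1 = [I, X2] [eps2; theta2]
  theta1 <- as.numeric(Tm %*% fit$posterior$eta)
  TC <- as.matrix(Tm %*% fit$posterior$C)
  v1 <- rowSums(TC * as.matrix(Tm))
  n_random <- d$n_random
  K <- d$D + 1L
  N <- d$N
  idx <- seq_len(n_random)
  tibble(
    subject = rep(fit$design$subject_levels, each = K),
    group = rep(fit$design$group_levels[fit$data$group_of], each = K),
    coef = rep(coef_label(0:d$D), times = N),
    estimate = theta1[idx],
    std.error = sqrt(pmax(v1[idx], 0))
  )
}

#' Predicted trajectory values
#'
#' Evaluates posterior mean trajectories over age, either per subject
#' (`level = 1`) or the group mean trajectory with its posterior standard
#' deviation (`level = 2`).
#'
#' @param object A [traj_fit].
#' @param ages Ages (years) at which to evaluate; defaults to a grid over the
#'   observed range.
#' @param level 1 for subject trajectories, 2 for group mean trajectories.
#' @param ... Unused.
#' @return A tibble with `age`, `fitted` and (level 2) `std.error`, plus
#'   `subject`/`group` identifiers.
#' @export
predict.traj_fit <- function(object, ages = NULL, level = 2, ...) {
  fit <- object
  d <- fit$design$dims
  if (is.null(ages)) {
    ages <- seq(min(fit$data$scans$age), max(fit$data$scans$age),
                length.out = 50)
  }
  tc <- ages - fit$data$ref_age
  # polynomial over the full fixed+random degree, fixed terms shared per group
  K <- d$D + 1L
  basis_r <- outer(tc, 0:d$D, `^`)
  basis_f <- if (d$Df > d$D) outer(tc, seq(d$D + 1, d$Df), `^`) else NULL
  if (level == 1) {
    ft <- fitted_trajectories(fit)
    ft_wide <- matrix(ft$estimate, ncol = K, byrow = TRUE)
    fixed_part <- fixed_effect_curve(fit, basis_f)
    out <- purrr::map_dfr(seq_len(d$N), function(i) {
      g <- fit$data$group_of[i]
      tibble(subject = fit$design$subject_levels[i],
             group = fit$design$group_levels[g],
             age = ages,
             fitted = as.numeric(basis_r %*% ft_wide[i, ]) +
               (if (is.null(fixed_part)) 0 else fixed_part[, g]))
    })
    return(out)
  }
  # level 2: group mean curve with posterior sd
  nm <- names(fit$posterior$theta2)
  purrr::map_dfr(seq_len(d$G), function(g) {
    pre <- if (d$G == 1) "" else paste0(fit$design$group_levels[g], ":")
    mean_terms <- paste0(pre, coef_label(0:d$D))
    fix_terms <- if (d$Df > d$D) {
      paste0(if (d$G > 1) pre, "fixed:", coef_label(seq(d$D + 1, d$Df)))
    }
    terms <- c(mean_terms, fix_terms)
    Bmat <- cbind(basis_r, basis_f)
    j <- match(terms, nm)
    mu <- as.numeric(Bmat %*% fit$posterior$theta2[j])
    Cg <- fit$posterior$C_theta2[j, j, drop = FALSE]
    se <- sqrt(pmax(rowSums((Bmat %*% Cg) * Bmat), 0))
    tibble(group = fit$design$group_levels[g], age = ages,
           fitted = mu, std.error = se)
  })
}

fixed_effect_curve <- function(fit, basis_f) {
  if (is.null(basis_f)) return(NULL)
  d <- fit$design$dims
  nm <- names(fit$posterior$theta2)
  sapply(seq_len(d$G), function(g) {
    pre <- if (d$G == 1) "" else paste0(fit$design$group_levels[g], ":")
    j <- match(paste0(pre, "fixed:", coef_label(seq(d$D + 1, d$Df))), nm)
    as.numeric(basis_f %*% fit$posterior$theta2[j])
  })
}
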