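# Synthetic trajectory ensembles, acquisition designs, non-Gaussian error
# families, the summary-statistic comparator and false-positive-rate
# calibration.

#' Configure a trajectory simulation
#'
#' Defaults reproduce the validation conditions used throughout the package:
#' ensembles of 64 subjects with 5 annual scans each, linear trajectories
#' with group mean intercept 1.2 and slope -5e-3 (arbitrary tissue-density
#' units per year), "large individual differences" (intercept variance 1e-2,
#' slope variance 1e-4), Gaussian measurement noise of standard deviation
#' 0.01, over the adult study interval 20-80 years.
#'
#' @param n_subjects Total number of subjects.
#' @param group_sizes Integer vector of subjects per group (defaults to a
#'   single group of `n_subjects`).
#' @param mean_params True second-level mean parameters: a vector
#'   (intercept, slope, ...) shared by all groups, or a matrix with one row
#'   per group. Length/columns determine the true polynomial degree.
#' @param var_params True between-subject variances per coefficient, vector
#'   or per-group matrix, same shape rules as `mean_params`. Zero variances
#'   are allowed (degenerate ensembles).
#' @param noise_sd Measurement noise standard deviation.
#' @param design `"balanced"` (identical age grid for all subjects, centred
#'   on the interval midpoint) or `"unbalanced"` (each subject's mean age
#'   uniform over `interval`, same within-subject spacing).
#' @param n_scans Scans per subject (sparsity; 1 = cross-sectional).
#' @param spacing Within-subject scan spacing in years (default annual).
#' @param interval Study age interval in years.
#' @param covariate_effects Optional matrix (covariates x coefficients) of
#'   true covariate effects on the trajectory coefficients; covariate values
#'   are drawn standard normal per subject and centred. Row names become
#'   covariate names.
#' @param error_family Error distribution: `"gaussian"`, `"gn1"`
#'   (exponential-power, symmetric, kurtosis-controlled) or `"gn2"` (skewed;
#'   see [sample_errors()]).
#' @param skewness,kurtosis Target skewness and excess kurtosis of the
#'   non-Gaussian errors.
#' @param error_level Which level receives the non-Gaussian errors:
#'   `"first"` (measurement noise) or `"second"` (coefficient residuals).
#' @param seed Random seed recorded in the output; `NULL` uses the ambient
#'   RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 64, group_sizes = NULL,
                       mean_params = c(1.2, -5e-3),
                       var_params = c(1e-2, 1e-4),
                       noise_sd = 0.01,
                       design = c("balanced", "unbalanced"),
                       n_scans = 5, spacing = 1, interval = c(20, 80),
                       covariate_effects = NULL,
                       error_family = c("gaussian", "gn1", "gn2"),
                       skewness = 0, kurtosis = 0,
                       error_level = c("first", "second"),
                       seed = NULL) {
  design <- match.arg(design)
  error_family <- match.arg(error_family)
  error_level <- match.arg(error_level)
  if (is.null(group_sizes)) group_sizes <- n_subjects
  if (sum(group_sizes) != n_subjects) {
    abort("group_sizes must sum to n_subjects")
  }
  G <- length(group_sizes)
  if (!is.matrix(mean_params)) {
    mean_params <- matrix(mean_params, nrow = G, ncol = length(mean_params),
                          byrow = TRUE)
  }
  if (!is.matrix(var_params)) {
    var_params <- matrix(var_params, nrow = G, ncol = length(var_params),
                         byrow = TRUE)
  }
  if (ncol(var_params) != ncol(mean_params) || nrow(mean_params) != G ||
      nrow(var_params) != G) {
    abort("mean_params and var_params must have one entry per coefficient and group")
  }
  if (any(var_params < 0)) abort("variances must be >= 0")
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (n_scans < 1) abort("at least one scan per subject is required")
  if (interval[1] >= interval[2]) abort("interval start must precede its end")
  structure(
    list(n_subjects = n_subjects, group_sizes = group_sizes,
         mean_params = mean_params, var_params = var_params,
         noise_sd = noise_sd, design = design, n_scans = n_scans,
         spacing = spacing, interval = interval,
         covariate_effects = covariate_effects,
         error_family = error_family, skewness = skewness,
         kurtosis = kurtosis, error_level = error_level, seed = seed),
    class = "sim_config"
  )
}

#' Sample per-subject acquisition ages
#'
#' Balanced designs give every subject the identical grid of `n_scans` ages
#' spaced `spacing` years apart and centred on the interval midpoint.
#' Unbalanced designs draw each subject's mean age uniformly over the study
#' interval, keeping the same within-subject spacing.
#'
#' @param config A [sim_config()].
#' @return A list of numeric age vectors, one per subject.
#' @export
sample_design <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_scans
  if (k < 1) abort("at least one scan per subject is required")
  offsets <- (seq_len(k) - (k + 1) / 2) * config$spacing
  centre <- mean(config$interval)
  if (config$design == "balanced") {
    replicate(config$n_subjects, centre + offsets, simplify = FALSE)
  } else {
    mean_ages <- runif(config$n_subjects, config$interval[1],
                       config$interval[2])
    lapply(mean_ages, function(m) m + offsets)
  }
}

gn1_excess_kurtosis <- function(beta) {
  exp(lgamma(5 / beta) + lgamma(1 / beta) - 2 * lgamma(3 / beta)) - 3
}

#' Draw zero-mean errors with controlled variance, skewness and kurtosis
#'
#' Two generalized-normal families complement the Gaussian: the symmetric
#' exponential-power family (`"gn1"`, density proportional to
#' \eqn{\exp(-|x/\alpha|^\beta)}) whose shape \eqn{\beta} is solved
#' numerically so the population excess kurtosis matches its target at zero
#' skewness, and a skewed family (`"gn2"`, a shifted log-normal transform of
#' a Gaussian) whose shape is solved so the population skewness matches its
#' target. Both are standardized so the population mean is exactly 0 and the
#' population variance exactly `variance`.
#'
#' @param n Number of draws.
#' @param family `"gaussian"`, `"gn1"` or `"gn2"`.
#' @param variance Target variance (exact in population).
#' @param skewness Target skewness (`"gn2"`; must be 0 for the others).
#' @param kurtosis Target excess kurtosis (`"gn1"`; must be 0 for
#'   `"gaussian"`, not adjustable for `"gn2"`).
#' @return Numeric vector of length `n`.
#' @export
sample_errors <- function(n, family = c("gaussian", "gn1", "gn2"),
                          variance = 1, skewness = 0, kurtosis = 0) {
  family <- match.arg(family)
  if (variance < 0) abort("variance must be >= 0")
  if (variance == 0) return(numeric(n) * 0)
  sdv <- sqrt(variance)
  if (family == "gaussian") {
    if (skewness != 0 || kurtosis != 0) {
      abort("the Gaussian family has skewness 0 and excess kurtosis 0")
    }
    return(rnorm(n, sd = sdv))
  }
  if (family == "gn1") {
    if (skewness != 0) {
      abort("gn1 (exponential power) is symmetric; target skewness must be 0")
    }
    if (kurtosis <= gn1_excess_kurtosis(60) || kurtosis > gn1_excess_kurtosis(0.3)) {
      abort(paste0("gn1 excess kurtosis must lie in (",
                   signif(gn1_excess_kurtosis(60), 3), ", ",
                   signif(gn1_excess_kurtosis(0.3), 3), "]"))
    }
    beta <- if (kurtosis == 0) 2 else {
      uniroot(function(b) gn1_excess_kurtosis(b) - kurtosis,
              lower = 0.3, upper = 60, tol = 1e-12)$root
    }
    alpha <- sdv * exp(0.5 * (lgamma(1 / beta) - lgamma(3 / beta)))
    g <- rgamma(n, shape = 1 / beta, scale = 1)
    sign <- ifelse(runif(n) < 0.5, -1, 1)
    return(sign * alpha * g^(1 / beta))
  }
  # gn2: X = xi + (alpha/kappa) (1 - exp(-kappa Z)), Z ~ N(0,1)
  if (kurtosis != 0) {
    abort("gn2 controls skewness; its kurtosis follows from the shape and cannot be targeted")
  }
  if (skewness == 0) return(rnorm(n, sd = sdv))
  lognormal_skew <- function(w) (exp(w) + 2) * sqrt(exp(w) - 1)
  w <- uniroot(function(w) lognormal_skew(w) - abs(skewness),
               lower = 1e-10, upper = 20, tol = 1e-12)$root
  kappa <- -sign(skewness) * sqrt(w)
  # X = c - (alpha/kappa) exp(-kappa Z); scale for exact population variance
  scale <- sdv / sqrt(exp(w) * (exp(w) - 1))
  z <- rnorm(n)
  x <- -sign(kappa) * scale * exp(-kappa * z)
  x - mean_gn2(kappa, scale)
}

mean_gn2 <- function(kappa, scale) {
  -sign(kappa) * scale * exp(kappa^2 / 2)
}

#' Simulate an ensemble of structural trajectories
#'
#' Generates ground-truth subject trajectories from the two-level model:
#' subject coefficients are drawn around the (per-group) second-level means
#' with the configured between-subject variances, scan ages follow the
#' acquisition design, and measurement noise is added. The exact parameters
#' used are attached as attribute `"truth"`.
#'
#' @param config A [sim_config()].
#' @return A [traj_data] object (reference age = interval midpoint) with
#'   attribute `"truth"`: `theta1` (subjects x coefficients), `theta2`
#'   (per-group means), `lambda` (log variances, `-Inf` for zero variance),
#'   `sigma2`, `Z`, `config` and the `seed` used.
#' @examples
#' sim <- simulate_ensemble(sim_config(n_subjects = 10, seed = 42))
#' attr(sim, "truth")$theta2
#' @export
simulate_ensemble <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$n_subjects
  K <- ncol(config$mean_params)
  G <- length(config$group_sizes)
  group_of <- rep(seq_len(G), times = config$group_sizes)
  ages <- sample_design(config)
  t_r <- mean(config$interval)

  # covariates: standard normal per subject, exactly centred
  Zeff <- config$covariate_effects
  Z <- NULL
  if (!is.null(Zeff)) {
    Zeff <- as.matrix(Zeff)
    if (ncol(Zeff) != K) {
      abort("covariate_effects needs one column per trajectory coefficient")
    }
    R <- nrow(Zeff)
    Z <- matrix(rnorm(N * R), N, R)
    Z <- sweep(Z, 2, colMeans(Z))
    if (is.null(rownames(Zeff))) rownames(Zeff) <- paste0("z", seq_len(R))
    colnames(Z) <- rownames(Zeff)
  }

  lvl2_family <- if (config$error_level == "second") config$error_family else "gaussian"
  lvl1_family <- if (config$error_level == "first") config$error_family else "gaussian"
  skw <- function(fam) if (fam == "gaussian") 0 else config$skewness
  krt <- function(fam) if (fam == "gaussian") 0 else config$kurtosis

  theta1 <- matrix(0, N, K)
  for (d in seq_len(K)) {
    mu_d <- config$mean_params[group_of, d]
    if (!is.null(Z)) mu_d <- mu_d + as.numeric(Z %*% Zeff[, d])
    eps_d <- numeric(N)
    for (g in seq_len(G)) {
      idx <- which(group_of == g)
      eps_d[idx] <- sample_errors(length(idx), lvl2_family,
                                  variance = config$var_params[g, d],
                                  skewness = skw(lvl2_family),
                                  kurtosis = krt(lvl2_family))
    }
    theta1[, d] <- mu_d + eps_d
  }

  m_i <- lengths(ages)
  subj_rep <- rep(seq_len(N), times = m_i)
  age_all <- unlist(ages, use.names = FALSE)
  tc <- age_all - t_r
  basis <- outer(tc, 0:(K - 1), `^`)
  g_t <- rowSums(basis * theta1[subj_rep, , drop = FALSE])
  scans <- tibble(
    subject = sprintf("s%06d", subj_rep),
    age = age_all,
    value = g_t,
    group = paste0("g", group_of[subj_rep])
  )
  scans$value <- scans$value +
    sample_errors(nrow(scans), lvl1_family, variance = config$noise_sd^2,
                  skewness = skw(lvl1_family), kurtosis = krt(lvl1_family))
  if (!is.null(Z)) {
    first <- match(unique(scans$subject), scans$subject)
    for (cv in colnames(Z)) {
      scans[[cv]] <- Z[match(scans$subject, scans$subject[first]), cv]
    }
  }

  out <- traj_data(scans,
                   group = if (G > 1) "group" else NULL,
                   covariates = colnames(Z),
                   ref_age = t_r)
  rownames(config$mean_params) <- paste0("g", seq_len(G))
  attr(out, "truth") <- list(
    theta1 = theta1,
    theta2 = config$mean_params,
    covariate_effects = Zeff,
    lambda = log(config$var_params),
    sigma2 = config$noise_sd^2,
    Z = Z,
    ref_age = t_r,
    config = config,
    seed = config$seed
  )
  out
}

#' Noise-variance schedule for the accuracy experiments
#'
#' The measurement-noise variance at level `p` of the simulation schedule:
#' \eqn{\sigma^2 = 0.01 / (1 + 25 (p - 1)^2)}, `p = 1, ..., 10`.
#'
#' @param p Noise level (1 = largest variance, 0.01).
#' @return Noise variance.
#' @export
noise_schedule <- function(p) 0.01 / (1 + 25 * (p - 1)^2)

#' Summary-statistic comparator
#'
#' The classical two-stage analysis: an independent ordinary least-squares
#' line per subject, then a one-sample t test of the subject slopes against
#' zero (one-sided for decline by default).
#'
#' @param data A data frame or [traj_data]; every subject needs at least two
#'   scans at distinct ages.
#' @param alternative Direction of the slope test (default `"less"`:
#'   decline).
#' @param ... Passed to [traj_data()] for raw data frames.
#' @return A one-row tibble: `mean_slope`, `statistic`, `df`, `p_value`, and
#'   the per-subject `slopes` as a list column.
#' @export
summary_statistic_test <- function(data, alternative = "less", ...) {
  data <- traj_data(data, ...)
  if (any(data$scans_per_subject < 2)) {
    abort("summary statistic undefined: every subject needs >= 2 scans")
  }
  si <- data$scans$subject_index
  slopes <- vapply(seq_len(data$n_subjects), function(i) {
    rows <- which(si == i)
    tc <- data$scans$age_c[rows]
    yv <- data$scans$value[rows]
    vt <- sum((tc - mean(tc))^2)
    if (vt <= 0) {
      abort(paste0("subject ", data$subject_levels[i],
                   " has no age spread; slope undefined"))
    }
    sum((tc - mean(tc)) * (yv - mean(yv))) / vt
  }, 0)
  tt <- t.test(slopes, alternative = alternative)
  tibble(
    mean_slope = mean(slopes),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    slopes = list(slopes)
  )
}

#' Empirical false-positive calibration of posterior probability maps
#'
#' Fits the trajectory model to many null units (no true effect for the
#' tested contrast), computes the exceedance probability of the contrast for
#' each unit, and reports the fraction of suprathreshold units over a grid of
#' probability thresholds. Null units are either simulated directly under a
#' zero effect (default) or produced by permuting whole-subject response
#' blocks of a supplied dataset against its design.
#'
#' @param config A [sim_config()] describing the null ensemble (its slope
#'   mean should be 0 for the default slope contrast).
#' @param n_units Number of independent null units.
#' @param contrast,gamma Contrast passed to [ppm()]; default `c(slope = -1)`,
#'   the one-sided test for decline.
#' @param p_t Probability threshold grid (default `c(0.8, 0.9, 0.95, 0.99)`).
#' @param spec Model specification used for fitting.
#' @param mode `"simulate"` (default) or `"permute"`.
#' @param data For `mode = "permute"`: the dataset whose subject response
#'   blocks are permuted (among subjects with equal scan counts).
#' @param seed Random seed.
#' @param prior,control Passed to the fitter.
#' @return A list of class `traj_fpr`: `calibration` tibble (`p_t`, `fpr`),
#'   per-unit exceedance `probs`, `n_units`, and the number of excluded
#'   (non-converged) units.
#' @export
empirical_fpr <- function(config = sim_config(mean_params = c(1.2, 0)),
                          n_units = 100,
                          contrast = c(slope = -1), gamma = 0,
                          p_t = c(0.8, 0.9, 0.95, 0.99),
                          spec = traj_spec(1),
                          mode = c("simulate", "permute"), data = NULL,
                          seed = NULL,
                          prior = traj_prior(), control = traj_control()) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  probs <- rep(NA_real_, n_units)
  excluded <- 0L
  if (mode == "simulate") {
    cfg <- config
    cfg$seed <- NULL
    for (u in seq_len(n_units)) {
      sim <- simulate_ensemble(cfg)
      fit <- fit_trajectories(sim, spec = spec, prior = prior,
                              control = control)
      if (!fit$converged) {
        excluded <- excluded + 1L
        next
      }
      probs[u] <- ppm(fit, contrast, gamma = gamma)$prob
    }
  } else {
    if (is.null(data)) abort("permutation mode needs a dataset")
    data <- traj_data(data)
    for (u in seq_len(n_units)) {
      perm <- permute_subject_blocks(data)
      fit <- fit_trajectories(perm, spec = spec, prior = prior,
                              control = control)
      if (!fit$converged) {
        excluded <- excluded + 1L
        next
      }
      probs[u] <- ppm(fit, contrast, gamma = gamma)$prob
    }
  }
  ok <- probs[!is.na(probs)]
  calibration <- tibble(
    p_t = p_t,
    fpr = vapply(p_t, function(pt) mean(ok > pt), 0)
  )
  structure(
    list(calibration = calibration, probs = probs,
         n_units = n_units, n_excluded = excluded),
    class = "traj_fpr"
  )
}

# permute whole-subject response blocks against the design, within strata of
# equal scans-per-subject
permute_subject_blocks <- function(data) {
  scans <- data$scans
  si <- scans$subject_index
  new_value <- scans$value
  for (m in unique(data$scans_per_subject)) {
    subjects <- which(data$scans_per_subject == m)
    if (length(subjects) < 2) next
    perm <- sample(subjects)
    for (j in seq_along(subjects)) {
      new_value[si == subjects[j]] <- scans$value[si == perm[j]]
    }
  }
  scans$value <- new_value
  traj_data(scans, group = NULL, covariates = data$covariate_names,
            ref_age = data$ref_age)
}

#' @export
print.traj_fpr <- function(x, ...) {
  cat("<traj_fpr> ", x$n_units, " null units (",
      x$n_excluded, " excluded)\n", sep = "")
  print(as.data.frame(x$calibration), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Parameter-recovery accuracy over noise levels
#'
#' Replicates the accuracy experiment at configurable scale: simulate an
#' ensemble, fit it, and accumulate root-mean-squared errors of the
#' first-level (per-subject) and second-level (group) intercept and slope
#' against the ground truth, averaged over replicates, for each level of the
#' noise schedule [noise_schedule()].
#'
#' @param config Base [sim_config()] (its `noise_sd` is overridden by the
#'   schedule unless `noise_levels` is `NULL`).
#' @param noise_levels Noise schedule levels `p` (default `c(1, 4, 7, 10)`);
#'   `NULL` keeps the configured `noise_sd` (reported as level `NA`).
#' @param replicates Replicates per level (desk-scale default 20).
#' @param spec Model specification for fitting.
#' @param seed Random seed.
#' @param prior,control Passed to the fitter.
#' @return A tibble with `noise_level`, `sigma2`, `level`
#'   (`"first"`/`"second"`), `coef`, and `rmse`.
#' @export
rmse_experiment <- function(config = sim_config(),
                            noise_levels = c(1, 4, 7, 10),
                            replicates = 20, spec = traj_spec(1),
                            seed = NULL,
                            prior = traj_prior(), control = traj_control()) {
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(config$mean_params)
  if (spec$degree + 1L != K) {
    abort("rmse_experiment compares like with like: spec degree must match the true degree")
  }
  labels <- coef_label(0:(K - 1))
  if (is.null(noise_levels)) noise_levels <- NA_real_
  purrr::map_dfr(noise_levels, function(p) {
    s2 <- if (is.na(p)) config$noise_sd^2 else noise_schedule(p)
    cfg <- config
    cfg$noise_sd <- sqrt(s2)
    cfg$seed <- NULL
    se1 <- matrix(0, replicates, K)
    se2 <- matrix(0, replicates, K)
    for (r in seq_len(replicates)) {
      sim <- simulate_ensemble(cfg)
      truth <- attr(sim, "truth")
      fit <- fit_trajectories(sim, spec = spec, prior = prior,
                              control = control)
      ft <- fitted_trajectories(fit)
      est1 <- matrix(ft$estimate, ncol = K, byrow = TRUE)
      se1[r, ] <- colMeans((est1 - truth$theta1)^2)
      # group means (single- or multi-group)
      est2 <- t(vapply(seq_len(sim$n_groups), function(g) {
        pre <- if (sim$n_groups == 1) "" else paste0(sim$group_levels[g], ":")
        fit$posterior$theta2[paste0(pre, labels)]
      }, numeric(K)))
      se2[r, ] <- colMeans((est2 - truth$theta2)^2)
    }
    purrr::map_dfr(seq_len(K), function(d) {
      tibble(noise_level = p, sigma2 = s2,
             level = c("first", "second"),
             coef = labels[d],
             rmse = c(sqrt(mean(se1[, d])), sqrt(mean(se2[, d]))))
    })
  })
}
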