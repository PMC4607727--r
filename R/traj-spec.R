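#' Specify a trajectory model
#'
#' A trajectory model is a polynomial in centred age with per-subject random
#' coefficients up to degree `degree` and, optionally, additional fixed-effect
#' terms (identical across subjects) for degrees `degree + 1` to
#' `fixed_degree`. Fixed effects are implemented hierarchically: their
#' second-level error variance is clamped to a very small constant so that the
#' first- and second-level fixed-effect parameters coincide.
#'
#' @param degree Degree `D` of random effects (0 = random intercept only,
#'   1 = random intercept and slope, ...).
#' @param fixed_degree Degree `D_f >= D` of fixed effects; equal to `degree`
#'   means no extra fixed-effect terms.
#' @param shared_covariates Logical; when several groups are modelled, should
#'   covariate effects be constrained equal across groups (`TRUE`) or
#'   estimated per group (`FALSE`, default)?
#' @param label Optional label used in model-comparison tables.
#' @return An object of class `traj_spec`.
#' @examples
#' traj_spec(degree = 1)                    # random intercept + slope
#' traj_spec(degree = 0, fixed_degree = 1)  # random intercept, fixed slope
#' @export
traj_spec <- function(degree = 1, fixed_degree = degree,
                      shared_covariates = FALSE, label = NULL) {
  degree <- as.integer(degree)
  fixed_degree <- as.integer(fixed_degree)
  if (degree < 0) abort("degree must be >= 0")
  if (fixed_degree < degree) {
    abort("fixed_degree must be >= degree (extra fixed effects only extend the polynomial)")
  }
  if (is.null(label)) {
    label <- paste0("D=", degree,
                    if (fixed_degree > degree) paste0(",Df=", fixed_degree))
  }
  structure(
    list(degree = degree, fixed_degree = fixed_degree,
         shared_covariates = isTRUE(shared_covariates), label = label),
    class = "traj_spec"
  )
}

#' @export
print.traj_spec <- function(x, ...) {
  cat("<traj_spec> random degree D=", x$degree,
      ", fixed degree Df=", x$fixed_degree,
      if (x$shared_covariates) ", shared covariate effects", "\n", sep = "")
  invisible(x)
}

#' Top-level prior on group trajectory parameters
#'
#' By default the top-level prior is flat: prior mean zero and an arbitrarily
#' large prior variance `exp(32)` on every second-level parameter, so that the
#' posterior is driven by the data and the estimated empirical priors.
#' An informative Gaussian prior can be supplied instead.
#'
#' @param mean Prior mean; scalar or vector over second-level parameters.
#' @param variance Prior variance; scalar or vector. Default `exp(32)`.
#' @param fixed_effect_variance Clamped second-level error variance for
#'   fixed-effect parameters; default `exp(-32)`. This is a configuration
#'   constant, not an estimated hyperparameter.
#' @return An object of class `traj_prior`.
#' @export
traj_prior <- function(mean = 0, variance = exp(32),
                       fixed_effect_variance = exp(-32)) {
  if (any(variance <= 0) || fixed_effect_variance <= 0) {
    abort("prior variances must be positive")
  }
  structure(list(mean = mean, variance = variance,
                 fixed_effect_variance = fixed_effect_variance),
            class = "traj_prior")
}

#' EM optimizer settings
#'
#' @param max_iter Maximum number of EM iterations (default 64).
#' @param tol_f Relative free-energy convergence tolerance: stop when the
#'   free-energy increase falls below `tol_f * max(1, |F|)` (default 1e-6).
#' @param tol_lambda Hyperparameter convergence tolerance on the largest
#'   absolute log-variance update (default 1e-3).
#' @param max_step Cap on each |Fisher-scoring step| in log-variance units
#'   (default 8); steps are halved (at most `max_halvings` times) while the
#'   free energy decreases.
#' @param max_halvings Maximum number of step halvings (default 6).
#' @param lambda_floor,lambda_ceiling Bounds on log variances; degenerate
#'   (zero-variance) components converge to the floor rather than diverging.
#' @param verbose Print the free-energy trace while fitting.
#' @return An object of class `traj_control`.
#' @export
traj_control <- function(max_iter = 64, tol_f = 1e-6, tol_lambda = 1e-3,
                         max_step = 8, max_halvings = 6,
                         lambda_floor = -32, lambda_ceiling = 32,
                         verbose = FALSE) {
  structure(list(max_iter = max_iter, tol_f = tol_f, tol_lambda = tol_lambda,
                 max_step = max_step, max_halvings = max_halvings,
                 lambda_floor = lambda_floor, lambda_ceiling = lambda_ceiling,
                 verbose = isTRUE(verbose)),
            class = "traj_control")
}

#' Read model settings from a key-value configuration file
#'
#' Reads a YAML (key: value) file and returns the corresponding
#' [traj_spec()], [traj_prior()] and [traj_control()] objects plus any data
#' column settings. Recognised keys: `degree`, `fixed_degree`,
#' `shared_covariates`, `covariates`, `ref_age`, `prior_mean`,
#' `prior_variance`, `fixed_effect_variance`, and any [traj_control()]
#' argument.
#'
#' @param file Path to a YAML configuration file.
#' @return A list with elements `spec`, `prior`, `control`, `covariates`,
#'   `ref_age`.
#' @export
read_traj_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  spec <- traj_spec(
    degree = cfg$degree %||% 1,
    fixed_degree = cfg$fixed_degree %||% cfg$degree %||% 1,
    shared_covariates = cfg$shared_covariates %||% FALSE
  )
  prior <- traj_prior(
    mean = cfg$prior_mean %||% 0,
    variance = cfg$prior_variance %||% exp(32),
    fixed_effect_variance = cfg$fixed_effect_variance %||% exp(-32)
  )
  ctrl_args <- cfg[intersect(names(cfg), names(formals(traj_control)))]
  control <- do.call(traj_control, ctrl_args)
  list(spec = spec, prior = prior, control = control,
       covariates = cfg$covariates, ref_age = cfg$ref_age)
}
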