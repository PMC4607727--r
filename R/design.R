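coef_label <- function(d) {
  # d is the polynomial degree of the term (0-based)
  lab <- c("intercept", "slope", "quadratic", "cubic")
  ifelse(d < length(lab), lab[pmin(d, length(lab) - 1) + 1],
         paste0("degree", d))
}

#' Build the first-level (within-subject) design matrix
#'
#' The first level regresses each subject's scans on raw powers of centred
#' age: subject block entry \eqn{(j, d) = (t_{ij} - t_r)^{d-1}} for
#' \eqn{d = 1, \dots, D+1}. Blocks are arranged block-diagonally in
#' person-scan order. When `fixed_degree > degree`, global fixed-effect
#' columns holding \eqn{(t_{ij}-t_r)^d}, \eqn{d = D+1, \dots, D_f}, are
#' appended (one set per group when several groups are modelled).
#'
#' @param data A [traj_data] object (or a data frame passed to [traj_data()]).
#' @param spec A [traj_spec] object.
#' @return A sparse `M x P1` design matrix (`P1 = N(D+1) + ` fixed columns),
#'   with column metadata in attributes `"n_random"` and `"fixed_cols"`.
#' @export
build_first_level_design <- function(data, spec) {
  data <- traj_data(data)
  stopifnot(inherits(spec, "traj_spec"))
  D <- spec$degree
  Df <- spec$fixed_degree
  M <- data$n_scans
  N <- data$n_subjects
  tc <- data$scans$age_c
  si <- data$scans$subject_index

  few <- which(data$scans_per_subject < D + 1)
  if (length(few) > 0) {
    warn(paste0(length(few), " subject(s) have fewer than D+1 = ", D + 1,
                " scans; their coefficients are informed mainly by the ",
                "group-level empirical prior"))
  }

  # random-effect block diagonal: row r of subject i, degrees 0..D
  deg <- 0:D
  i_idx <- rep(seq_len(M), each = D + 1)
  j_idx <- as.vector(vapply(seq_len(M), function(r) {
    (si[r] - 1L) * (D + 1L) + seq_len(D + 1L)
  }, integer(D + 1)))
  x_val <- as.vector(vapply(seq_len(M), function(r) tc[r]^deg,
                            numeric(D + 1)))

  n_random <- N * (D + 1L)
  # fixed-effect columns for degrees D+1..Df (per group when G > 1)
  G <- data$n_groups
  per_group_fixed <- G > 1
  fixed_degs <- if (Df > D) seq(D + 1L, Df) else integer(0)
  n_fix <- length(fixed_degs) * (if (per_group_fixed) G else 1L)
  fixed_cols <- character(0)
  if (n_fix > 0) {
    grp_row <- data$group_of[si]
    col <- n_random
    for (g in (if (per_group_fixed) seq_len(G) else 1L)) {
      rows <- if (per_group_fixed) which(grp_row == g) else seq_len(M)
      for (d in fixed_degs) {
        col <- col + 1L
        i_idx <- c(i_idx, rows)
        j_idx <- c(j_idx, rep(col, length(rows)))
        x_val <- c(x_val, tc[rows]^d)
        fixed_cols <- c(fixed_cols, paste0(
          if (per_group_fixed) paste0(data$group_levels[g], ":"),
          "fixed:", coef_label(d)))
      }
    }
  }

  X1 <- sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                     dims = c(M, n_random + n_fix))
  attr(X1, "n_random") <- n_random
  attr(X1, "fixed_cols") <- fixed_cols
  X1
}

#' Build the second-level (between-subject) design matrix
#'
#' Maps group-level parameters to the expected subject coefficients. For a
#' single group the random part is \eqn{[1_N\ Z] \otimes I_{D+1}}; for
#' several groups each group receives its own ones column (and, by default,
#' its own covariate columns). Fixed-effect parameters map to themselves via
#' an identity block.
#'
#' @inheritParams build_first_level_design
#' @return A sparse `P1 x P2` matrix with attribute `"theta2_names"`.
#' @export
build_second_level_design <- function(data, spec) {
  data <- traj_data(data)
  stopifnot(inherits(spec, "traj_spec"))
  D <- spec$degree
  G <- data$n_groups
  N <- data$n_subjects
  R <- length(data$covariate_names)
  Z <- data$Z
  if (R > 0) {
    cm <- abs(colMeans(Z))
    if (any(cm > 1e-10)) {
      abort(paste0("covariate(s) ",
                   paste(data$covariate_names[cm > 1e-10], collapse = ", "),
                   " are not centred; centre them (traj_data() does this ",
                   "automatically)"))
    }
  }

  shared <- spec$shared_covariates || G == 1
  K <- D + 1L
  n_random_rows <- N * K
  # column layout: per group [mean block, (covariate blocks if per-group)],
  # then shared covariate blocks, then fixed identity
  blocks_per_group <- 1L + if (shared) 0L else R
  p2_random <- G * blocks_per_group * K + (if (shared) R else 0L) * K

  theta2_names <- character(0)
  i_idx <- integer(0); j_idx <- integer(0); x_val <- numeric(0)
  col0 <- 0L
  gl <- data$group_levels
  prefix <- function(g) if (G == 1) "" else paste0(gl[g], ":")
  add_block <- function(subjects, values, col0) {
    # values: one scalar per subject; block is value * I_K at column col0
    rows <- as.vector(vapply(subjects, function(i) (i - 1L) * K + seq_len(K),
                             integer(K)))
    cols <- rep(col0 + seq_len(K), times = length(subjects))
    list(i = rows, j = cols, x = rep(values, each = K))
  }
  for (g in seq_len(G)) {
    subj_g <- which(data$group_of == g)
    b <- add_block(subj_g, rep(1, length(subj_g)), col0)
    i_idx <- c(i_idx, b$i); j_idx <- c(j_idx, b$j); x_val <- c(x_val, b$x)
    theta2_names <- c(theta2_names, paste0(prefix(g), coef_label(0:D)))
    col0 <- col0 + K
    if (!shared) {
      for (r in seq_len(R)) {
        b <- add_block(subj_g, Z[subj_g, r], col0)
        i_idx <- c(i_idx, b$i); j_idx <- c(j_idx, b$j); x_val <- c(x_val, b$x)
        theta2_names <- c(theta2_names,
                          paste0(prefix(g), data$covariate_names[r], ":",
                                 coef_label(0:D)))
        col0 <- col0 + K
      }
    }
  }
  if (shared && R > 0) {
    for (r in seq_len(R)) {
      b <- add_block(seq_len(N), Z[, r], col0)
      i_idx <- c(i_idx, b$i); j_idx <- c(j_idx, b$j); x_val <- c(x_val, b$x)
      theta2_names <- c(theta2_names,
                        paste0(data$covariate_names[r], ":", coef_label(0:D)))
      col0 <- col0 + K
    }
  }

  # fixed-effect identity block (Df > D)
  X1 <- NULL
  Df <- spec$fixed_degree
  per_group_fixed <- G > 1
  n_fix <- (Df - D) * (if (per_group_fixed) G else 1L)
  if (n_fix > 0) {
    i_idx <- c(i_idx, n_random_rows + seq_len(n_fix))
    j_idx <- c(j_idx, col0 + seq_len(n_fix))
    x_val <- c(x_val, rep(1, n_fix))
    fixed_degs <- seq(D + 1L, Df)
    fix_names <- if (per_group_fixed) {
      as.vector(sapply(seq_len(G), function(g)
        paste0(gl[g], ":fixed:", coef_label(fixed_degs))))
    } else {
      paste0("fixed:", coef_label(fixed_degs))
    }
    theta2_names <- c(theta2_names, fix_names)
    col0 <- col0 + n_fix
  }

  X2 <- sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                     dims = c(n_random_rows + n_fix, col0))
  attr(X2, "theta2_names") <- theta2_names
  X2
}

#' Build the covariance basis set
#'
#' The error covariances are parameterized as non-negative combinations of
#' known diagonal basis matrices: one isotropic first-level basis \eqn{I_M}
#' for measurement noise, and, for the second level, one diagonal indicator
#' per trajectory coefficient per group selecting that coefficient's slot for
#' every subject of the group. The fixed-effect slots are not free
#' hyperparameters; their variance is clamped (see [traj_prior()]).
#'
#' @inheritParams build_first_level_design
#' @return A list with `first_level` (indices `1:M`), `second_level` (a list
#'   of bases, each with `group`, `coef`, `indices` into the subject
#'   coefficient slot space of dimension `N(D+1)`), `clamped` (fixed-effect
#'   slot indices) and `n_hyper` (`1 + G(D+1)` free hyperparameters).
#' @export
build_covariance_bases <- function(spec, data) {
  data <- traj_data(data)
  stopifnot(inherits(spec, "traj_spec"))
  D <- spec$degree
  K <- D + 1L
  G <- data$n_groups
  N <- data$n_subjects
  second <- list()
  for (g in seq_len(G)) {
    subj_g <- which(data$group_of == g)
    for (d in seq_len(K)) {
      second[[length(second) + 1L]] <- list(
        group = g,
        coef = coef_label(d - 1L),
        label = paste0(if (G > 1) paste0(data$group_levels[g], ":"),
                       coef_label(d - 1L)),
        indices = (subj_g - 1L) * K + d
      )
    }
  }
  per_group_fixed <- G > 1
  n_fix <- (spec$fixed_degree - D) * (if (per_group_fixed) G else 1L)
  list(
    first_level = list(indices = seq_len(data$n_scans), dim = data$n_scans),
    second_level = second,
    slot_dim = N * K,
    clamped = if (n_fix > 0) N * K + seq_len(n_fix) else integer(0),
    n_hyper = 1L + G * K
  )
}

#' Build the complete design system for a trajectory model
#'
#' Bundles the first- and second-level design matrices and the covariance
#' basis set for one dataset/model pair.
#'
#' @inheritParams build_first_level_design
#' @return An object of class `traj_design`.
#' @export
build_design <- function(data, spec) {
  data <- traj_data(data)
  X1 <- build_first_level_design(data, spec)
  X2 <- build_second_level_design(data, spec)
  bases <- build_covariance_bases(spec, data)
  P1 <- ncol(X1)
  P2 <- ncol(X2)
  stopifnot(nrow(X2) == P1)
  structure(
    list(X1 = X1, X2 = X2, bases = bases, spec = spec,
         theta2_names = attr(X2, "theta2_names"),
         dims = list(M = data$n_scans, N = data$n_subjects,
                     P1 = P1, P2 = P2,
                     n_random = attr(X1, "n_random"),
                     D = spec$degree, Df = spec$fixed_degree,
                     G = data$n_groups),
         group_levels = data$group_levels,
         subject_levels = data$subject_levels),
    class = "traj_design"
  )
}

#' @export
print.traj_design <- function(x, ...) {
  d <- x$dims
  cat("<traj_design> M=", d$M, " scans, N=", d$N, " subjects, D=", d$D,
      ", Df=", d$Df, ", G=", d$G, "\n", sep = "")
  cat("  X1: ", d$M, "x", d$P1, "; X2: ", d$P1, "x", d$P2,
      "; free hyperparameters: ", x$bases$n_hyper, "\n", sep = "")
  invisible(x)
}

#' Augment the two-level model into a single linear system
#'
#' Rearranges the hierarchical model into non-hierarchical form by treating
#' the second-level errors as parameters, and appends pseudo-observation rows
#' for their zero prior expectation and for the top-level prior mean. The
#' augmented error covariance then carries every covariance component of the
#' model: measurement noise, between-subject covariance, the clamped
#' fixed-effect variance and the top-level prior covariance.
#'
#' @param design A [build_design()] result.
#' @param y Response vector in person-scan order (defaults to the `value`
#'   column of `data`).
#' @param data The [traj_data] the design was built from (needed only when
#'   `y` is not given).
#' @param prior A [traj_prior()]; flat by default.
#' @return An object of class `traj_augmented`: augmented response `ybar`
#'   (length `M + P1 + P2`), sparse augmented design `Xbar`, the index sets of
#'   each free variance component in augmented-row space, clamped/prior rows
#'   and their variances.
#' @export
augment_system <- function(design, y = NULL, data = NULL,
                           prior = traj_prior()) {
  stopifnot(inherits(design, "traj_design"))
  d <- design$dims
  if (is.null(y)) {
    if (is.null(data)) abort("supply y or data")
    data <- traj_data(data)
    y <- data$scans$value
  }
  if (length(y) != d$M) {
    abort(paste0("response length ", length(y),
                 " does not match design rows ", d$M))
  }
  if (!all(is.finite(y))) abort("non-finite response values")

  M <- d$M; P1 <- d$P1; P2 <- d$P2
  n <- M + P1 + P2
  prior_mean <- rep_len(prior$mean, P2)
  prior_var <- rep_len(prior$variance, P2)
  ybar <- c(y, rep(0, P1), prior_mean)

  X12 <- design$X1 %*% design$X2
  Xbar <- rbind(
    cbind(design$X1, X12),
    cbind(Diagonal(P1), sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(P1, P2))),
    cbind(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(P2, P1)), Diagonal(P2))
  )
  Xbar <- methods::as(Xbar, "CsparseMatrix")

  bases <- design$bases
  sets <- c(
    list(list(label = "noise", level = 1L, indices = seq_len(M))),
    lapply(bases$second_level, function(b) {
      list(label = b$label, level = 2L, indices = M + b$indices)
    })
  )

  structure(
    list(ybar = ybar, Xbar = Xbar, sets = sets,
         clamped_rows = M + bases$clamped,
         clamped_var = prior$fixed_effect_variance,
         prior_rows = M + P1 + seq_len(P2),
         prior_var = prior_var,
         design = design,
         dims = list(n = n, M = M, P1 = P1, P2 = P2,
                     p = P1 + P2, n_hyper = length(sets))),
    class = "traj_augmented"
  )
}
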