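#' Assemble a longitudinal trajectory dataset
#'
#' Validates and arranges a scans table (one row per scan) into the
#' person-scan order required by the trajectory model: all scans of the first
#' subject, then all scans of the second, and so on. Ages are centred at a
#' reference age and subject-level covariates are mean-centred.
#'
#' @param data A data frame with one row per scan.
#' @param subject Name of the subject-identifier column.
#' @param age Name of the acquisition-age column (years).
#' @param value Name of the response column (local tissue volume/density in
#'   arbitrary units), or `NULL` when responses are supplied separately (as in
#'   the voxelwise runner).
#' @param group Name of the group-label column (one label per subject), or
#'   `NULL` for a single group.
#' @param covariates Character vector of subject-level covariate columns.
#'   Covariates must be constant within subject; they are mean-centred across
#'   subjects (globally, not per group).
#' @param ref_age Reference age \eqn{t_r} (years) at which trajectories are
#'   developed. Defaults to the mean age over all scans.
#'
#' @return An object of class `traj_data`: a list with the arranged `scans`
#'   tibble (columns `subject`, `subject_index`, `age`, `age_c`, `value`,
#'   `group`, covariates), subject bookkeeping (`n_subjects`, `n_scans`,
#'   `scans_per_subject`, `group_of`), the centred covariate matrix `Z`, and
#'   `ref_age`.
#'
#' @examples
#' scans <- data.frame(
#'   subject = rep(c("s1", "s2"), each = 3),
#'   age     = c(70, 71, 72, 65, 66, 67),
#'   value   = c(1.2, 1.19, 1.18, 1.3, 1.28, 1.27)
#' )
#' td <- traj_data(scans)
#' td
#' @export
traj_data <- function(data, subject = "subject", age = "age", value = "value",
                      group = NULL, covariates = NULL, ref_age = NULL) {
  if (inherits(data, "traj_data")) {
    return(data)
  }
  stopifnot(is.data.frame(data))
  need <- c(subject, age, if (!is.null(value)) value, group, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("scans table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  scans <- tibble(
    subject = as.character(data[[subject]]),
    age     = as.numeric(data[[age]])
  )
  scans$value <- if (is.null(value)) NA_real_ else as.numeric(data[[value]])
  bad_age <- which(!is.finite(scans$age))
  if (length(bad_age) > 0) {
    abort(paste0("non-finite age at scan row(s) ",
                 paste(head(bad_age, 5), collapse = ", "),
                 " (subject ", scans$subject[bad_age[1]], ")"))
  }
  if (!is.null(value) && anyNA(scans$value)) {
    abort("non-finite response values; drop or impute these scans first")
  }

  scans$group <- if (is.null(group)) {
    factor(rep("all", nrow(scans)))
  } else {
    factor(as.character(data[[group]]))
  }
  for (cv in covariates) scans[[cv]] <- as.numeric(data[[cv]])

  # person-scan order: subjects in order of first appearance, scan order kept
  subj_levels <- unique(scans$subject)
  scans$subject <- factor(scans$subject, levels = subj_levels)
  ord <- order(as.integer(scans$subject))
  scans <- scans[ord, , drop = FALSE]
  scans$subject_index <- as.integer(scans$subject)

  n_subjects <- length(subj_levels)
  m_i <- as.integer(table(scans$subject))

  # per-subject group and covariates must be constant within subject
  first_row <- match(seq_len(n_subjects), scans$subject_index)
  group_of <- scans$group[first_row]
  if (!all(scans$group == group_of[scans$subject_index])) {
    abort("group label varies within subject; one group per subject required")
  }
  Z <- NULL
  cov_means <- NULL
  if (length(covariates) > 0) {
    Z <- sapply(covariates, function(cv) {
      v <- scans[[cv]][first_row]
      if (!all(is.finite(v))) abort(paste0("non-finite covariate '", cv, "'"))
      within_ok <- tapply(scans[[cv]], scans$subject_index,
                          function(x) max(x) - min(x) < 1e-12)
      if (!all(within_ok)) {
        abort(paste0("covariate '", cv, "' varies within subject; ",
                     "first-level covariates are not supported"))
      }
      v
    })
    Z <- matrix(Z, nrow = n_subjects,
                dimnames = list(NULL, covariates))
    cov_means <- colMeans(Z)
    Z <- sweep(Z, 2, cov_means)
    for (cv in covariates) {
      scans[[cv]] <- Z[scans$subject_index, cv]
    }
  }

  if (is.null(ref_age)) ref_age <- mean(scans$age)
  if (!is.finite(ref_age)) abort("ref_age must be finite")
  scans$age_c <- scans$age - ref_age

  scans <- scans[, c("subject", "subject_index", "age", "age_c", "value",
                     "group", covariates)]

  structure(
    list(
      scans = as_tibble(scans),
      n_subjects = n_subjects,
      n_scans = nrow(scans),
      scans_per_subject = m_i,
      subject_levels = subj_levels,
      group_levels = levels(group_of),
      group_of = as.integer(group_of),
      n_groups = nlevels(group_of),
      covariate_names = covariates %||% character(0),
      covariate_means = cov_means,
      Z = Z,
      ref_age = ref_age
    ),
    class = "traj_data"
  )
}

#' @export
print.traj_data <- function(x, ...) {
  cat("<traj_data> ", x$n_scans, " scans of ", x$n_subjects, " subjects",
      if (x$n_groups > 1) paste0(" in ", x$n_groups, " groups"), "\n", sep = "")
  cat("  scans per subject: ", paste(range(x$scans_per_subject), collapse = "-"),
      "; reference age: ", signif(x$ref_age, 4), " y\n", sep = "")
  if (length(x$covariate_names) > 0) {
    cat("  covariates (centred): ",
        paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read a scans table from delimited text
#'
#' Thin wrapper around [utils::read.table()] that feeds [traj_data()].
#' The file must contain columns `subject` and `age`; `value`, `group` and
#' covariate columns are picked up when present.
#'
#' @param file Path to a delimited text file with a header row.
#' @param sep Field separator (default tab; `","` for CSV).
#' @inheritParams traj_data
#' @return A [traj_data] object.
#' @export
read_scans_table <- function(file, sep = "\t", subject = "subject",
                             age = "age", value = "value", group = NULL,
                             covariates = NULL, ref_age = NULL) {
  df <- read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (is.null(group) && "group" %in% names(df)) group <- "group"
  if (!value %in% names(df)) value <- NULL
  traj_data(df, subject = subject, age = age, value = value, group = group,
            covariates = covariates, ref_age = ref_age)
}
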