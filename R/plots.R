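# ggplot2 displays for datasets, fits, calibration and model comparison

#' @method autoplot traj_data
#' @export
autoplot.traj_data <- function(object, ...) {
  scans <- object$scans
  p <- ggplot2::ggplot(scans, ggplot2::aes(x = .data$age, y = .data$value,
                                           group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::labs(x = "age (years)", y = "local volume / density (a.u.)")
  if (object$n_groups > 1) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p
}

#' Plot observed series, subject trajectories and the group mean trajectory
#'
#' @param object A [traj_fit].
#' @param n_subjects Number of subject trajectories drawn (default 30, as
#'   more clutters the display).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot traj_fit
#' @export
autoplot.traj_fit <- function(object, n_subjects = 30, ...) {
  scans <- object$data$scans
  shown <- head(object$design$subject_levels, n_subjects)
  indiv <- predict(object, level = 1)
  grp <- predict(object, level = 2)
  ggplot2::ggplot(grp, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fitted - 2 * .data$std.error,
                                      ymax = .data$fitted + 2 * .data$std.error,
                                      fill = .data$group),
                         alpha = 0.25, show.legend = object$design$dims$G > 1) +
    ggplot2::geom_line(
      data = dplyr::filter(indiv, .data$subject %in% shown),
      ggplot2::aes(y = .data$fitted, group = .data$subject),
      colour = "darkgreen", alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_point(
      data = dplyr::filter(scans, .data$subject %in% shown),
      ggplot2::aes(y = .data$value), size = 0.5, alpha = 0.4,
      colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted, colour = .data$group),
                       linewidth = 1, show.legend = object$design$dims$G > 1) +
    ggplot2::scale_colour_manual(values = rep("firebrick",
                                              object$design$dims$G),
                                 guide = "none") +
    ggplot2::labs(x = "age (years)", y = "local volume / density (a.u.)",
                  title = paste0("trajectories (", object$spec$label, ")"))
}

#' Plot the free-energy trace of an EM fit
#'
#' @param fit A [traj_fit].
#' @return A ggplot object.
#' @export
plot_free_energy <- function(fit) {
  stopifnot(inherits(fit, "traj_fit"))
  df <- tibble(iteration = seq_along(fit$trace) - 1, free_energy = fit$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                   y = .data$free_energy)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "free energy F")
}

#' @method autoplot traj_fpr
#' @export
autoplot.traj_fpr <- function(object, ...) {
  ggplot2::ggplot(object$calibration,
                  ggplot2::aes(x = 1 - .data$p_t, y = .data$fpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "nominal rate (1 - p_t)",
                  y = "empirical false-positive fraction")
}

#' @method autoplot traj_comparison
#' @export
autoplot.traj_comparison <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = stats::reorder(.data$model,
                                                       .data$delta_f),
                                    y = .data$delta_f,
                                    fill = .data$winner)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "log evidence relative to best model")
}
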