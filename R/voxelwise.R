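# Mass-univariate application: the trajectory model at every in-mask voxel
# of coregistered volumes, producing parameter, probability, hyperparameter
# and evidence maps.

#' Assemble an imaging study
#'
#' Pairs a scans table with coregistered volumes: one 3-D NIfTI volume per
#' scans-table row (or a single 4-D volume / array), plus a binary mask on
#' the same grid. All volumes must share grid dimensions and affine (affine
#' entries compared at tolerance 1e-4). When no mask is given, voxels whose
#' sample-mean intensity exceeds `mask_threshold` are analysed (0.1 is the
#' usual grey-matter threshold; 0.4 white matter, 0.2 CSF).
#'
#' @param scans A scans table (data frame or [traj_data]); a `value` column
#'   is not needed.
#' @param images Character vector of NIfTI paths in scans-table order, a
#'   single 4-D NIfTI path, or a 4-D numeric array (x, y, z, scan).
#' @param mask A NIfTI path, a logical/numeric array, or `NULL` (threshold
#'   the sample mean). Non-zero voxels are in-mask.
#' @param mask_threshold Sample-mean threshold used when `mask` is `NULL`.
#' @param ... Passed to [traj_data()] for raw data frames.
#' @return An object of class `image_study`.
#' @export
image_study <- function(scans, images, mask = NULL, mask_threshold = 0.1,
                        ...) {
  data <- traj_data(scans, value = NULL, ...)
  M <- data$n_scans

  template <- NULL
  if (is.character(images)) {
    vols_list <- lapply(images, function(f) {
      img <- tryCatch(RNifti::readNifti(f), error = function(e) {
        abort(paste0("cannot read volume '", f, "': ", conditionMessage(e)))
      })
      img
    })
    template <- vols_list[[1]]
    if (length(vols_list) == 1 && length(dim(vols_list[[1]])) == 4) {
      vols <- unclass(vols_list[[1]])
    } else {
      dims <- dim(vols_list[[1]])
      affine0 <- RNifti::xform(vols_list[[1]])
      for (j in seq_along(vols_list)) {
        if (!identical(dim(vols_list[[j]]), dims)) {
          abort(paste0("volume '", images[j], "' grid ",
                       paste(dim(vols_list[[j]]), collapse = "x"),
                       " differs from ", paste(dims, collapse = "x")))
        }
        if (max(abs(RNifti::xform(vols_list[[j]]) - affine0)) > 1e-4) {
          abort(paste0("volume '", images[j],
                       "' affine differs from the first volume"))
        }
      }
      vols <- array(0, c(dims, length(vols_list)))
      for (j in seq_along(vols_list)) vols[, , , j] <- vols_list[[j]]
    }
  } else {
    vols <- unclass(images)
    if (length(dim(vols)) == 3) dim(vols) <- c(dim(vols), 1L)
  }
  if (length(dim(vols)) != 4) abort("expected 3-D volumes or a 4-D stack")
  if (dim(vols)[4] != M) {
    abort(paste0(dim(vols)[4], " volumes but ", M, " scans-table rows"))
  }
  grid <- dim(vols)[1:3]

  if (is.null(mask)) {
    mean_img <- apply(vols, 1:3, mean)
    mask_arr <- mean_img > mask_threshold
  } else {
    if (is.character(mask)) mask <- unclass(RNifti::readNifti(mask))
    mask_arr <- array(as.logical(mask != 0), dim(mask))
  }
  if (!identical(dim(mask_arr), as.integer(grid)) &&
      !identical(dim(mask_arr), grid)) {
    abort(paste0("mask grid ", paste(dim(mask_arr), collapse = "x"),
                 " does not match volumes ", paste(grid, collapse = "x")))
  }

  structure(
    list(data = data, volumes = vols, mask = mask_arr, grid = grid,
         voxels = which(mask_arr), template = template),
    class = "image_study"
  )
}

#' @export
print.image_study <- function(x, ...) {
  cat("<image_study> grid ", paste(x$grid, collapse = "x"), ", ",
      length(x$voxels), " in-mask voxels, ", x$data$n_scans, " scans of ",
      x$data$n_subjects, " subjects\n", sep = "")
  invisible(x)
}

#' Extract the response series at one voxel
#'
#' Returns the per-scan values at an in-mask voxel in scans-table order.
#' Scans with non-finite values are dropped; the retained scans-table rows
#' are attached as attribute `"scan_rows"`. Out-of-mask or all-missing voxels
#' signal a `traj_voxel_skip` condition.
#'
#' @param study An [image_study].
#' @param voxel Linear voxel index or an `(i, j, k)` triple.
#' @return Numeric response vector with attribute `"scan_rows"`.
#' @export
extract_series <- function(study, voxel) {
  stopifnot(inherits(study, "image_study"))
  if (length(voxel) == 3) {
    voxel <- voxel[1] + (voxel[2] - 1) * study$grid[1] +
      (voxel[3] - 1) * study$grid[1] * study$grid[2]
  }
  if (!study$mask[voxel]) {
    abort("voxel outside mask", class = "traj_voxel_skip")
  }
  nvox <- prod(study$grid)
  y <- study$volumes[voxel + (seq_len(dim(study$volumes)[4]) - 1) * nvox]
  keep <- which(is.finite(y))
  if (length(keep) == 0) {
    abort("all scans missing at voxel", class = "traj_voxel_skip")
  }
  structure(y[keep], scan_rows = keep)
}

# fit one voxel's series; shares the prebuilt augmented system when no scans
# are missing
fit_voxel <- function(y_full, study, shared_aug, spec, prior, control) {
  keep <- which(is.finite(y_full))
  if (length(keep) == 0) return(NULL)
  if (length(keep) == length(y_full)) {
    aug <- shared_aug
    aug$ybar[seq_len(aug$dims$M)] <- y_full
    em_fit(aug, study$data, control = control)
  } else {
    scans <- study$data$scans[keep, , drop = FALSE]
    scans$value <- y_full[keep]
    sub <- traj_data(scans,
                     group = if (study$data$n_groups > 1) "group" else NULL,
                     covariates = study$data$covariate_names,
                     ref_age = study$data$ref_age)
    fit_trajectories(sub, spec = spec, prior = prior, control = control)
  }
}

#' Fit the trajectory model at every in-mask voxel
#'
#' Runs an independent EM model inversion per voxel and assembles output
#' maps: posterior mean and standard deviation of every second-level
#' parameter, contrast value / exceedance probability / suprathreshold mask
#' per requested contrast, each variance hyperparameter, the free energy and
#' a convergence flag. Out-of-mask voxels hold `NaN`. Results are identical
#' whatever the voxel evaluation order or number of worker processes.
#'
#' @param study An [image_study] (or a scans table, with `images`/`mask`
#'   forwarded to [image_study()]).
#' @param spec A [traj_spec].
#' @param contrasts Named list of contrasts as accepted by [ppm()], e.g.
#'   `list(decline = c(slope = -1))`.
#' @param gamma,p_t Thresholds passed to [ppm()].
#' @param prior,control Passed to the fitter.
#' @param cores Worker processes (forked; default 1).
#' @param output_dir When given, maps are written there as NIfTI via
#'   [write_mapset()].
#' @param ... Passed to [image_study()] when `study` is a scans table.
#' @return An object of class `traj_mapset`: named list `maps` of 3-D
#'   arrays, the `mask`, a `summary` tibble (voxel counts, convergence), and
#'   any file paths written.
#' @export
run_study <- function(study, spec = traj_spec(1), contrasts = NULL,
                      gamma = 0, p_t = 0.95,
                      prior = traj_prior(), control = traj_control(),
                      cores = 1, output_dir = NULL, ...) {
  if (!inherits(study, "image_study")) study <- image_study(study, ...)
  data <- study$data
  design <- build_design(data, spec)
  shared_aug <- augment_system(design, y = rep(0, data$n_scans),
                               prior = prior)
  theta2_names <- design$theta2_names
  hyper_labels <- c("noise", vapply(design$bases$second_level, `[[`, "",
                                    "label"))
  con_names <- names(contrasts) %||% character(0)

  nvox <- prod(study$grid)
  n_scan <- dim(study$volumes)[4]
  vol_mat <- matrix(study$volumes, nvox, n_scan)

  one_voxel <- function(v) {
    y <- vol_mat[v, ]
    fit <- tryCatch(
      fit_voxel(y, study, shared_aug, spec, prior, control),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(c(rep(NaN, 2 * length(theta2_names) + 3 * length(con_names) +
                     length(hyper_labels) + 1), 0, NaN))
    }
    con_vals <- if (length(con_names) > 0) {
      unlist(lapply(contrasts, function(cc) {
        pr <- ppm(fit, cc, gamma = gamma, p_t = p_t)
        c(pr$estimate, pr$prob, as.numeric(pr$suprathreshold))
      }))
    } else {
      numeric(0)
    }
    c(fit$posterior$theta2, fit$posterior$theta2_se, con_vals,
      fit$hyper$variance, fit$free_energy, as.numeric(fit$converged),
      fit$iterations)
  }

  res <- voxel_apply(study$voxels, one_voxel, cores)
  out_names <- c(paste0("param_", theta2_names, "_mean"),
                 paste0("param_", theta2_names, "_sd"),
                 if (length(con_names) > 0) {
                   as.vector(vapply(con_names, function(cn) {
                     paste0("con_", cn, c("_value", "_prob", "_supra"))
                   }, character(3)))
                 },
                 paste0("hyper_", hyper_labels),
                 "free_energy", "converged", "iterations")
  maps <- build_maps(res, out_names, study)
  summary <- tibble(
    n_voxels = length(study$voxels),
    n_converged = sum(res[, match("converged", out_names)] == 1,
                      na.rm = TRUE),
    mean_iterations = mean(res[, match("iterations", out_names)],
                           na.rm = TRUE),
    mean_free_energy = mean(res[, match("free_energy", out_names)],
                            na.rm = TRUE)
  )
  ms <- structure(
    list(maps = maps, mask = study$mask, template = study$template,
         summary = summary, files = NULL),
    class = "traj_mapset"
  )
  if (!is.null(output_dir)) ms$files <- write_mapset(ms, output_dir)
  ms
}

voxel_apply <- function(voxels, fun, cores) {
  res <- if (cores > 1) {
    chunks <- parallel::mclapply(voxels, fun, mc.cores = cores,
                                 mc.preschedule = TRUE)
    do.call(rbind, chunks)
  } else {
    do.call(rbind, lapply(voxels, fun))
  }
  res
}

build_maps <- function(res, out_names, study) {
  maps <- setNames(vector("list", length(out_names)), out_names)
  for (j in seq_along(out_names)) {
    arr <- array(NaN, study$grid)
    arr[study$voxels] <- res[, j]
    maps[[j]] <- arr
  }
  maps
}

#' @export
print.traj_mapset <- function(x, ...) {
  cat("<traj_mapset> ", length(x$maps), " maps over ",
      x$summary$n_voxels, " in-mask voxels (",
      x$summary$n_converged, " converged)\n", sep = "")
  cat("  ", paste(names(x$maps), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a map set as NIfTI volumes
#'
#' @param mapset A `traj_mapset` from [run_study()] or
#'   [compare_models_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_mapset <- function(mapset, dir) {
  stopifnot(inherits(mapset, "traj_mapset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- vapply(names(mapset$maps), function(nm) {
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".nii.gz"))
    img <- if (!is.null(mapset$template)) {
      RNifti::asNifti(mapset$maps[[nm]], reference = mapset$template)
    } else {
      RNifti::asNifti(mapset$maps[[nm]])
    }
    RNifti::writeNifti(img, f)
    f
  }, "")
  invisible(files)
}

#' Voxelwise model comparison
#'
#' Fits each candidate model at every in-mask voxel and returns per-model
#' log-evidence maps, pairwise log-Bayes-factor maps, and an integer
#' winning-model map (index into `specs`; voxels where no model converged
#' are `NaN`).
#'
#' @param study An [image_study].
#' @param specs List of at least two [traj_spec] objects.
#' @param prior,control,cores,output_dir As in [run_study()].
#' @return A `traj_mapset` whose maps are `F_<label>`, `logBF_<i>_vs_<j>`
#'   and `winner`.
#' @export
compare_models_study <- function(study, specs, prior = traj_prior(),
                                 control = traj_control(), cores = 1,
                                 output_dir = NULL) {
  stopifnot(inherits(study, "image_study"))
  if (length(specs) < 2) abort("supply at least two model specifications")
  labels <- make.unique(vapply(specs, `[[`, "", "label"))
  data <- study$data
  built <- lapply(specs, function(sp) {
    design <- build_design(data, sp)
    list(spec = sp,
         aug = augment_system(design, y = rep(0, data$n_scans),
                              prior = prior))
  })
  nvox <- prod(study$grid)
  n_scan <- dim(study$volumes)[4]
  vol_mat <- matrix(study$volumes, nvox, n_scan)

  one_voxel <- function(v) {
    y <- vol_mat[v, ]
    Fs <- vapply(built, function(b) {
      fit <- tryCatch(fit_voxel(y, study, b$aug, b$spec, prior, control),
                      error = function(e) NULL)
      if (is.null(fit) || !fit$converged) NaN else fit$free_energy
    }, 0)
    winner <- if (all(is.nan(Fs))) NaN else which.max(Fs)
    c(Fs, winner)
  }
  res <- voxel_apply(study$voxels, one_voxel, cores)

  pair_idx <- utils::combn(length(specs), 2)
  bf_names <- apply(pair_idx, 2, function(ij) {
    paste0("logBF_", labels[ij[1]], "_vs_", labels[ij[2]])
  })
  bf_cols <- apply(pair_idx, 2, function(ij) res[, ij[1]] - res[, ij[2]])
  if (is.null(dim(bf_cols))) bf_cols <- matrix(bf_cols, nrow = nrow(res))
  res_all <- cbind(res[, seq_along(specs), drop = FALSE], bf_cols,
                   res[, length(specs) + 1])
  out_names <- c(paste0("F_", labels), bf_names, "winner")
  maps <- build_maps(res_all, out_names, study)
  ms <- structure(
    list(maps = maps, mask = study$mask, template = study$template,
         summary = tibble(
           n_voxels = length(study$voxels),
           n_converged = sum(!is.nan(res[, length(specs) + 1]))
         ),
         files = NULL),
    class = "traj_mapset"
  )
  if (!is.null(output_dir)) ms$files <- write_mapset(ms, output_dir)
  ms
}
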