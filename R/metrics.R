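# Evaluation protocol: spherical VOIs, recovery coefficient
# RC = AC_measured / AC_true, background coefficient of variation
# CoV = 100 * SD_bgr / Mean_bgr (sample SD, n-1), RC-vs-CoV curves across
# iterations, matched-CoV comparison between algorithms, and kernel
# hyper-parameter sweeps.

#' Spherical VOI mask
#'
#' Voxel-centre inclusion against the analytic sphere: exactly the same
#' voxelization rule the phantom generator uses, so the RC of the truth
#' image is 1 by construction.
#'
#' @param grid an [image_grid()].
#' @param center_mm VOI centre (mm).
#' @param diameter_mm VOI diameter (mm, `> 0`).
#' @return Logical array on `grid`.
#' @export
sphere_voi_mask <- function(grid, center_mm, diameter_mm) {
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("`diameter_mm` must be > 0", call. = FALSE)
  }
  m <- sphere_mask_(grid, center_mm, diameter_mm)
  if (!any(m)) {
    stop("VOI contains no voxel centres (centre outside the grid?)",
         call. = FALSE)
  }
  m
}

#' Recovery coefficient of a VOI
#'
#' `RC = mean(image over mask) / true_concentration`; values below 1
#' indicate partial-volume (or count) losses.
#'
#' @param image a [volume_image()] (or array).
#' @param mask logical array (non-empty).
#' @param true_concentration true activity concentration (`> 0`).
#' @return The recovery coefficient (scalar).
#' @export
recovery_coefficient <- function(image, mask, true_concentration) {
  vals <- as_volume_values(image)
  mask <- as.logical(mask)
  if (!any(mask)) stop("`mask` is empty", call. = FALSE)
  if (!is.finite(true_concentration) || true_concentration <= 0) {
    stop("`true_concentration` must be > 0", call. = FALSE)
  }
  mean(vals[mask]) / true_concentration
}

#' Background coefficient of variation (percent)
#'
#' `CoV = 100 * SD / mean` over the background VOI, with the sample (n-1)
#' standard deviation. Scale-invariant; requires a non-zero mean.
#'
#' @param image a [volume_image()] (or array).
#' @param mask logical array selecting at least 2 voxels.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(image, mask) {
  vals <- as_volume_values(image)
  mask <- as.logical(mask)
  if (sum(mask) < 2L) stop("`mask` must select at least 2 voxels",
                           call. = FALSE)
  m <- mean(vals[mask])
  if (m == 0) stop("zero mean over the background VOI", call. = FALSE)
  100 * stats::sd(vals[mask]) / m
}

#' RC-vs-CoV curve over iterations
#'
#' Computes, for every saved iteration of a reconstruction, the recovery
#' coefficient of each sphere VOI and the background CoV. VOI masks are
#' rebuilt geometrically on the image grid from the phantom specification,
#' so the report can be computed on any reconstruction grid.
#'
#' @param result a [run_reconstruction()] result (with saved iterations).
#' @param bundle the [make_nema_phantom()] bundle defining VOIs and truths.
#' @return A tibble of class `voi_report` in long format: `algorithm`,
#'   `iteration`, `voi`, `rc`, `cov_bgr`.
#' @export
rc_cov_curve <- function(result, bundle) {
  if (!inherits(result, "recon_result")) {
    stop("`result` must be a recon_result", call. = FALSE)
  }
  if (!inherits(bundle, "phantom_bundle")) {
    stop("`bundle` must be a phantom_bundle", call. = FALSE)
  }
  grid <- result$final$grid
  spec <- bundle$spec
  masks <- lapply(seq_len(nrow(spec$spheres)), function(i) {
    sphere_voi_mask(grid, spec$spheres$center[[i]],
                    spec$spheres$diameter_mm[i])
  })
  names(masks) <- spec$spheres$id
  masks <- masks[order(names(masks))]
  truths <- stats::setNames(bundle$truth$true_concentration,
                            bundle$truth$voi)
  bgr <- sphere_voi_mask(grid, spec$bgr_center_mm, spec$bgr_diameter_mm)
  saved <- which(!vapply(result$images, is.null, logical(1)))
  rows <- lapply(saved, function(it) {
    img <- result$images[[it]]
    cov <- coefficient_of_variation(img, bgr)
    tibble::tibble(
      algorithm = result$algorithm,
      iteration = it,
      voi = names(masks),
      rc = vapply(names(masks), function(id) {
        recovery_coefficient(img, masks[[id]], truths[[id]])
      }, numeric(1)),
      cov_bgr = cov
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("voi_report", class(out))
  out
}

cov_by_iteration_ <- function(report) {
  dplyr::distinct(tibble::as_tibble(report)[, c("iteration", "cov_bgr")])
}

matched_iteration_ <- function(report, reference_cov) {
  cv <- cov_by_iteration_(report)
  d <- abs(cv$cov_bgr - reference_cov)
  # nearest CoV; ties broken toward the earlier iteration
  cv$iteration[order(d, cv$iteration)][1]
}

outside_range_by_ <- function(report, reference_cov) {
  cv <- cov_by_iteration_(report)$cov_bgr
  if (reference_cov >= min(cv) && reference_cov <= max(cv)) return(0)
  min(abs(reference_cov - min(cv)), abs(reference_cov - max(cv))) /
    abs(reference_cov)
}

#' Compare two reconstructions at matched background noise
#'
#' For each report, selects the saved iteration whose background CoV is
#' nearest to `reference_cov` (ties go to the earlier iteration) and returns
#' both algorithms' per-VOI recovery coefficients at those iterations, so RC
#' differences are compared at the same noise level.
#'
#' @param report_a,report_b `voi_report` tibbles from [rc_cov_curve()].
#' @param reference_cov reference CoV (percent). Errors if it lies outside
#'   both curves' CoV ranges by more than 50% (relative).
#' @return Tibble: `voi`, `rc_a`, `rc_b`, `iteration_a`, `iteration_b`,
#'   `cov_a`, `cov_b`, `algorithm_a`, `algorithm_b`.
#' @export
compare_at_matched_cov <- function(report_a, report_b, reference_cov) {
  if (!is.finite(reference_cov)) {
    stop("`reference_cov` must be finite", call. = FALSE)
  }
  oa <- outside_range_by_(report_a, reference_cov)
  ob <- outside_range_by_(report_b, reference_cov)
  if (oa > 0.5 && ob > 0.5) {
    stop("`reference_cov` lies outside both CoV ranges by more than 50%",
         call. = FALSE)
  }
  it_a <- matched_iteration_(report_a, reference_cov)
  it_b <- matched_iteration_(report_b, reference_cov)
  a <- tibble::as_tibble(report_a)[report_a$iteration == it_a, ]
  b <- tibble::as_tibble(report_b)[report_b$iteration == it_b, ]
  out <- dplyr::inner_join(
    dplyr::rename(a, rc_a = "rc", cov_a = "cov_bgr",
                  iteration_a = "iteration", algorithm_a = "algorithm"),
    dplyr::rename(b, rc_b = "rc", cov_b = "cov_bgr",
                  iteration_b = "iteration", algorithm_b = "algorithm"),
    by = "voi"
  )
  out[, c("voi", "rc_a", "rc_b", "iteration_a", "iteration_b",
          "cov_a", "cov_b", "algorithm_a", "algorithm_b")]
}

#' Sweep one kernel hyper-parameter
#'
#' Re-runs the reconstruction for each value of the named kernel parameter
#' (`sigma_p`, `sigma_s`, `sigma_c`, `sigma_d` or `window`) and collects the
#' RC/CoV reports into one long table, reproducing the protocol used to
#' optimize the kernel parameters.
#'
#' @param config a [recon_config()] (its kernel spec is modified per value).
#' @param parameter parameter name.
#' @param values numeric vector of values to sweep.
#' @param data,model,guidance as for [run_reconstruction()].
#' @param bundle phantom bundle defining VOIs (see [rc_cov_curve()]).
#' @return Long tibble: `value`, `algorithm`, `iteration`, `voi`, `rc`,
#'   `cov_bgr`.
#' @export
parameter_sweep <- function(config, parameter, values, data, model,
                            guidance, bundle) {
  if (!parameter %in% c("sigma_p", "sigma_s", "sigma_c", "sigma_d",
                        "window")) {
    stop("unknown kernel parameter: ", parameter, call. = FALSE)
  }
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg$kernel[[parameter]] <- if (parameter == "window") as.integer(v) else v
    res <- run_reconstruction(cfg, data, model, guidance)
    rep <- rc_cov_curve(res, bundle)
    rep$value <- v
    rep
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("value", "algorithm", "iteration", "voi", "rc", "cov_bgr")]
  class(out) <- c("voi_report", class(out))
  out
}

#' Plot RC-vs-CoV curves
#'
#' One panel per VOI, recovery coefficient against background CoV with
#' iterations advancing along each curve, one colour per algorithm: the
#' standard way these algorithm comparisons are read.
#'
#' @param object a `voi_report` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.voi_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$cov_bgr, y = .data$rc,
                               colour = .data$algorithm)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~voi, scales = "free_y") +
    ggplot2::labs(x = "background CoV (%)", y = "recovery coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a VOI report as CSV
#'
#' @param report a `voi_report` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_voi_report <- function(report, path) {
  readr::write_csv(tibble::as_tibble(report), path)
  invisible(path)
}
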