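# The triple registration chain: 6-DOF alignment to the spine (motion-intact
# anatomy), translation-only alignment to the implanted marker, and
# translation-only alignment to the in-organ reference structure. The
# difference between the last two translations is the per-phase marker-target
# deformation.

registration_result <- function(transform, metric_value, roi_label,
                                iterations, converged = TRUE,
                                series_id = transform$moving) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (!is.finite(metric_value)) stop("metric_value must be finite")
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(transform = transform, metric_value = metric_value,
                 roi_label = as.character(roi_label),
                 iterations = iterations, converged = isTRUE(converged),
                 series_id = as.character(series_id)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> series '%s', ROI '%s': metric %.4g after %d evaluations%s\n",
              x$series_id, x$roi_label, x$metric_value, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  print(x$transform)
  invisible(x)
}

#' Detect the implanted marker in a search region
#'
#' Thresholds the image inside the search ROI, keeps the 6-connected
#' above-threshold component with the largest voxel count, and returns its
#' intensity-weighted centroid in physical mm. The default threshold of
#' 1500 HU separates metal from bone.
#'
#' @param image An [image_volume()].
#' @param search_roi A [binary_structure()] on the image grid.
#' @param hu_threshold Intensity threshold; must be above soft tissue.
#' @return Numeric length 3: marker centroid (mm, LPS).
#' @export
detect_marker <- function(image, search_roi, hu_threshold = 1500) {
  stopifnot(inherits(image, "image_volume"))
  stopifnot(inherits(search_roi, "binary_structure"))
  stop_if_grid_mismatch(image, search_roi, "image and search ROI")
  if (!any(search_roi$mask)) stop("search ROI is empty")
  cand <- search_roi$mask & (image$data > hu_threshold)
  if (!any(cand))
    stop(sprintf("marker not found: no voxel above %g in the search ROI", hu_threshold))
  lab <- .label_components6_cpp(as.logical(cand), as.integer(dim(cand)))
  counts <- tabulate(lab[lab > 0L])
  best <- which.max(counts)
  idx <- which(lab == best)
  w <- image$data[idx]
  ai <- arrayInd(idx, dim(cand))
  pos <- sweep((ai - 1) %*% diag(image$spacing), 2, image$origin, "+")
  as.numeric(colSums(pos * w) / sum(w))
}

# physical coordinates + intensities of the true voxels of an ROI
roi_samples <- function(image, roi, stride = 1L) {
  idx <- which(roi$mask)
  if (stride > 1L) idx <- idx[seq(1L, length(idx), by = stride)]
  ai <- arrayInd(idx, dim(roi$mask))
  pts <- sweep((ai - 1) %*% diag(image$spacing), 2, image$origin, "+")
  list(pts = pts, vals = image$data[idx])
}

# mean squared intensity difference at fixed ROI points, moving sampled
# through the candidate transform; points mapping outside the moving grid
# are excluded (at least half must remain valid)
msd_metric <- function(params, fpts, fvals, moving, mgeom, center) {
  if (any(abs(params[1:3]) > 40) || any(abs(params[4:6]) > 10))
    return(1e12 + sum(pmax(abs(params[1:3]) - 40, 0)) +
             sum(pmax(abs(params[4:6]) - 10, 0)))
  tr <- rigid_transform(translation = params[1:3], rotation = params[4:6],
                        center = center)
  v0 <- phys_to_voxel0(apply_transform(tr, fpts), mgeom)
  mv <- .interp_trilinear_cpp(as.numeric(moving$data), as.integer(mgeom$dim), v0)
  ok <- !is.na(mv)
  if (sum(ok) < length(mv) / 2) return(1e12)
  mean((fvals[ok] - mv[ok])^2)
}

#' 6-DOF rigid registration to the spine
#'
#' Aligns a secondary series to the primary by minimizing the mean squared
#' intensity difference inside the spine ROI, with a multi-resolution
#' (subsampled ROI) derivative-free local search. The capture range is
#' bounded to +/-40 mm translation and +/-10 degrees rotation. Rotations use
#' intrinsic Z-Y-X Euler angles about the ROI centroid.
#'
#' @param fixed Primary [image_volume()].
#' @param moving Secondary [image_volume()].
#' @param spine_roi Non-empty [binary_structure()] on the fixed grid.
#' @param series_id Identifier of the moving series (for bookkeeping).
#' @return A `registration_result` whose transform maps primary-frame points
#'   to moving-frame points; its translation is the displacement of the
#'   spine from the primary to the secondary series.
#' @export
register_spine_6d <- function(fixed, moving, spine_roi, series_id = "secondary") {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  stop_if_grid_mismatch(fixed, spine_roi, "fixed image and spine ROI")
  if (!any(spine_roi$mask)) stop("spine ROI is empty")
  mgeom <- grid_of(moving)
  full <- roi_samples(fixed, spine_roi)
  center <- as.numeric(colMeans(full$pts))
  # coarse exhaustive translation initialization (capture range), then
  # multi-resolution derivative-free 6-DOF refinement
  s16 <- roi_samples(fixed, spine_roi, stride = 16L)
  base <- phys_to_voxel0(s16$pts, mgeom)
  steps <- seq(-12, 12, by = 1.5)
  offs <- as.matrix(expand.grid(x = steps, y = steps, z = steps))
  ncc <- .ncc_search_cpp(s16$vals, base, as.numeric(moving$data),
                         as.integer(mgeom$dim),
                         sweep(offs, 2, mgeom$spacing, "/"))
  params <- c(as.numeric(offs[which.max(ncc), ]), 0, 0, 0)
  evals <- nrow(offs)
  conv <- TRUE
  for (stride in c(16L, 8L)) {
    s <- roi_samples(fixed, spine_roi, stride = stride)
    npass <- if (stride == 16L) 2L else 1L # restart escapes simplex collapse
    for (pass in seq_len(npass)) {
      fit <- optim(params, msd_metric,
                   fpts = s$pts, fvals = s$vals, moving = moving,
                   mgeom = mgeom, center = center,
                   method = "Nelder-Mead",
                   control = list(maxit = if (stride == 16L) 400 else 450,
                                  reltol = 1e-7,
                                  parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
      params <- fit$par
      evals <- evals + fit$counts[["function"]]
    }
    conv <- conv && fit$convergence == 0L
  }
  if (!conv)
    warning("spine registration: optimizer did not report convergence; result flagged")
  registration_result(
    rigid_transform(translation = params[1:3], rotation = params[4:6],
                    center = center, fixed = "primary", moving = series_id),
    metric_value = fit$value, roi_label = spine_roi$label,
    iterations = max(1L, evals), converged = conv, series_id = series_id)
}

#' Translation-only registration to the marker
#'
#' Closed-form centroid matching: the marker is detected in both series
#' ([detect_marker()]) and the incremental translation is the moving-frame
#' marker centroid minus the spine-aligned prediction of the fixed marker
#' position. Rotations are copied unchanged from the prior (spine) result;
#' after the spine step the chain never re-estimates rotations, mirroring
#' single-marker tracking which compensates translations only.
#'
#' @param fixed Primary [image_volume()].
#' @param moving Secondary [image_volume()].
#' @param roi Marker search ROI on the fixed grid.
#' @param prior `registration_result` of the spine step (applied first).
#' @param hu_threshold Marker detection threshold (HU), default 1500.
#' @return A `registration_result`; its translation accumulates the prior
#'   translation plus the incremental marker alignment.
#' @export
register_translation_marker <- function(fixed, moving, roi, prior,
                                        hu_threshold = 1500) {
  stopifnot(inherits(prior, "registration_result"))
  m_fixed <- detect_marker(fixed, roi, hu_threshold)
  # carry the fixed-frame ROI into the moving frame through the prior so the
  # search region follows the spine alignment
  roi_moving <- resample_to_reference(roi, grid_of(moving),
                                      invert_transform(prior$transform))
  if (!any(roi_moving$mask)) roi_moving <- binary_structure(
    array(TRUE, grid_of(moving)$dim), moving, label = roi$label)
  m_moving <- detect_marker(moving, roi_moving, hu_threshold)
  increment <- m_moving - apply_transform(prior$transform, m_fixed)
  tr <- rigid_transform(translation = prior$transform$translation + increment,
                        rotation = prior$transform$rotation,
                        center = prior$transform$center,
                        fixed = prior$transform$fixed,
                        moving = prior$transform$moving)
  registration_result(tr, metric_value = sqrt(sum(increment^2)),
                      roi_label = roi$label, iterations = 1L,
                      converged = TRUE, series_id = prior$series_id)
}

#' Translation-only registration to the reference structure
#'
#' Maximizes the normalized cross-correlation of intensities inside the
#' reference-structure ROI over a dense translation search (+/-10 mm at
#' 0.5 mm steps) around the prior (marker) alignment, followed by parabolic
#' sub-step refinement along each axis. Deterministic: no random restarts.
#' Rotations are copied from the prior.
#'
#' @param fixed Primary [image_volume()].
#' @param moving Secondary [image_volume()].
#' @param roi Reference-structure ROI on the fixed grid (heterogeneous
#'   intensity required).
#' @param prior `registration_result` of the marker step.
#' @param search_mm Half-range of the translation search (mm).
#' @param step_mm Search step (mm).
#' @return A `registration_result`; translation = prior translation plus the
#'   NCC-optimal increment.
#' @export
register_translation_local <- function(fixed, moving, roi, prior,
                                       search_mm = 10, step_mm = 0.5) {
  stopifnot(inherits(prior, "registration_result"))
  stop_if_grid_mismatch(fixed, roi, "fixed image and reference ROI")
  if (!any(roi$mask)) stop("reference ROI is empty")
  s <- roi_samples(fixed, roi)
  if (sd(s$vals) < 1e-9)
    stop("reference structure not discriminable: ROI intensity is constant")
  mgeom <- grid_of(moving)
  base <- phys_to_voxel0(apply_transform(prior$transform, s$pts), mgeom)
  steps <- seq(-search_mm, search_mm, by = step_mm)
  offs <- as.matrix(expand.grid(x = steps, y = steps, z = steps))
  offs_vox <- sweep(offs, 2, mgeom$spacing, "/")
  ncc <- .ncc_search_cpp(s$vals, base, as.numeric(moving$data),
                         as.integer(mgeom$dim), offs_vox)
  if (max(ncc) <= -2)
    stop("reference structure not discriminable: no valid overlap in the search range")
  best <- offs[which.max(ncc), ]
  # parabolic refinement per axis around the grid optimum
  refine <- numeric(3)
  nst <- length(steps)
  bi <- vapply(1:3, function(a) which.min(abs(steps - best[a])), integer(1))
  arr <- array(ncc, c(nst, nst, nst))
  for (a in 1:3) {
    i <- bi
    if (i[a] > 1L && i[a] < nst) {
      im <- i; im[a] <- i[a] - 1L
      ip <- i; ip[a] <- i[a] + 1L
      c0 <- arr[i[1], i[2], i[3]]
      cm <- arr[im[1], im[2], im[3]]
      cp <- arr[ip[1], ip[2], ip[3]]
      den <- cm - 2 * c0 + cp
      if (is.finite(den) && den < -1e-12)
        refine[a] <- 0.5 * step_mm * (cm - cp) / den
    }
  }
  increment <- as.numeric(best) + refine
  tr <- rigid_transform(translation = prior$transform$translation + increment,
                        rotation = prior$transform$rotation,
                        center = prior$transform$center,
                        fixed = prior$transform$fixed,
                        moving = prior$transform$moving)
  registration_result(tr, metric_value = max(ncc), roi_label = roi$label,
                      iterations = nrow(offs), converged = TRUE,
                      series_id = prior$series_id)
}

#' Marker-target deformation vector of a secondary series
#'
#' The translation of the reference-structure registration minus the
#' translation of the marker registration, componentwise in LPS mm. Both
#' results must refer to the same secondary series.
#'
#' @param marker_result `registration_result` of the marker step.
#' @param ref_result `registration_result` of the reference-structure step.
#' @return A [deformation_vector_new()] object.
#' @export
deformation_vector <- function(marker_result, ref_result) {
  stopifnot(inherits(marker_result, "registration_result"),
            inherits(ref_result, "registration_result"))
  if (!identical(marker_result$series_id, ref_result$series_id))
    stop(sprintf("mismatched series: marker result is for '%s', reference result for '%s'",
                 marker_result$series_id, ref_result$series_id))
  deformation_vector_new(
    marker_result$series_id,
    ref_result$transform$translation - marker_result$transform$translation)
}

#' Run the full triple registration chain for one secondary series
#'
#' Convenience wrapper: spine 6-DOF, then marker translation, then
#' reference-structure translation, returning all three results and the
#' deformation vector.
#'
#' @param fixed Primary [image_volume()].
#' @param moving Secondary [image_volume()].
#' @param spine_roi,marker_roi,ref_roi ROIs on the fixed grid.
#' @param series_id Identifier of the secondary series.
#' @param hu_threshold Marker detection threshold (HU).
#' @return List with elements `spine`, `marker`, `refstruct`
#'   (`registration_result`s) and `deformation` (a deformation vector).
#' @export
register_chain <- function(fixed, moving, spine_roi, marker_roi, ref_roi,
                           series_id = "secondary", hu_threshold = 1500) {
  sp <- register_spine_6d(fixed, moving, spine_roi, series_id = series_id)
  mk <- register_translation_marker(fixed, moving, marker_roi, sp,
                                    hu_threshold = hu_threshold)
  rf <- register_translation_local(fixed, moving, ref_roi, mk)
  list(spine = sp, marker = mk, refstruct = rf,
       deformation = deformation_vector(mk, rf))
}
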