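# Core data model: volumes, masks, transforms, margins.
#
# All physical coordinates use the patient-based LPS convention:
#   +x = Left, -x = Right, +y = Posterior, -y = Anterior,
#   +z = Superior, -z = Inferior.
# The physical position of voxel (i, j, k) (1-based array index) is
#   origin + spacing * (c(i, j, k) - 1)   [mm].

#' CT-like image volume
#'
#' A 3D scalar intensity grid (Hounsfield-unit-like values) with voxel
#' spacing and origin in millimetres, on patient-based LPS axes
#' (+x left, +y posterior, +z superior).
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length 3, voxel size in mm along (x, y, z); all > 0.
#' @param origin Numeric length 3, physical position (mm) of voxel (1, 1, 1).
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(0, c(10, 10, 10)), spacing = c(1.5, 1.5, 1.5))
#' dim(vol$data)
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("image data must be a 3D array with positive dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Binary structure (mask) on an image grid
#'
#' A 3D boolean mask tied to the grid geometry of a reference volume:
#' CTV, ITV, PTV or a registration region of interest.
#'
#' @param mask 3D logical (or coercible) array.
#' @param grid An [image_volume()] (only its geometry is kept) or a list with
#'   `spacing` and `origin`.
#' @param label Free-text label for reports.
#' @return An object of class `binary_structure`.
#' @export
binary_structure <- function(mask, grid, label = "") {
  mask <- as.array(mask)
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  g <- grid_geometry(grid)
  structure(list(mask = mask, spacing = g$spacing, origin = g$origin,
                 label = as.character(label)),
            class = "binary_structure")
}

grid_geometry <- function(x) {
  if (inherits(x, "image_volume") || inherits(x, "binary_structure"))
    list(spacing = x$spacing, origin = x$origin)
  else if (is.list(x) && !is.null(x$spacing))
    list(spacing = as.numeric(x$spacing),
         origin = if (is.null(x$origin)) c(0, 0, 0) else as.numeric(x$origin))
  else stop("grid must be an image_volume, binary_structure, or list with spacing/origin")
}

grid_of <- function(x) {
  d <- if (inherits(x, "binary_structure")) dim(x$mask) else dim(x$data)
  list(dim = d, spacing = x$spacing, origin = x$origin)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "/"),
              paste(format(x$origin), collapse = "/")))
  invisible(x)
}

#' @export
print.binary_structure <- function(x, ...) {
  cat(sprintf("<binary_structure> '%s': %d/%s voxels true (%.3f cm^3)\n",
              x$label, sum(x$mask), format(length(x$mask)), volume_cm3(x)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "structures") {
  if (!same_grid(a, b))
    stop(sprintf("%s live on different grids; resample explicitly first (a: %s @ %s mm, b: %s @ %s mm)",
                 what,
                 paste(grid_of(a)$dim, collapse = "x"),
                 paste(format(a$spacing), collapse = "/"),
                 paste(grid_of(b)$dim, collapse = "x"),
                 paste(format(b$spacing), collapse = "/")))
  invisible(TRUE)
}

#' Rigid transform between two series
#'
#' A 6-parameter rigid-body transform. Following the usual resampling
#' convention, it maps physical points of the fixed (primary) frame to the
#' corresponding physical points of the moving (secondary) frame:
#' `T(x) = R (x - center) + center + translation`, with `R` built from
#' intrinsic Z-Y-X Euler angles. Its translation therefore reads as the
#' displacement of the registered anatomy from the primary series to the
#' secondary series, in LPS mm -- the "3D translation coordinates" recorded
#' at each step of the registration chain.
#'
#' @param translation Numeric length 3, mm.
#' @param rotation Numeric length 3, degrees, intrinsic Euler angles in the
#'   order (rz, ry, rx); each in (-180, 180].
#' @param center Numeric length 3, rotation centre in mm (defaults to the
#'   origin; registration routines use the ROI centroid).
#' @param fixed,moving Identifiers of the fixed (primary) and moving series.
#' @return An object of class `rigid_transform`.
#' @examples
#' t0 <- rigid_transform()          # identity
#' t1 <- rigid_transform(translation = c(0, 0, -8))
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0),
                            center = c(0, 0, 0), fixed = "primary",
                            moving = "secondary") {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  center <- as.numeric(center)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be 3 finite values (mm)")
  if (length(rotation) != 3L || any(!is.finite(rotation)) ||
      any(rotation <= -180 | rotation > 180))
    stop("rotation must be 3 finite Euler angles in (-180, 180] degrees")
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be 3 finite values (mm)")
  structure(list(translation = translation, rotation = rotation,
                 center = center, fixed = as.character(fixed),
                 moving = as.character(moving)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> %s -> %s: t = (%s) mm, r = (%s) deg\n",
              x$fixed, x$moving,
              paste(sprintf("%.2f", x$translation), collapse = ", "),
              paste(sprintf("%.2f", x$rotation), collapse = ", ")))
  invisible(x)
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to physical points
#'
#' @param transform A [rigid_transform()].
#' @param pts Numeric matrix (n x 3) of physical points (mm), or length-3
#'   vector.
#' @return Transformed points, same shape as input.
#' @export
apply_transform <- function(transform, pts) {
  vec <- is.null(dim(pts))
  p <- if (vec) matrix(as.numeric(pts), 1, 3) else as.matrix(pts)
  R <- rotation_matrix(transform$rotation)
  out <- sweep(p, 2, transform$center) %*% t(R)
  out <- sweep(out, 2, transform$center + transform$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform` (fixed/moving labels swapped).
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform$rotation)
  # inverse rotation = transpose; recover its ZYX Euler angles
  Ri <- t(R)
  ry <- asin(-Ri[3, 1])
  if (abs(cos(ry)) > 1e-12) {
    rz <- atan2(Ri[2, 1], Ri[1, 1])
    rx <- atan2(Ri[3, 2], Ri[3, 3])
  } else { # gimbal lock
    rz <- atan2(-Ri[1, 2], Ri[2, 2])
    rx <- 0
  }
  rot <- c(rz, ry, rx) * 180 / pi
  rot[rot <= -180] <- rot[rot <= -180] + 360
  rigid_transform(translation = as.numeric(-t(R) %*% transform$translation),
                  rotation = rot, center = transform$center,
                  fixed = transform$moving, moving = transform$fixed)
}

is_identity_transform <- function(transform, tol = 1e-9) {
  all(abs(transform$translation) <= tol) && all(abs(transform$rotation) <= tol)
}

#' Deformation vector of a secondary series
#'
#' The per-series marker-target geometry change: the translation of the
#' reference-structure registration minus the translation of the marker
#' registration, componentwise in LPS mm.
#'
#' @param series_id Identifier of the secondary series.
#' @param d Numeric length 3, mm.
#' @return An object of class `deformation_vector`.
#' @export
deformation_vector_new <- function(series_id, d) {
  d <- as.numeric(d)
  if (length(d) != 3L || any(!is.finite(d)))
    stop("deformation vector must have 3 finite components (mm)")
  structure(list(series_id = as.character(series_id), d = d),
            class = "deformation_vector")
}

#' @export
print.deformation_vector <- function(x, ...) {
  cat(sprintf("<deformation_vector> %s: (%s) mm\n", x$series_id,
              paste(sprintf("%.2f", x$d), collapse = ", ")))
  invisible(x)
}

#' Anisotropic anatomical margin
#'
#' Six non-negative expansion distances in mm along the major anatomical
#' directions. The zero margin is the identity expansion.
#'
#' @param anterior,posterior,right,left,superior,inferior Non-negative mm.
#' @return An object of class `anatomical_margin`.
#' @examples
#' anatomical_margin(left = 2, superior = 0.5)
#' @export
anatomical_margin <- function(anterior = 0, posterior = 0, right = 0,
                              left = 0, superior = 0, inferior = 0) {
  m <- c(anterior = anterior, posterior = posterior, right = right,
         left = left, superior = superior, inferior = inferior)
  m <- vapply(m, as.numeric, numeric(1))
  if (any(!is.finite(m)) || any(m < 0))
    stop("all six margins must be finite and >= 0 (mm)")
  structure(as.list(m), class = "anatomical_margin")
}

#' @export
print.anatomical_margin <- function(x, ...) {
  cat(sprintf("<anatomical_margin> A %.2f / P %.2f / R %.2f / L %.2f / S %.2f / I %.2f mm\n",
              x$anterior, x$posterior, x$right, x$left, x$superior, x$inferior))
  invisible(x)
}

#' Planning study: primary series, secondaries, CTV and ROIs
#'
#' @param primary Primary (expiration breath-hold) [image_volume()].
#' @param secondaries Named list of secondary [image_volume()]s keyed by phase
#'   label (e.g. `ibh`, `fb1`, `fb2`, `fb3`); at least one.
#' @param ctv Clinical target volume as a [binary_structure()] on the primary
#'   grid; non-empty.
#' @param rois Named list of [binary_structure()] ROIs, with at least
#'   `spine`, `marker` and `refstruct`; pairwise disjoint.
#' @return An object of class `study_set`.
#' @export
study_set <- function(primary, secondaries, ctv, rois) {
  stopifnot(inherits(primary, "image_volume"))
  if (length(secondaries) < 1L)
    stop("at least one secondary series is required")
  if (is.null(names(secondaries)) || any(names(secondaries) == ""))
    stop("secondaries must be a named list of image_volume (phase labels)")
  for (s in secondaries) stopifnot(inherits(s, "image_volume"))
  stopifnot(inherits(ctv, "binary_structure"))
  if (!any(ctv$mask)) stop("CTV must be non-empty")
  need <- c("spine", "marker", "refstruct")
  if (!all(need %in% names(rois)))
    stop("rois must include 'spine', 'marker' and 'refstruct'")
  for (r in rois) {
    stopifnot(inherits(r, "binary_structure"))
    stop_if_grid_mismatch(r, ctv, "ROI and CTV")
  }
  nm <- names(rois)
  for (i in seq_along(rois)) for (j in seq_len(i - 1L)) {
    if (any(rois[[i]]$mask & rois[[j]]$mask))
      stop(sprintf("ROIs '%s' and '%s' overlap; they must be pairwise disjoint",
                   nm[i], nm[j]))
  }
  structure(list(primary = primary, secondaries = secondaries,
                 ctv = ctv, rois = rois),
            class = "study_set")
}

#' Structure volume in cubic centimetres
#'
#' Count of true voxels times the voxel volume in mm^3, divided by 1000.
#' An empty mask has volume 0.
#'
#' @param s A [binary_structure()].
#' @return Volume in cm^3.
#' @examples
#' g <- image_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
#' volume_cm3(binary_structure(array(TRUE, c(10, 10, 10)), g))  # 1 cm^3
#' @export
volume_cm3 <- function(s) {
  stopifnot(inherits(s, "binary_structure"))
  sum(s$mask) * prod(s$spacing) / 1000
}

# round half away from zero (R's round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Translate a structure by a physical vector
#'
#' Shifts every true voxel by the nearest-integer voxel shift of
#' `d / spacing` (ties rounded half away from zero). Voxels shifted outside
#' the grid are dropped with a warning.
#'
#' @param s A [binary_structure()].
#' @param d Numeric length 3, translation in mm (LPS).
#' @return Translated [binary_structure()] on the same grid.
#' @export
translate_structure <- function(s, d) {
  stopifnot(inherits(s, "binary_structure"))
  d <- as.numeric(d)
  if (length(d) != 3L || any(!is.finite(d)))
    stop("translation d must be 3 finite values (mm)")
  shift <- as.integer(round_half_away(d / s$spacing))
  dm <- dim(s$mask)
  if (any(abs(shift) >= dm))
    stop(sprintf("voxel shift (%s) exceeds grid extent (%s)",
                 paste(shift, collapse = ", "), paste(dm, collapse = "x")))
  out <- array(FALSE, dm)
  src <- list(); dst <- list()
  for (ax in 1:3) {
    n <- dm[ax]; k <- shift[ax]
    if (k >= 0) { src[[ax]] <- seq_len(n - k); dst[[ax]] <- seq_len(n - k) + k }
    else        { src[[ax]] <- seq_len(n + k) - k; dst[[ax]] <- seq_len(n + k) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- s$mask[src[[1]], src[[2]], src[[3]]]
  lost <- sum(s$mask) - sum(out)
  if (lost > 0)
    warning(sprintf("translate_structure: %d voxel(s) shifted outside the grid were dropped", lost))
  binary_structure(out, s, label = s$label)
}

# continuous 0-based voxel coordinates of physical points on a grid
phys_to_voxel0 <- function(pts, geom) {
  sweep(sweep(as.matrix(pts), 2, geom$origin), 2, geom$spacing, "/")
}

# physical coordinates (mm) of all voxels of a grid, as an n x 3 matrix,
# in array (column-major) order
grid_coords <- function(geom) {
  d <- geom$dim
  i <- (seq_len(d[1]) - 1) * geom$spacing[1] + geom$origin[1]
  j <- (seq_len(d[2]) - 1) * geom$spacing[2] + geom$origin[2]
  k <- (seq_len(d[3]) - 1) * geom$spacing[3] + geom$origin[3]
  cbind(rep(i, times = d[2] * d[3]),
        rep(rep(j, each = d[1]), times = d[3]),
        rep(k, each = d[1] * d[2]))
}

#' Resample a volume or mask onto a reference grid
#'
#' Pull-back resampling: the output value at reference-grid point `x` is the
#' moving input sampled at `T(x)`, where the transform maps primary-frame
#' points into the moving series (see [rigid_transform()]). Scalar images use
#' trilinear interpolation; masks use nearest-neighbour so they stay boolean.
#' With the identity transform and matching grids the data are returned
#' bit-identical.
#'
#' @param moving An [image_volume()] or [binary_structure()].
#' @param reference_grid An [image_volume()], [binary_structure()], or list
#'   with `dim`, `spacing`, `origin`.
#' @param transform A [rigid_transform()] mapping reference-frame points to
#'   moving-frame points.
#' @param fill Value used outside the moving grid (scalar images only;
#'   default -1000, air).
#' @return Resampled object of the same kind on the reference grid.
#' @export
resample_to_reference <- function(moving, reference_grid, transform = rigid_transform(),
                                  fill = -1000) {
  is_mask <- inherits(moving, "binary_structure")
  if (!is_mask && !inherits(moving, "image_volume"))
    stop("moving must be an image_volume or binary_structure")
  ref <- if (is.list(reference_grid) && !is.null(reference_grid$dim))
    reference_grid else grid_of(reference_grid)
  mg <- grid_of(moving)
  if (is_identity_transform(transform) &&
      identical(ref$dim, mg$dim) &&
      all(abs(ref$spacing - mg$spacing) < 1e-9) &&
      all(abs(ref$origin - mg$origin) < 1e-9)) {
    return(moving)
  }
  pts <- apply_transform(transform, grid_coords(ref))
  v0 <- phys_to_voxel0(pts, mg)
  inside <- v0[, 1] >= -0.5 & v0[, 1] <= mg$dim[1] - 0.5 &
            v0[, 2] >= -0.5 & v0[, 2] <= mg$dim[2] - 0.5 &
            v0[, 3] >= -0.5 & v0[, 3] <= mg$dim[3] - 0.5
  if (!any(inside))
    stop(sprintf("empty overlap after transform: reference grid %s @ (%s) mm/voxel origin (%s) vs moving grid %s @ (%s) mm/voxel origin (%s)",
                 paste(ref$dim, collapse = "x"),
                 paste(format(ref$spacing), collapse = ", "),
                 paste(format(ref$origin), collapse = ", "),
                 paste(mg$dim, collapse = "x"),
                 paste(format(mg$spacing), collapse = ", "),
                 paste(format(mg$origin), collapse = ", ")))
  if (is_mask) {
    idx <- round(v0) # nearest neighbour, 0-based
    ok <- inside & idx[, 1] >= 0 & idx[, 1] < mg$dim[1] &
                   idx[, 2] >= 0 & idx[, 2] < mg$dim[2] &
                   idx[, 3] >= 0 & idx[, 3] < mg$dim[3]
    out <- rep(FALSE, prod(ref$dim))
    lin <- idx[ok, 1] + mg$dim[1] * (idx[ok, 2] + mg$dim[2] * idx[ok, 3]) + 1
    out[ok] <- as.logical(moving$mask[lin])
    binary_structure(array(out, ref$dim),
                     list(spacing = ref$spacing, origin = ref$origin),
                     label = moving$label)
  } else {
    vals <- .interp_trilinear_cpp(as.numeric(moving$data), as.integer(mg$dim), v0)
    vals[is.na(vals)] <- fill
    image_volume(array(vals, ref$dim), ref$spacing, ref$origin)
  }
}
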