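# Geometry deformation margin (GDM) construction: six-direction margins from
# deformation vectors, anisotropic and isotropic mask expansion, and the
# subvolume-union alternative.

#' Geometry deformation margin from deformation vectors
#'
#' For each of the six major anatomical directions the margin is the largest
#' deformation-vector component pointing that way across all motion-sampling
#' series, clamped at zero: the method guards against target underdose, so
#' inward (negative) maxima never shrink the volume. On LPS axes the left
#' margin is `max(0, max_s d_s . x)`, the right margin `max(0, max_s -d_s . x)`,
#' and likewise posterior/anterior from y and superior/inferior from z.
#'
#' @param vectors List of deformation vectors (or plain length-3 numerics).
#' @return An [anatomical_margin()].
#' @examples
#' gdm_margin(list(c(2, -1, 0.5), c(1, 1.5, -0.5)))
#' @export
gdm_margin <- function(vectors) {
  if (length(vectors) < 1L) stop("at least one deformation vector is required")
  m <- t(vapply(vectors, function(v) {
    d <- if (inherits(v, "deformation_vector")) v$d else as.numeric(v)
    if (length(d) != 3L || any(!is.finite(d)))
      stop("each deformation vector must have 3 finite components")
    d
  }, numeric(3)))
  anatomical_margin(
    left      = max(0, max(m[, 1])),
    right     = max(0, max(-m[, 1])),
    posterior = max(0, max(m[, 2])),
    anterior  = max(0, max(-m[, 2])),
    superior  = max(0, max(m[, 3])),
    inferior  = max(0, max(-m[, 3])))
}

# voxel extents of a margin on a grid: outward (ceiling) realization after
# discounting a 0.1-voxel tolerance. Outward voxelization is what makes the
# margin conservative -- a CTV copy whose translation rounds to k voxels
# stays covered even when the margin estimate is up to 0.4 voxel short --
# while the tolerance keeps sub-voxel registration jitter from inflating a
# genuinely zero margin to a full voxel.
ceil_voxels <- function(mm, pitch) as.integer(ceiling(mm / pitch - 0.1))

margin_voxels <- function(margin, spacing) {
  list(neg = c(ceil_voxels(margin$right, spacing[1]),
               ceil_voxels(margin$anterior, spacing[2]),
               ceil_voxels(margin$inferior, spacing[3])),
       pos = c(ceil_voxels(margin$left, spacing[1]),
               ceil_voxels(margin$posterior, spacing[2]),
               ceil_voxels(margin$superior, spacing[3])))
}

# 1D asymmetric binary dilation along axis `ax` by n_neg voxels toward lower
# indices and n_pos toward higher, via a running-window count
dilate_axis <- function(mask, ax, n_neg, n_pos) {
  if (n_neg == 0 && n_pos == 0) return(mask)
  d <- dim(mask)
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(mask, perm)
  dm <- dim(m)
  mm <- matrix(m, nrow = dm[1])
  cs <- apply(mm, 2, cumsum)
  n <- dm[1]
  # window for output i: input indices [i - n_pos, i + n_neg]
  hi <- pmin(seq_len(n) + n_neg, n)
  lo <- pmax(seq_len(n) - n_pos, 1)
  counts <- cs[hi, , drop = FALSE] -
    rbind(matrix(0, 1, ncol(cs)), cs)[lo, , drop = FALSE]
  out <- array(counts > 0, dm)
  aperm(out, order(perm))
}

#' Anisotropic (box) expansion of a structure
#'
#' Minkowski sum of the mask with the axis-aligned box
#' `[-right, +left] x [-anterior, +posterior] x [-inferior, +superior]` (mm,
#' LPS), realized as separable per-axis dilations on the voxel grid with
#' outward (ceiling) voxelization of each margin distance. This is the CTV
#' to ITV_GDM step. The box kernel with outward voxelization guarantees that
#' every CTV copy translated by an observed deformation vector is contained
#' in the result, even when the margin estimate is off by up to half a
#' voxel.
#' An octant-wise ellipsoid kernel is available for comparison studies with
#' planning systems that round their expansions.
#'
#' @param ctv A non-empty [binary_structure()].
#' @param margin An [anatomical_margin()].
#' @param kernel `"box"` (default) or `"ellipsoid"`.
#' @return Expanded [binary_structure()] on the same grid.
#' @export
expand_anisotropic <- function(ctv, margin, kernel = c("box", "ellipsoid")) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(ctv, "binary_structure"),
            inherits(margin, "anatomical_margin"))
  if (!any(ctv$mask)) stop("CTV must be non-empty")
  mv <- margin_voxels(margin, ctv$spacing)
  dm <- dim(ctv$mask)
  idx <- which(ctv$mask, arr.ind = TRUE)
  if (any(apply(idx, 2, min) - mv$neg < 1) ||
      any(apply(idx, 2, max) + mv$pos > dm))
    stop("expansion exceeds the grid; pad the grid before expanding")
  if (kernel == "box") {
    out <- ctv$mask
    for (ax in 1:3) out <- dilate_axis(out, ax, mv$neg[ax], mv$pos[ax])
  } else {
    out <- array(FALSE, dm)
    for (ox in -mv$neg[1]:mv$pos[1])
      for (oy in -mv$neg[2]:mv$pos[2])
        for (oz in -mv$neg[3]:mv$pos[3]) {
          r <- c(if (ox >= 0) mv$pos[1] else mv$neg[1],
                 if (oy >= 0) mv$pos[2] else mv$neg[2],
                 if (oz >= 0) mv$pos[3] else mv$neg[3])
          o <- c(ox, oy, oz)
          q <- sum((o[r > 0] / r[r > 0])^2) # octant ellipsoid test
          if (any(o[r == 0] != 0) || q > 1 + 1e-12) next
          sh <- shift_mask(ctv$mask, o)
          out <- out | sh
        }
  }
  binary_structure(out, ctv, label = paste0(ctv$label, "+gdm"))
}

# integer voxel shift of a mask (voxels leaving the grid are dropped)
shift_mask <- function(mask, shift) {
  dm <- dim(mask)
  out <- array(FALSE, dm)
  src <- list(); dst <- list()
  for (ax in 1:3) {
    n <- dm[ax]; k <- shift[ax]
    if (abs(k) >= n) return(out)
    if (k >= 0) { src[[ax]] <- seq_len(n - k); dst[[ax]] <- seq_len(n - k) + k }
    else        { src[[ax]] <- seq_len(n + k) - k; dst[[ax]] <- seq_len(n + k) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Union-of-subvolumes internal target volume (ITV_GDM-SUM)
#'
#' Union of the CTV with a copy translated by each observed deformation
#' vector ([translate_structure()]). The identity (expiration) copy is always
#' included since the CTV is defined on the expiration series. Compared with
#' the box expansion this undersamples continuous motion, so it is the
#' comparator for deformable-registration-style merged volumes.
#'
#' @param ctv A non-empty [binary_structure()].
#' @param vectors List of deformation vectors (possibly empty).
#' @return A [binary_structure()] on the CTV grid.
#' @export
itv_gdm_sum <- function(ctv, vectors) {
  stopifnot(inherits(ctv, "binary_structure"))
  if (!any(ctv$mask)) stop("CTV must be non-empty")
  out <- ctv$mask
  n0 <- sum(ctv$mask)
  for (v in vectors) {
    d <- if (inherits(v, "deformation_vector")) v$d else as.numeric(v)
    sh <- as.integer(round_half_away(d / ctv$spacing))
    shifted <- shift_mask(ctv$mask, sh)
    if (sum(shifted) < n0)
      stop("a translated CTV copy leaves the grid; pad the grid first")
    out <- out | shifted
  }
  binary_structure(out, ctv, label = paste0(ctv$label, "+gdm-sum"))
}

#' Isotropic (spherical) expansion of a structure
#'
#' Includes every voxel whose Euclidean distance to the input structure is
#' at most `r_mm`, computed with an exact anisotropic distance transform in
#' physical mm. This is the ITV to PTV step; the default clinical margin for
#' the workflow is 2 mm.
#'
#' @param itv A non-empty [binary_structure()].
#' @param r_mm Radius in mm, >= 0.
#' @return Expanded [binary_structure()] on the same grid.
#' @export
expand_isotropic <- function(itv, r_mm) {
  stopifnot(inherits(itv, "binary_structure"))
  if (!is.finite(r_mm) || r_mm < 0) stop("r_mm must be finite and >= 0")
  if (!any(itv$mask)) stop("structure must be non-empty")
  if (r_mm == 0) return(itv)
  d2 <- .edt_sq_cpp(as.logical(itv$mask), as.integer(dim(itv$mask)), itv$spacing)
  out <- array(d2 <= r_mm^2 + 1e-9, dim(itv$mask))
  # the expansion must not be clipped by the grid boundary
  idx <- which(itv$mask, arr.ind = TRUE)
  nvox <- ceiling(r_mm / itv$spacing)
  if (any(apply(idx, 2, min) - nvox < 1) ||
      any(apply(idx, 2, max) + nvox > dim(itv$mask)))
    stop("isotropic expansion exceeds the grid; pad the grid before expanding")
  binary_structure(out, itv, label = paste0(itv$label, "+", r_mm, "mm"))
}

#' Build the full GDM target set
#'
#' From a CTV and the deformation vectors of all motion-sampling series,
#' constructs the GDM margin, ITV_GDM (anisotropic expansion), ITV_GDM-SUM
#' (union of translated copies), and the two PTVs (isotropic expansion of
#' each ITV). The containment chain
#' CTV <= ITV_GDM-SUM <= ITV_GDM <= PTV_GDM holds by construction.
#'
#' @param ctv A non-empty [binary_structure()].
#' @param vectors List of deformation vectors.
#' @param iso_margin_mm Isotropic ITV to PTV margin in mm (default 2;
#'   3 reproduces the original-workflow PTV convention).
#' @param kernel Expansion kernel for ITV_GDM, `"box"` or `"ellipsoid"`.
#' @return An object of class `target_set` with elements `ctv`, `itv_gdm`,
#'   `itv_gdm_sum`, `ptv_gdm`, `ptv_gdm_sum`, `margin`, `iso_margin_mm`.
#' @export
build_target_set <- function(ctv, vectors, iso_margin_mm = 2,
                             kernel = c("box", "ellipsoid")) {
  kernel <- match.arg(kernel)
  if (!is.finite(iso_margin_mm) || iso_margin_mm < 0)
    stop("iso_margin_mm must be finite and >= 0")
  margin <- if (length(vectors) >= 1L) gdm_margin(vectors) else anatomical_margin()
  itv <- expand_anisotropic(ctv, margin, kernel = kernel)
  itv_sum <- itv_gdm_sum(ctv, vectors)
  ptv <- expand_isotropic(itv, iso_margin_mm)
  ptv_sum <- expand_isotropic(itv_sum, iso_margin_mm)
  structure(list(ctv = ctv, itv_gdm = itv, itv_gdm_sum = itv_sum,
                 ptv_gdm = ptv, ptv_gdm_sum = ptv_sum,
                 margin = margin, iso_margin_mm = iso_margin_mm,
                 kernel = kernel),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set>\n")
  print(x$margin)
  for (nm in c("ctv", "itv_gdm_sum", "itv_gdm", "ptv_gdm_sum", "ptv_gdm"))
    cat(sprintf("  %-12s %8.3f cm^3\n", nm, volume_cm3(x[[nm]])))
  invisible(x)
}
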