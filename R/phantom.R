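# Synthetic respiratory thorax phantom: CT-like breath-hold and
# free-breathing series with a rigid spine, a moving heart, an implanted
# high-intensity marker, a heterogeneous reference structure and a spherical
# target, plus exported ground truth for every stage of the registration and
# margin pipeline.
#
# Geometry is rendered analytically with a soft (~2 mm) edge profile so that
# structures move continuously with sub-voxel shifts, the way real anatomy
# does between CT acquisitions.

#' Phantom specification
#'
#' Defines the grid, the anatomy (HU-like palette: air -1000, soft tissue
#' 40, heart blood pool 300, spine 700, marker 3000, reference-structure
#' contrast +150 over the heart), and the per-phase motion model. The motion
#' model has four independent layers, mirroring what the registration chain
#' must disentangle: a whole-body (couch-like) shift seen by the spine, a
#' breathing heart shift, an extra marker offset `delta_m`, and an extra
#' reference-structure offset `delta_r`. The target moves with the reference
#' structure, so the true per-phase marker-target deformation is
#' `delta_r - delta_m`. All randomness (free-breathing draws, body shifts,
#' offsets, rendering noise) is fixed by `seed`.
#'
#' @param dim Grid size (voxels), default 96^3.
#' @param spacing Voxel size in mm, default 1.5 isotropic.
#' @param n_fb Number of free-breathing series (default 3; with the
#'   inspiration series this gives four motion-sampling secondaries).
#' @param amplitude_mm Breathing amplitude (superior-inferior, mm); the
#'   inspiration phase sits at the extreme.
#' @param marker_offset_mm,refstruct_offset_mm Half-ranges of the uniform
#'   per-phase extra offsets of marker and reference structure (mm).
#' @param body_shift_mm Half-range of the uniform per-phase whole-body
#'   shift (mm).
#' @param body_rotation_deg Optional per-phase body rotation about the
#'   z axis through the image centre (degrees); scalar or one per phase.
#' @param noise_sd Additive Gaussian noise SD in HU (default 20).
#' @param streaks If TRUE, add radial high-intensity spokes around the
#'   marker, approximating metal streak artifacts (off by default).
#' @param seed Integer seed fixing all randomness.
#' @param body_shifts,marker_offsets,refstruct_offsets Optional explicit
#'   per-phase values (matrix with one row per phase, or a single length-3
#'   vector recycled to all phases) overriding the seeded uniform draws --
#'   used to programme exact ground-truth scenarios.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(96L, 96L, 96L), spacing = c(1.5, 1.5, 1.5),
                         n_fb = 3L, amplitude_mm = 8,
                         marker_offset_mm = 2, refstruct_offset_mm = 3.5,
                         body_shift_mm = 3, body_rotation_deg = 0,
                         noise_sd = 20, streaks = FALSE, seed = 1L,
                         body_shifts = NULL, marker_offsets = NULL,
                         refstruct_offsets = NULL) {
  dim <- as.integer(dim)
  spacing <- as.numeric(spacing)
  stopifnot(length(dim) == 3L, all(dim >= 32L), length(spacing) == 3L,
            all(spacing > 0), n_fb >= 1L, amplitude_mm >= 0,
            marker_offset_mm >= 0, refstruct_offset_mm >= 0,
            body_shift_mm >= 0, noise_sd >= 0)
  extent <- (dim - 1L) * spacing
  cxy <- extent[1:2] / 2
  heart_center <- c(0.60 * extent[1], 0.42 * extent[2], 0.50 * extent[3])
  n_phases <- 1L + n_fb
  brot <- rep_len(as.numeric(body_rotation_deg), n_phases)
  structure(list(
    dim = dim, spacing = spacing, origin = c(0, 0, 0),
    body_center = cxy, body_radii = c(0.435 * extent[1], 0.365 * extent[2]),
    spine_center = c(cxy[1], 0.785 * extent[2]), spine_radius = 9,
    heart_center = heart_center, heart_radii = c(28, 26, 30),
    marker_rel = c(-15, 6, -10), marker_radius = 2.2,
    refstruct_rel = c(8, -5, 8),
    refstruct_blobs = rbind(c(0, 0, 0, 4),      # (dx, dy, dz, radius) mm
                            c(5, 2, -3, 2.5),
                            c(-4, 3, 3, 2.5),
                            c(2, -4, 4, 2),
                            c(-3, -3, -4, 2)),
    ctv_rel = c(10, 8, -8), ctv_radius = 9,
    hu = c(air = -1000, tissue = 40, heart = 300, spine = 700,
           marker = 3000, refstruct_contrast = 150),
    edge_mm = 2,
    n_fb = as.integer(n_fb), amplitude_mm = amplitude_mm,
    marker_offset_mm = marker_offset_mm,
    refstruct_offset_mm = refstruct_offset_mm,
    body_shift_mm = body_shift_mm, body_rotation_deg = brot,
    noise_sd = noise_sd, streaks = isTRUE(streaks),
    seed = as.integer(seed),
    body_shifts = fixed_phase_matrix(body_shifts, n_phases),
    marker_offsets = fixed_phase_matrix(marker_offsets, n_phases),
    refstruct_offsets = fixed_phase_matrix(refstruct_offsets, n_phases)),
    class = "phantom_spec")
}

fixed_phase_matrix <- function(x, n_phases) {
  if (is.null(x)) return(NULL)
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), n_phases, 3, byrow = TRUE)
  if (nrow(m) != n_phases || ncol(m) != 3L)
    stop(sprintf("per-phase override must be %d x 3", n_phases))
  m
}

#' Default breathing profile
#'
#' Per-phase heart shifts (mm, LPS): superior-inferior dominant, with
#' smaller anterior-posterior and left-right components. The inspiration
#' phase is deterministic and sits at the amplitude extreme (the heart moves
#' inferiorly by exactly `amplitude_mm`), reflecting that instructed
#' inspiration breath-holds tend to exaggerate the free-breathing range; the
#' free-breathing phases are drawn uniformly within the amplitude under the
#' given seed.
#'
#' @param n_phases Total number of phases (inspiration + free-breathing).
#' @param amplitude_mm Superior-inferior amplitude in mm, >= 0.
#' @param seed Integer seed for the free-breathing draws.
#' @return Matrix `n_phases` x 3 with rownames `ibh`, `fb1`, ...
#' @export
default_breathing_profile <- function(n_phases, amplitude_mm, seed = 1L) {
  stopifnot(n_phases >= 1L, amplitude_mm >= 0)
  a <- amplitude_mm
  out <- matrix(0, n_phases, 3,
                dimnames = list(c("ibh", if (n_phases > 1L)
                  paste0("fb", seq_len(n_phases - 1L))), c("x", "y", "z")))
  out[1, ] <- c(0.10 * a, 0.25 * a, -a) # inspiration: deterministic extreme
  if (n_phases > 1L) {
    n <- n_phases - 1L
    withr_seed <- function(expr) { # local RNG scope
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
              else suppressWarnings(rm(".Random.seed", envir = globalenv())))
      set.seed(seed)
      expr
    }
    draws <- withr_seed(cbind(runif(n, -0.15 * a, 0.15 * a),
                              runif(n, -0.30 * a, 0.30 * a),
                              runif(n, -a, a)))
    out[-1, ] <- draws
  }
  out
}

# soft-edge coverage weight from an approximate signed distance (mm)
soft_edge <- function(sd_mm, edge_mm) pmin(pmax(0.5 - sd_mm / edge_mm, 0), 1)

# render one phase; motion is a list with body (3), body_rot_deg (1),
# heart (3), dm (3), dr (3)
render_phase <- function(spec, motion, noise) {
  d <- spec$dim
  X <- grid_coords(list(dim = d, spacing = spec$spacing, origin = spec$origin))
  # body frame: undo body shift/rotation so anatomy renders at rest positions
  cb <- c(spec$body_center, (d[3] - 1) * spec$spacing[3] / 2)
  A <- sweep(X, 2, motion$body + cb)
  if (abs(motion$body_rot_deg) > 1e-12) {
    R <- rotation_matrix(c(motion$body_rot_deg, 0, 0))
    A <- A %*% R # = R^-1 applied to rows (R orthogonal, A %*% R == t(t(R) %*% t(A)))
  }
  A <- sweep(A, 2, cb, "+")
  v <- rep(spec$hu[["air"]], nrow(X))
  ew <- spec$edge_mm
  # body: elliptical cylinder
  rho <- sqrt(((A[, 1] - spec$body_center[1]) / spec$body_radii[1])^2 +
              ((A[, 2] - spec$body_center[2]) / spec$body_radii[2])^2)
  w <- soft_edge((rho - 1) * min(spec$body_radii), ew)
  v <- v + (spec$hu[["tissue"]] - v) * w
  # spine: circular cylinder, rigid with the body, with periodic vertebral
  # bodies and intervertebral discs so all three translations and the
  # axial rotation are identifiable from the spine alone
  dist_sp <- sqrt((A[, 1] - spec$spine_center[1])^2 +
                  (A[, 2] - spec$spine_center[2])^2) - spec$spine_radius
  w <- soft_edge(dist_sp, ew)
  u <- (A[, 3] - 21.5) %% 24          # disc centres every 24 mm
  disc <- soft_edge(pmin(u, 24 - u) - 2.5, ew)
  spine_val <- spec$hu[["spine"]] - 450 * disc
  v <- v + (spine_val - v) * w
  # transverse processes: a lateral ridge making y and the axial rotation
  # well conditioned
  dist_tp <- sqrt((abs(A[, 1] - spec$spine_center[1]) - 14)^2 +
                  (A[, 2] - spec$spine_center[2] - 2)^2) - 4
  w <- soft_edge(pmax(dist_tp, pmin(u, 24 - u) - 6), ew)
  v <- v + (spec$hu[["spine"]] - v) * w
  # heart: ellipsoid, shifted by the breathing motion
  hc <- spec$heart_center + motion$heart
  rho <- sqrt(((A[, 1] - hc[1]) / spec$heart_radii[1])^2 +
              ((A[, 2] - hc[2]) / spec$heart_radii[2])^2 +
              ((A[, 3] - hc[3]) / spec$heart_radii[3])^2)
  w <- soft_edge((rho - 1) * min(spec$heart_radii), ew)
  v <- v + (spec$hu[["heart"]] - v) * w
  # reference structure: heterogeneous blob cluster, heart motion + delta_r
  rc <- hc + spec$refstruct_rel + motion$dr
  for (b in seq_len(nrow(spec$refstruct_blobs))) {
    p <- rc + spec$refstruct_blobs[b, 1:3]
    dist_b <- sqrt((A[, 1] - p[1])^2 + (A[, 2] - p[2])^2 +
                   (A[, 3] - p[3])^2) - spec$refstruct_blobs[b, 4]
    w <- soft_edge(dist_b, ew)
    target_val <- spec$hu[["heart"]] + spec$hu[["refstruct_contrast"]]
    v <- v + (target_val - v) * w
  }
  # marker: small bright sphere, heart motion + delta_m
  mc <- hc + spec$marker_rel + motion$dm
  dist_m <- sqrt((A[, 1] - mc[1])^2 + (A[, 2] - mc[2])^2 +
                 (A[, 3] - mc[3])^2) - spec$marker_radius
  w <- soft_edge(dist_m, ew)
  v <- v + (spec$hu[["marker"]] - v) * w
  if (spec$streaks) {
    # radial high-intensity spokes in the axial plane around the marker
    dx <- A[, 1] - mc[1]; dy <- A[, 2] - mc[2]; dz <- A[, 3] - mc[3]
    r2d <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    spoke <- abs(sin(4 * ang)) < 0.08 & r2d > spec$marker_radius &
      r2d < 25 & abs(dz) < 2
    v[spoke] <- pmax(v[spoke], 1200 * (1 - r2d[spoke] / 30))
  }
  if (noise > 0) v <- v + rnorm(length(v), 0, noise)
  image_volume(array(v, d), spec$spacing, spec$origin)
}

# sphere mask on the phantom grid
sphere_mask <- function(spec, center, radius) {
  X <- grid_coords(list(dim = spec$dim, spacing = spec$spacing,
                        origin = spec$origin))
  d2 <- (X[, 1] - center[1])^2 + (X[, 2] - center[2])^2 + (X[, 3] - center[3])^2
  array(d2 <= radius^2, spec$dim)
}

box_mask <- function(spec, center, half_mm) {
  X <- grid_coords(list(dim = spec$dim, spacing = spec$spacing,
                        origin = spec$origin))
  array(abs(X[, 1] - center[1]) <= half_mm &
        abs(X[, 2] - center[2]) <= half_mm &
        abs(X[, 3] - center[3]) <= half_mm, spec$dim)
}

#' Generate the phantom study and its ground truth
#'
#' Renders the primary (expiration breath-hold) series at the rest geometry
#' and the secondary series (inspiration plus free-breathing phases) with
#' their programmed body, heart, marker and reference-structure motions,
#' adds Gaussian noise, and builds the CTV and the spine / marker /
#' reference-structure ROIs on the primary grid. The exported ground truth
#' holds, per phase, the body transform, the net marker and
#' reference-structure translations (heart motion plus the respective
#' offset), the true deformation vector (their difference, exactly
#' `delta_r - delta_m`), and the true CTV position in the marker-tracked
#' frame.
#'
#' @param spec A [phantom_spec()].
#' @return List of class `phantom_study` with elements `study` (a
#'   [study_set()]) and `truth` (per-phase ground truth, plus the per-phase
#'   true CTV masks).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n_phases <- 1L + spec$n_fb
  # the profile scopes its own RNG stream; give it a distinct derived seed so
  # its draws do not replay the body/offset draws below
  heart <- default_breathing_profile(n_phases, spec$amplitude_mm,
                                     seed = (spec$seed + 7919L) %% .Machine$integer.max)
  body <- if (!is.null(spec$body_shifts)) spec$body_shifts else
    matrix(runif(3 * n_phases, -spec$body_shift_mm, spec$body_shift_mm),
           n_phases, 3)
  dm <- if (!is.null(spec$marker_offsets)) spec$marker_offsets else
    matrix(runif(3 * n_phases, -spec$marker_offset_mm, spec$marker_offset_mm),
           n_phases, 3)
  dr <- if (!is.null(spec$refstruct_offsets)) spec$refstruct_offsets else
    matrix(runif(3 * n_phases, -spec$refstruct_offset_mm, spec$refstruct_offset_mm),
           n_phases, 3)
  phase_names <- rownames(heart)
  # every structure must stay inside the grid at every phase
  extent <- (spec$dim - 1L) * spec$spacing
  for (p in seq_len(n_phases)) {
    hc <- spec$heart_center + heart[p, ] + body[p, ]
    for (ctr in list(hc + spec$marker_rel + dm[p, ],
                     hc + spec$refstruct_rel + dr[p, ],
                     hc + spec$ctv_rel)) {
      if (any(ctr < 12) || any(ctr > extent - 12))
        stop(sprintf("phantom structure leaves the grid at phase '%s'; reduce motion or enlarge the grid",
                     phase_names[p]))
    }
  }
  zero <- list(body = c(0, 0, 0), body_rot_deg = 0,
               heart = c(0, 0, 0), dm = c(0, 0, 0), dr = c(0, 0, 0))
  primary <- render_phase(spec, zero, spec$noise_sd)
  secondaries <- list()
  for (p in seq_len(n_phases)) {
    motion <- list(body = body[p, ], body_rot_deg = spec$body_rotation_deg[p],
                   heart = heart[p, ], dm = dm[p, ], dr = dr[p, ])
    secondaries[[phase_names[p]]] <- render_phase(spec, motion, spec$noise_sd)
  }
  grid <- list(spacing = spec$spacing, origin = spec$origin)
  ctv <- binary_structure(
    sphere_mask(spec, spec$heart_center + spec$ctv_rel, spec$ctv_radius),
    grid, label = "ctv")
  spine_xy <- sphere_mask_cyl(spec, spec$spine_center, spec$spine_radius + 12)
  rois <- list(
    spine = binary_structure(spine_xy, grid, label = "spine"),
    marker = binary_structure(
      box_mask(spec, spec$heart_center + spec$marker_rel, 13), grid,
      label = "marker"),
    refstruct = binary_structure(
      box_mask(spec, spec$heart_center + spec$refstruct_rel, 8), grid,
      label = "refstruct"))
  study <- study_set(primary, secondaries, ctv, rois)
  truth <- list()
  for (p in seq_len(n_phases)) {
    defo <- dr[p, ] - dm[p, ]
    truth[[phase_names[p]]] <- list(
      body = rigid_transform(translation = body[p, ],
                             rotation = c(spec$body_rotation_deg[p], 0, 0),
                             center = c(spec$body_center,
                                        (spec$dim[3] - 1) * spec$spacing[3] / 2),
                             fixed = "primary", moving = phase_names[p]),
      marker_net = heart[p, ] + dm[p, ],
      refstruct_net = heart[p, ] + dr[p, ],
      deformation = deformation_vector_new(phase_names[p], defo),
      ctv_true = translate_structure(ctv, defo))
  }
  structure(list(study = study, truth = truth, spec = spec),
            class = "phantom_study")
}

# cylinder mask (all z) used for the spine ROI
sphere_mask_cyl <- function(spec, center_xy, radius) {
  X <- grid_coords(list(dim = spec$dim, spacing = spec$spacing,
                        origin = spec$origin))
  d2 <- (X[, 1] - center_xy[1])^2 + (X[, 2] - center_xy[2])^2
  array(d2 <= radius^2, spec$dim)
}

#' Run the registration chain on every secondary series of a phantom
#'
#' Convenience wrapper used by the validation suite and the pipeline: runs
#' [register_chain()] against each secondary of a generated phantom study
#' and returns chains plus estimated deformation vectors.
#'
#' @param ph A `phantom_study` from [generate_series()] (or any
#'   [study_set()] in `ph$study`).
#' @return List with `chains` (per secondary) and `vectors` (list of
#'   deformation vectors in the same order).
#' @export
register_study <- function(ph) {
  study <- if (inherits(ph, "phantom_study")) ph$study else ph
  stopifnot(inherits(study, "study_set"))
  chains <- list()
  for (nm in names(study$secondaries)) {
    chains[[nm]] <- register_chain(
      study$primary, study$secondaries[[nm]],
      spine_roi = study$rois$spine, marker_roi = study$rois$marker,
      ref_roi = study$rois$refstruct, series_id = nm)
  }
  list(chains = chains, vectors = lapply(chains, `[[`, "deformation"))
}
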