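# End-to-end orchestration: phantom -> triple registration -> GDM target
# construction -> comparisons -> report bundle, with a validated
# configuration, a manifest, and deterministic outputs under a fixed seed.

run_config_defaults <- function() {
  list(
    mode = "phantom",          # "phantom" or "files"
    out_dir = NULL,            # directory for artifacts (NULL: in-memory only)
    iso_margin_mm = 2.0,
    kernel = "box",            # "box" or "ellipsoid"
    coverage_fraction = 0.95,
    seed = 1L,
    hu_threshold = 1500,
    noise_sd = 20,
    amplitude_mm = 8,
    marker_offset_mm = 2,
    refstruct_offset_mm = 3.5,
    body_shift_mm = 3,
    n_fb = 3L,
    grid_dim = c(96L, 96L, 96L),
    spacing_mm = c(1.5, 1.5, 1.5),
    write_images = FALSE,      # write NRRD series/masks under out_dir
    # file mode inputs
    primary = NULL, secondaries = NULL, ctv = NULL,
    spine_roi = NULL, marker_roi = NULL, ref_roi = NULL,
    verbosity = 1L)
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; values are validated before any computation.
#'
#' @param ... Configuration values overriding the defaults (see Details).
#' @param config Optional list (e.g. from a YAML file) merged before `...`.
#' @details Keys: `mode` ("phantom" or "files"), `out_dir`, `iso_margin_mm`
#'   (default 2), `kernel` ("box"/"ellipsoid"), `coverage_fraction`, `seed`,
#'   `hu_threshold`, `noise_sd`, `amplitude_mm`, `n_fb`, `grid_dim`,
#'   `spacing_mm`, `write_images`, and in file mode the input paths
#'   `primary`, `secondaries` (named vector), `ctv`, `spine_roi`,
#'   `marker_roi`, `ref_roi`, plus `verbosity`.
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(..., config = NULL) {
  cfg <- run_config_defaults()
  user <- c(as.list(config), list(...))
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(user)] <- user
  if (!cfg$mode %in% c("phantom", "files")) stop("mode must be 'phantom' or 'files'")
  if (!cfg$kernel %in% c("box", "ellipsoid")) stop("kernel must be 'box' or 'ellipsoid'")
  if (!is.finite(cfg$iso_margin_mm) || cfg$iso_margin_mm < 0)
    stop("iso_margin_mm must be >= 0")
  if (cfg$coverage_fraction <= 0 || cfg$coverage_fraction > 1)
    stop("coverage_fraction must be in (0, 1]")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$mode == "files") {
    need <- c("primary", "ctv", "spine_roi", "marker_roi", "ref_roi")
    missing <- need[vapply(cfg[need], is.null, logical(1))]
    if (length(missing) || is.null(cfg$secondaries) || !length(cfg$secondaries))
      stop(sprintf("file mode requires primary, secondaries, ctv and the three ROIs (missing: %s)",
                   paste(c(missing, if (is.null(cfg$secondaries)) "secondaries"),
                         collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, stage, fmt, ...) {
  if (cfg$verbosity > 0)
    message(sprintf("[gdmrt:%s] %s", stage, sprintf(fmt, ...)))
}

load_study_from_files <- function(cfg) {
  primary <- read_image(cfg$primary)
  secs <- cfg$secondaries
  if (is.null(names(secs)) || any(names(secs) == ""))
    names(secs) <- paste0("sec", seq_along(secs))
  secondaries <- lapply(secs, read_image)
  study_set(primary, secondaries,
            ctv = read_mask(cfg$ctv, "ctv"),
            rois = list(spine = read_mask(cfg$spine_roi, "spine"),
                        marker = read_mask(cfg$marker_roi, "marker"),
                        refstruct = read_mask(cfg$ref_roi, "refstruct")))
}

#' Run the full target-definition pipeline
#'
#' Stages: obtain the study (render the phantom, or load images in file
#' mode); triple-register every secondary series; build the GDM margin and
#' all target volumes; compare the target volumes pairwise; and, in phantom
#' mode, check the estimated deformation vectors and target coverage against
#' the ground truth. Each stage aborts with a stage-labelled error; partial
#' artifacts already written remain on disk. Deterministic under a fixed
#' seed, and every run with an `out_dir` writes a manifest (config hash,
#' seed, package version).
#'
#' @param cfg A [run_config()].
#' @return List of class `pipeline_result` with `config`, `margin`,
#'   `vectors`, `targets` (a `target_set`), `comparisons` (data.frame),
#'   `volumes_cm3`, `containment`, and in phantom mode `truth_check`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  t0 <- proc.time()[["elapsed"]]
  input <- stage("input", {
    if (cfg$mode == "phantom") {
      spec <- phantom_spec(dim = cfg$grid_dim, spacing = cfg$spacing_mm,
                           n_fb = cfg$n_fb, amplitude_mm = cfg$amplitude_mm,
                           marker_offset_mm = cfg$marker_offset_mm,
                           refstruct_offset_mm = cfg$refstruct_offset_mm,
                           body_shift_mm = cfg$body_shift_mm,
                           noise_sd = cfg$noise_sd, seed = cfg$seed)
      ph <- generate_series(spec)
      list(study = ph$study, ph = ph)
    } else list(study = load_study_from_files(cfg), ph = NULL)
  })
  study <- input$study
  ph <- input$ph
  pipeline_log(cfg, "input", "study ready (%d secondaries) after %.1f s",
               length(study$secondaries), proc.time()[["elapsed"]] - t0)
  reg <- stage("registration", register_study(study))
  pipeline_log(cfg, "registration", "%d chains done after %.1f s",
               length(reg$chains), proc.time()[["elapsed"]] - t0)
  targets <- stage("gdm", build_target_set(study$ctv, reg$vectors,
                                           iso_margin_mm = cfg$iso_margin_mm,
                                           kernel = cfg$kernel))
  comparisons <- stage("compare", {
    pairs <- list(c("itv_gdm", "itv_gdm_sum"), c("ptv_gdm", "ptv_gdm_sum"),
                  c("ctv", "itv_gdm"), c("ctv", "itv_gdm_sum"))
    do.call(rbind, lapply(pairs, function(p)
      compare_structures(targets[[p[1]]], targets[[p[2]]])))
  })
  containment <- list(
    ctv_in_sum = !any(targets$ctv$mask & !targets$itv_gdm_sum$mask),
    sum_in_itv = !any(targets$itv_gdm_sum$mask & !targets$itv_gdm$mask),
    itv_in_ptv = !any(targets$itv_gdm$mask & !targets$ptv_gdm$mask),
    sum_in_ptv_sum = !any(targets$itv_gdm_sum$mask & !targets$ptv_gdm_sum$mask))
  volumes <- vapply(c(ctv = "ctv", itv_gdm_sum = "itv_gdm_sum",
                      itv_gdm = "itv_gdm", ptv_gdm_sum = "ptv_gdm_sum",
                      ptv_gdm = "ptv_gdm"),
                    function(nm) volume_cm3(targets[[nm]]), numeric(1))
  truth_check <- NULL
  if (!is.null(ph)) {
    errs <- vapply(names(ph$truth), function(nm)
      max(abs(reg$vectors[[nm]]$d - ph$truth[[nm]]$deformation$d)), numeric(1))
    missed <- vapply(names(ph$truth), function(nm)
      sum(ph$truth[[nm]]$ctv_true$mask & !targets$itv_gdm$mask), numeric(1))
    truth_check <- list(max_deformation_error_mm = max(errs),
                        per_phase_error_mm = errs,
                        missed_target_voxels = sum(missed))
  }
  result <- structure(list(
    config = unclass(cfg), margin = targets$margin,
    vectors = reg$vectors, chains = reg$chains, targets = targets,
    comparisons = comparisons, volumes_cm3 = as.list(volumes),
    containment = containment, truth_check = truth_check),
    class = "pipeline_result")
  if (!is.null(cfg$out_dir)) stage("report", write_report(result, cfg, study))
  result
}

report_payload <- function(result) {
  m <- result$margin
  list(
    margin_mm = list(A = m$anterior, P = m$posterior, R = m$right,
                     L = m$left, S = m$superior, I = m$inferior),
    vectors = lapply(result$vectors, function(v)
      list(series = v$series_id, d_mm = v$d)),
    volumes_cm3 = result$volumes_cm3,
    containment = result$containment,
    comparisons = lapply(seq_len(nrow(result$comparisons)), function(i)
      as.list(result$comparisons[i, ])),
    truth_check = if (is.null(result$truth_check)) NULL else
      list(max_deformation_error_mm = result$truth_check$max_deformation_error_mm,
           missed_target_voxels = result$truth_check$missed_target_voxels))
}

write_report <- function(result, cfg, study) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_payload(result),
                       file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write.csv(result$comparisons, file.path(cfg$out_dir, "comparisons.csv"),
            row.names = FALSE)
  for (nm in names(result$chains)) {
    write_transform_json(result$chains[[nm]]$refstruct$transform,
                         file.path(cfg$out_dir, sprintf("chain_%s.json", nm)))
  }
  if (isTRUE(cfg$write_images)) {
    for (nm in c("ctv", "itv_gdm", "itv_gdm_sum", "ptv_gdm", "ptv_gdm_sum"))
      write_image(result$targets[[nm]], file.path(cfg$out_dir, paste0(nm, ".nrrd")))
    write_image(study$primary, file.path(cfg$out_dir, "primary.nrrd"))
  }
  # manifest: configuration hash, seed, software version
  cfg_canon <- jsonlite::toJSON(unclass(cfg)[order(names(unclass(cfg)))],
                                auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  writeLines(as.character(cfg_canon), tf)
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(tf)),
         seed = cfg$seed,
         package_version = as.character(packageVersion("gdmrt"))),
    file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  unlink(tf)
  invisible(cfg$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$margin)
  cat(sprintf("  volumes (cm^3): %s\n",
              paste(sprintf("%s=%.2f", names(x$volumes_cm3),
                            unlist(x$volumes_cm3)), collapse = ", ")))
  cat(sprintf("  containment: %s\n",
              paste(sprintf("%s=%s", names(x$containment),
                            unlist(x$containment)), collapse = ", ")))
  if (!is.null(x$truth_check))
    cat(sprintf("  ground truth: max deformation error %.3f mm, %d missed target voxel(s)\n",
                x$truth_check$max_deformation_error_mm,
                x$truth_check$missed_target_voxels))
  invisible(x)
}
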