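# Reading and writing images, masks and transforms.
#
# NIfTI-1 goes through RNifti. NRRD support is a small built-in reader/writer
# for the subset this package produces: 3D, raw or gzip encoding,
# little-endian, axis-aligned space directions.

#' Read an image volume from NRRD or NIfTI
#'
#' Spacing and origin are taken from the file header (NRRD space directions /
#' NIfTI sform). Axis directions are interpreted on the package's LPS
#' convention.
#'
#' @param path File ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @return An [image_volume()].
#' @export
read_image <- function(path) {
  g <- read_any_image(path)
  image_volume(g$data, g$spacing, g$origin)
}

#' Read a binary mask from NRRD or NIfTI
#'
#' Voxels with value > 0.5 become TRUE.
#'
#' @param path File ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @param label Label for the resulting structure (default: file base name).
#' @return A [binary_structure()].
#' @export
read_mask <- function(path, label = NULL) {
  g <- read_any_image(path)
  if (is.null(label))
    label <- sub("\\.(nrrd|nii|nii\\.gz)$", "", basename(path))
  binary_structure(g$data > 0.5,
                   list(spacing = g$spacing, origin = g$origin), label = label)
}

#' Write an image volume or mask to NRRD or NIfTI
#'
#' Masks are stored as unsigned 8-bit 0/1; scalar images as 32-bit float.
#' Spacing and origin are preserved in the header.
#'
#' @param x An [image_volume()] or [binary_structure()].
#' @param path Output file ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  is_mask <- inherits(x, "binary_structure")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("x must be an image_volume or binary_structure")
  data <- if (is_mask) array(as.integer(x$mask), dim(x$mask)) else x$data
  fmt <- file_format(path)
  if (fmt == "nrrd") {
    write_nrrd(data, path, x$spacing, x$origin,
               type = if (is_mask) "uint8" else "float")
  } else {
    img <- RNifti::asNifti(data)
    RNifti::pixdim(img) <- x$spacing
    sf <- diag(c(x$spacing, 1))
    sf[1:3, 4] <- x$origin
    RNifti::sform(img) <- structure(sf, code = 1L)
    RNifti::writeNifti(img, path,
                       datatype = if (is_mask) "uint8" else "float")
  }
  invisible(path)
}

file_format <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
  else stop(sprintf("unsupported image format: '%s' (use .nrrd, .nii or .nii.gz)", path))
}

read_any_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file_format(path) == "nrrd") read_nrrd(path)
  else {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    list(data = array(as.numeric(img), dim(img)),
         spacing = abs(c(xf[1, 1], xf[2, 2], xf[3, 3])),
         origin = as.numeric(xf[1:3, 4]))
  }
}

nrrd_type_map <- c(uint8 = "uint8", uchar = "uint8",
                   "unsigned char" = "uint8",
                   short = "int16", "signed short" = "int16", int16 = "int16",
                   int = "int32", int32 = "int32",
                   float = "float", double = "double")

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop(sprintf("not an NRRD file: %s", path))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3) stop("only 3D NRRD volumes are supported")
  type <- nrrd_type_map[[tolower(fields[["type"]])]]
  if (is.null(type)) stop(sprintf("unsupported NRRD type '%s'", fields[["type"]]))
  enc <- tolower(fields[["encoding"]])
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(dirs, function(s)
      as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  raw_rest <- readBin(con, "raw", n = file.size(path)) # rest of file
  if (enc %in% c("gzip", "gz")) raw_rest <- memDecompress(raw_rest, type = "gzip")
  else if (enc != "raw") stop(sprintf("unsupported NRRD encoding '%s'", enc))
  endian <- if (!is.null(fields[["endian"]]) &&
                tolower(fields[["endian"]]) == "big") "big" else "little"
  vals <- switch(type,
    uint8 = as.numeric(readBin(raw_rest, "integer", n = n, size = 1, signed = FALSE)),
    int16 = as.numeric(readBin(raw_rest, "integer", n = n, size = 2, endian = endian)),
    int32 = as.numeric(readBin(raw_rest, "integer", n = n, size = 4, endian = endian)),
    float = readBin(raw_rest, "double", n = n, size = 4, endian = endian),
    double = readBin(raw_rest, "double", n = n, size = 8, endian = endian))
  if (length(vals) < n) stop("truncated NRRD data block")
  list(data = array(vals[seq_len(n)], sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(data, path, spacing, origin, type = "float") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# written by gdmrt",
    sprintf("type: %s", if (type == "uint8") "uint8" else type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(dim(data), collapse = " ")),
    sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
            spacing[1], spacing[2], spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%g,%g,%g)", origin[1], origin[2], origin[3]),
    "")
  writeLines(hdr, con, sep = "\n")
  if (type == "uint8") {
    writeBin(as.raw(as.integer(data)), con)
  } else if (type == "float") {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' Write a rigid transform to JSON
#'
#' Layout: `{"translation_mm": [x,y,z], "rotation_deg": [rz,ry,rx],
#' "center_mm": [x,y,z], "fixed": "...", "moving": "..."}`.
#'
#' @param transform A [rigid_transform()].
#' @param path Output `.json` file.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(translation_mm = transform$translation,
         rotation_deg = transform$rotation,
         center_mm = transform$center,
         fixed = transform$fixed,
         moving = transform$moving),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#'
#' @param path JSON file written by [write_transform_json()] (the `center_mm`
#'   key is optional and defaults to the origin).
#' @return A [rigid_transform()].
#' @export
read_transform_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(translation = j$translation_mm,
                  rotation = j$rotation_deg,
                  center = if (is.null(j$center_mm)) c(0, 0, 0) else j$center_mm,
                  fixed = if (is.null(j$fixed)) "primary" else j$fixed,
                  moving = if (is.null(j$moving)) "secondary" else j$moving)
}
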