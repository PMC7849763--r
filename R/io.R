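#' Read and write volumes
#'
#' Lossless round-trip of voxel data and spacing in three formats chosen by
#' extension: NIfTI (`.nii`, `.nii.gz`, via RNifti), MetaImage (`.mha`,
#' uncompressed `MET_DOUBLE`, local data) and raw doubles with a JSON sidecar
#' (`.raw` + `.json`). Axis order on disk is documented as `[Z, Y, X]`
#' fastest-moving-first, i.e. the in-memory `[x, y, z]` column-major layout
#' written as-is.
#'
#' @param volume a [vol3d()].
#' @param path output file; the format follows the extension.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [vol3d()].
#' @export
write_volume <- function(volume, path) {
  ext <- file_ext_lower(path)
  sp <- vol_spacing(volume)
  d <- dim(volume)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::asNifti(unclass(volume))
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path)
  } else if (ext == "mha") {
    write_mha(unclass(volume), sp, path)
  } else if (ext == "raw") {
    sidecar <- paste0(sub("\\.raw$", "", path), ".json")
    jsonlite::write_json(list(dim = d, spacing = sp, type = "double",
                              order = "zyx-fastest-x"),
                         sidecar, auto_unbox = TRUE, digits = NA)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.double(volume), con, size = 8, endian = "little")
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- file_ext_lower(path)
  if (ext %in% c("nii", "nii.gz")) {
    img <- RNifti::readNifti(path)
    sp <- attr(img, "pixdim")[1:3]
    vol3d(array(as.double(img), dim(img)), sp)
  } else if (ext == "mha") {
    read_mha(path)
  } else if (ext == "raw") {
    sidecar <- paste0(sub("\\.raw$", "", path), ".json")
    if (!file.exists(sidecar)) stop("missing JSON sidecar for ", path, call. = FALSE)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    n <- prod(meta$dim)
    con <- file(path, "rb")
    on.exit(close(con))
    x <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(x) != n)
      stop("truncated raw volume: expected ", n, " voxels, got ", length(x),
           call. = FALSE)
    vol3d(array(x, meta$dim), meta$spacing)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
}

file_ext_lower <- function(path) {
  if (grepl("\\.nii\\.gz$", path, ignore.case = TRUE)) return("nii.gz")
  tolower(sub(".*\\.", "", path))
}

write_mha <- function(arr, spacing, path) {
  d <- dim(arr)
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False", "CompressedData = False",
           sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
           sprintf("ElementSpacing = %.17g %.17g %.17g",
                   spacing[1], spacing[2], spacing[3]),
           sprintf("Offset = %.17g %.17g %.17g",
                   -d[1] * spacing[1] / 2 + spacing[1] / 2,
                   -d[2] * spacing[2] / 2 + spacing[2] / 2,
                   -d[3] * spacing[3] / 2 + spacing[3] / 2),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(arr), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data supported", call. = FALSE)
  d <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  sp <- as.double(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]])
  type <- hdr[["ElementType"]]
  n <- prod(d)
  x <- switch(type,
              MET_DOUBLE = readBin(con, "double", n = n, size = 8, endian = "little"),
              MET_FLOAT = readBin(con, "double", n = n, size = 4, endian = "little"),
              stop("unsupported MetaImage element type: ", type, call. = FALSE))
  if (length(x) != n)
    stop("truncated MetaImage data: expected ", n, " voxels, got ", length(x),
         call. = FALSE)
  vol3d(array(x, d), sp)
}

#' Read and write deformation fields
#'
#' Raw doubles plus a JSON sidecar stamped with the storage convention
#' (pull-back displacements, mm, grid layout), so that misuse of a field
#' file is detectable.
#'
#' @param dvf a [dvf3d()].
#' @param path `.raw` output path (sidecar written next to it).
#' @return `write_dvf` returns `path` invisibly; `read_dvf` a [dvf3d()].
#' @export
write_dvf <- function(dvf, path) {
  sidecar <- paste0(sub("\\.raw$", "", path), ".json")
  jsonlite::write_json(list(dim = dim(dvf), spacing = vol_spacing(dvf),
                            direction = attr(dvf, "direction"),
                            phase = attr(dvf, "phase"),
                            convention = "pull-back displacement, mm",
                            type = "double"),
                       sidecar, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.double(dvf), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_dvf
#' @export
read_dvf <- function(path) {
  sidecar <- paste0(sub("\\.raw$", "", path), ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar for ", path, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop("truncated DVF file", call. = FALSE)
  dvf3d(array(x, meta$dim), meta$spacing, direction = meta$direction,
        phase = meta$phase)
}

#' Read and write phase-sorted projection sets
#'
#' Single-container format: one JSON manifest holding the geometry, phase
#' count, per-phase view counts and gantry angles, next to one raw file with
#' all phases' line integrals concatenated in phase order. Round-trips are
#' bit-identical.
#'
#' @param projections a [projection_set()].
#' @param path `.json` manifest path (the `.raw` data file sits next to it).
#' @return `write_projections` returns `path` invisibly; `read_projections`
#'   a [projection_set()].
#' @export
write_projections <- function(projections, path) {
  g <- projections$geometry
  rawpath <- paste0(sub("\\.json$", "", path), ".raw")
  meta <- list(
    geometry = list(sad = g$sad, sdd = g$sdd, nu = g$nu, nv = g$nv,
                    du = g$du, dv = g$dv),
    n_phases = length(projections$stacks),
    views = vapply(projections$stacks, function(s) dim(s)[3], 1L),
    angles = lapply(projections$stacks, function(s) attr(s, "angles")))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  # angles are written into the binary container as well: JSON text would
  # round doubles, and the round-trip contract is bit-identity
  con <- file(rawpath, "wb")
  on.exit(close(con))
  for (s in projections$stacks) {
    writeBin(as.double(attr(s, "angles", exact = TRUE)), con, size = 8,
             endian = "little")
    writeBin(as.double(s), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$geometry) || is.null(meta$geometry$sad))
    stop("projection manifest lacks geometry attributes", call. = FALSE)
  # equal-length angle vectors may come back simplified into a matrix
  angles <- if (is.matrix(meta$angles))
    lapply(seq_len(nrow(meta$angles)), function(i) meta$angles[i, ])
  else if (is.list(meta$angles)) meta$angles
  else list(meta$angles)
  if (length(meta$views) != meta$n_phases ||
      length(angles) != meta$n_phases)
    stop("phase/view count mismatch in projection manifest", call. = FALSE)
  g <- meta$geometry
  for (t in seq_len(meta$n_phases))
    if (length(angles[[t]]) != meta$views[t])
      stop("angle list length does not match view count for phase ", t - 1L,
           call. = FALSE)
  rawpath <- paste0(sub("\\.json$", "", path), ".raw")
  con <- file(rawpath, "rb")
  on.exit(close(con))
  stacks <- vector("list", meta$n_phases)
  raw_angles <- vector("list", meta$n_phases)
  for (t in seq_len(meta$n_phases)) {
    ang <- readBin(con, "double", n = meta$views[t], size = 8,
                   endian = "little")
    if (length(ang) != meta$views[t] ||
        max(abs(ang - angles[[t]])) > 1e-9)
      stop("angle list in the data file disagrees with the manifest",
           call. = FALSE)
    n <- g$nu * g$nv * meta$views[t]
    x <- readBin(con, "double", n = n, size = 8, endian = "little")
    if (length(x) != n) stop("truncated projection data file", call. = FALSE)
    dim(x) <- c(g$nu, g$nv, meta$views[t])
    stacks[[t]] <- new_proj_stack(x, ang, t - 1L)
    raw_angles[[t]] <- ang
  }
  geom <- cone_beam_geometry(g$nu, g$nv, g$du, g$dv, raw_angles, g$sad, g$sdd)
  projection_set(stacks, geom)
}
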