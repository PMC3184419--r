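# Volume input/output: NIfTI-1 through RNifti and raw little-endian float
# with a JSON sidecar. Both formats round-trip values and header metadata;
# valid intervals and the periodic-time flag travel in the sidecar since
# NIfTI has no native field for them.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(vol, path, extent, datatype) {
  meta <- list(
    extent = extent, spacing = vol$spacing, order = "x-fastest",
    datatype = datatype, periodic_t = vol$periodic_t,
    valid = lapply(vol$valid, as.integer)
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

apply_sidecar <- function(vol, path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(vol)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!is.null(meta$spacing)) vol$spacing <- as.numeric(meta$spacing)
  if (!is.null(meta$periodic_t)) vol$periodic_t <- isTRUE(meta$periodic_t)
  if (!is.null(meta$valid)) {
    vol$valid <- lapply(seq_len(4L), function(a) {
      if (is.matrix(meta$valid)) as.integer(meta$valid[a, ])
      else as.integer(meta$valid[[a]])
    })
  }
  vol
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)

#' Write a volume to disk
#'
#' NIfTI-1 (`.nii` / `.nii.gz`, dims ordered x, y, z, t) or raw
#' little-endian float (any other extension) with a JSON sidecar recording
#' extent, spacing, voxel order, data type, valid intervals and the
#' periodic-time flag. Round trips through [read_volume()] are bit exact
#' for float64 and within single-precision rounding for float32.
#'
#' @param vol a [volume4d()].
#' @param path output path; the format follows the extension.
#' @param datatype `"float64"` (bit-exact) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  vol <- as_volume4d(vol)
  ext <- dim(vol$values)
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(vol$values)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path,
                       datatype = if (datatype == "float32") "float" else "double")
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(vol$values), con,
             size = if (datatype == "float32") 4L else 8L, endian = "little")
  }
  write_sidecar(vol, path, ext, datatype)
  invisible(path)
}

#' Read a volume from disk
#'
#' Reads NIfTI-1 or raw-float volumes written by [write_volume()] (raw
#' files require the JSON sidecar for the extent). 3D inputs are promoted
#' to 4D with a singleton time axis and a warning; non-finite values and
#' truncated raw payloads are rejected with informative errors.
#'
#' @param path input path.
#' @return a [volume4d()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    vals <- as.array(img)
    attributes(vals) <- list(dim = dim(vals))   # drop nifti image attributes
    nd <- length(dim(vals))
    if (nd > 4L) stop("field dim: more than 4 dimensions in ", path)
    if (nd == 3L) warning("3D input promoted to 4D with a singleton time axis")
    if (nd < 2L) stop("field dim: fewer than 2 dimensions in ", path)
    pd <- attr(img, "pixdim")
    vol <- volume4d(as_dim4(vals))
    if (!is.null(pd) && length(pd) >= nd) {
      vol$spacing[seq_len(nd)] <- pd[seq_len(nd)]
    }
  } else {
    sp <- sidecar_path(path)
    if (!file.exists(sp)) stop("raw volume requires a sidecar: ", sp)
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    ext <- as.integer(meta$extent)
    if (length(ext) == 3L) {
      warning("3D input promoted to 4D with a singleton time axis")
      ext <- c(ext, 1L)
    }
    if (length(ext) != 4L) stop("field extent: expected 3 or 4 dimensions")
    size <- if (identical(meta$datatype, "float32")) 4L else 8L
    expected <- prod(ext) * size
    actual <- file.size(path)
    if (actual != expected) {
      stop(sprintf("field data: expected %d bytes for extent %s, found %d",
                   expected, paste(ext, collapse = "x"), actual))
    }
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "double", n = prod(ext), size = size, endian = "little")
    vol <- volume4d(array(vals, ext))
  }
  if (!all(is.finite(vol$values))) stop("field values: non-finite entries in ", path)
  apply_sidecar(vol, path)
}
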