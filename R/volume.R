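#' 4D scalar volume
#'
#' The basic data container of the package: a 4D scalar field ordered
#' (x, y, z, t) with per-axis voxel spacing, per-axis valid index intervals
#' and a periodic-time flag. 2D and 3D data are carried with trailing
#' singleton extents.
#'
#' The valid interval of an axis is the index range (1-based, inclusive) in
#' which the values depend only on real data; filtering operations shrink it
#' on axes processed in `"valid"` mode and leave it untouched on circular
#' axes.
#'
#' @param values numeric array with up to 4 dimensions; all values finite.
#' @param spacing physical step per axis; defaults to 0.75 mm in x, y, z
#'   (typical cardiac CT) and 1 arbitrary unit in t.
#' @param valid list of four `c(first, last)` integer pairs, or `NULL` for
#'   the full extent.
#' @param periodic_t should the time axis be treated as circular (cardiac
#'   data is gated over the heart cycle)?
#' @return an object of class `volume4d` with elements `values`, `spacing`,
#'   `valid` and `periodic_t`.
#' @export
volume4d <- function(values, spacing = c(0.75, 0.75, 0.75, 1),
                     valid = NULL, periodic_t = TRUE) {
  values <- as_dim4(values)
  storage.mode(values) <- "double"
  stopifnot_finite(values)
  ext <- dim(values)
  if (length(spacing) != 4L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 4 positive finite numbers")
  }
  if (is.null(valid)) valid <- lapply(ext, function(n) c(1L, n))
  for (a in 1:4) {
    v <- valid[[a]]
    if (v[1L] < 1L || v[2L] > ext[a]) stop("valid interval outside extent on axis ", a)
  }
  structure(
    list(values = values, spacing = as.numeric(spacing), valid = valid,
         periodic_t = isTRUE(periodic_t)),
    class = "volume4d"
  )
}

as_volume4d <- function(x, template = NULL) {
  if (inherits(x, "volume4d")) return(x)
  if (!is.null(template)) {
    volume4d(x, spacing = template$spacing, periodic_t = template$periodic_t)
  } else {
    volume4d(x)
  }
}

#' @export
print.volume4d <- function(x, ...) {
  ext <- dim(x$values)
  cat(sprintf("volume4d: %s, spacing %s, periodic t: %s\n",
              paste(ext, collapse = " x "),
              paste(signif(x$spacing, 3), collapse = " x "),
              x$periodic_t))
  v <- vapply(x$valid, function(v) sprintf("[%d,%d]", v[1L], v[2L]), "")
  cat("  valid:", paste(v, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$values)

# Shrink the valid interval of one axis by a margin on both sides.
shrink_valid <- function(valid, axis, margin) {
  v <- valid[[axis]]
  valid[[axis]] <- c(v[1L] + margin, v[2L] - margin)
  valid
}

valid_is_empty <- function(valid) {
  any(vapply(valid, function(v) v[2L] < v[1L], TRUE))
}
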