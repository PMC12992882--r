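#' Volumetric image containers
#'
#' `volume_grid()` wraps a 3D scalar array together with its voxel spacing
#' (mm per axis) and a 4x4 voxel-to-world affine. `label_volume()` is the
#' companion container for integer-labelled masks and additionally carries a
#' label map (integer id -> segment name). Both are plain S3 lists so that
#' the array is always directly accessible as `$data`.
#'
#' The package-wide grid convention is *canonical orientation*: the first
#' array axis runs left to right, so hemisphere splitting is axis-aligned
#' (see [read_volume()] for reorientation on load).
#'
#' @param data 3D numeric (or integer, for labels) array.
#' @param spacing Numeric length-3, strictly positive, voxel size in mm.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine
#'   built from `spacing`.
#' @param units One of `"HU"`, `"normalized"`, `"filtered"`.
#' @param label_map Named integer vector mapping label ids to segment names,
#'   e.g. `c(`MCA-L` = 1L)`. Every nonzero voxel value must appear in it.
#' @return A `volume_grid` or `label_volume` object.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), affine = NULL,
                        units = c("HU", "normalized", "filtered")) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L) {
    stop("volume_grid requires a 3D array, got ", length(dim(data)), " dimensions")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive finite values (mm)")
  }
  if (any(!is.finite(data))) {
    stop("volume contains non-finite voxels (NaN/Inf rejected)")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  structure(
    list(data = data, spacing = spacing, affine = affine, units = units),
    class = "volume_grid"
  )
}

#' @rdname volume_grid
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                         label_map = NULL) {
  if (length(dim(data)) != 3L) {
    stop("label_volume requires a 3D array, got ", length(dim(data)), " dimensions")
  }
  storage.mode(data) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 strictly positive finite values (mm)")
  }
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  ids <- sort(unique(data[data != 0L]))
  if (is.null(label_map)) {
    label_map <- stats::setNames(ids, as.character(ids))
  }
  label_map <- stats::setNames(as.integer(label_map), names(label_map))
  missing_ids <- setdiff(ids, label_map)
  if (length(missing_ids) > 0) {
    stop("label ids without a label_map entry: ", paste(missing_ids, collapse = ", "))
  }
  structure(
    list(data = data, spacing = spacing, affine = as.matrix(affine),
         label_map = label_map),
    class = c("label_volume", "volume_grid")
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label_volume" else "volume_grid"
  cat(sprintf("<%s> %s voxels, spacing %s mm",
              kind, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x")))
  if (inherits(x, "label_volume")) {
    cat(sprintf(", %d labels", length(x$label_map)))
  } else {
    cat(sprintf(", units=%s", x$units))
  }
  cat("\n")
  invisible(x)
}

#' Check that two volumes live on the same grid
#'
#' Pure predicate: `TRUE` iff array shapes match and the affines agree
#' elementwise within an absolute tolerance of `1e-3` (sub-voxel at mm
#' scale). Inputs are assumed co-registered upstream; this guards against
#' silently mixing grids.
#'
#' @param a,b `volume_grid` / `label_volume` objects.
#' @return Logical scalar.
#' @export
check_grid_compat <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) return(FALSE)
  all(abs(a$affine - b$affine) <= 1e-3)
}

stop_if_incompatible <- function(a, b, what = "volumes") {
  if (!check_grid_compat(a, b)) {
    stop("grid mismatch between ", what,
         " (check_grid_compat failed: shapes or affines differ)")
  }
  invisible(TRUE)
}

# voxel volume in mm^3
voxel_volume <- function(x) prod(x$spacing)

#' @export
dim.volume_grid <- function(x) dim(x$data)
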