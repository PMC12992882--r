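#' Read and write volumes as NIfTI-1
#'
#' `read_volume()` loads a NIfTI-1/2 file (plain or gzipped) and returns a
#' [volume_grid()] (or [label_volume()] when `labels = TRUE`). On load the
#' image is reoriented to the package's canonical axis order -- "RAS", i.e.
#' the first array axis runs patient-left to patient-right -- so hemisphere
#' splitting is always axis-aligned. Reorientation is idempotent: loading a
#' file written by [write_volume()] changes nothing.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param labels Read as an integer label mask instead of a scalar image.
#' @param label_map Optional named integer vector naming the label ids.
#' @param units Intensity units for scalar images (default `"HU"`).
#' @return A `volume_grid` or `label_volume`.
#' @export
read_volume <- function(path, labels = FALSE, label_map = NULL, units = "HU") {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- RNifti::asNifti(array(as.array(img), dim = d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected a 3D volume, got ", length(d), " dimensions in ", path)
  }
  RNifti::orientation(img) <- "RAS"
  data <- as.array(img)
  data <- array(as.vector(data), dim = dim(data))  # drop RNifti attributes
  affine <- matrix(as.numeric(unclass(RNifti::xform(img))), 4, 4)
  # spacing from the affine columns; the header pixdim field is not trusted
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (labels) {
    if (any(abs(data - round(data)) > 1e-6)) {
      stop("label volume contains non-integer voxel values: ", path)
    }
    label_volume(round(data), spacing = spacing, affine = affine,
                 label_map = label_map)
  } else {
    volume_grid(data, spacing = spacing, affine = affine, units = units)
  }
}

#' @rdname read_volume
#' @param x A `volume_grid` or `label_volume`.
#' @export
write_volume <- function(x, path) {
  data <- x$data
  if (inherits(x, "label_volume")) storage.mode(data) <- "integer"
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(x$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Intensity preprocessing: clip to 1-500 HU, then z-score per scan
#'
#' CTA intensities are clipped to the `[1, 500]` HU window (bounds
#' inclusive; values below 1 HU are set to 1, above 500 HU to 500) and then
#' z-score normalized using the mean and standard deviation of the clipped
#' scan. By default the normalization support is the whole volume; pass a
#' mask via `within` to compute the moments over its nonzero support only
#' (all voxels are still transformed). The transform is monotone after
#' clipping, so voxel rank order inside the clip window is preserved.
#'
#' @param image A `volume_grid` with `units == "HU"`.
#' @param within Optional `label_volume`; moments computed over its support.
#' @param lower,upper Clip window in HU.
#' @return A `volume_grid` with `units == "normalized"`.
#' @export
clip_znorm <- function(image, within = NULL, lower = 1, upper = 500) {
  if (!inherits(image, "volume_grid") || inherits(image, "label_volume")) {
    stop("clip_znorm expects a scalar volume_grid")
  }
  if (!identical(image$units, "HU")) {
    stop("clip_znorm expects units = 'HU', got '", image$units, "'")
  }
  clipped <- pmin(pmax(image$data, lower), upper)
  support <- if (is.null(within)) {
    rep(TRUE, length(clipped))
  } else {
    stop_if_incompatible(image, within, "image and normalization mask")
    as.vector(within$data != 0L)
  }
  vals <- clipped[support]
  m <- mean(vals)
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a constant scan (sd = 0 over the normalization support)")
  }
  out <- (clipped - m) / s
  volume_grid(array(out, dim = dim(image$data)), spacing = image$spacing,
              affine = image$affine, units = "normalized")
}
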