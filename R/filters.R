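# Texture-enhancement filter bank: coif-1 stationary wavelet sub-bands and
# Laplacian-of-Gaussian responses. Both preserve the input grid so every
# filtered image can be sampled under the original ROI masks.

# Coiflet-1 analysis filters (orthonormal; lowpass sums to sqrt(2), the
# highpass is its quadrature mirror and has a vanishing moment, so detail
# bands of a constant image are exactly zero up to float rounding).
coif1_lo <- c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
              0.8525720202116004, 0.3378976624574818, -0.07273261951252645)
coif1_hi <- c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
              0.3848648468648578, 0.07273261951252645, -0.015655728135791993)

# circular shift of a 3D array along one axis
circ_shift <- function(a, by, axis) {
  d <- dim(a)
  n <- d[axis]
  by <- ((by %% n) + n) %% n
  if (by == 0) return(a)
  idx <- c(seq_len(n - by) + by, seq_len(by))
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# periodic (circular) 1D convolution along an axis: out[i] = sum_k h[k] x[i+k-1]
# (filter anchored at its first tap; the anchor is a fixed documented
# convention -- all sub-bands share it, so ROI statistics are unaffected)
conv_axis_periodic <- function(a, h, axis) {
  if (dim(a)[axis] < length(h)) {
    stop("axis ", axis, " (length ", dim(a)[axis],
         ") is shorter than the filter support (", length(h), ")")
  }
  out <- array(0, dim(a))
  for (k in seq_along(h)) {
    out <- out + h[k] * circ_shift(a, k - 1L, axis)
  }
  out
}

#' One-level stationary coif-1 wavelet decomposition (8 sub-bands)
#'
#' Separable single-level 3D decomposition with the Coiflet-1 analysis pair
#' applied along each axis in turn (L = lowpass, H = highpass), without
#' decimation (stationary/undecimated transform, periodic boundary): every
#' sub-band stays on the input grid, so the original ROI masks apply
#' directly. Band names follow the axis order of application: `LLL`, `HLL`,
#' `LHL`, `HHL`, `LLH`, `HLH`, `LHH`, `HHH`, where position 1/2/3 is the
#' filter used along array axis 1/2/3.
#'
#' @param image A `volume_grid`; each axis must be at least 6 voxels.
#' @return Named list of 8 `volume_grid`s with `units = "filtered"`.
#' @export
wavelet_bands <- function(image) {
  stopifnot(inherits(image, "volume_grid"))
  a <- image$data
  ax1 <- list(L = conv_axis_periodic(a, coif1_lo, 1L),
              H = conv_axis_periodic(a, coif1_hi, 1L))
  bands <- list()
  for (f1 in c("L", "H")) {
    b1 <- ax1[[f1]]
    for (f2 in c("L", "H")) {
      b2 <- conv_axis_periodic(b1, if (f2 == "L") coif1_lo else coif1_hi, 2L)
      for (f3 in c("L", "H")) {
        b3 <- conv_axis_periodic(b2, if (f3 == "L") coif1_lo else coif1_hi, 3L)
        bands[[paste0(f1, f2, f3)]] <- volume_grid(
          b3, spacing = image$spacing, affine = image$affine, units = "filtered")
      }
    }
  }
  bands[c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")]
}

# 1D Gaussian and second-derivative-of-Gaussian kernels, sampled and
# moment-corrected (g sums to 1; g'' sums to 0) so constants map to 0.
gauss_kernel <- function(sigma_vox, deriv2 = FALSE) {
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (!deriv2) return(g)
  g2 <- (x^2 / sigma_vox^4 - 1 / sigma_vox^2) * g
  g2 - mean(g2)
}

# replicate-padded 1D convolution along an axis via stats::filter on a
# permuted matrix view
conv_axis_replicate <- function(a, h, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  mat <- matrix(ap, nrow = n, ncol = m)
  half <- (length(h) - 1L) %/% 2L
  padded <- rbind(mat[rep(1L, half), , drop = FALSE], mat,
                  mat[rep(n, half), , drop = FALSE])
  # stats::filter cross-correlates with the reversed kernel; kernels here are
  # symmetric (g) or even (g''), so orientation is immaterial
  fl <- stats::filter(padded, h, method = "convolution", sides = 2)
  out <- matrix(fl[(half + 1L):(half + n), ], nrow = n, ncol = m)
  aperm(array(out, d[perm]), order(perm))
}

#' Scale-normalized Laplacian-of-Gaussian filter
#'
#' Separable implementation: the response is
#' `sigma^2 * sum_i d2/dx_i^2 [G_sigma * image]`, with `sigma` in mm
#' converted per axis to voxels via the image spacing, Gaussian kernels
#' truncated at 4 sigma, and replicate boundary handling. The `sigma^2`
#' factor is the standard scale normalization making responses comparable
#' across sigmas.
#'
#' @param image A `volume_grid`.
#' @param sigma Scale in mm, `> 0`.
#' @return A `volume_grid` with `units = "filtered"`.
#' @export
log_filter <- function(image, sigma) {
  stopifnot(inherits(image, "volume_grid"), sigma > 0)
  if (sigma < max(image$spacing) / 2) {
    warning("sigma = ", sigma, " mm is under-resolved for voxel spacing ",
            paste(image$spacing, collapse = "x"), " mm")
  }
  sig_vox <- sigma / image$spacing
  g <- lapply(1:3, function(i) gauss_kernel(sig_vox[i]))
  g2 <- lapply(1:3, function(i) gauss_kernel(sig_vox[i], deriv2 = TRUE))
  acc <- array(0, dim(image$data))
  for (i in 1:3) {
    term <- image$data
    for (j in 1:3) {
      h <- if (j == i) g2[[j]] else g[[j]]
      term <- conv_axis_replicate(term, h, j)
    }
    # d2/dx^2 in voxel units -> physical units via spacing^2
    acc <- acc + term / image$spacing[i]^2
  }
  volume_grid(sigma^2 * acc, spacing = image$spacing, affine = image$affine,
              units = "filtered")
}
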