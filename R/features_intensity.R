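#' Gray-level discretization with a fixed bin count
#'
#' Equal-width, left-closed bins over the ROI's min-max range: level
#' `floor((x - min) / w) + 1` with `w = (max - min) / n_bins`, and the ROI
#' maximum assigned to the top bin. A constant ROI maps entirely to level 1.
#'
#' @param image `volume_grid` (or 3D array).
#' @param mask Binary `label_volume` (or array); must be nonempty.
#' @param n_bins Number of gray levels B (>= 2).
#' @return Integer 3D array: levels 1..B inside the mask, 0 outside.
#' @export
discretize <- function(image, mask, n_bins = 32L) {
  img <- if (inherits(image, "volume_grid")) image$data else image
  msk <- if (inherits(mask, "volume_grid")) mask$data else mask
  stopifnot(n_bins >= 2)
  idx <- which(msk != 0)
  if (length(idx) == 0) stop("discretize: empty mask")
  vals <- img[idx]
  lo <- min(vals); hi <- max(vals)
  out <- array(0L, dim(img))
  if (hi == lo) {
    out[idx] <- 1L
    return(out)
  }
  w <- (hi - lo) / n_bins
  lev <- pmin(floor((vals - lo) / w) + 1L, n_bins)
  out[idx] <- as.integer(lev)
  out
}

#' First-order (intensity histogram) features of an ROI
#'
#' The standard 18-feature first-order set. Moment features (variance,
#' skewness, kurtosis, MAD) use population (1/N) normalization; kurtosis is
#' not excess-corrected (a Gaussian scores 3). Entropy and uniformity are
#' computed on the discretized gray levels (see [discretize()]); all others
#' on the raw ROI intensities.
#'
#' @param image `volume_grid` or 3D array of intensities.
#' @param mask Binary mask (volume or array), nonempty.
#' @param n_bins Bin count for the entropy/uniformity histogram.
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(image, mask, n_bins = 32L) {
  img <- if (inherits(image, "volume_grid")) image$data else image
  msk <- if (inherits(mask, "volume_grid")) mask$data else mask
  idx <- which(msk != 0)
  if (length(idx) == 0) stop("firstorder_features: empty ROI")
  x <- img[idx]
  n <- length(x)
  vv <- if (inherits(image, "volume_grid")) prod(image$spacing) else 1
  m <- mean(x)
  cx <- x - m
  varp <- mean(cx^2)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inner <- x[x >= q[1] & x <= q[4]]
  lev <- discretize(img, msk, n_bins)[idx]
  p <- tabulate(lev, max(lev)) / n
  p <- p[p > 0]
  c(
    Mean = m,
    Median = stats::median(x),
    P10 = q[1],
    P90 = q[4],
    Minimum = min(x),
    Maximum = max(x),
    Range = max(x) - min(x),
    InterquartileRange = q[3] - q[2],
    Variance = varp,
    Skewness = if (varp > 0) mean(cx^3) / varp^1.5 else 0,
    Kurtosis = if (varp > 0) mean(cx^4) / varp^2 else 0,
    Energy = sum(x^2),
    TotalEnergy = vv * sum(x^2),
    RootMeanSquared = sqrt(mean(x^2)),
    MeanAbsoluteDeviation = mean(abs(cx)),
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2)
  )
}
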