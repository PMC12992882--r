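# Texture matrices per standardized 3D conventions: symmetric normalized
# gray-level co-occurrence matrices (GLCM) and gray-level run-length
# matrices (GLRLM) over the 13 unique 3D directions, features aggregated by
# direction mean.

# the 13 unique 3D offsets (one representative per +/- pair)
texture_directions <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  keep <- apply(dirs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  as.matrix(dirs[keep, , drop = FALSE])
}

# crop level array + mask to the mask bounding box (texture is
# translation-invariant, so this is purely a speed device)
crop_bbox <- function(lev, msk) {
  idx <- which(msk != 0)
  ai <- arrayInd(idx, dim(msk))
  rng <- apply(ai, 2, range)
  lev[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3], drop = FALSE]
}

# raw co-occurrence counts for one offset (unsymmetrized)
glcm_counts <- function(lev, d, n_lev) {
  dm <- dim(lev)
  src <- list(); dst <- list()
  for (ax in 1:3) {
    n <- dm[ax]
    if (abs(d[ax]) >= n) return(matrix(0, n_lev, n_lev))
    src[[ax]] <- if (d[ax] >= 0) seq_len(n - d[ax]) else seq.int(1 - d[ax], n)
    dst[[ax]] <- src[[ax]] + d[ax]
  }
  a <- lev[src[[1]], src[[2]], src[[3]], drop = FALSE]
  b <- lev[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(matrix(0, n_lev, n_lev))
  counts <- tabulate((a[ok] - 1L) * n_lev + b[ok], n_lev * n_lev)
  matrix(counts, n_lev, n_lev, byrow = TRUE)
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric, per-direction-normalized GLCM at the configured voxel
#' distance, features averaged over the 13 unique 3D directions. Returns
#' the 22-feature set (the standardized GLCM set without MCC and without
#' SumAverage, which duplicates 2 x JointAverage under symmetry).
#'
#' @param disc_image Integer level array from [discretize()] (0 outside ROI).
#' @param mask Binary mask (volume or array).
#' @param distance Co-occurrence distance in voxels (default 1).
#' @param n_bins Number of gray levels used at discretization.
#' @return Named numeric vector of 22 features.
#' @export
glcm_features <- function(disc_image, mask, distance = 1L, n_bins = 32L) {
  msk <- if (inherits(mask, "volume_grid")) mask$data else mask
  if (sum(msk != 0) < 2) stop("glcm_features: ROI smaller than 2 voxels")
  lev <- crop_bbox(disc_image * (msk != 0), msk)
  dirs <- texture_directions() * as.integer(distance)
  feats <- NULL
  for (k in seq_len(nrow(dirs))) {
    cm <- glcm_counts(lev, dirs[k, ], n_bins)
    cm <- cm + t(cm)
    if (sum(cm) == 0) next
    P <- cm / sum(cm)
    feats <- rbind(feats, glcm_feature_vector(P))
  }
  if (is.null(feats)) stop("glcm_features: no voxel pairs in any direction")
  colMeans(feats)
}

glcm_feature_vector <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * P); muy <- sum(j * P)
  sigx <- sqrt(sum((i - mux)^2 * P)); sigy <- sqrt(sum((j - muy)^2 * P))
  # p_{x+y}: k = 2..2ng ; p_{x-y}: k = 0..ng-1
  kpl <- 2:(2 * ng)
  pxy_sum <- vapply(kpl, function(k) sum(P[i + j == k]), 0)
  kmn <- 0:(ng - 1)
  pxy_dif <- vapply(kmn, function(k) sum(P[abs(i - j) == k]), 0)
  plog <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  HX <- plog(px); HY <- plog(py); HXY <- plog(P)
  # joint entropies against the independent distribution
  pipj <- outer(px, py)
  nz <- P > 0 & pipj > 0
  HXY1 <- -sum(P[nz] * log2(pipj[nz]))
  nz2 <- pipj > 0
  HXY2 <- -sum(pipj[nz2] * log2(pipj[nz2]))
  da <- sum(kmn * pxy_dif)
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2sq <- 1 - exp(-2 * (HXY2 - HXY))
  c(
    Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sigx > 0 && sigy > 0) {
      (sum(i * j * P) - mux * muy) / (sigx * sigy)
    } else 1,
    DifferenceAverage = da,
    DifferenceEntropy = plog(pxy_dif),
    DifferenceVariance = sum((kmn - da)^2 * pxy_dif),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = if (imc2sq > 0) sqrt(imc2sq) else 0,
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MaximumProbability = max(P),
    SumEntropy = plog(pxy_sum),
    SumSquares = sum((i - mux)^2 * P)
  )
}

# run-length matrix for one direction: P[level, run_length]
glrlm_matrix <- function(lev, d, n_lev) {
  dm <- dim(lev)
  nvox <- prod(dm)
  # neighbor at v - d (zero outside): run starts where predecessor differs
  shift_back <- function(a, d) {
    out <- array(0L, dm)
    src <- list(); dst <- list()
    for (ax in 1:3) {
      n <- dm[ax]
      if (abs(d[ax]) >= n) return(out)
      dst[[ax]] <- if (d[ax] >= 0) seq.int(1 + d[ax], n) else seq_len(n + d[ax])
      src[[ax]] <- dst[[ax]] - d[ax]
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  prev <- shift_back(lev, d)
  starts <- which(lev > 0L & lev != prev)
  if (length(starts) == 0) return(matrix(0, n_lev, 0))
  pos <- arrayInd(starts, dm)
  val <- lev[starts]
  run <- rep(1L, length(starts))
  alive <- seq_along(starts)
  cur <- pos
  max_run <- 1L
  runs <- integer(length(starts))
  repeat {
    nxt <- cur + matrix(d, nrow(cur), 3, byrow = TRUE)
    inb <- nxt[, 1] >= 1 & nxt[, 1] <= dm[1] & nxt[, 2] >= 1 & nxt[, 2] <= dm[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= dm[3]
    lin <- nxt[inb, 1] + (nxt[inb, 2] - 1L) * dm[1] + (nxt[inb, 3] - 1L) * dm[1] * dm[2]
    cont <- logical(nrow(nxt))
    cont[inb] <- lev[lin] == val[inb]
    runs[alive[!cont]] <- run[!cont]
    if (all(!cont)) break
    alive <- alive[cont]
    val <- val[cont]
    run <- run[cont] + 1L
    cur <- nxt[cont, , drop = FALSE]
  }
  max_l <- max(runs)
  counts <- tabulate((lev[starts] - 1L) * max_l + runs, n_lev * max_l)
  matrix(counts, n_lev, max_l, byrow = TRUE)
}

#' Gray-level run-length matrix features
#'
#' Runs of identical gray level along each of the 13 unique 3D directions;
#' the standard 16-feature GLRLM set, averaged over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(disc_image, mask, n_bins = 32L) {
  msk <- if (inherits(mask, "volume_grid")) mask$data else mask
  np <- sum(msk != 0)
  if (np < 2) stop("glrlm_features: ROI smaller than 2 voxels")
  lev <- crop_bbox(disc_image * (msk != 0), msk)
  dirs <- texture_directions()
  feats <- NULL
  for (k in seq_len(nrow(dirs))) {
    P <- glrlm_matrix(lev, dirs[k, ], n_bins)
    if (length(P) == 0 || sum(P) == 0) next
    feats <- rbind(feats, glrlm_feature_vector(P, np))
  }
  colMeans(feats)
}

glrlm_feature_vector <- function(P, np) {
  nr <- sum(P)
  i <- row(P); l <- col(P)
  p <- P / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  pr <- p[p > 0]
  c(
    ShortRunEmphasis = sum(P / l^2) / nr,
    LongRunEmphasis = sum(P * l^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(P)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((l - mu_l)^2 * p),
    RunEntropy = -sum(pr * log2(pr)),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * i^2 * l^2) / nr
  )
}
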