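# Shared fixtures and independent oracles for the test suite.

# small, fast phantom configuration (coarse grid, shallow tree)
tiny_phantom <- function(..., seed = 7L) {
  phantom_config(grid_shape = c(48, 48, 48), branching_depth = 2L,
                 seed = seed, ...)
}

# digital ball mask
ball_mask <- function(r, pad = 2) {
  n <- 2 * r + 2 * pad + 1
  cc <- (n + 1) / 2
  d2 <- outer(outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, "+"),
              (seq_len(n) - cc)^2, "+")
  array(as.integer(d2 <= r^2), c(n, n, n))
}

# synthetic feature table: n cases, p features, the first n_signal shifted
# by effect size d between classes
signal_table <- function(n = 300, p = 50, n_signal = 5, d = 2, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] + d * y
    tibble::tibble(
      case_id = sprintf("c%03d", seq_len(n)),
      label = factor(ifelse(y == 1, "sufficient", "non-sufficient"),
                     levels = c("non-sufficient", "sufficient")),
      y = y,
      tibble::as_tibble(X)
    )
  })
}

# brute-force AUROC by pair enumeration
auroc_bruteforce <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# O(n^2) double-loop DeLong variance components
delong_bruteforce <- function(sa, sb, y) {
  psi <- function(x) outer(x[y == 1], x[y == 0],
                           function(a, b) (a > b) + 0.5 * (a == b))
  Pa <- psi(sa); Pb <- psi(sb)
  m <- sum(y == 1); n <- sum(y == 0)
  s10 <- stats::cov(cbind(rowMeans(Pa), rowMeans(Pb)))
  s01 <- stats::cov(cbind(colMeans(Pa), colMeans(Pb)))
  list(auc_a = mean(Pa), auc_b = mean(Pb),
       var_diff = (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
         (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n)
}

# direct (non-separable) spatial LoG convolution oracle at one voxel
log_at_center_bruteforce <- function(img, spacing, sigma, center) {
  half <- ceiling(4 * sigma / min(spacing))
  acc <- 0
  d <- dim(img)
  # build the full 3D scale-normalized LoG kernel from sampled separable
  # moment-corrected 1D kernels (same kernel definition, different path:
  # one explicit triple loop instead of three axis convolutions)
  g <- lapply(1:3, function(i) collrad:::gauss_kernel(sigma / spacing[i]))
  g2 <- lapply(1:3, function(i) collrad:::gauss_kernel(sigma / spacing[i], deriv2 = TRUE))
  halfs <- vapply(g, function(k) (length(k) - 1L) %/% 2L, 1L)
  for (term_axis in 1:3) {
    ker <- list()
    for (ax in 1:3) ker[[ax]] <- if (ax == term_axis) g2[[ax]] else g[[ax]]
    s <- 0
    for (dx in -halfs[1]:halfs[1]) for (dy in -halfs[2]:halfs[2]) for (dz in -halfs[3]:halfs[3]) {
      ix <- min(max(center[1] + dx, 1), d[1])
      iy <- min(max(center[2] + dy, 1), d[2])
      iz <- min(max(center[3] + dz, 1), d[3])
      w <- ker[[1]][halfs[1] + 1 + dx] * ker[[2]][halfs[2] + 1 + dy] * ker[[3]][halfs[3] + 1 + dz]
      s <- s + w * img[ix, iy, iz]
    }
    acc <- acc + s / spacing[term_axis]^2
  }
  sigma^2 * acc
}

# explicit 1D circular convolution (wavelet oracle building block)
conv1_circular <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in seq_along(h)) {
      out[i] <- out[i] + h[k] * x[((i + k - 2) %% n) + 1]
    }
  }
  out
}

# axis-by-axis 1D wavelet transform oracle
wavelet_band_oracle <- function(a, f1, f2, f3) {
  lo <- collrad:::coif1_lo
  hi <- collrad:::coif1_hi
  pick <- function(f) if (f == "L") lo else hi
  b <- a
  for (ax in 1:3) {
    f <- c(f1, f2, f3)[ax]
    b <- apply(b, setdiff(1:3, ax), conv1_circular, h = pick(f))
    b <- aperm(b, order(c(ax, setdiff(1:3, ax))))
  }
  b
}

# exact Shapley values by enumeration over all feature subsets; the value
# of a coalition is the resubstitution AUROC of a forest retrained on it
shapley_exact <- function(X, y, seed, num_trees = 150L) {
  p <- ncol(X)
  feats <- colnames(X)
  vals <- new.env()
  coal_value <- function(S) {
    key <- paste0("s:", paste(S, collapse = ","))
    if (!is.null(vals[[key]])) return(vals[[key]])
    v <- if (length(S) == 0) 0.5 else {
      m <- collrad:::fit_ranger(X[, S, drop = FALSE], y,
                                default_params(), num_trees, seed)
      auroc(collrad:::ranger_prob(m, X[, S, drop = FALSE]), y)
    }
    vals[[key]] <- v
    v
  }
  phi <- stats::setNames(numeric(p), feats)
  subsets <- lapply(0:(2^p - 1), function(b) feats[bitwAnd(bitwShiftR(b, 0:(p - 1)), 1L) == 1L])
  for (f in feats) {
    for (S in subsets) {
      if (f %in% S) next
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[f] <- phi[f] + w * (coal_value(sort(c(S, f))) - coal_value(S))
    }
  }
  phi
}

# run the python reference oracle on an image+mask pair, returning a list
run_radiomics_oracle <- function(image, mask, n_bins = 32) {
  td <- withr::local_tempdir()
  ip <- file.path(td, "img.nii.gz")
  mp <- file.path(td, "msk.nii.gz")
  write_volume(image, ip)
  write_volume(mask, mp)
  script <- system.file("oracle", "radiomics_oracle.py", package = "collrad")
  out <- system2("python", c(script, ip, mp, n_bins), stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""))
}

rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

# 90-degree rotation about the third axis
rot90_z <- function(a) {
  b <- aperm(a, c(2, 1, 3))
  b[dim(b)[1]:1, , , drop = FALSE]
}
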