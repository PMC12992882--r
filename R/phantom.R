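#' Configuration for the synthetic cerebrovascular phantom
#'
#' The phantom emulates a template-space, brain-extracted CTA of an acute
#' large-vessel-occlusion patient: a mirror-symmetric two-hemisphere vessel
#' tree seeded at the internal carotid arteries, joined through a circle of
#' Willis (CoW) ring, with an M1-segment gap simulating the occlusion. The
#' collateral physiology is reduced to its Tan-score essence: voxels of the
#' vascular tree distal to the gap are retained with probability
#' `fill_fraction` relative to the mirrored contralateral tree, so the
#' occluded hemisphere's opacified vessel volume is `fill_fraction` times
#' the healthy side's.
#'
#' Tan analog of `fill_fraction`: `0 -> 0`, `(0, 0.5] -> 1`,
#' `(0.5, 1) -> 2`, `1 -> 3`; the dichotomized label is sufficient
#' (Tan 2-3) versus non-sufficient (Tan 0-1).
#'
#' @param grid_shape Voxels per axis; first (left-right) extent must be even
#'   so an exact midsagittal plane exists.
#' @param spacing Voxel size, mm per axis.
#' @param n_cases Number of cases for [generate_cohort()].
#' @param p_insufficient Proportion of non-sufficient cases (stratified).
#' @param fill_sufficient_range Interval within (0.5, 1] from which
#'   sufficient-case fill fractions are drawn.
#' @param fill_insufficient_range Interval within `[0, 0.5]` for
#'   non-sufficient cases.
#' @param vessel_hu_range Contrast-opacified vessel intensity interval (HU).
#' @param tissue_hu_mean,tissue_hu_sd Brain-tissue background (HU).
#' @param noise_sd Additive Gaussian image noise (HU).
#' @param branching_depth Levels of the distal bifurcating tree (>= 1).
#' @param jitter Relative geometric jitter of branch angles/lengths (0 = a
#'   perfectly mirror-symmetric, case-invariant tree).
#' @param seed Master seed for [generate_cohort()].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96, 96, 96),
                           spacing = c(1, 1, 1),
                           n_cases = 100,
                           p_insufficient = 0.33,
                           fill_sufficient_range = c(0.55, 1.0),
                           fill_insufficient_range = c(0.0, 0.5),
                           vessel_hu_range = c(200, 300),
                           tissue_hu_mean = 35,
                           tissue_hu_sd = 5,
                           noise_sd = 10,
                           branching_depth = 4,
                           jitter = 0.08,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 16))
  if (grid_shape[1] %% 2L != 0L) {
    stop("grid_shape[1] (left-right extent) must be even so a midline exists")
  }
  if (p_insufficient < 0 || p_insufficient > 1) {
    stop("p_insufficient must lie in [0, 1]")
  }
  chk_range <- function(r, lo, hi, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop(nm, " must be an ordered interval within [", lo, ", ", hi, "]")
    }
  }
  chk_range(fill_sufficient_range, 0.5, 1.0, "fill_sufficient_range")
  if (fill_sufficient_range[1] <= 0.5 && fill_sufficient_range[2] > 0.5) {
    # lower bound may touch but not cross 0.5 (open at 0.5)
    fill_sufficient_range[1] <- max(fill_sufficient_range[1], 0.5)
  }
  chk_range(fill_insufficient_range, 0.0, 0.5, "fill_insufficient_range")
  hu <- c(vessel_hu_range, tissue_hu_mean, tissue_hu_sd, noise_sd)
  if (any(!is.finite(hu))) stop("all HU parameters must be finite")
  stopifnot(branching_depth >= 1)
  structure(list(
    grid_shape = grid_shape, spacing = as.numeric(spacing),
    n_cases = as.integer(n_cases), p_insufficient = p_insufficient,
    fill_sufficient_range = fill_sufficient_range,
    fill_insufficient_range = fill_insufficient_range,
    vessel_hu_range = vessel_hu_range,
    tissue_hu_mean = tissue_hu_mean, tissue_hu_sd = tissue_hu_sd,
    noise_sd = noise_sd, branching_depth = as.integer(branching_depth),
    jitter = jitter, seed = as.integer(seed)
  ), class = "phantom_config")
}

# CoW segment label ids used throughout the package
cow_label_map <- function() {
  c("MCA-L" = 1L, "MCA-R" = 2L, "ICA-L" = 3L, "ICA-R" = 4L,
    "ACA" = 5L, "PCA" = 6L, "Acom" = 7L, "Pcom" = 8L, "BA" = 9L)
}

territory_label_map <- function() {
  c("M1-terr-L" = 1L, "M2-terr-L" = 2L, "ACA-terr-L" = 3L, "PCA-terr-L" = 4L,
    "M1-terr-R" = 5L, "M2-terr-R" = 6L, "ACA-terr-R" = 7L, "PCA-terr-R" = 8L)
}

# ---- geometry helpers (voxel coordinates, 1-based centers) ----

unit <- function(v) v / sqrt(sum(v^2))

# any unit vector orthogonal to d, rotated by phi around d
ortho_vec <- function(d, phi) {
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- unit(pracma_cross(d, ref))
  w <- pracma_cross(d, u)
  cos(phi) * u + sin(phi) * w
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# recursive bifurcating tree; returns list of segments
# each segment: list(p1, p2, r, level)
grow_tree <- function(p0, dir, len, r, depth, rng_draws, seg_list = list(),
                      level = 1L) {
  p1 <- p0 + dir * len
  seg_list[[length(seg_list) + 1L]] <- list(p1 = p0, p2 = p1, r = r, level = level)
  if (level >= depth) return(seg_list)
  dr <- rng_draws[[level]]
  theta <- (28 + dr$dtheta) * pi / 180
  u <- ortho_vec(dir, dr$phi)
  d1 <- unit(cos(theta) * dir + sin(theta) * u)
  d2 <- unit(cos(theta) * dir - sin(theta) * u)
  nlen <- len * 0.8 * (1 + dr$dlen)
  nr <- max(r * 0.85, 0.9)
  seg_list <- grow_tree(p1, d1, nlen, nr, depth, rng_draws, seg_list, level + 1L)
  seg_list <- grow_tree(p1, d2, nlen, nr, depth, rng_draws, seg_list, level + 1L)
  seg_list
}

# rasterize a segment into linear voxel indices of a dims grid
rasterize_segment <- function(p1, p2, r, dims) {
  lo <- pmax(floor(pmin(p1, p2) - r - 0.5), 1)
  hi <- pmin(ceiling(pmax(p1, p2) + r + 0.5), dims)
  if (any(lo > hi)) return(integer(0))
  xs <- seq.int(lo[1], hi[1]); ys <- seq.int(lo[2], hi[2]); zs <- seq.int(lo[3], hi[3])
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  d <- p2 - p1
  L2 <- sum(d^2)
  w <- sweep(g, 2, p1)
  t <- if (L2 > 0) pmin(pmax((w %*% d)[, 1] / L2, 0), 1) else 0
  proj <- outer(t, d) # n x 3
  dist2 <- rowSums((w - proj)^2)
  keep <- dist2 <= r^2
  if (!any(keep)) return(integer(0))
  gk <- g[keep, , drop = FALSE]
  as.integer(gk[, 1] + (gk[, 2] - 1) * dims[1] + (gk[, 3] - 1) * dims[1] * dims[2])
}

mirror_point <- function(p, nx) c(nx + 1 - p[1], p[2], p[3])

# Build the full bilateral segment set for one case.
# Returns list(segments = list of (p1,p2,r,label,distal,side), ...)
phantom_geometry <- function(config) {
  dims <- config$grid_shape
  nx <- dims[1]
  L <- min(dims * config$spacing)
  mid <- (nx + 1) / 2
  jit <- function(s) stats::runif(1, -config$jitter, config$jitter) * s

  # anchor points (right side; left is the mirror image)
  ica_x <- mid + 0.115 * nx
  ica_base <- c(ica_x, 0.50 * dims[2], 0.10 * dims[3])
  ica_top <- c(ica_x, 0.50 * dims[2], 0.355 * dims[3])
  m1_end <- c(mid + 0.27 * nx, 0.50 * dims[2], 0.375 * dims[3])
  aca_end <- c(mid + 0.015 * nx, 0.40 * dims[2], 0.42 * dims[3])
  ba_base <- c(mid, 0.65 * dims[2], 0.16 * dims[3])
  ba_top <- c(mid, 0.65 * dims[2], 0.34 * dims[3])
  pca_end <- c(mid + 0.10 * nx, 0.67 * dims[2], 0.40 * dims[3])

  r_ica <- max(1.5, 0.023 * L); r_m1 <- max(1.2, 0.019 * L)
  r_ring <- max(1.0, 0.014 * L); r_ba <- max(1.2, 0.018 * L)

  # branching feasibility: the deepest branch must still span >= 2.5 voxels
  len1 <- 0.13 * L
  len_min <- len1 * 0.8^(config$branching_depth - 1)
  if (len_min < 2.5 * max(config$spacing)) {
    stop("grid too small to contain branching_depth = ", config$branching_depth,
         " levels (deepest branch ", format(len_min, digits = 3),
         " mm < 2.5 voxels)")
  }

  # per-level jitter draws, shared by both hemispheres (mirror symmetry)
  rng_draws <- lapply(seq_len(max(config$branching_depth - 1L, 1L)), function(l) {
    list(dtheta = stats::runif(1, -1, 1) * 10 * (config$jitter / 0.08),
         phi = stats::runif(1, 0, 2 * pi),
         dlen = jit(1))
  })

  # only right-side and midline segments are emitted; the left hemisphere is
  # produced by mirroring rasterized voxel index sets, so the two sides are
  # voxel-exact mirror images (no floating-point asymmetry)
  segs <- list()
  add <- function(p1, p2, r, label, distal = FALSE, side = "M") {
    segs[[length(segs) + 1L]] <<- list(p1 = p1, p2 = p2, r = r, label = label,
                                       distal = distal, side = side)
  }

  m1_len_jit <- 1 + jit(1)
  m1e <- ica_top + (m1_end - ica_top) * m1_len_jit
  add(ica_base, ica_top, r_ica, "ICA", side = "R")
  add(ica_top, m1e, r_m1, "MCA", side = "R")
  add(ica_top, aca_end, r_ring, "ACA", side = "R")
  add(ica_top, pca_end, r_ring, "Pcom", side = "R")
  add(ba_top, pca_end, r_ring, "PCA", side = "R")
  dir0 <- unit(c(0.75, 0.1, 0.65))
  tree <- grow_tree(m1e, dir0, len1 * (1 + jit(1)),
                    max(1.2, 0.017 * L), config$branching_depth, rng_draws)
  for (sg in tree) {
    add(sg$p1, sg$p2, sg$r, "distal", distal = TRUE, side = "R")
  }
  add(ba_base, ba_top, r_ba, "BA")
  add(c(mid - 0.015 * nx, 0.40 * dims[2], 0.42 * dims[3]),
      c(mid + 0.015 * nx, 0.40 * dims[2], 0.42 * dims[3]), r_ring, "Acom")

  # clamp into the grid (symmetric box, so mirror symmetry is preserved)
  for (i in seq_along(segs)) {
    segs[[i]]$p1 <- pmin(pmax(segs[[i]]$p1, 2), dims - 1)
    segs[[i]]$p2 <- pmin(pmax(segs[[i]]$p2, 2), dims - 1)
  }
  list(segments = segs)
}

# mirror a set of linear voxel indices about the midsagittal plane
mirror_indices <- function(idx, dims) {
  x <- ((idx - 1L) %% dims[1]) + 1L
  rest <- idx - x
  as.integer(rest + (dims[1] + 1L - x))
}

# territory atlas is case-invariant given the grid
phantom_territory_atlas <- function(config) {
  dims <- config$grid_shape
  nx <- dims[1]
  mid <- (nx + 1) / 2
  ax <- seq_len(dims[1]); ay <- seq_len(dims[2]); az <- seq_len(dims[3])
  X <- array(rep(ax, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ay, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(az, each = dims[1] * dims[2]), dims)
  cx <- (dims + 1) / 2
  brain <- ((X - cx[1]) / (0.47 * dims[1]))^2 + ((Y - cx[2]) / (0.47 * dims[2]))^2 +
    ((Z - cx[3]) / (0.47 * dims[3]))^2 <= 1
  lat <- abs(X - mid)
  lab <- array(0L, dims)
  lm <- territory_label_map()
  mca_band <- brain & lat > 0.19 * nx & Z > 0.18 * dims[3] & Z < 0.80 * dims[3]
  med_band <- brain & lat <= 0.19 * nx & Z > 0.30 * dims[3]
  is_r <- X > mid
  lab[mca_band & Z <= 0.48 * dims[3] & !is_r] <- lm[["M1-terr-L"]]
  lab[mca_band & Z > 0.48 * dims[3] & !is_r] <- lm[["M2-terr-L"]]
  lab[mca_band & Z <= 0.48 * dims[3] & is_r] <- lm[["M1-terr-R"]]
  lab[mca_band & Z > 0.48 * dims[3] & is_r] <- lm[["M2-terr-R"]]
  lab[med_band & Y <= 0.5 * dims[2] & !is_r] <- lm[["ACA-terr-L"]]
  lab[med_band & Y > 0.5 * dims[2] & !is_r] <- lm[["PCA-terr-L"]]
  lab[med_band & Y <= 0.5 * dims[2] & is_r] <- lm[["ACA-terr-R"]]
  lab[med_band & Y > 0.5 * dims[2] & is_r] <- lm[["PCA-terr-R"]]
  atlas <- label_volume(lab, spacing = config$spacing, label_map = lm)
  comp <- build_mca_composite(atlas)
  mca_comp <- array(0L, dims)
  mca_comp[comp$mca_terr_L$data != 0L] <- 1L
  mca_comp[comp$mca_terr_R$data != 0L] <- 2L
  list(atlas = atlas, brain = brain,
       mca_territory = label_volume(mca_comp, spacing = config$spacing,
                                    label_map = c("mca_terr_L" = 1L,
                                                  "mca_terr_R" = 2L)))
}

tan_from_fill <- function(fill) {
  if (fill == 0) 0L else if (fill <= 0.5) 1L else if (fill < 1) 2L else 3L
}

draw_fill <- function(label, config) {
  if (label == "non-sufficient") {
    r <- config$fill_insufficient_range
    if (r[1] == 0 && stats::runif(1) < 0.15) return(0)
    stats::runif(1, max(r[1], 1e-3), r[2])
  } else {
    r <- config$fill_sufficient_range
    if (r[2] == 1 && stats::runif(1) < 0.25) return(1)
    stats::runif(1, max(r[1], 0.5 + 1e-3), min(r[2], 1 - 1e-6))
  }
}

#' Generate one synthetic CTA case
#'
#' Deterministic for a fixed `(config, case_seed)` pair. See
#' [phantom_config()] for the model. The occlusion is a gap carved from the
#' middle of the M1 segment on `occluded_side`; every vessel voxel distal to
#' the gap (the whole bifurcating tree of that hemisphere) is retained with
#' probability `fill_fraction`.
#'
#' @param config A [phantom_config()].
#' @param case_seed Integer seed for this case.
#' @param label Optional forced class (`"sufficient"`/`"non-sufficient"`);
#'   drawn with probability `p_insufficient` when `NULL`.
#' @param fill_fraction,occluded_side Optional overrides.
#' @param occlusion Set `FALSE` to skip the M1 gap (healthy-vessel phantom,
#'   used for symmetry checks).
#' @param atlas Optional precomputed territory atlas (cohort-level cache).
#' @return A `phantom_case` list: `image` (HU [volume_grid()]),
#'   `vessel_mask`, `cow_mask`, `territory_atlas`, `mca_territory` (binary
#'   L/R composite), `tan_score`, `label`, `occluded_side`, `fill_fraction`.
#' @export
generate_case <- function(config, case_seed, label = NULL,
                          fill_fraction = NULL, occluded_side = NULL,
                          occlusion = TRUE, atlas = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape
  nvox <- prod(dims)
  with_seed(as.integer(case_seed), {
    if (is.null(label)) {
      label <- if (stats::runif(1) < config$p_insufficient) "non-sufficient" else "sufficient"
    }
    if (is.null(fill_fraction)) fill_fraction <- draw_fill(label, config)
    if (is.null(occluded_side)) occluded_side <- sample(c("left", "right"), 1)
    geo <- phantom_geometry(config)

    lm <- cow_label_map()
    vessel <- logical(nvox)
    cow <- integer(nvox)
    distal_idx <- list(L = integer(0), R = integer(0))
    m1_idx <- list(L = integer(0), R = integer(0))
    sided <- c(ICA = "ICA", MCA = "MCA") # labels that exist per side
    for (sg in geo$segments) {
      idx <- rasterize_segment(sg$p1, sg$p2, sg$r, dims)
      if (sg$side == "M") {
        # midline structure: symmetrize so both hemispheres agree exactly
        idx <- union(idx, mirror_indices(idx, dims))
        vessel[idx] <- TRUE
        cow[idx] <- lm[[sg$label]]
        next
      }
      midx <- mirror_indices(idx, dims) # left-hemisphere twin
      vessel[idx] <- TRUE
      vessel[midx] <- TRUE
      if (sg$label %in% names(sided)) {
        cow[idx] <- lm[[paste0(sg$label, "-R")]]
        cow[midx] <- lm[[paste0(sg$label, "-L")]]
      } else if (sg$label %in% names(lm)) {
        cow[idx] <- lm[[sg$label]]
        cow[midx] <- lm[[sg$label]]
      }
      if (isTRUE(sg$distal)) {
        distal_idx$R <- c(distal_idx$R, idx)
        distal_idx$L <- c(distal_idx$L, midx)
      }
      if (sg$label == "MCA") {
        m1_idx$R <- c(m1_idx$R, idx)
        m1_idx$L <- c(m1_idx$L, midx)
      }
    }

    occ <- if (occluded_side == "left") "L" else "R"
    if (occlusion) {
      # carve the gap: middle stretch of the M1 segment, by x-extent
      m1v <- unique(m1_idx[[occ]])
      if (length(m1v)) {
        xs <- ((m1v - 1L) %% dims[1]) + 1L
        xr <- range(xs)
        gap <- m1v[xs > xr[1] + 0.40 * diff(xr) & xs < xr[1] + 0.75 * diff(xr)]
        vessel[gap] <- FALSE
        cow[gap] <- 0L
      }
      # distal filling relative to the (intact) contralateral tree
      dv <- sort(unique(distal_idx[[occ]]))
      if (fill_fraction <= 0) {
        drop <- dv
      } else if (fill_fraction >= 1) {
        drop <- integer(0)
      } else {
        drop <- dv[stats::runif(length(dv)) >= fill_fraction]
      }
      vessel[drop] <- FALSE
      cow[drop] <- 0L # distal voxels carry no CoW label, but keep the invariant tight
      distal_idx[[occ]] <- setdiff(dv, drop)
    }
    cow[!vessel] <- 0L
    distal_idx <- lapply(distal_idx, function(ii) sort(unique(ii)))

    if (is.null(atlas)) atlas <- phantom_territory_atlas(config)
    # image: tissue background inside the brain ellipsoid + vessel contrast + noise
    img <- array(0, dims)
    brain <- atlas$brain
    img[brain] <- stats::rnorm(sum(brain), config$tissue_hu_mean, config$tissue_hu_sd)
    vmu <- mean(config$vessel_hu_range)
    vsd <- diff(config$vessel_hu_range) / 4
    img[vessel] <- stats::rnorm(sum(vessel), vmu, vsd)
    img <- img + array(stats::rnorm(nvox, 0, config$noise_sd), dims)

    structure(list(
      image = volume_grid(img, spacing = config$spacing, units = "HU"),
      vessel_mask = label_volume(array(as.integer(vessel), dims),
                                 spacing = config$spacing,
                                 label_map = c(vessel = 1L)),
      cow_mask = label_volume(array(cow, dims), spacing = config$spacing,
                              label_map = lm),
      territory_atlas = atlas$atlas,
      mca_territory = atlas$mca_territory,
      distal_idx = distal_idx,
      tan_score = tan_from_fill(fill_fraction),
      label = label,
      occluded_side = occluded_side,
      fill_fraction = fill_fraction,
      seed = as.integer(case_seed)
    ), class = "phantom_case")
  })
}

#' Generate a stratified phantom cohort
#'
#' Class counts are exact: `round(n_cases * p_insufficient)` cases are
#' non-sufficient (stratified assignment, not binomial sampling). Case seeds
#' are derived deterministically from the master seed.
#'
#' @param config A [phantom_config()].
#' @return A list with `cases` (list of `phantom_case`) and `manifest`
#'   (tibble: case_id, seed, tan_score, label, occluded_side, fill_fraction).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_cases
  if (n < 0) stop("n_cases must be >= 0")
  n_insuf <- round(n * config$p_insufficient)
  labels <- c(rep("non-sufficient", n_insuf), rep("sufficient", n - n_insuf))
  if (n > 0) {
    perm <- with_seed(derive_seed(config$seed, "label-perm"), sample.int(n))
    labels <- labels[perm]
  }
  atlas <- if (n > 0) phantom_territory_atlas(config) else NULL
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- derive_seed(config$seed, paste0("case-", i))
    cases[[i]] <- generate_case(config, cs, label = labels[i], atlas = atlas)
    cases[[i]]$case_id <- sprintf("case_%03d", i)
  }
  manifest <- tibble::tibble(
    case_id = vapply(cases, function(cc) cc$case_id %||% NA_character_, ""),
    seed = vapply(cases, function(cc) cc$seed, 1L),
    tan_score = vapply(cases, function(cc) cc$tan_score, 1L),
    label = vapply(cases, function(cc) cc$label, ""),
    occluded_side = vapply(cases, function(cc) cc$occluded_side, ""),
    fill_fraction = vapply(cases, function(cc) cc$fill_fraction, 1.0)
  )
  list(cases = cases, manifest = manifest)
}

#' Write a phantom cohort to disk as NIfTI + CSV manifest
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases) {
    base <- file.path(dir, cs$case_id)
    write_volume(cs$image, paste0(base, "_cta.nii.gz"))
    write_volume(cs$vessel_mask, paste0(base, "_vessels.nii.gz"))
    write_volume(cs$cow_mask, paste0(base, "_cow.nii.gz"))
    write_volume(cs$territory_atlas, paste0(base, "_territory.nii.gz"))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}
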