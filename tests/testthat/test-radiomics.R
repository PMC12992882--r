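test_that("voxel and mesh volumes behave on elementary solids", {
  # single voxel: exact voxel volume, degenerate mesh features flagged
  m1 <- array(0L, c(5, 5, 5)); m1[3, 3, 3] <- 1L
  expect_warning(sf1 <- shape_features(m1), "degenerate")
  expect_equal(unname(sf1["VoxelVolume"]), 1)
  expect_true(is.na(sf1["Sphericity"]))

  # 10^3 solid cube at 1 mm
  cube <- array(1L, c(10, 10, 10))
  sf <- shape_features(cube)
  expect_equal(unname(sf["VoxelVolume"]), 1000)
  expect_lt(sf["Sphericity"], 1)
  expect_gt(sf["Sphericity"], 0.7)
  # mesh volume is the midpoint-surface volume (9.5^3 minus corner trims)
  expect_lt(abs(sf["MeshVolume"] - 985.67) / 985.67, 1e-3)
  expect_error(shape_features(array(0L, c(4, 4, 4))), "empty")
})

test_that("digital ball matches the independent mesh oracle", {
  b <- ball_mask(15)
  sf <- shape_features(b)
  o <- run_radiomics_oracle(
    volume_grid(array(0, dim(b))),
    label_volume(b)
  )
  so <- unlist(o$shape)
  # sphericity within 2% of the reference mesh pipeline
  expect_lt(rel_diff(sf["Sphericity"], so["Sphericity"]), 0.02)
  # a ball is not elongated
  expect_lt(abs(sf["Elongation"] - 1), 0.01)
  # axis lengths and diameters within 1%
  for (f in c("Maximum3DDiameter", "MajorAxisLength", "LeastAxisLength",
              "Maximum2DDiameterSlice", "VoxelVolume")) {
    expect_lt(rel_diff(sf[f], so[f]), 0.01)
  }
})

test_that("anisotropic spacing scales volumes and areas physically", {
  b <- ball_mask(6)
  iso <- shape_features(b, spacing = c(1, 1, 1))
  an <- shape_features(b, spacing = c(2, 1, 1))
  expect_equal(unname(an["VoxelVolume"]), unname(2 * iso["VoxelVolume"]))
  expect_equal(unname(an["MeshVolume"]), unname(2 * iso["MeshVolume"]),
               tolerance = 1e-9)
})

test_that("discretization follows left-closed equal-width binning", {
  img <- array(c(0, 0.5, 1.0), c(3, 1, 1))
  msk <- array(1L, c(3, 1, 1))
  expect_identical(as.vector(discretize(img, msk, 2))[1:3], c(1L, 2L, 2L))
  # constant ROI occupies a single level
  expect_identical(unique(as.vector(discretize(array(4, c(3, 1, 1)), msk, 8))[1:3]), 1L)
  # never more than B occupied levels
  withr::with_seed(1, v <- array(rnorm(64), c(4, 4, 4)))
  lev <- discretize(v, array(1L, c(4, 4, 4)), 5)
  expect_lte(length(unique(as.vector(lev))), 5)
  expect_identical(range(lev), c(1L, 5L))
})

test_that("first-order features match hand enumeration and additivity", {
  fo <- firstorder_features(array(c(1, 1, 3, 3), c(4, 1, 1)),
                            array(1L, c(4, 1, 1)))
  expect_equal(unname(fo["Mean"]), 2)
  expect_equal(unname(fo["Energy"]), 20)
  expect_equal(unname(fo["Range"]), 2)
  expect_equal(unname(fo["Variance"]), 1)

  # constant ROI: variance 0, entropy 0, uniformity 1
  fc <- firstorder_features(array(7, c(3, 3, 3)), array(1L, c(3, 3, 3)))
  expect_equal(unname(fc[c("Variance", "Entropy", "Uniformity")]), c(0, 0, 1))

  # energy doubles when the ROI voxel multiset is duplicated
  img <- array(c(1, 2, 5, 9, 1, 2, 5, 9), c(8, 1, 1))
  half <- array(0L, c(8, 1, 1)); half[1:4] <- 1L
  full <- array(1L, c(8, 1, 1))
  expect_equal(unname(firstorder_features(img, full)["Energy"]),
               2 * unname(firstorder_features(img, half)["Energy"]))
})

test_that("GLCM counts and contrast match exhaustive pair enumeration on the toy grid", {
  lev <- array(0L, c(3, 3, 1))
  lev[, , 1] <- matrix(c(1, 1, 2,
                         1, 2, 2,
                         2, 2, 1), 3, 3, byrow = TRUE)
  counts <- collrad:::glcm_counts(lev, c(1, 0, 0), 2)
  # oracle: enumerate all neighbour pairs by hand
  cnt <- matrix(0, 2, 2)
  for (j in 1:3) for (i in 1:2) {
    cnt[lev[i, j, 1], lev[i + 1, j, 1]] <- cnt[lev[i, j, 1], lev[i + 1, j, 1]] + 1
  }
  expect_equal(counts, cnt)
  P <- counts + t(counts); P <- P / sum(P)
  contrast <- sum((row(P) - col(P))^2 * P)
  v <- collrad:::glcm_feature_vector(P)
  expect_equal(unname(v["Contrast"]), contrast)
})

test_that("each direction's normalized GLCM sums to one", {
  withr::with_seed(4, img <- array(rnorm(6^3), c(6, 6, 6)))
  msk <- array(0L, c(6, 6, 6)); msk[2:5, 2:5, 2:5] <- 1L
  disc <- discretize(img, msk, 8)
  for (k in seq_len(13)) {
    d <- collrad:::texture_directions()[k, ]
    cm <- collrad:::glcm_counts(disc * (msk != 0), d, 8)
    cm <- cm + t(cm)
    expect_lt(abs(sum(cm / sum(cm)) - 1), 1e-12)
  }
})

test_that("constant ROIs give degenerate texture in the documented way", {
  img <- array(5, c(4, 4, 4)); msk <- array(1L, c(4, 4, 4))
  disc <- discretize(img, msk, 32)
  g <- glcm_features(disc, msk, 1, 32)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["MaximumProbability"]), 1)
  expect_equal(unname(g["JointEnergy"]), 1)
  rl <- glrlm_features(disc, msk, 32)
  # a constant 4^3 ROI has maximal runs: run percentage well below 1
  expect_lt(rl["RunPercentage"], 0.5)
  expect_gt(rl["LongRunEmphasis"], 1)
  expect_error(glcm_features(disc, array(0L, c(4, 4, 4))), "2 voxels")
})

test_that("GLRLM runs match a hand-enumerated line", {
  lev <- array(c(1L, 1L, 2L, 2L, 2L, 1L), c(6, 1, 1))
  P <- collrad:::glrlm_matrix(lev, c(1, 0, 0), 2)
  # runs: level1 x2, level2 x3, level1 x1
  expect_equal(P[1, 1], 1) # one run of length 1 (level 1)
  expect_equal(P[1, 2], 1) # one run of length 2 (level 1)
  expect_equal(P[2, 3], 1) # one run of length 3 (level 2)
  expect_equal(sum(P), 3)
})

test_that("features are invariant under whole-grid translation", {
  case <- generate_case(tiny_phantom(seed = 17), 3)
  roi <- assemble_rois(case, "C")$rois$ica_L
  norm <- clip_znorm(case$image)
  shift <- function(a, by = c(2, 3, 1)) {
    out <- array(0, dim(a))
    d <- dim(a)
    out[(1 + by[1]):d[1], (1 + by[2]):d[2], (1 + by[3]):d[3]] <-
      a[1:(d[1] - by[1]), 1:(d[2] - by[2]), 1:(d[3] - by[3])]
    out
  }
  sroi <- array(as.integer(shift(roi$data)), dim(roi$data))
  simg <- shift(norm$data)
  expect_equal(shape_features(roi$data), shape_features(sroi), tolerance = 1e-9)
  expect_equal(firstorder_features(norm$data, roi$data),
               firstorder_features(simg, sroi), tolerance = 1e-9)
  d1 <- discretize(norm$data, roi$data, 16)
  d2 <- discretize(simg, sroi, 16)
  expect_equal(glcm_features(d1, roi$data, 1, 16),
               glcm_features(d2, sroi, 1, 16), tolerance = 1e-9)
  expect_equal(glrlm_features(d1, roi$data, 16),
               glrlm_features(d2, sroi, 16), tolerance = 1e-9)
})

test_that("extract_table builds the documented provenance-coded columns", {
  coh <- generate_cohort(tiny_phantom(n_cases = 4, seed = 19))
  tbl <- extract_table(coh$cases, "A")
  # 2 ROIs x 14 shape features
  expect_identical(ncol(tbl) - 3L, 28L)
  expect_true(all(grepl("^vessels_[LR]\\|original\\|shape\\|", names(tbl)[-(1:3)])))
  tbl2 <- extract_table(coh$cases, "A")
  expect_identical(tbl, tbl2) # deterministic

  # variant B over original + 8 wavelet + 3 LoG images x 56 features x 2 ROIs
  tblB <- extract_table(coh$cases[1], "B")
  expect_identical(ncol(tblB) - 3L, 2L * 12L * 56L)
  cols <- names(tblB)[-(1:3)]
  expect_identical(length(unique(cols)), length(cols))
  filters <- unique(vapply(strsplit(cols, "\\|"), `[`, "", 2))
  expect_length(filters, 12)
})
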