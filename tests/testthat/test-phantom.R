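test_that("case generation is deterministic and internally consistent", {
  cfg <- tiny_phantom()
  a <- generate_case(cfg, 123)
  b <- generate_case(cfg, 123)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$vessel_mask$data, b$vessel_mask$data)
  expect_identical(a$cow_mask$data, b$cow_mask$data)
  # vessel mask contains the CoW support
  expect_true(all(a$vessel_mask$data[a$cow_mask$data != 0L] == 1L))
  # CoW labels partition their support (single integer array by design,
  # but every nonzero id must be a known label)
  expect_true(all(a$cow_mask$data %in% c(0L, collrad:::cow_label_map())))
  # label consistent with Tan dichotomization and fill range
  expect_identical(a$label == "sufficient", a$tan_score >= 2L)
  if (a$label == "sufficient") expect_gt(a$fill_fraction, 0.5)
  else expect_lte(a$fill_fraction, 0.5)
  # masks share the image grid
  expect_true(check_grid_compat(a$image, a$vessel_mask))
  expect_true(check_grid_compat(a$image, a$territory_atlas))
})

test_that("healthy symmetric phantom has equal left/right vessel volumes", {
  cfg <- tiny_phantom(seed = 11)
  cs <- generate_case(cfg, 55, occlusion = FALSE, fill_fraction = 1,
                      label = "sufficient")
  h <- split_hemispheres(cs$vessel_mask)
  expect_identical(sum(h$left$data), sum(h$right$data))
})

test_that("distal filling fraction is reproduced on the emitted masks", {
  cfg <- phantom_config(seed = 1) # default study-scale grid
  for (s in 1:3) {
    cs <- generate_case(cfg, s, label = "non-sufficient", fill_fraction = 0.3,
                        occluded_side = "left")
    ratio <- length(cs$distal_idx$L) / length(cs$distal_idx$R)
    expect_gte(ratio, 0.25)
    expect_lte(ratio, 0.35)
    # retained distal voxels really are on the emitted mask
    expect_true(all(cs$vessel_mask$data[cs$distal_idx$L] == 1L))
  }
})

test_that("cohorts are stratified exactly, with deterministic manifests", {
  cfg <- tiny_phantom(n_cases = 12, p_insufficient = 0.33, seed = 3)
  coh <- generate_cohort(cfg)
  expect_identical(sum(coh$manifest$label == "non-sufficient"), 4L) # round(12*.33)
  expect_identical(nrow(coh$manifest), 12L)
  expect_identical(coh$manifest$label == "sufficient",
                   coh$manifest$tan_score >= 2L)

  # n = 0: empty but valid
  empty <- generate_cohort(tiny_phantom(n_cases = 0))
  expect_length(empty$cases, 0)
  expect_identical(nrow(empty$manifest), 0L)

  # different master seeds differ in at least one vessel mask
  coh2 <- generate_cohort(tiny_phantom(n_cases = 12, p_insufficient = 0.33,
                                       seed = 4))
  same <- vapply(seq_len(12), function(i) {
    identical(coh$cases[[i]]$vessel_mask$data, coh2$cases[[i]]$vessel_mask$data)
  }, TRUE)
  expect_false(all(same))

  expect_error(phantom_config(p_insufficient = 1.2), "p_insufficient")
})

test_that("occluded-side distal volume is monotone in the fill fraction", {
  cfg <- tiny_phantom(seed = 9)
  fills <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  means <- vapply(fills, function(f) {
    mean(vapply(1:20, function(s) {
      cs <- generate_case(cfg, s, label = if (f > 0.5) "sufficient" else "non-sufficient",
                          fill_fraction = f, occluded_side = "left")
      length(cs$distal_idx$L)
    }, 0))
  }, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("hemispheric volume ratios separate the two classes", {
  cfg <- tiny_phantom(n_cases = 0, seed = 21)
  ratio_of <- function(cs) {
    h <- split_hemispheres(cs$vessel_mask)
    v <- sort(c(sum(h$left$data), sum(h$right$data)))
    v[1] / v[2]
  }
  suff <- vapply(1:50, function(s) {
    ratio_of(generate_case(cfg, s, label = "sufficient"))
  }, 0)
  insuf <- vapply(1:50, function(s) {
    ratio_of(generate_case(cfg, 1000 + s, label = "non-sufficient"))
  }, 0)
  wt <- stats::wilcox.test(suff, insuf)
  # rank statistic far outside its null band
  expect_lt(wt$p.value, 0.05)
  expect_gt(mean(suff), mean(insuf))
})

test_that("a grid too small for the branching depth fails explicitly", {
  expect_error(generate_case(phantom_config(grid_shape = c(24, 24, 24),
                                            branching_depth = 6), 1),
               "grid too small")
})

test_that("cohorts round-trip through NIfTI + manifest on disk", {
  cfg <- tiny_phantom(n_cases = 2, seed = 13)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$manifest$label, coh$manifest$label)
  expect_identical(back$cases[[1]]$vessel_mask$data,
                   coh$cases[[1]]$vessel_mask$data)
  expect_equal(back$cases[[1]]$image$data, coh$cases[[1]]$image$data,
               tolerance = 1e-5)
})
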