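test_that("hemisphere split is an exact partition at the midline", {
  dims <- c(8, 6, 6)
  m <- array(0L, dims)
  withr::with_seed(5, m[sample(length(m), 60)] <- 1L)
  lv <- label_volume(m)
  h <- split_hemispheres(lv)
  expect_identical(sum(h$left$data) + sum(h$right$data), sum(m))
  expect_identical(sum(h$left$data & h$right$data), 0L)
  expect_identical(array(as.integer(h$left$data | h$right$data), dims), m)

  # mask confined to the left half leaves the right empty
  ml <- array(0L, dims); ml[1:4, , ] <- 1L
  hl <- split_hemispheres(label_volume(ml))
  expect_identical(sum(hl$right$data), 0L)
  expect_identical(sum(hl$left$data), sum(ml))

  expect_error(split_hemispheres(label_volume(array(0L, dims))), "empty")
})

test_that("CoW label merge keeps MCA/ICA and pools the communicating vessels", {
  lm <- collrad:::cow_label_map()
  dims <- c(6, 6, 6)
  m <- array(0L, dims)
  m[1:9] <- lm # one voxel per segment
  cow <- label_volume(m, label_map = lm)
  merged <- merge_cow_labels(cow)
  expect_setequal(names(merged$label_map),
                  c("MCA-L", "MCA-R", "ICA-L", "ICA-R", "communicating"))
  comm_id <- merged$label_map[["communicating"]]
  # ACA, PCA, Acom, Pcom, BA all map to the communicating class
  for (seg in c("ACA", "PCA", "Acom", "Pcom", "BA")) {
    expect_identical(merged$data[which(m == lm[[seg]])], comm_id)
  }
  # MCA-L voxels unchanged in support
  expect_identical(which(merged$data == merged$label_map[["MCA-L"]]),
                   which(m == lm[["MCA-L"]]))
  # total labeled voxel count preserved
  expect_identical(sum(merged$data != 0L), sum(m != 0L))
  # already-merged input is the identity
  again <- merge_cow_labels(merged)
  expect_identical(again$data, merged$data)
  # unknown label id is named in the error
  bad <- label_volume(array(c(7L, rep(0L, 215)), dims),
                      label_map = c(mystery = 7L))
  expect_error(merge_cow_labels(bad), "mystery")
  # aliases map non-canonical names onto segments
  ali <- label_volume(array(c(2L, rep(0L, 215)), dims), label_map = c(A3 = 2L))
  merged2 <- merge_cow_labels(ali, alias = c(A3 = "ACA"))
  expect_identical(merged2$data[1], merged2$label_map[["communicating"]])
})

test_that("MCA territory composites keep only MCA subregions, per side", {
  lm <- collrad:::territory_label_map()
  dims <- c(8, 6, 6)
  m <- array(0L, dims)
  m[1, 1, 1] <- lm[["M1-terr-L"]]
  m[2, 1, 1] <- lm[["M2-terr-L"]]
  m[3, 1, 1] <- lm[["ACA-terr-L"]]
  m[8, 1, 1] <- lm[["M1-terr-R"]]
  atlas <- label_volume(m, label_map = lm)
  comp <- build_mca_composite(atlas)
  expect_identical(which(comp$mca_terr_L$data != 0L),
                   which(m == lm[["M1-terr-L"]] | m == lm[["M2-terr-L"]]))
  expect_identical(sum(comp$mca_terr_L$data & comp$mca_terr_R$data), 0L)
  # a side with zero MCA voxels warns and returns an empty composite
  m2 <- m; m2[8, 1, 1] <- 0L
  expect_warning(comp2 <- build_mca_composite(label_volume(m2, label_map = lm)),
                 "side R")
  expect_identical(sum(comp2$mca_terr_R$data), 0L)
  # an atlas with no MCA subregions errors
  m3 <- array(0L, dims); m3[1] <- lm[["ACA-terr-L"]]
  expect_error(build_mca_composite(label_volume(m3, label_map = lm)), "MCA")
})

test_that("ROI assembly yields the variant-specific named sets", {
  case <- generate_case(tiny_phantom(), 31)
  a <- assemble_rois(case, "A")
  expect_named(a$rois, c("vessels_L", "vessels_R"))
  b <- assemble_rois(case, "B")
  expect_named(b$rois, c("mca_terr_L", "mca_terr_R"))
  cc <- assemble_rois(case, "C")
  expect_length(cc$rois, 7)
  expect_named(cc$rois, c("hemi_L", "hemi_R", "ica_L", "ica_R",
                          "mca_L", "mca_R", "communicating"))
  # hemispheric ROIs of variant C equal variant A's ROIs
  expect_identical(cc$rois$hemi_L$data, a$rois$vessels_L$data)
  expect_identical(cc$rois$hemi_R$data, a$rois$vessels_R$data)
  # all grid-compatible with the image
  for (r in cc$rois) expect_true(check_grid_compat(case$image, r))
  # missing mask is named
  broken <- case; broken$cow_mask <- NULL
  expect_error(assemble_rois(broken, "C"), "cow_mask")
})

test_that("label alias tables parse from key = value text", {
  path <- withr::local_tempfile(lines = c("# comment", "A3 = ACA", "P2=PCA"))
  al <- read_label_aliases(path)
  expect_identical(al, c(A3 = "ACA", P2 = "PCA"))
  bad <- withr::local_tempfile(lines = "nonsense line")
  expect_error(read_label_aliases(bad), "malformed")
})
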