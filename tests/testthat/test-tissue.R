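test_that("a constant image yields an empty mask with a warning", {
  img <- as_core_image(array(1, dim = c(64, 64, 3)), resolution = 0.25)
  expect_warning(m <- compute_tissue_mask(img), "degenerate")
  expect_equal(sum(m$mask), 0)
  expect_equal(dim(m$mask), c(64, 64))
})

test_that("a dark disc on white is recovered up to the closing kernel", {
  core <- simulate_core_image(256, 256, n_fragments = 1, noise_sd = 0,
                              seed = 4)
  img <- as_core_image(core$pixels, resolution = 0.25,
                       core_id = core$core_id)
  m <- compute_tissue_mask(img)
  truth <- core$truth_mask
  # recovered mask contains the disc and adds at most a thin closing rim
  expect_true(all(m$mask[truth]))
  expect_lt(sum(m$mask & !truth) / sum(truth), 0.10)
})

test_that("hole suppression converts the area threshold through the resolution", {
  img_of <- function(hole_px) {
    core <- simulate_core_image(400, 400, n_fragments = 1,
                                hole_areas_px = hole_px, noise_sd = 0,
                                seed = 6)
    as_core_image(core$pixels, resolution = 0.25, core_id = "h")
  }
  # 1470 um^2 at 0.25 um/px = 23,520 px^2
  m <- compute_tissue_mask(img_of(30000))
  expect_equal(m$hole_px2, 23520)
  inner <- m$mask[160:240, 160:240]
  expect_true(all(!inner))            # large hole preserved as background

  m2 <- compute_tissue_mask(img_of(10000))
  inner2 <- m2$mask[170:230, 170:230]
  expect_true(all(inner2))            # small hole filled
})

test_that("mask computation is deterministic and idempotent on binary input", {
  core <- simulate_core_image(200, 200, n_fragments = 1, seed = 8)
  img <- as_core_image(core$pixels, resolution = 0.25)
  m1 <- compute_tissue_mask(img)
  m2 <- compute_tissue_mask(img)
  expect_identical(m1$mask, m2$mask)

  # re-masking the binarised image reproduces the same tissue region
  binary <- array(1, dim = dim(core$pixels))
  for (ch in 1:3) binary[, , ch][m1$mask] <- 0
  m3 <- compute_tissue_mask(as_core_image(binary, resolution = 0.25))
  expect_identical(m3$mask, m1$mask)
})

test_that("patch grids tile from the origin and respect the tissue fraction", {
  full <- as_core_image(array(0.2, dim = c(512, 512, 3)),
                        resolution = 0.25, core_id = "full")
  mask_full <- structure(list(mask = matrix(TRUE, 512, 512),
                              resolution = 0.25, core_id = "full"),
                         class = "tissue_mask")
  g <- extract_patch_grid(full, mask_full, 256, 0.5)
  expect_equal(nrow(g), 4)
  expect_setequal(paste(g$row, g$col),
                  c("0 0", "0 256", "256 0", "256 256"))

  none <- mask_full
  none$mask <- matrix(FALSE, 512, 512)
  expect_equal(nrow(extract_patch_grid(full, none, 256, 0.5)), 0)

  # left half tissue: only the left column of patches survives
  half <- mask_full
  half$mask <- cbind(matrix(TRUE, 512, 256), matrix(FALSE, 512, 256))
  gh <- extract_patch_grid(full, half, 256, 0.5)
  expect_equal(nrow(gh), 2)
  expect_true(all(gh$col == 0))
  expect_equal(gh$tissue_fraction, c(1, 1))

  # patch larger than the image: empty grid; partial patches dropped
  expect_equal(nrow(extract_patch_grid(full, mask_full, 600, 0.5)), 0)
  g300 <- extract_patch_grid(full, mask_full, 300, 0.5)
  expect_equal(nrow(g300), 1)
})

test_that("augmentation cardinalities match the 4x and 13x schemes", {
  bags <- toy_bags(3, n = 2, d = 4)
  a4 <- augment_cohort(bags, mode = "geo4")
  expect_equal(nrow(a4), 12)
  expect_equal(sum(a4$transform == "identity"), 3)

  a13 <- augment_cohort(bags, mode = "geocolour13")
  expect_equal(nrow(a13), 39)

  one <- augment_cohort(bags[1], mode = "geo4")
  expect_equal(nrow(one), 4)
  # augmented copies keep the original's survival label
  expect_true(all(vapply(one$item, `[[`, numeric(1), "time") ==
                    bags[[1]]$time))
})

test_that("geometric transforms preserve tissue pixel count and grid cardinality", {
  core <- simulate_core_image(256, 256, n_fragments = 2, seed = 9)
  img <- as_core_image(core$pixels, resolution = 0.25, core_id = "t")
  img$truth_mask <- core$truth_mask
  aug <- augment_cohort(list(img), mode = "geo4")
  base_count <- sum(core$truth_mask)
  for (i in seq_len(nrow(aug))) {
    item <- aug$item[[i]]
    expect_equal(sum(item$truth_mask), base_count)
    m <- compute_tissue_mask(item, keep_largest = FALSE)
    g <- extract_patch_grid(item, m, 64, 0.5)
    if (aug$transform[[i]] == "identity") base_grid <- nrow(g)
  }
  # square image: flips preserve the retained patch count
  m0 <- compute_tissue_mask(img, keep_largest = FALSE)
  mh <- compute_tissue_mask(aug$item[[which(aug$transform == "hflip")]],
                            keep_largest = FALSE)
  expect_equal(sum(m0$mask), sum(mh$mask))
  g0 <- extract_patch_grid(img, m0, 64, 0.5)
  gh <- extract_patch_grid(aug$item[[which(aug$transform == "hflip")]],
                           mh, 64, 0.5)
  expect_equal(nrow(g0), nrow(gh))
})

test_that("super-patch block permutations mirror the image transforms", {
  # TL, TR, BL, BR indices under each transform, derived by hand
  expect_equal(milsurv:::superpatch_block_perm("hflip"), c(2L, 1L, 4L, 3L))
  expect_equal(milsurv:::superpatch_block_perm("vflip"), c(3L, 4L, 1L, 2L))
  expect_equal(milsurv:::superpatch_block_perm("rot90"), c(3L, 1L, 4L, 2L))
  expect_equal(milsurv:::superpatch_block_perm("rot180"), c(4L, 3L, 2L, 1L))

  bag <- patient_bag("G", matrix(rep(1:4, each = 2), 1, 8, byrow = TRUE),
                     time = 1, event = 1L, d = 2, grid = 2L)
  out <- milsurv:::geo_transform_bag(bag, "hflip")
  expect_equal(drop(out$instances), rep(c(2, 1, 4, 3), each = 2))
})

test_that("images and masks round-trip through PNG files", {
  core <- simulate_core_image(64, 64, n_fragments = 1, seed = 10)
  img <- as_core_image(core$pixels, resolution = 0.25, core_id = "rt")
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  back <- read_core_image(f, resolution = 0.25)
  expect_equal(dim(back$pixels), dim(img$pixels))
  expect_lt(max(abs(back$pixels - img$pixels)), 0.01)

  m <- compute_tissue_mask(img)
  fm <- withr::local_tempfile(fileext = ".png")
  write_image(m, fm)
  mr <- read_core_image(fm, resolution = 0.25)
  expect_equal(mr$pixels > 0.5, m$mask, ignore_attr = TRUE)
})
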