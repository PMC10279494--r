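test_that("phantom generation is deterministic with edges and valid range", {
  p1 <- generate_phantom(96, 96, seed = 4)
  p2 <- generate_phantom(96, 96, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_phantom(96, 96, seed = 5)))
  expect_gte(min(p1), 0)
  expect_lte(max(p1), 1)
  # edges exist: the Laplacian response is non-trivial
  expect_gt(max(abs(laplacian(p1))), 0.01)
  # degenerate spec: no shapes, no noise, flat background -> constant image
  flat <- generate_phantom(64, 64, n_shapes = 0, noise_sd = 0,
                           background = "flat", smooth = 0, seed = 1)
  expect_identical(flat, matrix(0.1, 64, 64))
  expect_error(generate_phantom(16, 64), "at least 32")
})

test_that("paired samples respect the exact scale relation", {
  ph <- generate_phantom(240, 240, seed = 6)
  for (mode in c("BD", "TD")) {
    pair <- make_pair(ph, mode, 2L)
    expect_identical(dim(pair$lr), c(120L, 120L))
    expect_identical(dim(pair$hr), c(240L, 240L))
    expect_identical(pair$mode, mode)
  }
  # constants survive both simulators
  cst <- matrix(0.5, 64, 64)
  expect_equal(make_pair(cst, "BD", 2)$lr, matrix(0.5, 32, 32),
               tolerance = 1e-12)
  expect_equal(make_pair(cst, "TD", 2)$lr, matrix(0.5, 32, 32),
               tolerance = 1e-12)
})

test_that("patch extraction pairs LR and HR regions at s-times the offset", {
  ph <- generate_phantom(96, 96, seed = 7)
  pair <- make_pair(ph, "BD", 2L)
  pt <- extract_patch_pair(pair, patch = 24L, seed = 3)
  expect_identical(dim(pt$lr), c(24L, 24L))
  expect_identical(dim(pt$hr), c(48L, 48L))
  # HR patch is the crop at exactly twice the LR offset
  off <- pt$offset
  expect_identical(pt$hr, ph[(2 * off[1] + 1):(2 * off[1] + 48),
                             (2 * off[2] + 1):(2 * off[2] + 48)])
  # BD re-degrade oracle: downsampling the HR member reproduces the LR
  # member bit for bit
  expect_identical(bicubic_downsample(pt$hr, 2L), pt$lr)
  # determinism per seed
  expect_identical(extract_patch_pair(pair, 24L, seed = 3)$offset, off)
  # LR exactly patch-sized: only offset (0, 0) is possible
  small <- make_pair(generate_phantom(48, 48, seed = 8), "BD", 2L)
  only <- extract_patch_pair(small, 24L, seed = 99)
  expect_identical(only$offset, c(0L, 0L))
  expect_identical(only$hr, small$hr)
  expect_error(extract_patch_pair(small, 30L), "exceeds")
  # TD patches crop both members
  tdp <- make_pair(generate_phantom(96, 96, seed = 9), "TD", 2L)
  tpt <- extract_patch_pair(tdp, 24L, seed = 1)
  o <- tpt$offset
  expect_identical(tpt$lr, tdp$lr[(o[1] + 1):(o[1] + 24),
                                  (o[2] + 1):(o[2] + 24)])
})

test_that("augmentation applies the same transform to both members", {
  ph <- generate_phantom(96, 96, seed = 10)
  pair <- extract_patch_pair(make_pair(ph, "BD", 2L), 24L, seed = 5)
  # flip is an involution
  f1 <- augment_pair(pair, flip = TRUE, rotate = FALSE)
  expect_false(identical(f1$lr, pair$lr))
  f2 <- augment_pair(f1, flip = TRUE, rotate = FALSE)
  expect_identical(f2$lr, pair$lr)
  expect_identical(f2$hr, pair$hr)
  # rotation has order 4
  r <- pair
  for (k in 1:4) r <- augment_pair(r, flip = FALSE, rotate = TRUE)
  expect_identical(r$lr, pair$lr)
  expect_identical(r$hr, pair$hr)
  # seeded coin flips are reproducible
  a1 <- augment_pair(pair, seed = 21)
  a2 <- augment_pair(pair, seed = 21)
  expect_identical(a1$lr, a2$lr)
  # re-degrade oracle survives augmentation of a BD pair (flip/rotation
  # commute with the symmetric separable kernel up to summation order)
  aug <- augment_pair(pair, flip = TRUE, rotate = TRUE)
  expect_equal(bicubic_downsample(aug$hr, 2L), aug$lr, tolerance = 1e-12)
})

test_that("dataset splitting follows 70/10/20 with floor and covers items", {
  sp <- split_dataset(1:10, seed = 2)
  expect_identical(lengths(sp), c(train = 7L, val = 1L, test = 2L))
  all_items <- sort(c(sp$train, sp$val, sp$test))
  expect_identical(all_items, 1:10)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_identical(split_dataset(1:10, seed = 2), sp)
  expect_false(identical(split_dataset(1:10, seed = 3), sp))
  sp33 <- split_dataset(1:33, seed = 1)
  expect_identical(unname(lengths(sp33)), c(23L, 3L, 7L))
  expect_error(split_dataset(1:10, fractions = c(0.7, 0.2, 0.2)), "summing")
  # list input keeps list elements
  spl <- split_dataset(as.list(letters[1:10]), seed = 4)
  expect_type(spl$train, "list")
})

test_that("image round trips stay within one quantisation step", {
  set.seed(30)
  img <- matrix(runif(32 * 32), 32, 32)
  f8 <- withr::local_tempfile(fileext = ".png")
  write_image(img, f8, bit_depth = 8L)
  expect_lt(max(abs(read_image(f8) - img)), 1 / 255)
  f16 <- withr::local_tempfile(fileext = ".tif")
  write_image(img, f16, bit_depth = 16L)
  expect_lt(max(abs(read_image(f16) - img)), 1 / (2^16 - 1))
  # representable constants round-trip exactly
  cst <- matrix(100 / 255, 16, 16)
  write_image(cst, f8)
  expect_equal(read_image(f8), cst, tolerance = 1e-7)
  cst16 <- matrix(40000 / 65535, 16, 16)
  write_image(cst16, f16, bit_depth = 16L)
  expect_equal(read_image(f16), cst16, tolerance = 1e-12)
  expect_error(read_image("does-not-exist.png"), "not found")
  expect_error(write_image(img, withr::local_tempfile(fileext = ".bmp")),
               "unsupported")
  expect_error(write_image(img, withr::local_tempfile(fileext = ".png"),
                           bit_depth = 16L), "tif")
})

test_that("NIfTI volumes are sliced along the third axis and rescaled", {
  vol <- array(seq(0, 1000, length.out = 16 * 16 * 4), dim = c(16, 16, 4))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), f)
  slices <- read_volume_slices(f)
  expect_length(slices, 4)
  expect_identical(dim(slices[[1]]), c(16L, 16L))
  rng <- range(unlist(slices))
  expect_equal(rng, c(0, 1), tolerance = 1e-6)
  # slices preserve the volume's spatial content up to the global rescale
  expect_equal(slices[[2]], vol[, , 2] / 1000, tolerance = 1e-4)
  expect_error(read_volume_slices("missing.nii"), "not found")
})

test_that("manifests round-trip through CSV", {
  df <- data.frame(id = c("a", "b"), split = c("train", "test"),
                   path_lr = c("lr/a.png", "lr/b.png"),
                   path_hr = c("hr/a.png", "hr/b.png"),
                   mode = "BD", scale = 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_manifest(df, f)
  back <- read_manifest(f)
  expect_identical(back$id, df$id)
  expect_identical(back$scale, c(2L, 2L))
  expect_error(write_manifest(df[, 1:3], f), "columns")
})
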