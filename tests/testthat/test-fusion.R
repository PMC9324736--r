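test_that("fuse is the per-voxel map lookup", {
  pair <- random_pair(seed = 6)

  # level-1 map reproduces adc_norm exactly
  out1 <- fuse(pair, intensity_map(level = 1))
  expect_identical(as.vector(unclass(out1)), as.vector(pair$adc_norm))

  # pure-DWI map reproduces 1 - dwi_norm exactly
  out90 <- fuse(pair, intensity_map(tilt = 90, suppression = 0))
  expect_identical(as.vector(unclass(out90)), as.vector(1 - pair$dwi_norm))

  # constant pair -> constant output equal to the map value at that point
  cp <- normalized_pair(array(0.3, c(2, 2, 2)), array(0.2, c(2, 2, 2)))
  m5 <- intensity_map(level = 5)
  outc <- fuse(cp, m5)
  expect_true(all(unclass(outc) == m5$value(0.3, 0.2)))

  # provenance and shape
  expect_identical(dim(out1), dim(pair$adc_norm))
  expect_equal(attr(out1, "params")$level, 1L)

  # mismatched grids are a parameter error at construction
  expect_error(normalized_pair(array(0.1, c(2, 2, 2)), array(0.1, c(2, 2, 3))),
               "shape")
})

test_that("fusion is a pure per-voxel function: permutation commutes, reruns are identical", {
  pair <- random_pair(seed = 7)
  m <- intensity_map(level = 6)
  n <- length(pair$adc_norm)
  out <- as.vector(unclass(fuse(pair, m)))

  set.seed(1)
  p <- sample.int(n)
  shp <- c(1L, 1L, n)
  perm_pair <- normalized_pair(array(pair$adc_norm[p], shp),
                               array(pair$dwi_norm[p], shp))
  out_perm <- as.vector(unclass(fuse(perm_pair, m)))
  expect_identical(out_perm, out[p])

  # bit-identical rerun
  expect_identical(unclass(fuse(pair, m)), unclass(fuse(pair, m)))

  # range invariant on random inputs
  expect_true(all(out >= 0 & out <= 1))
})

test_that("fuse_series matches direct fuse calls per level", {
  pair <- random_pair(shape = c(2L, 6L, 6L), seed = 8)
  vols <- fuse_series(pair, levels = 1:9)
  expect_length(vols, 9L)
  expect_identical(as.vector(unclass(vols[["level_1"]])), as.vector(pair$adc_norm))
  for (l in c(3L, 7L)) {
    expect_identical(unclass(vols[[paste0("level_", l)]]),
                     unclass(fuse(pair, intensity_map(level = l))))
  }

  # duplicates give identical volumes
  dup <- fuse_series(pair, levels = c(5L, 5L))
  expect_identical(unclass(dup[[1]]), unclass(dup[[2]]))

  expect_error(fuse_series(pair, levels = integer(0)), "non-empty")
  expect_error(fuse_series(pair, levels = c(1, 10)), "1..9")
})

test_that("mean background intensity is non-decreasing with level on the phantom", {
  ph <- small_phantom(seed = 3)
  pair <- normalize_patient(ph$series)
  vols <- fuse_series(pair, 1:9)
  bg <- as.integer(ph$mask) == 0L & as.vector(pair$dwi_norm) < 0.05
  means <- vapply(vols, function(v) mean(as.vector(unclass(v))[bg]), 0)
  expect_true(all(diff(means) >= -1e-12))
})

test_that("contrast_report summarizes classes and the tumor-vs-PZ contrast", {
  # constant image, single class
  img <- array(0.4, c(2, 3, 3))
  mask1 <- label_mask(array(0L, c(2, 3, 3)))
  rep1 <- contrast_report(img, mask1, labels = "background")
  expect_equal(rep1$mean, 0.4)
  expect_equal(rep1$sd, 0)
  expect_true(is.na(tumor_pz_contrast(rep1)))  # pca/pz rows missing -> NA

  # two constant classes 0.2 / 0.7 -> contrast 0.5
  lab <- array(0L, c(1, 2, 2)); lab[1, 1, ] <- 1L; lab[1, 2, ] <- 2L
  img2 <- array(0, c(1, 2, 2)); img2[1, 1, ] <- 0.2; img2[1, 2, ] <- 0.7
  rep2 <- contrast_report(img2, label_mask(lab))
  expect_equal(tumor_pz_contrast(rep2), 0.5)

  # absent requested label: NA row, not an error
  expect_true(is.na(rep2$mean[rep2$class == "tz"]))
  expect_equal(rep2$n_voxels[rep2$class == "tz"], 0L)

  # tidy()/glance() expose the same numbers
  expect_identical(nrow(tidy(rep2)), 4L)
  expect_equal(glance(rep2)$tumor_pz_contrast, 0.5)
})

test_that("level-5 mcDI beats the plain ADC on tumor-vs-PZ contrast (default phantom)", {
  ph <- generate_phantom()
  pair <- normalize_patient(ph$series)
  mc5 <- fuse(pair, intensity_map(level = 5))
  c_mcdi <- tumor_pz_contrast(contrast_report(mc5, ph$mask))
  c_adc <- tumor_pz_contrast(contrast_report(array(pair$adc_norm, dim(pair$adc_norm)),
                                             ph$mask))
  expect_gte(c_mcdi, c_adc)
})
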