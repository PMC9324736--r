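test_that("level 1 is exactly the identity (ADC) map", {
  m1 <- intensity_map(level = 1)
  set.seed(2)
  a <- runif(2000); d <- runif(2000)
  expect_identical(m1$value(a, d), a)
  expect_equal(m1$value(0.7, 0.9), 0.7)

  grid <- seq(0, 1, length.out = 257)
  g <- expand.grid(a = grid, d = grid)
  expect_equal(max(abs(m1$value(g$a, g$d) - g$a)), 0)

  # level 1 cannot carry tilt or suppression
  expect_error(intensity_map(level = 1, tilt = 20), "identity")
  expect_error(intensity_map(level = 1, suppression = 0.5), "identity")
})

test_that("the 90-degree, zero-suppression map is the pure inverted DWI readout", {
  m <- intensity_map(tilt = 90, suppression = 0)
  set.seed(3)
  a <- runif(2000); d <- runif(2000)
  expect_identical(m$value(a, d), 1 - d)
  expect_equal(m$value(0.3, 1.0), 0)
})

test_that("parameter validation enforces the stated domains", {
  expect_error(intensity_map(level = 0), "1..9")
  expect_error(intensity_map(level = 10), "1..9")
  expect_error(intensity_map(level = 2.5), "1..9")
  expect_error(intensity_map(level = 5, tau = 1), "tau")
  expect_error(intensity_map(level = 5, tau = -0.1), "tau")
  expect_error(intensity_map(tilt = 45), "both")
  expect_error(intensity_map(level = 3, tilt = 100), "90")
  expect_error(intensity_map(level = 3, suppression = 1.5), "suppression")
  expect_error(intensity_map(level = 5, scheme = "sepia"), "unknown color scheme")
  expect_error(rasterize(intensity_map(level = 5), resolution = 1), ">= 2")
})

test_that("maps are monotone: non-decreasing in ADC, non-increasing in DWI (d >= tau)", {
  res <- 256L
  centers <- (seq_len(res) - 0.5) / res
  above <- centers >= 0.05
  for (lev in 1:9) {
    ras <- rasterize(intensity_map(level = lev), res)
    expect_true(all(ras >= 0 & ras <= 1))
    # along ADC (rows), at every DWI
    expect_true(all(apply(ras, 2, function(col) all(diff(col) >= -1e-12))))
    # along DWI (columns), in the d >= tau region
    expect_true(all(apply(ras[, above], 1, function(row) all(diff(row) <= 1e-12))))
  }
})

test_that("background value is non-decreasing in level inside the no-tumor zone", {
  a <- rep(seq(0, 1, length.out = 21), each = 5)
  d <- rep(c(0, 0.01, 0.02, 0.03, 0.049), times = 21)
  vals <- sapply(1:9, function(l) intensity_map(level = l)$value(a, d))
  expect_true(all(apply(vals, 1, function(v) all(diff(v) >= -1e-12))))

  # the (0,1) corner is the darkest reachable point for every level
  for (l in 1:9) expect_equal(intensity_map(level = l)$value(0, 1), 0)
})

test_that("maps are continuous: bounded increments on a fine raster", {
  res <- 512L
  for (lev in c(2L, 5L, 9L)) {
    ras <- rasterize(intensity_map(level = lev), res)
    # Lipschitz bound: |dv/da| <= 1, and across d the suppression adds at
    # most suppression/tau per unit d; allow that bound plus slack
    w <- (lev - 1) / 8
    bound_a <- 1.5 / res
    bound_d <- (1 + w / 0.05) * 1.5 / res
    expect_lt(max(abs(diff(ras))), bound_a)          # steps along ADC
    expect_lt(max(abs(t(diff(t(ras))))), bound_d)    # steps along DWI
  }
})

test_that("rasterize samples bin centers on the stated grid", {
  m5 <- intensity_map(level = 5)
  ras <- rasterize(m5, 64L)
  centers <- (seq_len(64) - 0.5) / 64
  expect_equal(ras[13, 40], m5$value(centers[13], centers[40]))

  # level-1 raster: constant along DWI, the ADC ramp along rows
  r1 <- rasterize(intensity_map(level = 1), 256L)
  expect_equal(r1[, 1], (seq_len(256) - 0.5) / 256)
  expect_true(all(apply(r1, 1, function(row) length(unique(row)) == 1L)))
})

test_that("color maps follow the Fig-6 conventions", {
  cm <- build_color_map(level = 5, scheme = "hot")
  # background (d < tau): vertical grayscale capped at 50% gray
  expect_equal(as.vector(cm$value(1, 0)), c(0.5, 0.5, 0.5))
  expect_equal(as.vector(cm$value(0, 0)), c(0, 0, 0))
  expect_equal(as.vector(cm$value(0.6, 0.02)), rep(0.3, 3))

  # above tau the ramp is in color (channels differ somewhere)
  mid <- as.vector(cm$value(0.3, 0.5))
  expect_false(all(abs(mid - mid[1]) < 1e-9))

  # grayscale scheme degenerates to the gray map everywhere
  gs <- build_color_map(level = 5, scheme = "grayscale")
  gm <- build_map(level = 5)
  set.seed(8)
  a <- runif(500); d <- runif(500)
  expect_identical(gs$value(a, d), gm$value(a, d))

  # rgb rasters have three channels in range
  ras <- rasterize(cm, 32L)
  expect_identical(dim(ras), c(32L, 32L, 3L))
  expect_true(all(ras >= 0 & ras <= 1))
})

test_that("map configs round-trip through plain-text JSON", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "map.json")
  m <- intensity_map(level = 7, tau = 0.08, scheme = "hot")
  write_map_config(m, p)
  back <- read_map_config(p)
  expect_equal(back$params, m$params)
  set.seed(1)
  a <- runif(100); d <- runif(100)
  expect_identical(back$value(a, d), m$value(a, d))
})
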