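two_point_series <- function(s0, s800, shape = c(1L, 1L, 1L)) {
  diffusion_series(list(array(s0, shape), array(s800, shape)), c(0, 800))
}

test_that("fit_adc matches the closed-form ln-ratio on hand cases", {
  # equal signals -> ADC 0
  expect_equal(as.vector(fit_adc(two_point_series(1000, 1000))), 0)

  # S(800) = S(0) * exp(-0.8) -> ADC = 1.0e-3 mm^2/s = 1000 storage units
  expect_equal(as.vector(fit_adc(two_point_series(1000, 1000 * exp(-0.8)))),
               1000, tolerance = 1e-12)

  # ln(1000)/800 * 1e6 ~ 8634 -> clipped to 4095
  expect_equal(as.vector(fit_adc(two_point_series(1000, 1))), 4095)

  # non-positive signal at either b-value -> ADC 0, not an error
  expect_equal(as.vector(fit_adc(two_point_series(0, 10))), 0)
  expect_equal(as.vector(fit_adc(two_point_series(10, 0))), 0)

  # negative ADC (signal increase) clips to 0
  expect_equal(as.vector(fit_adc(two_point_series(100, 200))), 0)

  # requesting a b-value absent from the series is a parameter error
  expect_error(fit_adc(two_point_series(10, 5), 0, 700), "not in the series")
})

test_that("compute_cdwi evaluates the mono-exponential extrapolation", {
  sh <- c(1L, 1L, 1L)
  series <- two_point_series(1000, 449.329)
  adc <- adc_volume(array(1000, sh))  # 1.0e-3 mm^2/s

  # independent exponential evaluation: 449.329 * exp(-0.7)
  out <- compute_cdwi(series, adc, b_ref = 800, b_target = 1500)
  expect_equal(as.vector(out), 449.329 * exp(-0.7), tolerance = 1e-12)

  # b_target = b_ref -> identity
  same <- compute_cdwi(series, adc, b_ref = 800, b_target = 800)
  expect_equal(as.vector(same), 449.329)

  # ADC = 0 -> input unchanged at any target
  z <- compute_cdwi(series, adc_volume(array(0, sh)), 800, 3000)
  expect_equal(as.vector(z), 449.329)

  expect_error(compute_cdwi(series, adc, b_ref = 123, b_target = 1500),
               "not in the series")
})

test_that("cdwi is monotone decreasing in b_target for positive ADC", {
  set.seed(5)
  sh <- c(2L, 3L, 3L)
  series <- diffusion_series(
    list(array(runif(18, 500, 1500), sh), array(runif(18, 10, 400), sh)),
    c(0, 800))
  adc <- adc_volume(array(runif(18, 100, 3000), sh))
  targets <- c(800, 1000, 1500, 2000, 3000)
  sigs <- lapply(targets, function(bt) as.vector(compute_cdwi(series, adc, 800, bt)))
  for (i in seq_len(length(targets) - 1)) {
    expect_true(all(sigs[[i + 1]] < sigs[[i]]))
  }
})

test_that("fit_adc then cdwi back to b_high is the identity (no clipping)", {
  set.seed(11)
  sh <- c(3L, 5L, 5L)
  s0 <- array(runif(prod(sh), 200, 2000), sh)
  adc_true <- array(runif(prod(sh), 100, 3500), sh)
  s800 <- s0 * exp(-800 * adc_true / 1e6)
  series <- diffusion_series(list(s0, s800), c(0, 800))

  adc <- fit_adc(series)
  expect_equal(as.vector(adc), as.vector(adc_true), tolerance = 1e-9)

  back <- compute_cdwi(series, adc, b_ref = 0, b_target = 800)
  expect_equal(as.vector(back), as.vector(s800), tolerance = 1e-6)
})

test_that("normalize_dwi divides by the global per-patient maximum", {
  sh <- c(1L, 2L, 2L)
  b0 <- array(c(2000, 100, 50, 10), sh)     # series max 2000 ('bladder' at b0)
  hb <- array(c(500, 20, 10, 5), sh)
  series <- diffusion_series(list(b0, hb), c(0, 800))

  n <- normalize_dwi(series, volume3d(hb))
  expect_equal(n[1, 1, 1], 500 / 2000)  # 0.25: divided by the global max
  expect_true(all(n >= 0 & n <= 1))
  expect_lt(max(n), 1)  # the maximizing voxel is in b0, not in hb

  # hb volume containing the series max normalizes its peak to exactly 1
  series2 <- diffusion_series(list(array(10, sh), b0), c(0, 800))
  n2 <- normalize_dwi(series2, volume3d(b0))
  expect_equal(max(n2), 1)

  # all-zero series is a degenerate input
  zs <- diffusion_series(list(array(0, sh), array(0, sh)), c(0, 800))
  expect_error(normalize_dwi(zs, volume3d(array(0, sh))), "degenerate")
})

test_that("normalize_adc divides by the 4095 storage ceiling", {
  sh <- c(1L, 1L, 3L)
  adc <- adc_volume(array(c(4095, 0, 819), sh))
  n <- normalize_adc(adc)
  expect_equal(as.vector(n), c(1, 0, 819 / 4095))
  expect_error(adc_volume(array(5000, sh)), "4095")
  expect_error(adc_volume(array(-1, sh)), "4095")
})

test_that("fit_adc recovers phantom ground truth exactly on noise-free data", {
  ph <- small_phantom()
  adc <- fit_adc(ph$series)
  rel <- abs(as.vector(adc) - as.vector(ph$adc_true)) / as.vector(ph$adc_true)
  expect_lt(max(rel), 1e-3)
})
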