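make_series <- function(arr, tr = 0.85) {
  structure(list(data = arr, tr = tr, voxel_mm = c(1, 1, 1)),
            class = "functional_series")
}

test_that("restricted smoothing preserves constants and single voxels", {
  lab <- small_slab(c(8, 8, 22))
  bin <- bin_layers(lab$depth)
  cellmask <- !is.na(bin) & bin == 2 & lab$roi == 1
  arr <- array(100, c(8, 8, 22, 2))
  sm <- masked_gaussian_smooth(make_series(arr), lab, 2.35)
  # constant image within a cell stays constant (renormalized kernel)
  expect_equal(sm$data, arr, tolerance = 1e-12)
  expect_identical(masked_gaussian_smooth(make_series(arr), lab, 0)$data, arr)
})

test_that("smoothing matches brute-force masked convolution, no leakage", {
  lab <- small_slab(c(8, 7, 22))
  set.seed(31)
  arr <- array(rnorm(8 * 7 * 22 * 2, 100), c(8, 7, 22, 2))
  sm <- masked_gaussian_smooth(make_series(arr), lab, 2.35)
  sig <- 2.35 / (2 * sqrt(2 * log(2)))
  h <- ceiling(3 * sig)
  bin <- bin_layers(lab$depth)
  cellid <- ifelse(is.na(bin) | lab$roi == 0, NA, (lab$roi - 1) * 3 + bin)
  idx <- which(!is.na(cellid))
  set.seed(32)
  for (i in sample(idx, 12)) {
    ai <- arrayInd(i, dim(lab$depth))
    num <- 0; den <- 0
    for (dx in -h:h) for (dy in -h:h) for (dz in -h:h) {
      x <- ai[1] + dx; y <- ai[2] + dy; z <- ai[3] + dz
      if (x < 1 || x > 8 || y < 1 || y > 7 || z < 1 || z > 22) next
      if (is.na(cellid[x, y, z]) || cellid[x, y, z] != cellid[i]) next
      w <- exp(-(dx^2 + dy^2 + dz^2) / (2 * sig^2))
      num <- num + w * arr[x, y, z, 1]
      den <- den + w
    }
    expect_equal(sm$data[ai[1], ai[2], ai[3], 1], num / den,
                 tolerance = 1e-10)
  }
  # out-of-mask voxels pass through untouched
  out <- which(is.na(cellid))[1:20]
  expect_equal(sm$data[, , , 1][out], arr[, , , 1][out])
})

test_that("cross-cell leakage is exactly zero", {
  lab <- small_slab(c(8, 8, 22))
  bin <- bin_layers(lab$depth)
  arr <- array(100, c(8, 8, 22, 1))
  # spike the middle bin; deep and superficial bins must be unaffected
  arr[, , , 1][!is.na(bin) & bin == 2] <- 500
  sm <- masked_gaussian_smooth(make_series(arr), lab, 2.35)
  other <- !is.na(bin) & bin != 2
  expect_equal(sm$data[, , , 1][other], rep(100, sum(other)),
               tolerance = 1e-12)
})

test_that("DCT high-pass removes slow drift and is an idempotent projection", {
  n <- 820; tr <- 0.85
  expect_equal(floor(2 * n * tr * 0.003), 4) # K for the default session
  tt <- (seq_len(n) - 0.5) * tr
  dc <- matrix(7, n, 1)
  expect_equal(dct_highpass(dc, 0.003, tr), dc)
  slow <- matrix(cos(2 * pi * 0.001 * tt), n, 1)
  filt <- dct_highpass(slow, 0.003, tr)
  # amplitude remaining at 0.001 Hz: regression of the residual on the
  # centered input cosine
  cc <- slow - mean(slow)
  amp_left <- sum((filt - mean(filt)) * cc) / sum(cc^2)
  expect_lt(abs(amp_left), 0.05)
  set.seed(41)
  y <- matrix(rnorm(2 * n), n, 2) + 50
  once <- dct_highpass(y, 0.003, tr)
  expect_equal(dct_highpass(once, 0.003, tr), once, tolerance = 1e-10)
  expect_equal(colMeans(once), colMeans(y)) # mean re-added
  expect_error(dct_highpass(y, 10, tr), "cutoff")
})

test_that("percent signal change is zero-mean and flags bad voxels", {
  arr <- array(200, c(2, 2, 1, 5))
  arr[1, 1, 1, ] <- c(200, 210, 190, 200, 200)
  psc <- percent_signal_change(make_series(arr))
  expect_equal(psc$data[1, 1, 1, 2], 5)
  expect_equal(psc$data[2, 2, 1, ], rep(0, 5))
  m <- matrix(psc$data, 4, 5)
  expect_equal(rowMeans(m), rep(0, 4))
  arr2 <- arr; arr2[2, 1, 1, ] <- 0
  psc2 <- percent_signal_change(make_series(arr2))
  expect_equal(attr(psc2, "invalid_voxels"), 1L)
  expect_true(all(is.na(psc2$data[2, 1, 1, ])))
})

test_that("RVT of a pure sinusoid is its analytic amplitude rate", {
  fs <- 50; amp <- 2; period <- 4
  t <- seq(0, 600, by = 1 / fs)
  resp <- amp * sin(2 * pi * t / period)
  vt <- seq(10, 590, by = 0.85)
  r <- rvt(resp, fs, vt, expected_period_s = period)
  expect_length(r, length(vt))
  expect_rel_equal(r, 2 * amp / period, 0.05)
  # linear in amplitude
  r2 <- rvt(2 * resp, fs, vt, expected_period_s = period)
  expect_equal(r2, 2 * r, tolerance = 1e-8)
  expect_error(rvt(rep(0, 1000), fs, vt), "no detectable")
})

test_that("BPM recovers the pulse rate", {
  fs <- 50
  t <- seq(0, 600, by = 1 / fs)
  vt <- seq(10, 590, by = 0.85)
  for (hz in c(1, 1.2)) {
    pulse <- sin(2 * pi * hz * t)
    b <- bpm(pulse, fs, vt, expected_period_s = 1 / hz)
    expect_length(b, length(vt))
    expect_rel_equal(b, 60 * hz, 0.03)
  }
  expect_error(bpm(rep(0, 1000), fs, vt), "no detectable")
})
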