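geom16 <- array_geometry(n_elements = 16)

test_that("spatial coherence is 1 for identical channels at every lag", {
  sig <- sin(2 * pi * (1:40) / 8)
  A <- matrix(sig, 40, 16)
  for (m in c(1, 3, 7, 15)) {
    expect_equal(spatial_coherence(A, m), 1)
  }
})

test_that("alternating-sign channels give lag-1 coherence of -1", {
  sig <- rnorm(30)
  A <- sapply(1:16, function(i) sig * (-1)^i)
  expect_equal(spatial_coherence(A, 1), -1)
  expect_equal(spatial_coherence(A, 2), 1)
})

test_that("independent white-noise channels have near-zero mean coherence", {
  set.seed(300)
  vals <- replicate(400, spatial_coherence(matrix(rnorm(25 * 16), 25, 16), 1))
  expect_lt(abs(mean(vals)), 3 / sqrt(400 * 15 * 25))
})

test_that("coherence is invariant to a common positive rescaling", {
  set.seed(301)
  A <- matrix(rnorm(20 * 16), 20, 16)
  for (m in c(1, 4)) {
    expect_equal(spatial_coherence(A * 37.5, m), spatial_coherence(A, m))
  }
})

test_that("zero-energy channels are skipped and the all-zero case returns 0", {
  set.seed(302)
  A <- matrix(rnorm(20 * 8), 20, 8)
  A[, 3] <- 0
  keep <- c(1, 4, 5, 6, 7)  # lag-1 pairs with both members nonzero
  manual <- mean(sapply(keep, function(i) {
    j <- i + 1
    sum(A[, i] * A[, j]) / sqrt(sum(A[, i]^2) * sum(A[, j]^2))
  }))
  expect_equal(spatial_coherence(A, 1), manual)
  expect_equal(spatial_coherence(matrix(0, 20, 8), 1), 0)
  expect_error(spatial_coherence(A, 8), "lag")
})

test_that("compiled SLSC kernel matches the reference estimator", {
  set.seed(303)
  A <- matrix(rnorm(200 * 16), 200, 16)
  kern_half <- 5L
  rows <- c(50L, 100L, 150L)
  lags <- slscgcnr:::cpp_slsc_aligned(A, rows - 1L, kern_half, 4L)
  for (k in seq_along(rows)) {
    win <- A[(rows[k] - kern_half):(rows[k] + kern_half), ]
    for (m in 1:4) {
      expect_equal(lags[k, m], spatial_coherence(win, m))
    }
  }
})

test_that("SLSC pixels of noiseless identical channels equal M, and bounds hold", {
  sig <- rep(sin(2 * pi * (1:160) / 10), 1)
  A <- matrix(sig, 160, 16)
  al <- fake_aligned(list(A), geometry = geom16)
  img <- slsc_image(al, slsc_params(M = 7), decimation = 4L)
  interior <- img$values[5:35, 1]
  expect_true(all(abs(interior - 7) < 1e-8))
  imgn <- slsc_image(al, slsc_params(M = 7, normalize_by_M = TRUE), decimation = 4L)
  expect_true(all(imgn$values <= 1 + 1e-12))
  expect_error(slsc_image(al, slsc_params(M = 16)), "smaller")
})

test_that("truncation never increases a pixel and noise-only SLSC stays near zero", {
  set.seed(304)
  A <- matrix(rnorm(400 * 16), 400, 16)
  al <- fake_aligned(list(A), geometry = geom16)
  raw <- slsc_image(al, slsc_params(M = 7, truncate_negative = FALSE))
  trunc <- slsc_image(al, slsc_params(M = 7, truncate_negative = TRUE))
  expect_true(all(trunc$values <= raw$values + 1e-12 | raw$values < 0))
  expect_true(all(trunc$values >= 0))
  expect_lt(abs(mean(raw$values)), 0.5)  # E[R(m)] ~ 0 for i.i.d. channels
  perlag <- slsc_image(al, slsc_params(M = 7, per_lag_truncate = TRUE))
  expect_true(all(perlag$values >= trunc$values - 1e-12))
})

test_that("delay-and-sum gives coherent N-fold gain and flat tone envelope", {
  n <- 260  # integer number of tone periods, so the analytic signal is exact
  tone <- sin(2 * pi * (1:n) / 10)
  A <- matrix(tone, n, 16)
  al <- fake_aligned(list(A), geometry = geom16)
  img <- das_bmode(al, decimation = 1L)
  interior <- img$values[30:230, 1]
  expect_true(all(abs(interior - 16) < 0.05))  # N x unit amplitude, flat
})

test_that("log compression maps max to 0 dB with a -20 dB decade and keeps order", {
  vals <- matrix(c(1, 0.1, 0.5, 0.02), 2, 2)
  img <- ultrasound_image(vals, "bmode_linear", 1e-4, 1e-4)
  lg <- log_compress(img, 60)
  expect_equal(max(lg$values), 0)
  expect_equal(lg$values[2, 1], -20)
  expect_equal(order(vals), order(lg$values))
  expect_true(all(lg$values >= -60))
  zero <- ultrasound_image(matrix(0, 2, 2), "bmode_linear", 1e-4, 1e-4)
  expect_error(log_compress(zero), "all-zero")
})

test_that("receive delays align a focal point target across the aperture", {
  geom <- array_geometry()
  zf <- geom$transmit_focus_depth
  ph <- structure(list(
    scatterers = data.frame(lateral = 0, axial = zf, amplitude = 1),
    lesions = list(),
    extent = list(lateral = c(-10e-3, 10e-3), axial = c(5e-3, 30e-3)),
    seed = 1L
  ), class = "phantom")
  cd <- simulate_channel_data(ph, geom, 0, cull_margin = 1)
  al <- apply_receive_delays(cd, depth_range = c(0.018, 0.022))
  A <- al$lines[[1]]
  peaks <- apply(abs(A), 2, which.max)
  # all elements peak within half an RF period of the same depth row
  expect_lt(diff(range(peaks)), 6)
  expect_lt(abs(al$depths[round(median(peaks))] - zf), 2e-4)
  # zero input stays zero
  cd0 <- cd
  cd0$samples[[1]][] <- 0
  expect_true(all(apply_receive_delays(cd0, c(0.018, 0.022))$lines[[1]] == 0))
})

test_that("lateral speckle autocorrelation width matches the diffraction limit", {
  geom <- array_geometry()
  ext <- list(lateral = c(-4e-3, 4e-3), axial = c(0.018, 0.022))
  ph <- make_phantom(ext, 2e8, seed = 55)
  lines_x <- seq(-1.5e-3, 1.5e-3, by = 0.06e-3)
  cd <- simulate_channel_data(ph, geom, lines_x, pulse_cycles = 6, seed = 56)
  al <- apply_receive_delays(cd, depth_range = c(0.0195, 0.0205))
  I <- das_bmode(al, decimation = 2)$values^2
  vc <- sweep(I, 1, rowMeans(I))
  ac <- sapply(0:25, function(lag) {
    if (lag == 0) mean(rowSums(vc * vc)) else
      mean(rowSums(vc[, 1:(ncol(vc) - lag)] * vc[, (lag + 1):ncol(vc)]))
  })
  ac <- ac / ac[1]
  fwhm <- 2 * approx(ac, 0:25, xout = 0.5)$y * 0.06e-3
  predicted <- wavelength(geom) * 0.02 / (geom$n_elements * geom$pitch)
  expect_lt(abs(fwhm / predicted - 1), 0.25)
})
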