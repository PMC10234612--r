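test_that("spectra locate tones and satisfy the normalization contract", {
  Tn <- 512; tr <- 0.35
  t <- (0:(Tn - 1)) * tr
  tone <- 100 + sin(2 * pi * 0.05 * t)
  arr <- aperm(array(tone, c(Tn, 6, 6, 4)), c(2, 3, 4, 1))
  masks <- list(gm = array(TRUE, c(6, 6, 4)))
  ps <- power_spectrum(complex_series(arr + 0i, tr_s = tr), masks)
  expect_equal(ps$freq_hz[which.max(ps$mean$gm)],
               ps$freq_hz[which.min(abs(ps$freq_hz - 0.05))])
  expect_equal(sum(ps$mean$gm), 1, tolerance = 1e-12)
  expect_equal(as.vector(rowSums(do.call(rbind,
    lapply(ps$per_run, rowSums)))), 1, tolerance = 1e-12)
})

test_that("white-noise spectra are flat after voxel averaging", {
  set.seed(2)
  arr <- array(rnorm(14 * 14 * 12 * 128, 100, 1), c(14, 14, 12, 128))
  ps <- power_spectrum(arr, list(all = array(TRUE, c(14, 14, 12))),
                       tr_s = 1)
  expect_lt(max(ps$mean$all) / min(ps$mean$all), 1.5)
  r <- peak_to_floor(ps, 0.2, c(0.05, 0.45))
  expect_equal(r, 1, tolerance = 0.3)
})

test_that("peak-to-floor ratio is scale invariant", {
  Tn <- 256; tr <- 0.5
  t <- (0:(Tn - 1)) * tr
  x <- 100 + 0.5 * sin(2 * pi * 0.1 * t)
  arr <- aperm(array(x, c(Tn, 4, 4, 4)), c(2, 3, 4, 1)) +
    array(rnorm(4 * 4 * 4 * Tn, 0, 0.3), c(4, 4, 4, Tn))
  masks <- list(gm = array(TRUE, c(4, 4, 4)))
  p1 <- power_spectrum(arr, masks, tr_s = tr)
  p2 <- power_spectrum(arr * 7, masks, tr_s = tr)
  r1v <- peak_to_floor(p1, 0.1, c(0.3, 0.9))
  r2v <- peak_to_floor(p2, 0.1, c(0.3, 0.9))
  expect_equal(r1v, r2v, tolerance = 1e-10)
  expect_gt(r1v, 3)
  expect_error(power_spectrum(arr, list(gm = array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("spectral energy matches temporal sum of squares (Parseval)", {
  set.seed(5)
  Tn <- 64
  arr <- array(rnorm(4 * 4 * 2 * Tn), c(4, 4, 2, Tn))
  sp <- amplitude_spectra(arr, tr_s = 1)
  Y <- t(matrix(arr, 32, Tn))
  ss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  # fold the half spectrum: bins 1..T/2-1 appear twice, Nyquist once
  nb <- nrow(sp$amplitude)
  energy <- 2 * colSums(sp$amplitude[-nb, , drop = FALSE]^2) +
    sp$amplitude[nb, ]^2
  expect_equal(energy / Tn, ss, tolerance = 1e-6)
})
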