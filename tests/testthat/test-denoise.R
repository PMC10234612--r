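test_that("patch side follows the smallest-cube 11:1 rule", {
  expect_identical(select_patch_side(118), 11L)  # 159.3 s / 1.35 s run
  expect_identical(select_patch_side(76), 10L)   # 159.6 s / 2.1 s run
  expect_identical(select_patch_side(1), 3L)
  expect_identical(select_patch_side(1000, ratio = 1), 10L)
})

test_that("g-factor normalization is exact and flattens noise", {
  spec <- noise_spec(sigma = 1, g_max = 2, n_volumes = 300,
                     grid_dims = c(16, 16, 8), n_runs = 1)
  sim <- simulate_run(spec)
  g <- sim$truth$g_map
  expect_equal(gfactor_normalize(sim$series, array(1, dim(g)))$data,
               sim$series$data)
  back <- gfactor_normalize(gfactor_normalize(sim$series, g, "forward"),
                            g, "inverse")
  expect_equal(back$data, sim$series$data, tolerance = 1e-12)
  norm <- gfactor_normalize(sim$series, g, "forward")
  sdv <- apply(Re(norm$data), 1:3, sd)
  expect_lt(sd(sdv) / mean(sdv), 0.05)
  expect_error(gfactor_normalize(sim$series, g * 0), "positive")
})

test_that("phase normalization removes smooth phase, preserves magnitude", {
  spec <- clean_spec(grid_dims = c(32, 32, 12), n_volumes = 30, n_runs = 1)
  sim <- simulate_run(spec)
  pn <- phase_normalize(sim$series, filter_fwhm_mm = 4)
  expect_equal(Mod(pn$series$data), Mod(sim$series$data), tolerance = 1e-10)
  mask <- as.vector(sim$truth$brain_mask)
  expect_lt(sd(Arg(pn$series$data)[mask]), 0.05)
  # zero-phase input passes through
  m <- magnitude_series(sim$series)
  pn0 <- phase_normalize(m)
  expect_equal(pn0$series$data, m$data, tolerance = 1e-12)
  # exact restoration from the returned field
  restored <- pn$series$data * exp(1i * pn$phase_field)
  expect_equal(restored, sim$series$data, tolerance = 1e-12)
})

test_that("noise singular-value threshold scales and matches the asymptote", {
  expect_identical(noise_singular_threshold(100, 50, 0), 0)
  t1 <- noise_singular_threshold(60, 40, 1, n_mc = 10, seed = 7)
  t2 <- noise_singular_threshold(60, 40, 2, n_mc = 10, seed = 7)
  expect_equal(t2, 2 * t1)
  tau <- noise_singular_threshold(200, 200, 1, n_mc = 30)
  expect_equal(tau, sqrt(2) * (sqrt(200) + sqrt(200)), tolerance = 0.02)
})

test_that("noise sd estimation recovers truth and is scale equivariant", {
  spec <- noise_spec(sigma = 1, n_volumes = 60, grid_dims = c(15, 15, 10),
                     n_runs = 1)
  sim <- simulate_run(spec)
  s_hat <- estimate_noise_sigma(sim$series, "patch_mp")
  expect_equal(s_hat, 1, tolerance = 0.05)
  zero <- complex_series(array(0 + 0i, c(8, 8, 8, 20)))
  expect_equal(estimate_noise_sigma(zero, "patch_mp"), 0)
  scaled <- series_like(sim$series, sim$series$data * 3.5)
  expect_equal(estimate_noise_sigma(scaled, "patch_mp"), 3.5 * s_hat,
               tolerance = 1e-8)
  mask <- array(TRUE, c(15, 15, 10))
  expect_equal(estimate_noise_sigma(sim$series, "noise_region", mask), 1,
               tolerance = 0.05)
  expect_error(estimate_noise_sigma(sim$series, "noise_region",
                                    array(FALSE, c(15, 15, 10))), "mask")
})

test_that("single-patch denoising equals the direct SVD reference", {
  set.seed(42)
  d <- c(8, 8, 8); Tn <- 30
  arr <- array(rnorm(prod(d) * Tn, 100, 1), c(d, Tn))
  ser <- complex_series(arr)
  res <- nordic_denoise(ser, scheme = patch_scheme(side = 8), sigma = 1,
                        magnitude_only = TRUE, n_mc = 20)
  X <- matrix(arr, prod(d), Tn)
  ref <- svt_reference(X, res$threshold)
  expect_equal(as.vector(Re(res$denoised$data)), as.vector(ref),
               tolerance = 1e-8)
  expect_identical(length(res$rank_map$ranks), 1L)
})

test_that("denoised + removed reconstruct the input exactly", {
  spec <- noise_spec(sigma = 1, grid_dims = c(12, 12, 8), n_volumes = 40,
                     n_runs = 1)
  sim <- simulate_run(spec)
  res <- nordic_denoise(sim$series, scheme = patch_scheme(side = 8),
                        n_mc = 10)
  expect_equal(res$denoised$data + res$removed$data, sim$series$data,
               tolerance = 1e-12)
})

test_that("zero threshold with full sliding reproduces the input", {
  spec <- clean_spec(grid_dims = c(14, 14, 10), n_volumes = 40, n_runs = 1)
  sim <- simulate_run(spec, make_block_schedule(n_cycles = 1))
  res <- nordic_denoise(sim$series, scheme = patch_scheme(side = 8),
                        sigma = 0)
  expect_equal(res$denoised$data, sim$series$data, tolerance = 1e-7)
})

test_that("larger noise estimates never increase retained rank", {
  spec <- phantom_spec(grid_dims = c(12, 12, 8), n_volumes = 40, n_runs = 1,
                       sigma_thermal = 2)
  sim <- simulate_run(spec, make_block_schedule(n_cycles = 1))
  r_small <- nordic_denoise(sim$series, scheme = patch_scheme(side = 8),
                            sigma = 1, n_mc = 10)$rank_map$ranks
  r_big <- nordic_denoise(sim$series, scheme = patch_scheme(side = 8),
                          sigma = 4, n_mc = 10)$rank_map$ranks
  expect_true(all(r_big <= r_small))
})

test_that("invalid denoiser inputs are rejected", {
  ser <- complex_series(array(1 + 0i, c(8, 8, 8, 30)))
  ser$data[1] <- NA
  expect_error(nordic_denoise(ser, scheme = patch_scheme(side = 8)),
               "non-finite")
  ok <- complex_series(array(1 + 0i, c(8, 8, 8, 600)))
  expect_error(nordic_denoise(ok, scheme = patch_scheme(side = 8)),
               "ratio")
})

test_that("MPPCA recovers noise sd and planted ranks", {
  set.seed(11)
  sig <- ranks <- numeric(60)
  for (i in 1:60) {
    est <- llrfmri:::mp_sigma_estimate(matrix(rnorm(125 * 100), 125, 100))
    sig[i] <- est$sigma; ranks[i] <- est$rank
  }
  expect_equal(mean(sig), 1, tolerance = 0.08)
  expect_true(all(ranks <= 1))

  edge <- sqrt(125) + sqrt(100)
  exact <- vapply(1:20, function(i) {
    u <- rnorm(125); v <- rnorm(100)
    X <- matrix(rnorm(125 * 100), 125, 100) +
      10 * edge * outer(u / sqrt(sum(u^2)), v / sqrt(sum(v^2)))
    llrfmri:::mp_sigma_estimate(X)$rank == 1
  }, logical(1))
  expect_true(all(exact))
})

test_that("MPPCA denoising passes noiseless data through", {
  set.seed(2)
  d <- c(10, 10, 8); Tn <- 40
  U <- matrix(abs(rnorm(prod(d) * 3)), prod(d), 3)
  W <- matrix(abs(rnorm(3 * Tn)), 3, Tn)
  arr <- array(U %*% W + 50, c(d, Tn))  # exact rank 4, non-negative
  res <- mppca_denoise(complex_series(arr), patch_scheme(side = 5))
  expect_lt(max(abs(Re(res$denoised$data) - arr)) / max(arr), 1e-6)
})

test_that("MPPCA on a pure-noise phantom estimates sigma", {
  spec <- noise_spec(sigma = 1, grid_dims = c(14, 14, 10), n_volumes = 60,
                     n_runs = 1)
  sim <- simulate_run(spec)
  res <- mppca_denoise(magnitude_series(sim$series))
  # magnitude of complex noise has Rayleigh sd ~ 0.655 sigma
  expect_equal(res$sigma_hat, sqrt(2 - pi / 2), tolerance = 0.08)
  expect_lte(stats::median(res$rank_map$ranks), 1)
})

test_that("spatial smoothing has unit DC gain and exact identity at 0", {
  arr <- array(rnorm(16 * 16 * 8 * 5), c(16, 16, 8, 5))
  expect_identical(gaussian_smooth(arr, 0), arr)
  cst <- array(3, c(12, 12, 8, 2))
  expect_equal(gaussian_smooth(cst, 1.5), cst, tolerance = 1e-10)
})

test_that("temporal smoothing window matches the 9-10.5 s rule", {
  # TR = 1.35 s: only w = 7 gives w * TR in [9, 10.5]
  Tn <- 140
  x <- sin(2 * pi * (0:(Tn - 1)) / 7)  # period = w * TR
  arr <- aperm(array(x, c(Tn, 6, 6, 4)), c(2, 3, 4, 1))
  sm <- temporal_smooth(complex_series(arr + 0i, tr_s = 1.35))
  mid <- Re(sm$data[3, 3, 2, 10:130])
  expect_lt(max(abs(mid)), 0.05)
  cst <- complex_series(array(2 + 0i, c(6, 6, 4, 30)), tr_s = 1.35)
  expect_equal(temporal_smooth(cst)$data, cst$data, tolerance = 1e-12)
  expect_error(temporal_smooth(cst, tr_s = 6), "window")
})

test_that("removed-noise maps follow the folded-Gaussian oracle", {
  spec <- noise_spec(sigma = 1, g_max = 2, grid_dims = c(16, 16, 8),
                     n_volumes = 120, n_runs = 1)
  sim <- simulate_run(spec)
  zero <- series_like(sim$series, sim$series$data * 0)
  m <- removed_noise_map(sim$series, zero)
  g <- sim$truth$g_map
  # mean |complex noise| = sigma g sqrt(pi/2)
  expect_equal(mean(m / (sqrt(pi / 2) * g)), 1, tolerance = 0.02)
  expect_gt(cor(as.vector(m), as.vector(g)), 0.95)
  expect_equal(removed_noise_map(sim$series, sim$series),
               array(0, c(16, 16, 8)))
  # invariance to a common additive image
  shift <- series_like(sim$series,
                       sim$series$data + 5)
  zshift <- series_like(zero, zero$data + 5)
  expect_equal(removed_noise_map(shift, zshift), m, tolerance = 1e-12)
  expect_error(removed_noise_map(sim$series,
                                 complex_series(array(0i, c(8, 8, 8, 2)))),
               "shape")
})
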