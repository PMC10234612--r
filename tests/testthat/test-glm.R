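test_that("mean-100 scaling contract holds", {
  arr <- array(250, c(8, 8, 4, 20))
  sc <- scale_to_mean100(arr)
  expect_equal(sc, array(100, c(8, 8, 4, 20)))
  set.seed(1)
  arr2 <- array(runif(8 * 8 * 4 * 20, 50, 150), c(8, 8, 4, 20))
  sc2 <- scale_to_mean100(arr2)
  mu <- apply(sc2, 1:3, mean)
  expect_equal(as.vector(mu), rep(100, 256), tolerance = 1e-9)
  # in-mask voxel with non-positive mean excluded with warning
  arr2[1, 1, 1, ] <- 0
  expect_warning(scale_to_mean100(arr2, mask = array(TRUE, c(8, 8, 4))),
                 "non-positive")
})

test_that("a 2% baseline modulation fits as beta = 2 in scaled units", {
  spec <- clean_spec(grid_dims = c(16, 16, 8), n_volumes = 89, n_runs = 1,
                     task_amplitudes = list(target = c(target = 2,
                                                       nontarget = 0)))
  sched <- make_block_schedule(n_cycles = 4)
  sim <- simulate_run(spec, sched)
  sc <- scale_to_mean100(sim$series, sim$truth$brain_mask)
  des <- build_design(sched, 89, spec$tr_s, "canonical", drift_order = 1)
  fit <- glsq_fit(sc, des, "ols")
  b <- fit$beta[1, as.vector(sim$truth$roi_target)]
  expect_equal(mean(b), 2, tolerance = 0.01)
})

test_that("canonical HRF has the expected double-gamma shape", {
  t <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(t)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-6)
  expect_gte(t[which.max(h)], 4.5); expect_lte(t[which.max(h)], 6.5)
  expect_gte(t[which.min(h)], 14); expect_lte(t[which.min(h)], 18)
  expect_error(canonical_hrf(t, list(peak_disp = -1)), "dispersion")
})

test_that("design construction covers canonical, tent and drift cases", {
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      condition = character(0))
  d0 <- build_design(empty, 40, 1, drift_order = 1)
  expect_equal(ncol(d0$matrix), 2)
  expect_equal(d0$labels, c("drift0", "drift1"))

  ev <- data.frame(onset = 10, duration = 1, condition = "a")
  dt <- build_design(ev, 40, 1, basis = "tent", drift_order = 0,
                     tent_window_s = 5)
  tm <- dt$matrix[, dt$task_cols]
  # shifted identity block: lag l fires l volumes after onset (t = 10 s
  # is volume 11 at TR 1)
  expect_equal(which(tm[, 1] == 1), 11)
  expect_equal(which(tm[, 6] == 1), 16)

  # 12 s on/off block at TR 1.35: dominant frequency 1/24 Hz
  sched <- make_block_schedule(n_cycles = 4)
  dc <- build_design(sched, 89, 1.35, drift_order = 0)
  x <- dc$matrix[, 1] - mean(dc$matrix[, 1])
  amp <- Mod(fft(x))[2:45]
  fgrid <- (1:44) / (89 * 1.35)
  expect_equal(fgrid[which.max(amp)], 1 / 24, tolerance = 0.15)

  # colliding columns are named in the error
  dup <- data.frame(onset = c(10, 10), duration = c(1, 1),
                    condition = c("a", "b"))
  expect_error(build_design(dup, 40, 1, basis = "tent", drift_order = 0,
                            tent_window_s = 5), "rank deficient")
})

test_that("noiseless fits are exact under every noise model", {
  set.seed(3)
  sched <- make_block_schedule(n_cycles = 3)
  des <- build_design(sched, 89, 1.35, drift_order = 1)
  beta_true <- c(2, 50, 1)
  y <- des$matrix %*% beta_true
  Y <- matrix(y, length(y), 12)
  for (nm in c("ols", "ar1", "arma11")) {
    fit <- glsq_fit(Y, des, nm)
    expect_equal(as.vector(fit$beta[, 1]), beta_true, tolerance = 1e-8,
                 label = nm)
  }
  expect_error(glsq_fit(Y * NA, des), "non-finite")
  expect_error(glsq_fit(Y[1:3, ], des$matrix[1:3, ]), "p >= T")
})

test_that("null contrast t-values follow the Student-t law", {
  set.seed(9)
  sched <- make_block_schedule(n_cycles = 3)
  des <- build_design(sched, 89, 1.35, drift_order = 1)
  Y <- matrix(rnorm(89 * 10000), 89, 10000)
  fit <- glsq_fit(Y, des, "ols")
  ks <- stats::ks.test(fit$tstat[1, ], stats::pt, df = fit$dof)
  expect_gt(ks$p.value, 0.01)
  expect_identical(fit$dof, 89L - 3L)
})

test_that("FIR deconvolution is exact for a full-rank tent design", {
  set.seed(4)
  ev <- data.frame(onset = c(13.5, 54, 94.5), duration = 1.35,
                   condition = "target")
  des <- build_design(ev, 100, 1.35, basis = "tent", drift_order = 1,
                      tent_window_s = 20)
  curve_true <- canonical_hrf(des$tent_lags) * 3
  y <- des$matrix %*% c(curve_true, 80, 2)
  Ym <- matrix(rep(y, 5), length(y), 5)
  attr(Ym, "tr_s") <- 1.35
  ff <- fir_fit(Ym, ev, tent_window_s = 20, drift_order = 1)
  expect_equal(as.vector(ff$curves$target[, 1]), as.vector(curve_true),
               tolerance = 1e-8)
  expect_equal(ff$lags_s, (0:floor(20 / 1.35)) * 1.35)
})

test_that("FIR estimates from noisy phantoms are unbiased", {
  spec0 <- clean_spec(grid_dims = c(12, 12, 8), n_volumes = 100, n_runs = 1,
                      tr_s = 1.35,
                      task_amplitudes = list(target = c(target = 3,
                                                        nontarget = 0)))
  ev <- data.frame(onset = c(13.5, 54, 94.5), duration = 1.35,
                   condition = "target")
  attr(ev, "total_s") <- 135
  sim0 <- simulate_run(spec0, ev)
  v <- which(as.vector(sim0$truth$roi_target))[3]
  sc0 <- scale_to_mean100(sim0$series, sim0$truth$brain_mask)
  truth_curve <- fir_fit(sc0, ev, tent_window_s = 20)$curves$target[, v]

  set.seed(77)
  Tn <- 100
  y0 <- series_matrix(sc0, "real")[v, ]
  curves <- replicate(200, {
    y <- y0 + rnorm(Tn, 0, 3)
    Ym <- matrix(y, Tn, 1)
    attr(Ym, "tr_s") <- 1.35
    fir_fit(Ym, ev, tent_window_s = 20)$curves$target[, 1]
  })
  mc_se <- 3 / sqrt(200)  # per-lag standard error bound (design-dependent)
  expect_lt(max(abs(rowMeans(curves) - truth_curve)), 4 * mc_se)
})
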