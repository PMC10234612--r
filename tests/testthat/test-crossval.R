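test_that("R^2 satisfies its boundary cases and null behavior", {
  y <- c(1, 3, 2, 5, 4)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 5)), 0)
  expect_warning(r2(rep(2, 5), y), "zero-variance")
  set.seed(1)
  Tn <- 20
  null_r2 <- replicate(5000, r2(rnorm(Tn), rnorm(Tn)))
  expect_lt(mean(null_r2), 0)
  expect_equal(mean(null_r2), -Tn / (Tn - 1) * (1 + 1 / (Tn - 1)),
               tolerance = 0.15)
})

test_that("noiseless leave-one-out map is 1 in task voxels, ~0 elsewhere", {
  spec <- clean_spec(grid_dims = c(14, 14, 8), n_volumes = 89, n_runs = 3,
                     task_amplitudes = list(target = c(target = 3,
                                                       nontarget = 0)))
  session <- simulate_session(spec, make_block_schedule(n_cycles = 4))
  runs <- scaled_magnitude_runs(session)
  loo <- loo_canonical_r2_map(runs, session$schedules)
  roi <- session$truth$roi_target
  expect_equal(min(loo[roi]), 1, tolerance = 1e-6)
  wm <- session$truth$tissue_labels == 3L
  expect_true(all(is.na(loo[wm]) | abs(loo[wm]) < 1e-6))
})

test_that("null-task leave-one-out R^2 stays near zero", {
  spec <- phantom_spec(grid_dims = c(14, 14, 8), n_volumes = 120,
                       n_runs = 6,
                       sigma_thermal = 3, spont = NULL, physio = list(),
                       task_amplitudes = list(target = c(target = 0,
                                                         nontarget = 0)))
  session <- simulate_session(spec, make_block_schedule(n_cycles = 4))
  runs <- scaled_magnitude_runs(session)
  loo <- loo_canonical_r2_map(runs, session$schedules)
  gm <- session$truth$tissue_labels == 2L
  expect_lt(max(loo[gm], na.rm = TRUE), 0.02)
})

test_that("exhaustive leave-p-out bookkeeping and noiseless limit hold", {
  spec <- clean_spec(grid_dims = c(14, 14, 8), n_volumes = 100, n_runs = 4,
                     task_amplitudes = list(target = c(target = 3,
                                                       nontarget = 0)))
  ev <- data.frame(onset = c(13.5, 54, 94.5), duration = 1.35,
                   condition = "target")
  attr(ev, "total_s") <- 135
  session <- simulate_session(spec, ev)
  runs <- scaled_magnitude_runs(session)
  mask_map <- array(1 * session$truth$roi_target, spec$grid_dims)
  tab <- lpo_fir_crossval(runs, runs, session$schedules,
                          thresholds = 0.5, mask_map = mask_map,
                          tent_window_s = 32.4)
  expect_equal(tab$n_perm, choose(4, tab$n_train))
  expect_equal(tab$mean_r2, rep(1, 3), tolerance = 1e-4)
  expect_error(lpo_fir_crossval(runs, runs, session$schedules,
                                p_values = 4), "1..N-1")
})

test_that("R^2 increases with phantom contrast-to-noise", {
  r2_at <- function(amp) {
    spec <- phantom_spec(grid_dims = c(14, 14, 8), n_volumes = 89,
                         n_runs = 2, sigma_thermal = 3, spont = NULL,
                         physio = list(), master_seed = 13,
                         tissue_geometry = list(csf_outer = 1,
                                                gm_outer = 0.9,
                                                wm_outer = 0.55,
                                                vein_fraction = 0),
                         task_amplitudes = list(
                           target = c(target = amp, nontarget = 0)))
    session <- simulate_session(spec, make_block_schedule(n_cycles = 4))
    runs <- scaled_magnitude_runs(session)
    loo <- loo_canonical_r2_map(runs, session$schedules)
    mean(loo[session$truth$roi_target])
  }
  vals <- vapply(c(1, 3, 6), r2_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("equivalent-runs readout picks the first matching row", {
  st <- data.frame(train_source = "standard", test_source = "standard",
                   p_out = 5:1, n_train = 1:5, threshold = 0.15,
                   mean_r2 = c(0.05, 0.12, 0.15, 0.17, 0.18),
                   se_r2 = 0, n_perm = 6)
  dn <- data.frame(train_source = "nordic", test_source = "standard",
                   p_out = 5, n_train = 1, threshold = 0.15,
                   mean_r2 = 0.14, se_r2 = 0, n_perm = 6)
  expect_identical(equivalent_runs(st, dn), 3L)
  dn$mean_r2 <- 0.5
  expect_identical(equivalent_runs(st, dn), Inf)
})
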