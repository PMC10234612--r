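test_that("g-factor map honors its range contract", {
  spec <- noise_spec()
  expect_equal(make_gfactor(spec), array(1, spec$grid_dims))

  spec2 <- noise_spec(g_max = 2)
  g <- make_gfactor(spec2)
  expect_equal(min(g), 1, tolerance = 0.01)
  expect_equal(max(g), 2, tolerance = 0.01)
  expect_identical(g, make_gfactor(spec2))  # deterministic

  spec_bad <- noise_spec()
  spec_bad$g_params$g_min <- 0.5
  expect_error(make_gfactor(spec_bad), "g_min")
})

test_that("block schedule arithmetic matches the 12 s on/off paradigm", {
  s <- make_block_schedule(on_s = 12, off_s = 12, n_cycles = 3, lead_s = 12)
  expect_equal(s$onset, c(12, 36, 60))
  expect_equal(s$duration, rep(12, 3))
  expect_equal(attr(s, "total_s"), 84)

  expect_equal(nrow(make_block_schedule(n_cycles = 0)), 0)

  # six 12/12 cycles + lead spans a 159.3 s run within one cycle
  s6 <- make_block_schedule(n_cycles = 6)
  expect_lt(abs(attr(s6, "total_s") - 159.3), 24)
})

test_that("event schedules are reproducible with correct packing", {
  s <- make_event_schedule(3, stim_s = 2, isi_s = 2, blank_fraction = 0,
                           seed = 5, lead_s = 0)
  expect_equal(diff(s$onset), c(4, 4))

  s1 <- make_event_schedule(10, seed = 99)
  s2 <- make_event_schedule(10, seed = 99)
  expect_identical(s1, s2)

  expect_error(make_event_schedule(40, seed = 1, run_dur_s = 30),
               "does not fit|only")

  # 10% blanks on average over many seeds
  blanks <- vapply(1:1000, function(i) {
    s <- make_event_schedule(40, blank_fraction = 0.1, seed = i)
    (attr(s, "total_s") - 12) / 4 - 40
  }, numeric(1))
  expect_equal(mean(blanks), 4, tolerance = 0.15)
})

test_that("noiseless simulation equals the clean signal", {
  spec <- clean_spec(grid_dims = c(16, 16, 8), n_volumes = 60, n_runs = 1)
  sim <- simulate_run(spec)
  expect_equal(Mod(sim$series$data), sim$truth$clean_magnitude,
               tolerance = 1e-12)
  # phase equals the generated smooth phase wherever magnitude > 0
  nz <- sim$truth$clean_magnitude > 0
  expect_lt(max(abs(Arg(sim$series$data)[nz])), pi)
})

test_that("thermal noise has the prescribed channel statistics", {
  spec <- noise_spec(sigma = 1, n_volumes = 200, grid_dims = c(16, 16, 8),
                     n_runs = 1)
  sim <- simulate_run(spec)
  re_sd <- apply(Re(sim$series$data), 1:3, sd)
  expect_equal(mean(re_sd), 1, tolerance = 0.03)

  # magnitude of zero-signal voxels is Rayleigh with scale sigma:
  # mean = sigma * sqrt(pi/2)
  mag <- Mod(sim$series$data)
  expect_equal(mean(mag), sqrt(pi / 2), tolerance = 0.03)

  # temporal-std map (both channels pooled) reproduces g(x)
  spec_g <- noise_spec(sigma = 1, g_max = 2, n_volumes = 300,
                       grid_dims = c(16, 16, 8), n_runs = 1)
  sim_g <- simulate_run(spec_g)
  sd_map <- sqrt((apply(Re(sim_g$series$data), 1:3, var) +
                    apply(Im(sim_g$series$data), 1:3, var)) / 2)
  expect_gt(cor(as.vector(sd_map), as.vector(sim_g$truth$g_map)), 0.98)
})

test_that("identical spec and seed reproduce the run bit for bit", {
  spec <- phantom_spec(grid_dims = c(12, 12, 8), n_volumes = 40, n_runs = 2)
  a <- simulate_run(spec, run_index = 2)
  b <- simulate_run(spec, run_index = 2)
  expect_identical(a$series$data, b$series$data)
  c <- simulate_run(spec, run_index = 1)
  expect_false(identical(a$series$data, c$series$data))
})

test_that("regressing the noiseless run on its own design recovers betas", {
  spec <- clean_spec(grid_dims = c(16, 16, 8), n_volumes = 89, n_runs = 1,
                     drift_amp_pct = 0.3,
                     task_amplitudes = list(target = c(target = 2,
                                                       nontarget = 0)))
  sched <- make_block_schedule(n_cycles = 4)
  sim <- simulate_run(spec, sched)
  # raw (unscaled) magnitude: fitted beta = baseline * amp / 100 exactly
  des <- build_design(sched, 89, spec$tr_s, "canonical", drift_order = 2)
  fit <- glsq_fit(magnitude_series(sim$series), des, "ols")
  b <- fit$beta[1, as.vector(sim$truth$roi_target)]
  expect_equal(max(abs(b - 2)), 0, tolerance = 1e-8)
  out <- fit$beta[1, as.vector(sim$truth$tissue_labels == 3L)]
  expect_equal(max(abs(out)), 0, tolerance = 1e-8)
})

test_that("ROI ground truth is consistent", {
  spec <- phantom_spec(grid_dims = c(16, 16, 8), n_volumes = 40)
  an <- llrfmri:::phantom_anatomy(spec)
  expect_false(any(an$roi_target & an$roi_nontarget))
  expect_true(all(an$labels[an$roi_target] == 2L))
  expect_true(all(an$labels[an$roi_nontarget] == 2L))
  tb <- llrfmri:::phantom_true_beta(spec, an)
  expect_true(all(tb$target[!(an$roi_target | an$roi_nontarget)] == 0))
})

test_that("negative clean magnitudes are clipped with a warning", {
  spec <- clean_spec(grid_dims = c(12, 12, 8), n_volumes = 40, n_runs = 1,
                     task_amplitudes = list(target = c(target = -150,
                                                       nontarget = 0)))
  expect_warning(simulate_run(spec, make_block_schedule(n_cycles = 1)),
                 "clipping")
})
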