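test_that("global FWHM estimator is calibrated to applied kernels", {
  set.seed(3)
  arr <- array(rnorm(40 * 40 * 20 * 8), c(40, 40, 20, 8))
  for (f in c(1.5, 3)) {
    est <- global_fwhm(gaussian_smooth(arr, f), detrend = FALSE)
    expect_equal(mean(est$fwhm_vox), f, tolerance = 0.05 * f)
  }
  # composition of kernels adds in quadrature
  est2 <- global_fwhm(gaussian_smooth(gaussian_smooth(arr, 1.5), 2),
                      detrend = FALSE)
  expect_equal(mean(est2$fwhm_vox), sqrt(1.5^2 + 2^2), tolerance = 0.05 * 2.5)
  # unsmoothed white noise is sub-voxel or undefined
  est0 <- suppressWarnings(global_fwhm(arr, detrend = FALSE))
  expect_true(all(is.na(est0$fwhm_vox) | est0$fwhm_vox < 0.5))
  expect_error(global_fwhm(arr, mask = array(FALSE, c(40, 40, 20))),
               "100 voxels")
})

test_that("ACF model fits recover pure Gaussian and pure exponential", {
  r <- seq(0.5, 8, by = 0.5)
  m1 <- fit_acf_model(r, exp(-r^2 / (2 * 4)))
  expect_equal(m1$a, 1, tolerance = 0.02)
  expect_equal(m1$fwhm, 2 * sqrt(8 * log(2)), tolerance = 0.02 * 5)
  m2 <- fit_acf_model(r, exp(-r / 3))
  expect_equal(m2$a, 0, tolerance = 0.02)
  expect_equal(m2$c, 3, tolerance = 0.02 * 3)
  # degenerate: unit correlation at r = 0, zero beyond -> minimum FWHM
  m3 <- fit_acf_model(c(0, 1, 2, 3, 4), c(1, 0, 0, 0, 0))
  expect_lt(m3$fwhm, 0.5)
  expect_error(fit_acf_model(1:3, c(1, 0.5, 0.2)), "4 distance bins")
})

test_that("local ACF maps distinguish smooth from independent fields", {
  set.seed(8)
  d <- c(14, 14, 10); Tn <- 40
  mask <- array(TRUE, d)
  rough <- array(rnorm(prod(d) * Tn), c(d, Tn))
  lr <- local_acf_fwhm(rough, mask, radius_voxels = 4)
  expect_lt(median(lr$fwhm_map, na.rm = TRUE), 0.5)

  smooth <- gaussian_smooth(rough, 2)
  ls <- local_acf_fwhm(smooth, mask, radius_voxels = 4)
  med <- median(ls$fwhm_map, na.rm = TRUE)
  expect_equal(med, 2, tolerance = 0.3)
  iqr <- diff(quantile(ls$fwhm_map, c(0.25, 0.75), na.rm = TRUE))
  expect_lt(iqr / med, 0.25)

  # two-compartment contrast: smoothed half vs independent half
  two <- rough
  two[1:7, , , ] <- array(gaussian_smooth(
    array(rnorm(prod(d) * Tn), c(d, Tn)), 2)[1:7, , , ], c(7, d[2:3], Tn))
  lt <- local_acf_fwhm(two, mask, radius_voxels = 4)
  m_smooth <- median(lt$fwhm_map[2:6, , ], na.rm = TRUE)
  m_rough <- median(lt$fwhm_map[9:13, , ], na.rm = TRUE)
  expect_gt(m_smooth, m_rough)
  iqr_in <- diff(quantile(lt$fwhm_map[2:6, , ], c(0.25, 0.75),
                          na.rm = TRUE))
  expect_gt((m_smooth - m_rough) / max(iqr_in, 1e-6), 4)
})

test_that("cluster labeling respects connectivity", {
  m <- array(FALSE, c(6, 6, 4))
  m[1:2, 1, 1] <- TRUE          # 2-voxel cluster
  m[4, 4, 2] <- TRUE; m[5, 5, 3] <- TRUE  # corner contact: 26-conn only
  l26 <- label_clusters(m, 26)
  expect_equal(sort(l26$sizes), c(2, 2))
  l6 <- label_clusters(m, 6)
  expect_equal(sort(l6$sizes), c(1, 1, 2))
})

test_that("Monte-Carlo cluster thresholds behave like a null", {
  ct <- cluster_size_threshold(0, grid = c(32, 32, 32), n_sim = 200,
                               seed = 4)
  expect_lte(ct$k_min, 3)
  ct2 <- cluster_size_threshold(2, grid = c(32, 32, 32), n_sim = 150,
                                seed = 4)
  ct4 <- cluster_size_threshold(4, grid = c(32, 32, 32), n_sim = 150,
                                seed = 4)
  expect_lte(ct$k_min, ct2$k_min)
  expect_lte(ct2$k_min, ct4$k_min)
  cta <- cluster_size_threshold(0, grid = c(24, 24, 24), n_sim = 100,
                                cluster_alpha = 1, seed = 2)
  expect_identical(cta$k_min, 1L)
})

test_that("ROI definition keeps only large supra-threshold clusters", {
  t_map <- array(0, c(16, 16, 6))
  t_map[2:4, 2:4, 2:3] <- 10   # 18 voxels > min_cluster
  t_map[10, 10, 2:6] <- 10     # 5 voxels < min_cluster
  roi <- define_rois(t_map, dof = 100, min_cluster = 10)
  expect_equal(sum(roi), 18)
  expect_true(all(roi[2:4, 2:4, 2:3]))
  expect_equal(sum(define_rois(array(0, c(16, 16, 6)), dof = 100)), 0)
})

test_that("ROI recovery from a phantom t-map is accurate at mean t ~ 6", {
  spec <- phantom_spec(master_seed = 7,
                       task_amplitudes = list(target = c(target = 3,
                                                         nontarget = 0)),
                       n_runs = 4)
  session <- simulate_session(spec)
  std <- scaled_magnitude_runs(session)
  Tn <- spec$n_volumes
  ord <- llrfmri:::drift_order_rule(Tn, spec$tr_s)
  des <- llrfmri:::concat_design(session$schedules, 1:4, Tn, spec$tr_s,
                                 "canonical", ord)
  Y <- do.call(rbind, lapply(std, function(r) t(series_matrix(r, "real"))))
  fit <- glsq_fit(Y, des$X, "ar1")
  roi <- define_rois(array(fit$tstat[1, ], spec$grid_dims), fit$dof)
  truth <- session$truth$roi_target
  dice <- 2 * sum(roi & truth) / (sum(roi) + sum(truth))
  expect_gt(dice, 0.7)
})
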