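#' Write a complex series as a magnitude/phase NIfTI pair
#'
#' Files `<prefix>_mag.nii.gz` and `<prefix>_ph.nii.gz`, the common scanner
#' export convention; voxel size and TR are stored in the NIfTI pixdim.
#'
#' @param series a [complex_series()].
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_series <- function(series, prefix) {
  s <- as_series(series)
  paths <- paste0(prefix, c("_mag.nii.gz", "_ph.nii.gz"))
  for (i in 1:2) {
    arr <- if (i == 1) Mod(s$data) else Arg(s$data)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(s$voxel_size_mm, s$tr_s)
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read a complex series from a magnitude/phase NIfTI pair
#'
#' @param prefix path prefix as used by [write_series()]; a missing phase
#'   file yields a zero-phase (magnitude-only) series.
#' @return a [complex_series()].
#' @export
read_series <- function(prefix) {
  magf <- paste0(prefix, "_mag.nii.gz")
  phf <- paste0(prefix, "_ph.nii.gz")
  if (!file.exists(magf)) stop("missing magnitude file: ", magf)
  mag <- RNifti::readNifti(magf)
  pd <- RNifti::pixdim(mag)
  vs <- pd[1:3]
  tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  strip <- function(img) array(as.numeric(img), dim(img))
  ph <- if (file.exists(phf)) strip(RNifti::readNifti(phf)) else 0
  series_from_polar(strip(mag), ph, vs, tr)
}

#' Write a 3D map as NIfTI
#' @param map 3D array.
#' @param path output file.
#' @param voxel_size_mm voxel size stored in the header.
#' @export
write_volume <- function(map, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(map * 1)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI map
#' @param path file path.
#' @return numeric array.
#' @export
read_volume <- function(path) as.array(RNifti::readNifti(path))

#' Write a stimulus schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`.
#'
#' @param schedule schedule data.frame (`onset`, `duration`, `condition`).
#' @param path output file.
#' @export
write_events <- function(schedule, path) {
  df <- data.frame(onset = schedule$onset, duration = schedule$duration,
                   trial_type = schedule$condition)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path events file with columns `onset`, `duration`, `trial_type`.
#' @return schedule data.frame (`onset`, `duration`, `condition`).
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("onset", "duration", "trial_type"))
    if (!col %in% names(df))
      stop(sprintf("events file %s is missing required column \"%s\"",
                   path, col))
  data.frame(onset = as.numeric(df$onset),
             duration = as.numeric(df$duration),
             condition = as.character(df$trial_type),
             stringsAsFactors = FALSE)
}

#' Write a phantom session to disk
#'
#' Per run: magnitude/phase NIfTI pair and events TSV; plus the g-factor
#' map, tissue label map, ROI masks and a JSON ground-truth sidecar.
#'
#' @param session a [simulate_session()] result.
#' @param dir output directory (created).
#' @return invisibly, the directory.
#' @export
write_phantom_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- session$spec$voxel_size_mm
  for (r in seq_along(session$runs)) {
    write_series(session$runs[[r]], file.path(dir, sprintf("run-%02d", r)))
    write_events(session$schedules[[r]],
                 file.path(dir, sprintf("run-%02d_events.tsv", r)))
  }
  tr <- session$truth
  write_volume(tr$g_map, file.path(dir, "gfactor.nii.gz"), vs)
  write_volume(tr$tissue_labels, file.path(dir, "tissue_labels.nii.gz"), vs)
  write_volume(tr$roi_target, file.path(dir, "roi_target.nii.gz"), vs)
  write_volume(tr$roi_nontarget, file.path(dir, "roi_nontarget.nii.gz"), vs)
  sidecar <- list(sigma = tr$sigma,
                  master_seed = session$spec$master_seed,
                  tr_s = session$spec$tr_s,
                  voxel_size_mm = vs,
                  n_runs = length(session$runs),
                  true_hrf = tr$true_hrf,
                  task_amplitudes = session$spec$task_amplitudes)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Benchmark configuration
#'
#' @param spec a [phantom_spec()].
#' @param variants processing variants to compare; `"none"` (the standard
#'   reference) is always included.
#' @param noise_model GLM noise model for t-statistics.
#' @param evaluations character subset of `c("tstats", "smoothness",
#'   "spectra", "crossval", "lpr")`.
#' @param crossval_threshold selection-map threshold for cross-validation.
#' @param out_dir optional output directory for tables/JSON.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(spec = phantom_spec(),
                             variants = c("none", "nordic", "smooth1",
                                          "smooth1.5"),
                             noise_model = "ar1",
                             evaluations = c("tstats", "smoothness"),
                             crossval_threshold = 0.15,
                             out_dir = NULL) {
  variants <- union("none", variants)
  structure(list(spec = spec, variants = variants,
                 noise_model = noise_model, evaluations = evaluations,
                 crossval_threshold = crossval_threshold,
                 out_dir = out_dir),
            class = "benchmark_config")
}

# Apply one processing variant to the complex runs; returns magnitude runs
# (complex_series with zero phase) ready for scaling.
apply_variant <- function(variant, runs, g_map) {
  lapply(runs, function(run) {
    switch(variant,
      none = series_like(run, Mod(run$data)),
      nordic = {
        den <- nordic_denoise(run, g = g_map)$denoised
        series_like(run, Mod(den$data))
      },
      mppca = mppca_denoise(run)$denoised,
      smooth1 = gaussian_smooth(series_like(run, Mod(run$data) + 0i), 1),
      `smooth1.5` = gaussian_smooth(series_like(run, Mod(run$data) + 0i),
                                    1.5),
      tsmooth = temporal_smooth(series_like(run, Mod(run$data) + 0i)),
      stop("unknown variant: ", variant))
  })
}

#' Run the phantom benchmark
#'
#' Generates a phantom session, applies each processing variant, and runs
#' the enabled evaluations: all-run GLM t-statistics summarized in
#' standard-defined and ground-truth ROIs, residual smoothness, tissue
#' spectra, leave-p-out FIR cross-validation (standard vs denoised), and
#' the LPR probe. Fully reproducible from the spec's master seed.
#'
#' @param config a [benchmark_config()].
#' @return list: `tstats`, `smoothness`, `spectra`, `crossval`, `lpr`
#'   (enabled ones), `rois`, `session` info. Tables are also written under
#'   `out_dir` when configured.
#' @export
run_benchmark <- function(config) {
  spec <- config$spec
  session <- simulate_session(spec)
  truth <- session$truth
  g_map <- truth$g_map
  Tn <- spec$n_volumes
  ord <- drift_order_rule(Tn, spec$tr_s)
  mask <- truth$brain_mask

  processed <- list()
  for (v in config$variants)
    processed[[v]] <- lapply(apply_variant(v, session$runs, g_map),
                             scale_to_mean100, mask = mask)

  conds <- names(spec$task_amplitudes)
  contrast_fit <- function(runs_scaled) {
    des <- concat_design(session$schedules, seq_along(runs_scaled), Tn,
                         spec$tr_s, "canonical", ord,
                         hrf_params = spec$hrf_params)
    p <- ncol(des$X)
    cvec <- numeric(p)
    cvec[1] <- 1
    if (length(conds) > 1) cvec[2] <- -1
    Y <- do.call(rbind, lapply(runs_scaled, function(r)
      t(series_matrix(r, "magnitude"))))
    glsq_fit(Y, des$X, config$noise_model,
             contrasts = list(task = cvec))
  }

  fits <- lapply(processed, contrast_fit)
  dof <- fits[[1]]$dof
  t_std <- array(fits[["none"]]$contrast_tstat[1, ], spec$grid_dims)
  roi <- define_rois(t_std, dof)
  if (!any(roi)) roi <- truth$roi_target  # degenerate low-CNR fallback

  out <- list(config = config,
              rois = list(target_standard = roi,
                          target_truth = truth$roi_target))

  if ("tstats" %in% config$evaluations) {
    out$tstats <- do.call(rbind, lapply(names(fits), function(v) {
      tv <- fits[[v]]$contrast_tstat[1, as.vector(roi)]
      data.frame(variant = v, roi = "target", mean_t = mean(tv),
                 sd_t = sd(tv), n_voxels = sum(roi),
                 stringsAsFactors = FALSE)
    }))
  }

  if ("smoothness" %in% config$evaluations) {
    out$smoothness <- do.call(rbind, lapply(names(fits), function(v) {
      res4 <- array(t(fits[[v]]$residuals[seq_len(Tn), , drop = FALSE]),
                    c(spec$grid_dims, Tn))
      est <- global_fwhm(complex_series(res4 + 0i, spec$voxel_size_mm,
                                        spec$tr_s),
                         mask = mask, detrend = FALSE, stage = "residual")
      data.frame(variant = v, mean_fwhm_mm = est$mean_fwhm_mm,
                 stringsAsFactors = FALSE)
    }))
    base <- out$smoothness$mean_fwhm_mm[out$smoothness$variant == "none"]
    out$smoothness$increase_pct <-
      100 * (out$smoothness$mean_fwhm_mm - base) / base
  }

  if ("spectra" %in% config$evaluations) {
    tis <- list(gm = truth$tissue_labels == 2L,
                wm = truth$tissue_labels == 3L,
                csf = truth$tissue_labels == 1L)
    out$spectra <- lapply(processed, power_spectrum, tissue_masks = tis)
  }

  if ("crossval" %in% config$evaluations) {
    loo <- loo_canonical_r2_map(processed[["none"]], session$schedules)
    cv <- list()
    cv$standard_standard <- lpo_fir_crossval(
      processed[["none"]], processed[["none"]], session$schedules,
      thresholds = config$crossval_threshold, mask_map = loo,
      train_label = "standard", test_label = "standard")
    if ("nordic" %in% config$variants) {
      cv$nordic_standard <- lpo_fir_crossval(
        processed[["nordic"]], processed[["none"]], session$schedules,
        thresholds = config$crossval_threshold, mask_map = loo,
        train_label = "nordic", test_label = "standard")
      cv$nordic_nordic <- lpo_fir_crossval(
        processed[["nordic"]], processed[["nordic"]], session$schedules,
        thresholds = config$crossval_threshold, mask_map = loo,
        train_label = "nordic", test_label = "nordic")
      cv$equivalent_runs <- equivalent_runs(cv$standard_standard,
                                            cv$nordic_standard,
                                            config$crossval_threshold)
    }
    out$crossval <- cv
    out$loo_map <- loo
  }

  if ("lpr" %in% config$evaluations) {
    sig <- spec$sigma_thermal
    den <- function(x) nordic_denoise(x, g = g_map, sigma = sig)$denoised
    out$lpr <- lpr_probe(den, session$runs[[1]],
                         amplitudes = c(0.1, 1, 10), n_locations = 9,
                         seed = spec$master_seed, sigma = sig, mask = mask)
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in intersect(c("tstats", "smoothness"), names(out)))
      utils::write.table(out[[nm]],
                         file.path(config$out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    summary_json <- list(
      master_seed = spec$master_seed,
      variants = config$variants,
      tstats = if (!is.null(out$tstats)) out$tstats,
      smoothness = if (!is.null(out$smoothness)) out$smoothness)
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
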