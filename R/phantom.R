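#' Specification of a synthetic complex-valued fMRI session
#'
#' Collects every parameter of the phantom generator: grid geometry, noise
#' level, g-factor field, nested tissue compartments with vein voxels, task
#' amplitudes in percent signal change, physiological oscillations, polynomial
#' drift, smooth image phase and the master seed. Defaults describe a
#' thermal-noise-dominated block-design session: gray-matter baseline 100
#' (arbitrary units) with per-channel thermal noise sd 4.6 (temporal SNR
#' ~22 before denoising), calibrated once so that the standard (undenoised)
#' all-run GLM yields a Target-ROI mean t-statistic near 6, the regime of
#' the reference high-resolution acquisitions.
#'
#' @param grid_dims integer length-3, voxels per axis (all >= 8).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param tr_s repetition time in seconds.
#' @param n_runs number of runs in the session.
#' @param n_volumes volumes per run (>= 30).
#' @param sigma_thermal per-channel (real/imaginary) thermal noise standard
#'   deviation, in the same arbitrary units as `baseline`.
#' @param noise_smooth_fwhm_vox intrinsic spatial correlation of the thermal
#'   noise, as the FWHM (voxels) of a variance-preserving Gaussian kernel
#'   applied to the noise channels; 0 (default) = strictly i.i.d. noise.
#'   Nonzero values emulate the slight super-nominal smoothness that image
#'   reconstruction (interpolation, partial Fourier zero-filling) imparts to
#'   real data, and give residual-smoothness comparisons a meaningful
#'   baseline.
#' @param g_params list: `g_min`, `g_max` (>= 1) and `fwhm_vox`, the spatial
#'   scale of the smooth g-factor field.
#' @param tissue_geometry list of fractional ellipsoid radii delimiting CSF,
#'   gray matter and white matter shells, plus `vein_fraction`, the fraction
#'   of gray-matter voxels carrying high-amplitude vein fluctuations.
#' @param baseline named numeric: magnitudes for background, csf, gm, wm.
#' @param task_amplitudes named list, one entry per condition, each a
#'   numeric vector `c(target = , nontarget = )` of percent signal change in
#'   the two functional ROIs.
#' @param physio list of physiological components, each
#'   `list(freq_hz, amp_pct, weights = c(csf, gm, wm))`.
#' @param spont list or `NULL`: spontaneous (resting-state-like) BOLD
#'   fluctuations, spatially smooth (`fwhm_vox`) and temporally low-passed
#'   (moving average over `tau_s` seconds), per-voxel sd `amp_pct` percent,
#'   restricted to gray matter by `weights`. Structured noise that no
#'   thermal-noise denoiser should remove; limits cross-run predictability.
#' @param drift_order polynomial (Legendre) drift order per run.
#' @param drift_amp_pct sd of each random drift coefficient, percent.
#' @param vein_amp_factor vein fluctuation sd as a multiple of the thermal
#'   noise sd expressed in percent of the gray-matter baseline.
#' @param hrf_params double-gamma parameters, see [canonical_hrf()].
#' @param phase_params list: `static_fwhm_vox` and `static_amp_rad` for the
#'   smooth static phase field, `drift_amp_rad` for the per-volume global
#'   phase drift.
#' @param master_seed integer master seed; all per-run and per-component
#'   seeds are derived from it by fixed offsets.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(32, 32, 12),
                         voxel_size_mm = c(1, 1, 1),
                         tr_s = 1.35,
                         n_runs = 6,
                         n_volumes = 118,
                         sigma_thermal = 4.6,
                         noise_smooth_fwhm_vox = 0,
                         g_params = list(g_min = 1, g_max = 1.6,
                                         fwhm_vox = 12),
                         tissue_geometry = list(csf_outer = 1, gm_outer = 0.9,
                                                wm_outer = 0.55,
                                                vein_fraction = 0.005),
                         baseline = c(background = 0, csf = 130, gm = 100,
                                      wm = 80),
                         task_amplitudes = list(
                           target = c(target = 3, nontarget = 0),
                           surround = c(target = 0, nontarget = 3)),
                         physio = list(
                           list(freq_hz = 0.3, amp_pct = 0.3,
                                weights = c(csf = 1, gm = 0.5, wm = 0.2)),
                           list(freq_hz = 1.0, amp_pct = 0.3,
                                weights = c(csf = 1, gm = 0.4, wm = 0.1))),
                         spont = list(amp_pct = 0.3, fwhm_vox = 4,
                                      tau_s = 8,
                                      weights = c(csf = 0.3, gm = 1,
                                                  wm = 0.3)),
                         drift_order = 2,
                         drift_amp_pct = 0.3,
                         vein_amp_factor = 4,
                         hrf_params = list(),
                         phase_params = list(static_fwhm_vox = 24,
                                             static_amp_rad = 0.5,
                                             drift_amp_rad = 0.05),
                         master_seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L)
  if (any(grid_dims < 8L)) stop("all grid dimensions must be >= 8")
  if (n_volumes < 30L) stop("n_volumes must be >= 30")
  if (sigma_thermal < 0) stop("sigma_thermal must be >= 0")
  if (g_params$g_min < 1) stop("g_min must be >= 1 (parallel imaging never
    attenuates noise)")
  if (g_params$g_max < g_params$g_min) stop("g_max must be >= g_min")
  amps <- unlist(task_amplitudes)
  if (length(amps) && any(!is.finite(amps)))
    stop("task amplitudes must be finite")
  spec <- list(grid_dims = grid_dims,
               voxel_size_mm = as.numeric(voxel_size_mm),
               tr_s = tr_s, n_runs = as.integer(n_runs),
               n_volumes = as.integer(n_volumes),
               sigma_thermal = sigma_thermal,
               noise_smooth_fwhm_vox = noise_smooth_fwhm_vox,
               g_params = g_params,
               tissue_geometry = tissue_geometry, baseline = baseline,
               task_amplitudes = task_amplitudes, physio = physio,
               spont = spont,
               drift_order = drift_order, drift_amp_pct = drift_amp_pct,
               vein_amp_factor = vein_amp_factor, hrf_params = hrf_params,
               phase_params = phase_params,
               master_seed = as.integer(master_seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Smooth g-factor map for a phantom
#'
#' Generates the spatially varying noise-amplification field of an
#' accelerated acquisition as a smooth Gaussian random field rescaled to
#' `[g_min, g_max]`. Deterministic given the spec's master seed.
#'
#' @param spec a [phantom_spec()].
#' @return 3D array of g values, all >= 1.
#' @export
make_gfactor <- function(spec) {
  gp <- spec$g_params
  if (gp$g_min < 1) stop("g_min must be >= 1")
  if (gp$g_max == gp$g_min)
    return(array(gp$g_min, spec$grid_dims))
  with_seed(substream_seed(spec$master_seed, "gfactor"), {
    f <- smooth_field3d(spec$grid_dims, gp$fwhm_vox)
    gp$g_min + (gp$g_max - gp$g_min) * (f - min(f)) / (max(f) - min(f))
  })
}

#' Block-design stimulus schedule
#'
#' Standard on/off block paradigm for a single condition: `lead_s` of rest,
#' then `n_cycles` repetitions of `on_s` of stimulation followed by `off_s`
#' of rest.
#'
#' @param on_s,off_s block durations in seconds (> 0).
#' @param n_cycles number of on/off cycles.
#' @param lead_s initial rest period in seconds.
#' @param condition condition label for the "on" events.
#' @return A data.frame with columns `onset`, `duration`, `condition` and
#'   attribute `total_s`, the schedule length `lead + n_cycles * (on + off)`.
#' @export
make_block_schedule <- function(on_s = 12, off_s = 12, n_cycles = 3,
                                lead_s = 12, condition = "target") {
  stopifnot(on_s > 0, off_s > 0, lead_s >= 0, n_cycles >= 0)
  onset <- if (n_cycles > 0) lead_s + (seq_len(n_cycles) - 1) * (on_s + off_s)
           else numeric(0)
  sched <- data.frame(onset = onset,
                      duration = rep(on_s, length(onset)),
                      condition = rep(condition, length(onset)),
                      stringsAsFactors = FALSE)
  attr(sched, "total_s") <- lead_s + n_cycles * (on_s + off_s)
  sched
}

#' Randomized event-related stimulus schedule
#'
#' Events of duration `stim_s` separated by at least `isi_s`, with a random
#' fraction of blank trials inserted among them (each blank adds one empty
#' slot of `stim_s + isi_s`, jittering the effective ISI). Condition labels
#' are assigned in a random balanced order.
#'
#' @param n_events number of (non-blank) stimulus events.
#' @param stim_s stimulus duration, seconds (> 0).
#' @param isi_s minimum interstimulus interval, seconds (> 0).
#' @param blank_fraction expected blanks per event in `[0, 1)`; the number of
#'   blanks is Binomial(`n_events`, `blank_fraction`).
#' @param seed RNG seed making the schedule reproducible.
#' @param conditions condition labels cycled over events.
#' @param lead_s initial rest period.
#' @param run_dur_s optional run length in seconds; an error is raised if the
#'   schedule does not fit.
#' @return A data.frame as in [make_block_schedule()].
#' @export
make_event_schedule <- function(n_events, stim_s = 2, isi_s = 2,
                                blank_fraction = 0.1, seed = 1,
                                conditions = "target", lead_s = 12,
                                run_dur_s = NULL) {
  stopifnot(stim_s > 0, isi_s > 0,
            blank_fraction >= 0, blank_fraction < 1, n_events >= 0)
  with_seed(seed, {
    n_blank <- if (blank_fraction > 0) rbinom(1, n_events, blank_fraction)
               else 0L
    slot <- stim_s + isi_s
    n_slots <- n_events + n_blank
    is_blank <- rep(FALSE, n_slots)
    if (n_blank > 0) is_blank[sample(n_slots, n_blank)] <- TRUE
    onsets <- lead_s + (seq_len(n_slots) - 1) * slot
    onsets <- onsets[!is_blank]
    labels <- rep(conditions, length.out = n_events)
    if (n_events > 1) labels <- sample(labels)
    total <- lead_s + n_slots * slot
    if (!is.null(run_dur_s) && total > run_dur_s)
      stop(sprintf("schedule needs %.1f s but the run is only %.1f s",
                   total, run_dur_s))
    sched <- data.frame(onset = onsets,
                        duration = rep(stim_s, n_events),
                        condition = labels, stringsAsFactors = FALSE)
    attr(sched, "total_s") <- total
    sched
  })
}

# Deterministic anatomy of the phantom: nested ellipsoidal shells (CSF ring,
# gray-matter shell, white-matter core) inside a background of zero signal,
# two disjoint wedge-shaped functional ROIs inside gray matter, and a sparse
# random set of gray-matter "vein" voxels. Codes: 0 background, 1 CSF,
# 2 GM, 3 WM; veins are flagged separately (they remain GM voxels).
phantom_anatomy <- function(spec) {
  d <- spec$grid_dims
  tg <- spec$tissue_geometry
  cx <- (d + 1) / 2
  ax <- d / 2 * 0.95
  x <- (seq_len(d[1]) - cx[1]) / ax[1]
  y <- (seq_len(d[2]) - cx[2]) / ax[2]
  z <- (seq_len(d[3]) - cx[3]) / ax[3]
  r <- sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
  labels <- array(0L, d)
  labels[r <= tg$csf_outer] <- 1L
  labels[r <= tg$gm_outer] <- 2L
  labels[r <= tg$wm_outer] <- 3L
  theta <- outer(outer(x, y, function(a, b) atan2(b, a)), rep(1, d[3]))
  gm <- labels == 2L
  roi_target <- gm & abs(theta) <= pi / 4
  roi_nontarget <- gm & abs(theta) >= 3 * pi / 4
  veins <- array(FALSE, d)
  gm_idx <- which(gm)
  n_vein <- round(tg$vein_fraction * length(gm_idx))
  if (n_vein > 0) {
    with_seed(substream_seed(spec$master_seed, "vein"), {
      veins[sample(gm_idx, n_vein)] <- TRUE
    })
  }
  list(labels = labels, roi_target = roi_target,
       roi_nontarget = roi_nontarget, veins = veins,
       brain_mask = labels > 0L)
}

# True percent-signal-change map per condition (3D per condition).
phantom_true_beta <- function(spec, anatomy) {
  lapply(spec$task_amplitudes, function(a) {
    b <- array(0, spec$grid_dims)
    b[anatomy$roi_target] <- a[["target"]]
    b[anatomy$roi_nontarget] <- a[["nontarget"]]
    b
  })
}

#' Simulate one run of the phantom
#'
#' Builds the clean complex signal `baseline * exp(i * phase) *
#' (1 + task% + physio% + drift% + vein%)` and adds independent Gaussian
#' thermal noise with per-channel sd `sigma_thermal * g(x)` to the real and
#' imaginary channels. Task responses are the stimulus schedule convolved
#' with the double-gamma HRF; vein voxels carry slow high-amplitude
#' fluctuations spread to their neighbours with a 1-voxel-FWHM kernel.
#'
#' @param spec a [phantom_spec()].
#' @param schedule stimulus schedule (see [make_block_schedule()]); events
#'   must end before the run does. Conditions must be named in
#'   `spec$task_amplitudes`.
#' @param run_index 1-based run number; determines the per-run noise,
#'   physiology and drift substreams.
#' @param g_map optional precomputed g-factor map (3D array); defaults to
#'   [make_gfactor()] of the spec.
#' @param anatomy optional precomputed [phantom_anatomy()] (internal reuse).
#' @return list with elements `series` (a [complex_series()]) and `truth`
#'   (tissue labels, ROI masks, true beta maps, true HRF, g map, sigma,
#'   per-run seed, clean magnitude).
#' @export
simulate_run <- function(spec, schedule = NULL, run_index = 1,
                         g_map = NULL, anatomy = NULL) {
  d <- spec$grid_dims
  Tn <- spec$n_volumes
  tr <- spec$tr_s
  if (is.null(schedule))
    schedule <- make_block_schedule(n_cycles = max(1, floor(
      (Tn * tr - 12) / 24)))
  if (nrow(schedule) > 0 &&
      max(schedule$onset + schedule$duration) > Tn * tr)
    stop("schedule does not fit within the run")
  if (is.null(g_map)) g_map <- make_gfactor(spec)
  if (is.null(anatomy)) anatomy <- phantom_anatomy(spec)
  nvox <- prod(d)
  labels <- anatomy$labels
  baseline <- c(spec$baseline[["background"]], spec$baseline[["csf"]],
                spec$baseline[["gm"]], spec$baseline[["wm"]])[labels + 1L]

  # task component, percent units
  true_beta <- phantom_true_beta(spec, anatomy)
  pct <- matrix(0, nvox, Tn)
  conds <- unique(schedule$condition)
  unknown <- setdiff(conds, names(spec$task_amplitudes))
  if (length(unknown))
    stop("schedule conditions missing from task_amplitudes: ",
         paste(unknown, collapse = ", "))
  regressors <- list()
  for (cn in conds) {
    x <- convolve_schedule(schedule[schedule$condition == cn, , drop = FALSE],
                           Tn, tr, spec$hrf_params)
    regressors[[cn]] <- x
    pct <- pct + outer(as.vector(true_beta[[cn]]), x)
  }

  # physiological oscillations, coherent across space with tissue weighting
  # and a smooth spatial amplitude modulation
  if (length(spec$physio)) {
    with_seed(substream_seed(spec$master_seed, "physio", run_index), {
      tgrid <- (seq_len(Tn) - 1) * tr
      for (p in spec$physio) {
        w <- c(0, p$weights[["csf"]], p$weights[["gm"]],
               p$weights[["wm"]])[labels + 1L]
        modf <- 1 + 0.3 * smooth_field3d(d, 8)
        ph0 <- runif(1, 0, 2 * pi)
        pct <- pct + outer(p$amp_pct * w * as.vector(modf),
                           sin(2 * pi * p$freq_hz * tgrid + ph0))
      }
    })
  }

  # spontaneous fluctuations: spatially smooth random fields, temporally
  # low-passed, unit-variance-normalized then scaled to amp_pct
  if (!is.null(spec$spont) && spec$spont$amp_pct > 0) {
    with_seed(substream_seed(spec$master_seed, "generic", run_index), {
      sp <- spec$spont
      w <- c(0, sp$weights[["csf"]], sp$weights[["gm"]],
             sp$weights[["wm"]])[labels + 1L]
      field <- array(rnorm(nvox * Tn), c(d, Tn))
      for (t in seq_len(Tn))
        field[, , , t] <- gaussian_blur3d(field[, , , t, drop = FALSE][, , , 1],
                                          sp$fwhm_vox)
      wlen <- max(1L, round(sp$tau_s / tr))
      fm <- t(matrix(field, nvox, Tn))  # time x voxels
      fm <- stats::filter(fm, rep(1 / wlen, wlen), sides = 2,
                          circular = TRUE)
      fm <- t(matrix(as.numeric(fm), Tn, nvox))
      fm <- fm / sd(fm)
      pct <- pct + sp$amp_pct * w * fm
    })
  }

  # low-order polynomial drift (Legendre basis, random coefficients)
  if (spec$drift_order >= 1 && spec$drift_amp_pct > 0) {
    with_seed(substream_seed(spec$master_seed, "drift", run_index), {
      L <- legendre_basis(Tn, spec$drift_order)[, -1, drop = FALSE]
      cf <- rnorm(ncol(L), 0, spec$drift_amp_pct)
      modf <- 1 + 0.3 * smooth_field3d(d, 10)
      pct <- pct + outer(as.vector(modf), as.vector(L %*% cf))
    })
  }

  # vein fluctuations: slow noise at selected voxels, spread spatially
  sigma_pct <- if (spec$baseline[["gm"]] > 0)
    100 * spec$sigma_thermal / spec$baseline[["gm"]] else 0
  if (any(anatomy$veins) && spec$vein_amp_factor > 0 && sigma_pct > 0) {
    with_seed(substream_seed(spec$master_seed, "vein", run_index + 1000), {
      vein_sd <- spec$vein_amp_factor * sigma_pct
      vi <- which(anatomy$veins)
      vts <- matrix(rnorm(length(vi) * Tn), length(vi), Tn)
      ma <- 5  # slow: moving-average over 5 volumes
      kern <- rep(1 / ma, ma)
      vts <- t(apply(vts, 1, function(v)
        stats::filter(v, kern, sides = 2, circular = TRUE)))
      vts <- vts / sd(vts) * vein_sd
      vein4 <- array(0, c(d, Tn))
      for (t in seq_len(Tn)) {
        vol <- array(0, d)
        vol[vi] <- vts[, t]
        vein4[, , , t] <- gaussian_blur3d(vol, 1)
      }
      pct <- pct + matrix(vein4, nvox, Tn)
    })
  }

  mag <- baseline * (1 + pct / 100)
  if (any(mag < 0)) {
    warning(sprintf("clipping %d negative magnitude samples to zero",
                    sum(mag < 0)))
    mag[mag < 0] <- 0
  }

  # smooth static phase plus small per-volume global phase drift
  pp <- spec$phase_params
  phase_static <- with_seed(substream_seed(spec$master_seed, "phase"), {
    pp$static_amp_rad * smooth_field3d(d, pp$static_fwhm_vox)
  })
  phase_drift <- with_seed(
    substream_seed(spec$master_seed, "phase", run_index), {
      pp$drift_amp_rad * sin(2 * pi * (seq_len(Tn) - 1) / Tn +
                               runif(1, 0, 2 * pi))
    })
  phase <- outer(as.vector(phase_static), rep(1, Tn)) +
    matrix(phase_drift, nvox, Tn, byrow = TRUE)

  clean <- mag * exp(1i * phase)
  run_seed <- substream_seed(spec$master_seed, "noise", run_index)
  data <- if (spec$sigma_thermal > 0) {
    with_seed(run_seed, {
      nre <- matrix(rnorm(nvox * Tn), nvox, Tn)
      nim <- matrix(rnorm(nvox * Tn), nvox, Tn)
      fsm <- spec$noise_smooth_fwhm_vox %||% 0
      if (fsm > 0) {
        # variance-preserving intrinsic correlation of the noise channels
        for (t in seq_len(Tn)) {
          a <- gaussian_blur3d(array(nre[, t], d), fsm)
          b <- gaussian_blur3d(array(nim[, t], d), fsm)
          nre[, t] <- a; nim[, t] <- b
        }
        nre <- nre / sd(nre); nim <- nim / sd(nim)
      }
      sdvec <- spec$sigma_thermal * as.vector(g_map)
      clean + complex(real = sdvec * nre, imaginary = sdvec * nim)
    })
  } else clean
  dim(data) <- c(d, Tn)

  hrf_t <- seq(0, 30, by = tr)
  truth <- list(tissue_labels = labels,
                roi_target = anatomy$roi_target,
                roi_nontarget = anatomy$roi_nontarget,
                veins = anatomy$veins,
                brain_mask = anatomy$brain_mask,
                true_beta = true_beta,
                true_hrf = canonical_hrf(hrf_t, spec$hrf_params),
                regressors = regressors,
                g_map = g_map, sigma = spec$sigma_thermal,
                run_seed = run_seed,
                clean_magnitude = array(mag, c(d, Tn)))
  class(truth) <- "phantom_truth"
  list(series = complex_series(data, spec$voxel_size_mm, spec$tr_s),
       truth = truth)
}

#' Simulate a full multi-run phantom session
#'
#' @param spec a [phantom_spec()].
#' @param schedules a single schedule reused for every run, or a list of
#'   length `n_runs`.
#' @return list with `runs` (list of [complex_series()]), `schedules`,
#'   `truth` (shared ground truth from run 1) and `spec`.
#' @export
simulate_session <- function(spec, schedules = NULL) {
  if (is.null(schedules))
    schedules <- make_block_schedule(n_cycles = max(1, floor(
      (spec$n_volumes * spec$tr_s - 12) / 24)))
  if (is.data.frame(schedules))
    schedules <- rep(list(schedules), spec$n_runs)
  stopifnot(length(schedules) == spec$n_runs)
  g_map <- make_gfactor(spec)
  anatomy <- phantom_anatomy(spec)
  runs <- vector("list", spec$n_runs)
  truth <- NULL
  for (r in seq_len(spec$n_runs)) {
    sim <- simulate_run(spec, schedules[[r]], r, g_map, anatomy)
    runs[[r]] <- sim$series
    if (r == 1L) truth <- sim$truth
  }
  list(runs = runs, schedules = schedules, truth = truth, spec = spec)
}
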