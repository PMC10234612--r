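# Shared fixtures: small phantom configurations built in code.

# Minimal clean phantom: no noise, no structured fluctuations, no veins.
clean_spec <- function(...) {
  defaults <- list(sigma_thermal = 0, physio = list(), spont = NULL,
                   drift_amp_pct = 0,
                   tissue_geometry = list(csf_outer = 1, gm_outer = 0.9,
                                          wm_outer = 0.55,
                                          vein_fraction = 0),
                   g_params = list(g_min = 1, g_max = 1, fwhm_vox = 12))
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Pure-noise phantom: all baselines zero, unit sigma by default.
noise_spec <- function(sigma = 1, g_max = 1, ...) {
  phantom_spec(sigma_thermal = sigma, physio = list(), spont = NULL,
               drift_amp_pct = 0,
               tissue_geometry = list(csf_outer = 1, gm_outer = 0.9,
                                      wm_outer = 0.55, vein_fraction = 0),
               baseline = c(background = 0, csf = 0, gm = 0, wm = 0),
               g_params = list(g_min = 1, g_max = g_max, fwhm_vox = 12),
               ...)
}

# Direct SVD-truncate-reconstruct reference for one Casorati matrix:
# independent oracle for the patch sweep.
svt_reference <- function(X, tau) {
  sv <- svd(X)
  keep <- sv$d > tau
  if (!any(keep)) return(X * 0)
  sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(Conj(sv$v[, keep, drop = FALSE])))
}

magnitude_series <- function(run) series_like(run, Mod(run$data))

scaled_magnitude_runs <- function(session) {
  mask <- session$truth$brain_mask
  lapply(session$runs, function(r)
    scale_to_mean100(magnitude_series(r), mask))
}
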