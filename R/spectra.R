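#' Per-voxel temporal amplitude spectra
#'
#' Amplitude spectrum `|FFT|` of each voxel's timeseries, bins 1 to
#' floor(T/2) (DC excluded), frequencies in Hz up to Nyquist `1/(2 TR)`.
#'
#' @param series a [complex_series()] or 4D array (magnitude used).
#' @param tr_s TR override for plain arrays.
#' @return list: `freq_hz`, `amplitude` (bins x voxels).
#' @export
amplitude_spectra <- function(series, tr_s = NULL) {
  s <- as_series(series)
  tr <- tr_s %||% s$tr_s
  Y <- t(series_matrix(s, "real"))  # T x V
  Tn <- nrow(Y)
  stopifnot(Tn >= 16)
  nb <- floor(Tn / 2)
  A <- Mod(mvfft(Y))[1 + seq_len(nb), , drop = FALSE]
  list(freq_hz = seq_len(nb) / (Tn * tr), amplitude = A)
}

#' Tissue-wise normalized temporal spectra with across-run dispersion
#'
#' For each run the amplitude spectrum is averaged across voxels within
#' each tissue class and normalized to unit sum over frequencies; the
#' summary holds mean and standard deviation across runs. Mirrors the
#' standard frequency-domain readout of denoising performance: coherent
#' task/physiological peaks survive, the broadband thermal floor drops.
#'
#' @param runs one scaled run or a list of runs ([complex_series()] or 4D
#'   arrays; input should already be scaled, e.g. [scale_to_mean100()]).
#' @param tissue_masks named list of logical 3D arrays.
#' @param tr_s TR override for plain arrays.
#' @param normalize divide each run's tissue spectrum by its sum.
#' @return list of class `spectrum_summary`: `freq_hz`, `mean` and `sd`
#'   (named list per tissue), `per_run` (tissue -> runs x bins matrix),
#'   `n_voxels`.
#' @export
power_spectrum <- function(runs, tissue_masks, tr_s = NULL,
                           normalize = TRUE) {
  if (!is.list(runs) || inherits(runs, "complex_series")) runs <- list(runs)
  if (any(!vapply(tissue_masks, any, logical(1))))
    stop("empty tissue mask: ",
         paste(names(tissue_masks)[!vapply(tissue_masks, any, logical(1))],
               collapse = ", "))
  per_run <- list()
  freq <- NULL
  for (r in seq_along(runs)) {
    sp <- amplitude_spectra(runs[[r]], tr_s)
    freq <- sp$freq_hz
    for (tn in names(tissue_masks)) {
      v <- as.vector(tissue_masks[[tn]])
      m <- rowMeans(sp$amplitude[, v, drop = FALSE])
      if (normalize) m <- m / sum(m)
      per_run[[tn]] <- rbind(per_run[[tn]], m)
    }
  }
  structure(list(freq_hz = freq,
                 mean = lapply(per_run, colMeans),
                 sd = lapply(per_run, function(m)
                   if (nrow(m) > 1) apply(m, 2, sd) else rep(NA_real_,
                                                             ncol(m))),
                 per_run = per_run,
                 n_voxels = vapply(tissue_masks, sum, numeric(1))),
            class = "spectrum_summary")
}

#' Peak-to-floor ratio of a spectrum
#'
#' Amplitude at the grid frequency nearest `f_target` divided by the median
#' amplitude over a noise-floor band; quantifies how clearly a task or
#' physiological peak stands out of the broadband floor.
#'
#' @param summary a [power_spectrum()] result.
#' @param f_target peak frequency, Hz.
#' @param floor_band length-2 Hz range for the floor (must not contain
#'   `f_target`... the target bin is excluded if it falls inside).
#' @param tissue tissue name (default first).
#' @return scalar ratio.
#' @export
peak_to_floor <- function(summary, f_target, floor_band,
                          tissue = names(summary$mean)[1]) {
  f <- summary$freq_hz
  m <- summary$mean[[tissue]]
  it <- which.min(abs(f - f_target))
  band <- which(f >= floor_band[1] & f <= floor_band[2] & seq_along(f) != it)
  if (!length(band)) stop("empty floor band")
  m[it] / median(m[band])
}
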