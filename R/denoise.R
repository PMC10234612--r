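#' Patch side from the spatial:temporal ratio rule
#'
#' The locally low-rank denoiser uses cubic patches whose voxel count is at
#' least `ratio` times the number of volumes: the returned side is the
#' smallest integer k with `k^3 >= ratio * T`.
#'
#' @param n_volumes number of volumes T (>= 1).
#' @param ratio target spatial:temporal ratio (default 11).
#' @return integer patch side.
#' @export
select_patch_side <- function(n_volumes, ratio = 11) {
  stopifnot(n_volumes >= 1, ratio > 0)
  as.integer(ceiling((ratio * n_volumes)^(1 / 3) - 1e-9))
}

#' Patch scheme for locally low-rank denoising
#'
#' @param side patch side in voxels (`NULL`: derive from the ratio rule at
#'   denoising time).
#' @param stride patch grid stride in voxels (1 = full sliding window).
#' @param ratio spatial:temporal ratio used when `side` is `NULL`.
#' @param boundary boundary policy; `"clip"` shrinks patches that do not fit
#'   an axis to that axis' extent.
#' @return list of class `patch_scheme`.
#' @export
patch_scheme <- function(side = NULL, stride = 1, ratio = 11,
                         boundary = "clip") {
  if (!is.null(side) && side < 2) stop("patch side must be >= 2")
  if (stride < 1) stop("stride must be >= 1")
  structure(list(side = side, stride = as.integer(stride), ratio = ratio,
                 boundary = boundary), class = "patch_scheme")
}

# Start positions of the sliding patch grid along one axis; the final
# position is always included so the grid covers the full extent.
patch_starts <- function(d, k, stride) {
  if (k >= d) return(1L)
  s <- seq.int(1L, d - k + 1L, by = stride)
  if (s[length(s)] != d - k + 1L) s <- c(s, d - k + 1L)
  s
}

#' g-factor normalization
#'
#' Divides (forward) or multiplies (inverse) every timepoint by the
#' spatially varying noise amplification g(x), making thermal noise
#' spatially homogeneous before patch denoising.
#'
#' @param series a [complex_series()] or 4D array.
#' @param g 3D positive array.
#' @param direction `"forward"` or `"inverse"`.
#' @param mask optional logical 3D array restricting the check for
#'   non-positive g values.
#' @return series of the input type.
#' @export
gfactor_normalize <- function(series, g, direction = c("forward", "inverse"),
                              mask = NULL) {
  direction <- match.arg(direction)
  s <- as_series(series)
  gv <- as.vector(g)
  chk <- if (is.null(mask)) gv else gv[as.vector(mask)]
  if (any(chk <= 0)) stop("g-factor must be strictly positive in the mask")
  fac <- if (direction == "forward") 1 / gv else gv
  out <- series_like(s, series_matrix(s) * fac)
  if (inherits(series, "complex_series")) out else Re(out$data)
}

#' Phase normalization
#'
#' Estimates a smooth per-volume phase field by Gaussian low-pass filtering
#' of the complex image and divides it out, leaving magnitudes untouched.
#' The returned phase field restores the original series exactly.
#'
#' @param series a [complex_series()].
#' @param filter_fwhm_mm low-pass kernel FWHM in mm; default 10 voxels.
#' @return list: `series` (phase-normalized), `phase_field` (4D radians).
#' @export
phase_normalize <- function(series, filter_fwhm_mm = NULL) {
  s <- as_series(series)
  vs <- s$voxel_size_mm
  if (is.null(filter_fwhm_mm)) filter_fwhm_mm <- 10 * min(vs)
  if (filter_fwhm_mm <= 0) stop("filter_fwhm_mm must be positive")
  fwhm_vox <- filter_fwhm_mm / vs
  d <- dim(s$data)
  phase_field <- array(0, d)
  out <- s$data
  for (t in seq_len(d[4])) {
    sm <- gaussian_blur3d(s$data[, , , t, drop = FALSE][, , , 1], fwhm_vox)
    ph <- Arg(sm)
    phase_field[, , , t] <- ph
    out[, , , t] <- s$data[, , , t] * exp(-1i * ph)
  }
  list(series = complex_series(out, vs, s$tr_s), phase_field = phase_field)
}

.threshold_cache <- new.env(parent = emptyenv())

#' Monte-Carlo noise singular-value threshold
#'
#' The denoising threshold tau is the mean over `n_mc` draws of the largest
#' singular value of an m x n matrix of i.i.d. Gaussian entries with
#' per-channel standard deviation `sigma` (complex entries by default:
#' independent real and imaginary channels). Scales linearly in sigma;
#' results for sigma = 1 are cached per (m, n, n_mc, seed, field).
#'
#' @param m,n matrix dimensions (>= 1).
#' @param sigma per-channel noise sd (>= 0).
#' @param n_mc number of Monte-Carlo draws.
#' @param seed RNG seed; fixed default for reproducible thresholds.
#' @param field `"complex"` or `"real"` matrix entries.
#' @return threshold tau (scalar).
#' @export
noise_singular_threshold <- function(m, n, sigma, n_mc = 100, seed = 42,
                                     field = c("complex", "real")) {
  field <- match.arg(field)
  stopifnot(m >= 1, n >= 1, sigma >= 0, n_mc >= 1)
  if (sigma == 0) return(0)
  key <- paste(m, n, n_mc, seed, field, sep = "_")
  if (is.null(.threshold_cache[[key]])) {
    .threshold_cache[[key]] <- with_seed(seed, {
      mean(vapply(seq_len(n_mc), function(i) {
        A <- matrix(rnorm(m * n), m, n)
        B <- if (field == "complex") matrix(rnorm(m * n), m, n)
             else matrix(0, m, n)
        largest_sv(A, B)
      }, numeric(1)))
    })
  }
  sigma * .threshold_cache[[key]]
}

# Marchenko-Pastur noise sd estimate from one (real) Casorati matrix:
# R-level mirror of the criterion used by the C++ MPPCA sweep, also used to
# pool noise estimates over calibration patches.
mp_sigma_estimate <- function(X) {
  n_small <- min(dim(X)); n_large <- max(dim(X))
  G <- if (ncol(X) <= nrow(X)) crossprod(X) else tcrossprod(X)
  lam <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values) /
    n_large
  lam[lam < 0] <- 0
  clam <- cumsum(lam)
  p <- seq_len(n_small)
  sig1 <- clam / p
  sig2 <- (lam - lam[1]) / (4 * sqrt(p / n_small))
  noise <- which(sig2 <= sig1)
  p_noise <- if (length(noise)) max(noise) else 0L
  list(sigma = if (p_noise > 0) sqrt(sig1[p_noise]) else 0,
       rank = n_small - p_noise)
}

#' Estimate the thermal noise standard deviation
#'
#' `patch_mp`: median over non-overlapping patches of the Marchenko-Pastur
#' noise estimate (for complex input the real and imaginary channels are
#' stacked, so the estimate is per channel). Assumes spatially homogeneous
#' noise, i.e. a g-normalized series. `noise_region`: channel-wise standard
#' deviation over a signal-free mask.
#'
#' @param series a [complex_series()] or 4D array.
#' @param mode `"patch_mp"` or `"noise_region"`.
#' @param mask logical 3D array (required for `noise_region`).
#' @param patch_side side of the estimation patches (default 5).
#' @return estimated per-channel noise sd.
#' @export
estimate_noise_sigma <- function(series, mode = c("patch_mp", "noise_region"),
                                 mask = NULL, patch_side = 5) {
  mode <- match.arg(mode)
  s <- as_series(series)
  d <- dim(s$data)
  if (mode == "noise_region") {
    if (is.null(mask) || !any(mask)) stop("noise_region mode needs a
      non-empty mask")
    vals <- series_matrix(s)[as.vector(mask), , drop = FALSE]
    if (any(Im(vals) != 0)) {
      return(sd(c(Re(vals) - mean(Re(vals)), Im(vals) - mean(Im(vals)))))
    }
    v <- Re(vals)
    if (all(v == 0)) return(0)
    return(sqrt(mean(v^2) / 2))  # Rayleigh scale for magnitude-only data
  }
  k <- min(patch_side, d[1], d[2], d[3])
  V <- series_matrix(s)
  complex_in <- any(Im(V) != 0)
  sig <- c()
  for (z0 in seq(1, d[3] - k + 1, by = k))
    for (y0 in seq(1, d[2] - k + 1, by = k))
      for (x0 in seq(1, d[1] - k + 1, by = k)) {
        vox <- as.vector(outer(outer(x0:(x0 + k - 1),
                                     (y0:(y0 + k - 1) - 1) * d[1], `+`),
                               (z0:(z0 + k - 1) - 1) * d[1] * d[2], `+`))
        X <- V[vox, , drop = FALSE]
        Xr <- if (complex_in) rbind(Re(X), Im(X)) else Re(X)
        sig <- c(sig, mp_sigma_estimate(Xr)$sigma)
      }
  median(sig)
}

# Common result container for all denoisers.
denoise_result <- function(input, denoised, sigma_hat, threshold, ranks,
                           starts, sides) {
  input <- as_series(input)
  removed <- series_like(input, input$data - denoised$data)
  structure(list(denoised = denoised, removed = removed,
                 sigma_hat = sigma_hat, threshold = threshold,
                 rank_map = list(ranks = ranks, starts = starts,
                                 sides = sides)),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf(
    "<denoise_result> sigma_hat = %.4g, threshold = %.4g, mean rank = %.2f\n",
    x$sigma_hat, x$threshold, mean(x$rank_map$ranks)))
  invisible(x)
}

#' NORDIC-style locally low-rank denoising
#'
#' Pipeline: g-factor normalize, phase normalize, then for every position of
#' a sliding cubic patch build the (patch voxels) x T Casorati matrix, zero
#' all singular values at or below the Monte-Carlo noise threshold
#' [noise_singular_threshold()], reconstruct, and average overlapping patch
#' estimates with uniform weights; finally restore phase and inverse
#' g-normalize. Only components indistinguishable from thermal noise at
#' per-channel sd `sigma` are removed.
#'
#' @param series a [complex_series()] (or 4D array, treated as
#'   magnitude-only data).
#' @param g optional 3D g-factor map (default: homogeneous noise).
#' @param scheme a [patch_scheme()]; `NULL` for defaults (side from the
#'   11:1 ratio rule, stride 1).
#' @param sigma `"auto"` (Marchenko-Pastur estimate from the normalized
#'   data) or a numeric per-channel noise sd.
#' @param n_mc,seed Monte-Carlo settings for the threshold.
#' @param magnitude_only skip phase normalization and threshold for a real
#'   noise matrix; used for parity with magnitude-only comparators.
#' @param strict_ratio error if the patch volume is smaller than T.
#' @return a `denoise_result`: `denoised`, `removed` (input - denoised),
#'   `sigma_hat`, `threshold`, `rank_map`.
#' @export
nordic_denoise <- function(series, g = NULL, scheme = NULL, sigma = "auto",
                           n_mc = 100, seed = 42, magnitude_only = FALSE,
                           strict_ratio = TRUE) {
  s <- as_series(series)
  d <- dim(s$data)
  Tn <- d[4]
  if (Tn < 2) stop("need at least 2 volumes")
  if (any(!is.finite(Re(s$data))) || any(!is.finite(Im(s$data))))
    stop("non-finite values in input series")
  if (is.null(scheme)) scheme <- patch_scheme()
  k <- scheme$side %||% select_patch_side(Tn, scheme$ratio)
  sides <- pmin(k, d[1:3])
  m <- prod(sides)
  if (strict_ratio && m < Tn)
    stop(sprintf("patch volume %d < T = %d violates the spatial:temporal
      ratio rule; enlarge the patch or set strict_ratio = FALSE", m, Tn))
  if (is.null(g)) g <- array(1, d[1:3])

  work <- as_series(gfactor_normalize(s, g, "forward"))
  phase_field <- NULL
  if (!magnitude_only) {
    pn <- phase_normalize(work)
    work <- pn$series
    phase_field <- pn$phase_field
  }
  sigma_hat <- if (identical(sigma, "auto"))
    estimate_noise_sigma(work, "patch_mp") else as.numeric(sigma)
  tau <- noise_singular_threshold(m, Tn, sigma_hat, n_mc = n_mc, seed = seed,
                                  field = if (magnitude_only) "real"
                                          else "complex")

  sx <- patch_starts(d[1], sides[1], scheme$stride)
  sy <- patch_starts(d[2], sides[2], scheme$stride)
  sz <- patch_starts(d[3], sides[3], scheme$stride)
  V <- series_matrix(work)
  sw <- cpp_llr_svt(V, dim(s$data), sx, sy, sz, sides, tau)
  den <- sw$acc / as.vector(sw$weight)
  out <- series_like(work, den)
  if (!magnitude_only)
    out <- series_like(out, out$data * exp(1i * phase_field))
  out <- as_series(gfactor_normalize(out, g, "inverse"))
  starts <- as.matrix(expand.grid(x = sx, y = sy, z = sz))
  denoise_result(s, out, sigma_hat, tau, sw$ranks, starts, sides)
}

#' Marchenko-Pastur PCA (MPPCA) denoising
#'
#' Magnitude-domain patch PCA: for each patch the trailing eigenvalues of
#' the Casorati covariance are classified as noise when their spread is
#' consistent with the Marchenko-Pastur bulk for the sigma^2 implied by
#' their mean; the patch is reconstructed from the remaining components and
#' overlapping patches are averaged. Default patch side 5 for T < 150,
#' else 7.
#'
#' @param series a [complex_series()] (magnitude used) or 4D numeric array.
#' @param scheme a [patch_scheme()]; `NULL` for defaults.
#' @return a `denoise_result`; `sigma_hat` is the median patch noise
#'   estimate.
#' @export
mppca_denoise <- function(series, scheme = NULL) {
  s <- as_series(series)
  d <- dim(s$data)
  Tn <- d[4]
  if (Tn < 2) stop("need at least 2 volumes")
  if (is.null(scheme)) scheme <- patch_scheme()
  k <- scheme$side %||% (if (Tn < 150) 5L else 7L)
  sides <- pmin(k, d[1:3])
  V <- series_matrix(s, "magnitude")
  if (any(!is.finite(V))) stop("non-finite values in input series")
  sx <- patch_starts(d[1], sides[1], scheme$stride)
  sy <- patch_starts(d[2], sides[2], scheme$stride)
  sz <- patch_starts(d[3], sides[3], scheme$stride)
  sw <- cpp_mppca(V, dim(s$data), sx, sy, sz, sides)
  den <- sw$acc / as.vector(sw$weight)
  out <- series_like(s, den)
  mag_in <- series_like(s, V)
  starts <- as.matrix(expand.grid(x = sx, y = sy, z = sz))
  denoise_result(mag_in, out, median(sw$sigmas), NA_real_, sw$ranks,
                 starts, sides)
}

#' Volume-wise Gaussian spatial smoothing
#'
#' Plain 3D Gaussian convolution of every volume, kernel FWHM given in
#' voxels (the common "+1 voxel", "+1.5 voxel" comparators).
#'
#' @param series a [complex_series()] or 4D array.
#' @param fwhm_voxels kernel FWHM in voxel units (>= 0; 0 = identity).
#' @return series of the input type.
#' @export
gaussian_smooth <- function(series, fwhm_voxels) {
  stopifnot(fwhm_voxels >= 0)
  if (fwhm_voxels == 0) return(series)
  s <- as_series(series)
  d <- dim(s$data)
  out <- s$data
  for (t in seq_len(d[4]))
    out[, , , t] <- gaussian_blur3d(s$data[, , , t, drop = FALSE][, , , 1],
                                    fwhm_voxels)
  if (inherits(series, "complex_series"))
    complex_series(out, s$voxel_size_mm, s$tr_s)
  else Re(out)
}

#' Sliding-window temporal smoothing
#'
#' Centered moving average over the largest odd number of timepoints w with
#' `w * TR` inside `[window_lo_s, window_hi_s]`; edges use symmetrically
#' shrunk windows.
#'
#' @param series a [complex_series()] or 4D array.
#' @param tr_s TR override for plain arrays (read from the series
#'   otherwise).
#' @param window_lo_s,window_hi_s window bounds in seconds.
#' @return series of the input type.
#' @export
temporal_smooth <- function(series, tr_s = NULL, window_lo_s = 9,
                            window_hi_s = 10.5) {
  stopifnot(window_lo_s <= window_hi_s)
  s <- as_series(series)
  tr <- tr_s %||% s$tr_s
  w <- floor(window_hi_s / tr)
  if (w %% 2 == 0) w <- w - 1
  if (w < 1 || w * tr < window_lo_s)
    stop(sprintf("no odd window length w has w * TR in [%g, %g] s",
                 window_lo_s, window_hi_s))
  h <- (w - 1) / 2
  V <- series_matrix(s)
  Tn <- ncol(V)
  cs <- cbind(0 + 0i, t(apply(V, 1, cumsum)))
  out <- V
  for (t in seq_len(Tn)) {
    ht <- min(h, t - 1, Tn - t)
    out[, t] <- (cs[, t + ht + 1] - cs[, t - ht]) / (2 * ht + 1)
  }
  res <- series_like(s, out)
  if (inherits(series, "complex_series")) res else Re(res$data)
}

#' Map of the noise removed by a denoiser
#'
#' Complex mode: temporal mean of the magnitude of the complex difference
#' between the standard and denoised series. Magnitude mode: absolute value
#' of the temporal mean difference.
#'
#' @param standard,denoised matching series.
#' @param complex_mode use the complex-difference definition.
#' @return 3D map.
#' @export
removed_noise_map <- function(standard, denoised, complex_mode = TRUE) {
  a <- as_series(standard); b <- as_series(denoised)
  if (!identical(dim(a$data), dim(b$data))) stop("shape mismatch")
  d <- dim(a$data)
  diffm <- series_matrix(a) - series_matrix(b)
  m <- if (complex_mode) rowMeans(Mod(diffm)) else abs(rowMeans(Re(diffm)))
  array(m, d[1:3])
}
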