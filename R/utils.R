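#' @useDynLib llrfmri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor qt qnorm pt optim nls fft mvfft
#'   median quantile rbinom dgamma coef resid lm poly uniroot
NULL

# Run code under a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All randomness in the package flows through
# this helper so results are reproducible from a master seed without
# clobbering the user's RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Named substreams derived from one master seed by fixed offsets, so that
# e.g. the g-factor field does not change when the number of runs changes.
substream_seed <- function(master_seed, component, index = 0L) {
  offsets <- c(gfactor = 101L, phase = 211L, tissue = 307L, noise = 401L,
               physio = 503L, drift = 601L, vein = 701L, schedule = 811L,
               threshold = 907L, generic = 1009L)
  off <- offsets[[component]]
  if (is.null(off)) stop("unknown substream component: ", component)
  (as.double(master_seed) * 1000003 + off * 9176 + index * 7919) %%
    2147483629
}

# 3D Gaussian smoothing of a (possibly complex) 3D array via FFT, i.e.
# periodic convolution with a unit-gain Gaussian kernel whose FWHM is given
# per axis in voxels. fwhm of 0 along an axis leaves that axis untouched.
gaussian_blur3d <- function(vol, fwhm_vox) {
  d <- dim(vol)
  if (length(fwhm_vox) == 1L) fwhm_vox <- rep(fwhm_vox, 3L)
  if (all(fwhm_vox <= 0)) return(vol)
  transfer <- gaussian_transfer(d, fwhm_vox)
  out <- fft(fft(vol) * transfer, inverse = TRUE) / prod(d)
  if (!is.complex(vol)) Re(out) else out
}

# Frequency-domain transfer function of the separable Gaussian kernel.
gaussian_transfer <- function(d, fwhm_vox) {
  axis_tf <- function(n, fwhm) {
    if (fwhm <= 0) return(rep(1, n))
    sigma <- fwhm / sqrt(8 * log(2))
    f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1) / n  # cycles/voxel
    exp(-2 * pi^2 * sigma^2 * f^2)
  }
  tx <- axis_tf(d[1], fwhm_vox[1])
  ty <- axis_tf(d[2], fwhm_vox[2])
  tz <- axis_tf(d[3], fwhm_vox[3])
  array(outer(outer(tx, ty), tz), dim = d)
}

# Smooth Gaussian random field on a 3D grid, standardized to zero mean and
# unit variance (used for g-factor bumps, smooth phase, vein spread tests).
smooth_field3d <- function(d, fwhm_vox) {
  f <- array(rnorm(prod(d)), dim = d)
  f <- gaussian_blur3d(f, fwhm_vox)
  (f - mean(f)) / sd(f)
}

# Legendre polynomial basis (columns 0..order) evaluated on T points mapped
# to [-1, 1]; orthogonal-ish drift regressors with good conditioning.
legendre_basis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1L) P[, 2] <- x
  if (order >= 2L) {
    for (k in 2:order)  # recurrence: k P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  }
  colnames(P) <- paste0("drift", 0:order)
  P
}

# Largest singular value of a complex matrix given as real/imaginary parts,
# via the Hermitian Gram matrix of the smaller dimension (fast path used by
# the Monte-Carlo noise threshold).
largest_sv <- function(A, B) {
  if (nrow(A) < ncol(A)) { A <- t(A); B <- -t(B) }  # conj transpose
  H <- crossprod(A) + crossprod(B) + 1i * (crossprod(A, B) - crossprod(B, A))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev[1], 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
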