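#' Global spatial-autocorrelation FWHM
#'
#' Estimates image smoothness per axis from the lag-1 spatial correlation of
#' the (optionally detrended, volume-wise standardized) data inside a mask:
#' under a Gaussian spatial ACF, a field produced by smoothing white noise
#' with a kernel of FWHM f has lag-1 correlation `exp(-2 log(2) dx^2 / f^2)`,
#' so `FWHM = dx * sqrt(-2 log 2 / log r1)`. The estimator is calibrated:
#' data smoothed with a kernel of FWHM f report f. Any post-acquisition
#' blurring shows up as an increase relative to unprocessed data.
#'
#' @param series a [complex_series()] or 4D array (magnitude used); for GLM
#'   residuals pass the residual series with `detrend = FALSE`.
#' @param mask logical 3D array (>= 100 voxels); default: all voxels.
#' @param detrend remove per-voxel mean + Legendre polynomial trends first.
#' @param detrend_order polynomial order for detrending (default quadratic).
#' @param stage label stored with the estimate (`"pre"`, `"post"`,
#'   `"residual"`).
#' @return list of class `smoothness_estimate`: `fwhm_mm` (per axis, NA
#'   where the lag-1 correlation is non-positive, i.e. sub-voxel /
#'   undefined), `mean_fwhm_mm`, `fwhm_vox`, `r1`, `n_voxels`, `stage`.
#' @export
global_fwhm <- function(series, mask = NULL, detrend = TRUE,
                        detrend_order = 2, stage = "pre") {
  s <- as_series(series)
  d <- dim(s$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (sum(mask) < 100) stop("mask must contain at least 100 voxels")
  Y <- t(series_matrix(s, "real"))  # T x V
  if (detrend) {
    L <- legendre_basis(nrow(Y), detrend_order)
    Y <- Y - L %*% qr.coef(qr(L), Y)
  }
  maskv <- as.vector(mask)
  dims <- d[1:3]
  coords <- arrayInd(which(maskv), dims)
  lin <- function(co) co[, 1] + dims[1] * (co[, 2] - 1) +
    dims[1] * dims[2] * (co[, 3] - 1)
  r1 <- numeric(3)
  for (ax in 1:3) {
    co2 <- coords
    co2[, ax] <- co2[, ax] + 1L
    ok <- co2[, ax] <= dims[ax]
    i1 <- lin(coords[ok, , drop = FALSE])
    i2 <- lin(co2[ok, , drop = FALSE])
    ok2 <- maskv[i2]
    A <- Y[, i1[ok2], drop = FALSE]
    B <- Y[, i2[ok2], drop = FALSE]
    Ac <- A - rowMeans(A); Bc <- B - rowMeans(B)
    rv <- rowSums(Ac * Bc) /
      sqrt(pmax(rowSums(Ac^2) * rowSums(Bc^2), .Machine$double.eps))
    r1[ax] <- mean(rv)
  }
  # invert the exact discrete lag-1 correlation of a periodic Gaussian
  # kernel (per axis length); agrees with the continuous-ACF closed form
  # FWHM = dx * sqrt(-2 log 2 / log r1) for FWHM >~ 1.5 voxels but stays
  # calibrated for sub-1.5-voxel kernels where aliasing matters
  fwhm_vox <- vapply(1:3, function(ax) {
    if (is.na(r1[ax]) || r1[ax] <= 0) return(NA_real_)
    invert_kernel_r1(r1[ax], dims[ax])
  }, numeric(1))
  if (any(is.na(fwhm_vox)))
    warning("non-positive lag-1 correlation on some axis: sub-voxel /
      undefined, excluded from the mean")
  fwhm_mm <- fwhm_vox * s$voxel_size_mm
  structure(list(fwhm_mm = fwhm_mm, mean_fwhm_mm = mean(fwhm_mm, na.rm = TRUE),
                 fwhm_vox = fwhm_vox, r1 = r1, n_voxels = sum(mask),
                 stage = stage),
            class = "smoothness_estimate")
}

# Lag-1 autocorrelation of white noise smoothed with the package's periodic
# Gaussian kernel of FWHM f voxels, along an axis of length n:
# r1(f) = sum_k |H_k|^2 cos(2 pi k / n) / sum_k |H_k|^2.
kernel_r1 <- function(f, n) {
  sigma <- f / sqrt(8 * log(2))
  k <- 0:(n - 1)
  fr <- pmin(k, n - k) / n
  H2 <- exp(-4 * pi^2 * sigma^2 * fr^2)
  sum(H2 * cos(2 * pi * k / n)) / sum(H2)
}

# Monotone inversion of kernel_r1 on a grid (cached per axis length).
.r1_cache <- new.env(parent = emptyenv())
invert_kernel_r1 <- function(r1, n) {
  key <- as.character(n)
  if (is.null(.r1_cache[[key]])) {
    f_grid <- seq(0.05, n / 2, by = 0.05)
    .r1_cache[[key]] <- list(f = f_grid,
                             r1 = vapply(f_grid, kernel_r1, numeric(1),
                                         n = n))
  }
  tab <- .r1_cache[[key]]
  stats::approx(tab$r1, tab$f, xout = min(r1, max(tab$r1)), rule = 2)$y
}

#' Fit a Gaussian + mono-exponential spatial ACF model
#'
#' Least-squares fit of `rho(r) = a exp(-r^2 / (2 b^2)) + (1 - a)
#' exp(-r / c)` with `a` in `[0, 1]` and `b, c > 0`; the smoothness FWHM is
#' twice the radius at which the fitted curve crosses one half.
#'
#' @param distances distance-bin centers (>= 4 bins), in mm or voxels.
#' @param correlations mean correlation per bin.
#' @return list of class `acf_model`: `a`, `b`, `c`, `fwhm` (same units as
#'   `distances`), `fallback` (TRUE when the mixed fit failed and a pure
#'   Gaussian was used).
#' @export
fit_acf_model <- function(distances, correlations, n_starts = 12) {
  keep <- is.finite(distances) & is.finite(correlations)
  distances <- distances[keep]; correlations <- correlations[keep]
  if (length(distances) < 4) stop("need at least 4 distance bins")
  dfit <- data.frame(r = distances, rho = correlations)
  rmax <- max(distances)
  # multi-start Levenberg-Marquardt: the Gaussian/exponential split has
  # local minima (e.g. pure-exponential data can be mis-fit with a = 1);
  # per-voxel map fitting uses a reduced start set (n_starts = 4) for speed
  starts <- expand.grid(a = c(0.1, 0.5, 0.9),
                        b = c(rmax / 6, rmax / 2),
                        c = c(rmax / 6, rmax / 2))
  starts <- starts[seq_len(min(n_starts, nrow(starts))), , drop = FALSE]
  fit <- NULL; best <- Inf
  for (i in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        rho ~ a * exp(-r^2 / (2 * b^2)) + (1 - a) * exp(-r / c),
        data = dfit,
        start = as.list(starts[i, ]),
        lower = c(a = 0, b = 1e-3, c = 1e-3),
        upper = c(a = 1, b = 10 * rmax, c = 10 * rmax),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand)) {
      sse <- sum(resid(cand)^2)
      if (sse < best) { best <- sse; fit <- cand }
      if (best < 1e-10) break
    }
  }
  fallback <- is.null(fit)
  if (fallback && max(correlations) < 0.1) {
    # no measurable correlation at any distance: sub-voxel smoothness
    pars <- c(a = 1, b = 1e-3, c = 1e-3)
  } else if (fallback) {
    # pure-Gaussian fallback: log-linear regression on positive bins
    pos <- correlations > 1e-6
    b <- if (sum(pos) >= 2) {
      sl <- coef(lm(log(correlations[pos]) ~ 0 + I(-distances[pos]^2 / 2)))
      1 / sqrt(max(sl, 1e-6))
    } else 1e-3
    pars <- c(a = 1, b = unname(b), c = 1e-3)
  } else {
    pars <- coef(fit)
  }
  rho_hat <- function(r) {
    pars[["a"]] * exp(-r^2 / (2 * pars[["b"]]^2)) +
      (1 - pars[["a"]]) * exp(-r / pars[["c"]])
  }
  upper <- 10 * rmax
  fwhm <- if (rho_hat(upper) >= 0.5) 2 * upper
          else if (rho_hat(1e-9) < 0.5) 0
          else 2 * uniroot(function(r) rho_hat(r) - 0.5,
                           c(1e-9, upper))$root
  structure(list(a = unname(pars[["a"]]), b = unname(pars[["b"]]),
                 c = unname(pars[["c"]]), fwhm = fwhm, fallback = fallback),
            class = "acf_model")
}

#' Local (neighborhood) spatial ACF FWHM map
#'
#' For every in-mask voxel, the Pearson correlation between its timeseries
#' and every in-mask neighbor within a spherical neighborhood is computed,
#' binned by Euclidean distance (1-voxel bins), and the Gaussian +
#' mono-exponential ACF model is fitted per voxel; the map holds the fitted
#' FWHM expressed as the equivalent applied Gaussian kernel (the fitted ACF
#' half-width divided by sqrt(2)), the same calibrated scale as
#' [global_fwhm()]. Highlights regional variation in effective smoothness
#' (e.g. around high-fluctuation vein voxels).
#'
#' @param residuals a [complex_series()] or 4D array of GLM residuals (or a
#'   list of them, one per run: maps are estimated per run and averaged).
#' @param mask logical 3D array.
#' @param radius_voxels neighborhood radius in voxels.
#' @param min_neighbors voxels with fewer usable neighbors are set NA.
#' @return list: `fwhm_map` (3D, mm), `n_fit`, `radius_voxels`.
#' @export
local_acf_fwhm <- function(residuals, mask, radius_voxels = 10,
                           min_neighbors = 20) {
  if (!is.list(residuals) || inherits(residuals, "complex_series"))
    residuals <- list(residuals)
  maps <- lapply(residuals, function(r)
    local_acf_fwhm_run(r, mask, radius_voxels, min_neighbors))
  fwhm <- Reduce(`+`, lapply(maps, function(m) {
    m[is.na(m)] <- 0; m
  })) / Reduce(`+`, lapply(maps, function(m) !is.na(m) + 0))
  fwhm[!is.finite(fwhm)] <- NA
  list(fwhm_map = fwhm, n_fit = sum(is.finite(fwhm)),
       radius_voxels = radius_voxels)
}

local_acf_fwhm_run <- function(series, mask, radius_voxels, min_neighbors) {
  s <- as_series(series)
  d <- dim(s$data)
  if (n_volumes(s) < 30) stop("need at least 30 volumes")
  dims <- d[1:3]
  Tn <- d[4]
  Y <- series_matrix(s, "real")
  Y <- Y - rowMeans(Y)
  nrm <- sqrt(rowSums(Y^2))
  Z <- Y / pmax(nrm, .Machine$double.eps)
  Z[nrm == 0 | !as.vector(mask), ] <- 0
  valid <- as.vector(mask) & nrm > 0

  R <- ceiling(radius_voxels)
  offs <- as.matrix(expand.grid(dx = -R:R, dy = -R:R, dz = -R:R))
  dist <- sqrt(rowSums(offs^2))
  keep <- dist > 0 & dist <= radius_voxels
  offs <- offs[keep, , drop = FALSE]; dist <- dist[keep]
  # half-space: each unordered pair visited once, contributes to both ends
  half <- offs[, 3] > 0 | (offs[, 3] == 0 &
            (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))
  offs <- offs[half, , drop = FALSE]; dist <- dist[half]
  bins <- pmax(1L, as.integer(round(dist)))
  nb <- max(bins)
  centers <- as.numeric(tapply(dist, bins, mean))  # true mean bin distance

  nvox <- prod(dims)
  csum <- matrix(0, nvox, nb)
  cnt <- matrix(0, nvox, nb)
  Zarr <- array(Z, c(dims, Tn))
  Varr <- array(as.numeric(valid), dims)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    xr <- max(1, 1 - o[1]):min(dims[1], dims[1] - o[1])
    yr <- max(1, 1 - o[2]):min(dims[2], dims[2] - o[2])
    zr <- max(1, 1 - o[3]):min(dims[3], dims[3] - o[3])
    if (!length(xr) || !length(yr) || !length(zr)) next
    A <- Zarr[xr, yr, zr, , drop = FALSE]
    B <- Zarr[xr + o[1], yr + o[2], zr + o[3], , drop = FALSE]
    cc <- apply(A * B, 1:3, sum)
    vv <- Varr[xr, yr, zr] * Varr[xr + o[1], yr + o[2], zr + o[3]]
    cc <- cc * vv
    # scatter into the two endpoint voxels of each pair
    target1 <- array(FALSE, dims); target1[xr, yr, zr] <- TRUE
    target2 <- array(FALSE, dims)
    target2[xr + o[1], yr + o[2], zr + o[3]] <- TRUE
    b <- bins[i]
    csum[target1, b] <- csum[target1, b] + as.vector(cc)
    cnt[target1, b] <- cnt[target1, b] + as.vector(vv)
    csum[target2, b] <- csum[target2, b] + as.vector(cc)
    cnt[target2, b] <- cnt[target2, b] + as.vector(vv)
  }

  vs <- mean(s$voxel_size_mm)
  fwhm <- rep(NA_real_, nvox)
  idx <- which(valid & rowSums(cnt) >= min_neighbors)
  for (v in idx) {
    use <- cnt[v, ] > 0
    if (sum(use) < 4) next
    mdl <- tryCatch(
      fit_acf_model(centers[use] * vs, csum[v, use] / cnt[v, use],
                    n_starts = 4),
      error = function(e) NULL)
    # report in applied-kernel units: a Gaussian kernel of FWHM f yields a
    # field ACF of FWHM f * sqrt(2), matching the global estimator's scale
    if (!is.null(mdl)) fwhm[v] <- mdl$fwhm / sqrt(2)
  }
  array(fwhm, dims)
}

#' Label contiguous supra-threshold clusters
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return list: `labels` (integer 3D array, 0 = background), `sizes`.
#' @export
label_clusters <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  labels <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = labels, sizes = integer(0)))
  co <- arrayInd(idx, d)
  inside <- array(FALSE, d); inside[idx] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  cur <- 0L
  sizes <- integer(0)
  for (seed_i in seq_along(idx)) {
    v <- idx[seed_i]
    if (labels[v] != 0L) next
    cur <- cur + 1L
    stack <- matrix(co[seed_i, ], 1)
    labels[v] <- cur
    size <- 1L
    while (nrow(stack)) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      nb <- sweep(offs, 2, p, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      li <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      newv <- li[inside[li] & labels[li] == 0L]
      if (length(newv)) {
        labels[newv] <- cur
        size <- size + length(newv)
        stack <- rbind(stack, arrayInd(newv, d))
      }
    }
    sizes <- c(sizes, size)
  }
  list(labels = labels, sizes = sizes)
}

#' Monte-Carlo cluster-size threshold from smoothness-matched noise
#'
#' Simulates noise-only volumes with the given smoothness (Gaussian-kernel
#' convolution), thresholds |z| at the one-sided `voxel_p` quantile, and
#' records the largest cluster per simulation; the returned `k_min` is the
#' smallest cluster size whose null exceedance probability is at most
#' `cluster_alpha`.
#'
#' @param acf_or_fwhm applied smoothing-kernel FWHM in voxels (numeric), or
#'   an [fit_acf_model()] result (its half-maximum radius sets an
#'   approximating Gaussian kernel; the mono-exponential tail is not
#'   simulated).
#' @param grid integer length-3 simulation grid.
#' @param voxel_p one-sided voxel-wise threshold probability.
#' @param n_sim number of noise simulations (>= 100).
#' @param cluster_alpha cluster-wise false positive rate.
#' @param connectivity 6 or 26.
#' @param seed RNG seed.
#' @return list: `k_min`, `max_sizes` (per simulation), `voxel_p`,
#'   `cluster_alpha`.
#' @export
cluster_size_threshold <- function(acf_or_fwhm, grid = c(32, 32, 32),
                                   voxel_p = 0.001, n_sim = 10000,
                                   cluster_alpha = 0.05, connectivity = 26,
                                   seed = 1) {
  stopifnot(n_sim >= 100)
  fwhm <- if (inherits(acf_or_fwhm, "acf_model"))
    acf_or_fwhm$fwhm / sqrt(2) else as.numeric(acf_or_fwhm)
  zthr <- qnorm(1 - voxel_p)
  max_sizes <- with_seed(seed, {
    vapply(seq_len(n_sim), function(i) {
      vol <- array(rnorm(prod(grid)), grid)
      if (fwhm > 0) {
        vol <- gaussian_blur3d(vol, fwhm)
        vol <- vol / sd(vol)
      }
      supra <- vol > zthr
      if (!any(supra)) return(0L)
      max(label_clusters(supra, connectivity)$sizes)
    }, integer(1))
  })
  k <- 1L
  while (mean(max_sizes >= k) > cluster_alpha) k <- k + 1L
  list(k_min = k, max_sizes = max_sizes, voxel_p = voxel_p,
       cluster_alpha = cluster_alpha)
}

#' Define functional ROIs from a t-map
#'
#' Thresholds the t-map at the one-sided `voxel_p` quantile of the Student-t
#' distribution with `dof` degrees of freedom, labels contiguous
#' supra-threshold components, and keeps those with at least `min_cluster`
#' voxels.
#'
#' @param t_map 3D array of t-values.
#' @param dof degrees of freedom (> 2).
#' @param voxel_p voxel-wise threshold probability.
#' @param min_cluster minimum cluster size in voxels.
#' @param connectivity 6 or 26.
#' @param sign `"pos"` or `"neg"`: direction of the effect.
#' @return logical 3D mask (possibly empty).
#' @export
define_rois <- function(t_map, dof, voxel_p = 0.001, min_cluster = 10,
                        connectivity = 26, sign = c("pos", "neg")) {
  sign <- match.arg(sign)
  stopifnot(dof > 2)
  thr <- qt(1 - voxel_p, dof)
  supra <- if (sign == "pos") t_map > thr else t_map < -thr
  supra[is.na(supra)] <- FALSE
  if (!any(supra)) return(array(FALSE, dim(t_map)))
  lab <- label_clusters(supra, connectivity)
  keep <- which(lab$sizes >= min_cluster)
  array(lab$labels %in% keep, dim(t_map))
}
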