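#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma-density-shaped lobes, the common "SPM-style"
#' parameterization: a positive lobe peaking near 5-6 s and a negative
#' undershoot near 15-17 s, peak-normalized to 1.
#'
#' @param t time grid in seconds (t >= 0).
#' @param params optional list overriding `peak_delay` (6), `under_delay`
#'   (16), `peak_disp` (1), `under_disp` (1), `under_ratio` (1/6). Delays
#'   and dispersions are in seconds; dispersions must be positive.
#' @return numeric vector of HRF samples, max 1 on a dense grid.
#' @export
canonical_hrf <- function(t, params = list()) {
  p <- utils::modifyList(list(peak_delay = 6, under_delay = 16,
                              peak_disp = 1, under_disp = 1,
                              under_ratio = 1 / 6), params)
  if (p$peak_disp <= 0 || p$under_disp <= 0)
    stop("HRF dispersions must be positive")
  h <- function(x) {
    dgamma(x, shape = p$peak_delay / p$peak_disp, scale = p$peak_disp) -
      p$under_ratio *
        dgamma(x, shape = p$under_delay / p$under_disp, scale = p$under_disp)
  }
  dense <- seq(0, max(32, max(t)), by = 0.02)
  h(t) / max(h(dense))
}

# Convolve a stimulus schedule (boxcars) with the canonical HRF on a fine
# grid (dt = 0.05 s) and sample at the TR grid t = (0:(T-1)) * tr. Shared by
# the phantom generator and design construction so that noiseless
# simulation + regression recovers amplitudes exactly.
convolve_schedule <- function(schedule, n_volumes, tr_s, hrf_params = list(),
                              dt = 0.05) {
  total_s <- n_volumes * tr_s
  fine_t <- seq(0, total_s, by = dt)
  box <- numeric(length(fine_t))
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset[i]
    box[fine_t >= on & fine_t < on + schedule$duration[i]] <- 1
  }
  hrf <- canonical_hrf(seq(0, 32, by = dt), hrf_params)
  conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine_t)] * dt
  if (max(conv) > 0) conv <- conv / max(conv)  # peak response = 1
  idx <- round((seq_len(n_volumes) - 1) * tr_s / dt) + 1L
  conv[idx]
}

#' Scale a series to a temporal mean of 100
#'
#' Standard percent-signal-change scaling: each in-mask voxel's timeseries is
#' multiplied by `100 / temporal mean`; out-of-mask voxels are set to zero.
#' For complex input the complex data are scaled by the real factor computed
#' from the magnitude mean, preserving phase.
#'
#' @param series a [complex_series()] or 4D numeric array.
#' @param mask logical 3D array; default: voxels with positive temporal mean
#'   magnitude. In-mask voxels with non-positive mean are excluded with a
#'   warning.
#' @return object of the same type as `series`, scaled.
#' @export
scale_to_mean100 <- function(series, mask = NULL) {
  was_array <- !inherits(series, "complex_series")
  s <- as_series(series)
  m <- series_matrix(s, "magnitude")
  mu <- rowMeans(m)
  if (is.null(mask)) {
    mask <- mu > 0
  } else {
    mask <- as.vector(mask)
    bad <- mask & mu <= 0
    if (any(bad)) {
      warning(sprintf("excluding %d in-mask voxels with non-positive mean",
                      sum(bad)))
      mask[bad] <- FALSE
    }
  }
  fac <- ifelse(mask, 100 / pmax(mu, .Machine$double.eps), 0)
  out <- series_matrix(s) * fac
  res <- series_like(s, out)
  if (was_array) array(Re(res$data), dim(s$data)) else res
}

#' Build a task + drift design matrix
#'
#' Canonical basis: one regressor per condition, the stimulus boxcar
#' convolved with the double-gamma HRF sampled at the TR. TENT (FIR) basis:
#' one delta regressor per TR lag from onset up to `tent_window_s`, onsets
#' rounded to the nearest TR (ties toward the earlier TR). Legendre
#' polynomial drift columns 0..`drift_order` are appended.
#'
#' @param schedule stimulus schedule data.frame (`onset`, `duration`,
#'   `condition`).
#' @param n_volumes number of volumes T.
#' @param tr_s TR in seconds.
#' @param basis `"canonical"` or `"tent"`.
#' @param drift_order Legendre drift order (>= 0).
#' @param tent_window_s FIR estimation window in seconds from onset.
#' @param hrf_params passed to [canonical_hrf()] for the canonical basis.
#' @return list of class `design_matrix`: `matrix` (T x p), `labels`,
#'   `task_cols`, `drift_cols`, `basis`, `conditions`, `tent_lags`.
#' @export
build_design <- function(schedule, n_volumes, tr_s,
                         basis = c("canonical", "tent"), drift_order = 1,
                         tent_window_s = 21.6, hrf_params = list()) {
  basis <- match.arg(basis)
  conds <- unique(schedule$condition)
  cols <- list(); labels <- character(0)
  tent_lags <- NULL
  for (cn in conds) {
    sc <- schedule[schedule$condition == cn, , drop = FALSE]
    if (basis == "canonical") {
      cols[[length(cols) + 1L]] <-
        convolve_schedule(sc, n_volumes, tr_s, hrf_params)
      labels <- c(labels, cn)
    } else {
      n_lags <- floor(tent_window_s / tr_s) + 1L
      tent_lags <- (seq_len(n_lags) - 1L) * tr_s
      X <- matrix(0, n_volumes, n_lags)
      onset_tr <- ceiling(sc$onset / tr_s - 0.5)  # nearest, ties earlier
      for (o in onset_tr) {
        rows <- o + seq_len(n_lags) - 0L
        ok <- rows >= 1 & rows <= n_volumes
        X[cbind(rows[ok], which(ok))] <- X[cbind(rows[ok], which(ok))] + 1
      }
      for (l in seq_len(n_lags)) cols[[length(cols) + 1L]] <- X[, l]
      labels <- c(labels, paste0(cn, "#", seq_len(n_lags) - 1L))
    }
  }
  task <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, n_volumes, 0)
  drift <- legendre_basis(n_volumes, drift_order)
  X <- cbind(task, drift)
  colnames(X) <- c(labels, colnames(drift))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; colliding columns: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(matrix = X, labels = colnames(X),
                 task_cols = seq_len(ncol(task)),
                 drift_cols = ncol(task) + seq_len(ncol(drift)),
                 basis = basis, conditions = conds, tent_lags = tent_lags,
                 tr_s = tr_s),
            class = "design_matrix")
}

# Expected lag-1 autocorrelation of OLS residuals as a function of the AR(1)
# parameter of the noise, from the design's residual-forming matrix M:
# E[r' L r] / E[r' r] = tr(M L M Sigma(phi)) / tr(M Sigma(phi)). Tabulated
# on a phi grid and inverted by interpolation; removes the design-dependent
# downward bias of the naive Yule-Walker estimate.
ar1_moment_invert <- function(X, r1_obs) {
  n <- nrow(X)
  H <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  M <- diag(n) - H
  L <- matrix(0, n, n)
  L[cbind(1:(n - 1), 2:n)] <- 0.5
  L[cbind(2:n, 1:(n - 1))] <- 0.5
  MLM <- M %*% L %*% M
  lagmat <- abs(outer(seq_len(n), seq_len(n), `-`))
  phis <- seq(-0.95, 0.95, by = 0.01)
  ratio <- vapply(phis, function(p) {
    S <- p^lagmat
    sum(MLM * S) / sum(M * S)
  }, numeric(1))
  # ratio is monotone increasing in phi; invert by interpolation
  phi <- stats::approx(ratio, phis, xout = r1_obs, rule = 2)$y
  pmin(pmax(phi, -0.95), 0.95)
}

# AR(1) correlation whitening: first row scaled so that W %*% y has white
# unit-scale innovations when y is AR(1) with parameter phi.
whiten_ar1 <- function(y_or_x, phi) {
  n <- nrow(y_or_x)
  out <- y_or_x
  out[1, ] <- sqrt(1 - phi^2) * y_or_x[1, ]
  out[2:n, ] <- y_or_x[2:n, , drop = FALSE] -
    phi * y_or_x[1:(n - 1), , drop = FALSE]
  out
}

# Whitening matrix for ARMA(1,1) correlation rho(k) = rho1 * phi^(k-1),
# via the inverse Cholesky factor of the T x T correlation matrix.
whiten_arma11_matrix <- function(n, phi, rho1) {
  k <- abs(outer(seq_len(n), seq_len(n), `-`))
  R <- ifelse(k == 0, 1, rho1 * phi^(pmax(k - 1, 0)))
  ch <- chol(R)
  backsolve(ch, diag(n), transpose = TRUE)
}

# Moment-matching ARMA(1,1) estimate from residual autocorrelations r1, r2:
# phi = r2 / r1; theta solves r1 = (1 + phi*theta)(phi + theta) /
# (1 + 2*phi*theta + theta^2). Bounded to (-0.95, 0.95).
estimate_arma11 <- function(r1, r2) {
  phi <- ifelse(abs(r1) > 1e-8, r2 / r1, 0)
  phi <- pmin(pmax(phi, -0.95), 0.95)
  theta <- numeric(length(r1))
  for (i in seq_along(r1)) {
    f <- function(th) {
      (1 + phi[i] * th) * (phi[i] + th) /
        (1 + 2 * phi[i] * th + th^2) - r1[i]
    }
    lo <- f(-0.949); hi <- f(0.949)
    theta[i] <- if (is.finite(lo) && is.finite(hi) && lo * hi < 0)
      uniroot(f, c(-0.949, 0.949))$root else 0
  }
  list(phi = phi, theta = pmin(pmax(theta, -0.95), 0.95))
}

#' Generalized least squares fit with serially correlated noise
#'
#' Ordinary least squares first pass, a per-voxel noise model fit on the
#' residuals (`ar1`: lag-1 Yule-Walker with small-sample bias correction;
#' `arma11`: moment matching on lags 1-2), then a prewhitened refit. Noise
#' parameters are binned on a fine grid so whitening matrices are shared
#' between voxels.
#'
#' @param series a [complex_series()] (magnitude used), 4D numeric array, or
#'   a T x V numeric matrix of timeseries.
#' @param design a [build_design()] result or a plain T x p matrix.
#' @param noise_model `"ols"`, `"ar1"` or `"arma11"`.
#' @param contrasts optional named list of length-p contrast vectors.
#' @return list of class `glm_fit`: `beta`, `se`, `tstat` (p x V),
#'   `residuals` (T x V, from the whitened fit mapped back to the original
#'   scale for `ols`/diagnostics), `sigma2`, `dof`, `noise_params`,
#'   `contrast_beta`/`contrast_tstat` if contrasts given.
#' @export
glsq_fit <- function(series, design, noise_model = c("ols", "ar1", "arma11"),
                     contrasts = NULL) {
  noise_model <- match.arg(noise_model)
  Y <- if (is.matrix(series)) series else t(series_matrix(series, "magnitude"))
  if (any(!is.finite(Y))) stop("non-finite values in input series")
  X <- if (inherits(design, "design_matrix")) design$matrix else design
  n <- nrow(X); p <- ncol(X)
  if (p >= n) stop("design has p >= T")
  dof <- n - p

  qrX <- qr(X)
  beta_ols <- qr.coef(qrX, Y)
  res <- Y - X %*% beta_ols

  fit_with <- function(Xw, Yw) {
    XtX_inv <- chol2inv(chol(crossprod(Xw)))
    bet <- XtX_inv %*% crossprod(Xw, Yw)
    rw <- Yw - Xw %*% bet
    s2 <- colSums(rw^2) / dof
    se <- sqrt(outer(diag(XtX_inv), s2))
    list(beta = bet, se = se, sigma2 = s2, XtX_inv = XtX_inv, resid = rw)
  }

  noise_params <- NULL
  if (noise_model == "ols") {
    f <- fit_with(X, Y)
    out_res <- res
  } else {
    r0 <- colSums(res^2)
    r1 <- colSums(res[-1, , drop = FALSE] * res[-n, , drop = FALSE]) /
      pmax(r0, .Machine$double.eps)
    if (noise_model == "ar1") {
      # invert the design-induced bias of the residual lag-1 correlation:
      # for residuals r = M y with y ~ AR1(phi), E[r'Lr] / E[r'r] =
      # tr(MLM Sigma) / tr(M Sigma); solve for phi on a grid
      phi <- ar1_moment_invert(X, r1)
      # empirical-Bayes shrinkage across voxels: the sampling variance of a
      # lag-1 autocorrelation estimate is ~ (1 - phi^2) / T; shrink toward
      # the map mean by the usual moment rule, pooling fully when the map
      # is homogeneous and barely at all when real heterogeneity dominates
      if (length(phi) > 10) {
        v_i <- (1 - phi^2) / n
        tau2 <- max(0, stats::var(phi) - mean(v_i))
        w <- tau2 / (tau2 + v_i)
        phi <- pmin(pmax(mean(phi) + w * (phi - mean(phi)), -0.95), 0.95)
      }
      bins <- round(phi / 0.02) * 0.02
      beta <- matrix(NA_real_, p, ncol(Y))
      se <- matrix(NA_real_, p, ncol(Y))
      sigma2 <- numeric(ncol(Y))
      out_res <- matrix(NA_real_, n, ncol(Y))
      for (b in unique(bins)) {
        cols <- which(bins == b)
        Xw <- whiten_ar1(X, b)
        f <- fit_with(Xw, whiten_ar1(Y[, cols, drop = FALSE], b))
        beta[, cols] <- f$beta; se[, cols] <- f$se
        sigma2[cols] <- f$sigma2
        out_res[, cols] <- Y[, cols, drop = FALSE] - X %*% f$beta
      }
      noise_params <- list(phi = phi)
      f <- list(beta = beta, se = se, sigma2 = sigma2)
    } else {
      r2l <- colSums(res[-(1:2), , drop = FALSE] *
                       res[1:(n - 2), , drop = FALSE]) /
        pmax(r0, .Machine$double.eps)
      est <- estimate_arma11(r1, r2l)
      bphi <- round(est$phi / 0.05) * 0.05
      brho <- round(r1 / 0.05) * 0.05
      key <- paste(bphi, brho)
      beta <- matrix(NA_real_, p, ncol(Y))
      se <- matrix(NA_real_, p, ncol(Y))
      sigma2 <- numeric(ncol(Y))
      out_res <- matrix(NA_real_, n, ncol(Y))
      for (kk in unique(key)) {
        cols <- which(key == kk)
        W <- whiten_arma11_matrix(n, bphi[cols[1]],
                                  min(max(brho[cols[1]], -0.9), 0.9))
        f <- fit_with(W %*% X, W %*% Y[, cols, drop = FALSE])
        beta[, cols] <- f$beta; se[, cols] <- f$se
        sigma2[cols] <- f$sigma2
        out_res[, cols] <- Y[, cols, drop = FALSE] - X %*% f$beta
      }
      noise_params <- list(phi = est$phi, theta = est$theta)
      f <- list(beta = beta, se = se, sigma2 = sigma2)
    }
  }

  tstat <- f$beta / pmax(f$se, .Machine$double.eps)
  tstat[f$se == 0] <- NA_real_
  out <- list(beta = f$beta, se = f$se, tstat = tstat,
              residuals = out_res, sigma2 = f$sigma2, dof = dof,
              noise_model = noise_model, noise_params = noise_params,
              design = if (inherits(design, "design_matrix")) design
                       else NULL)
  if (!is.null(contrasts)) {
    XtX_inv <- chol2inv(chol(crossprod(X)))
    out$contrast_beta <- out$contrast_tstat <-
      matrix(NA_real_, length(contrasts), ncol(Y),
             dimnames = list(names(contrasts), NULL))
    for (i in seq_along(contrasts)) {
      cv <- contrasts[[i]]
      cb <- drop(crossprod(cv, f$beta))
      cse <- sqrt(drop(crossprod(cv, XtX_inv %*% cv)) * f$sigma2)
      out$contrast_beta[i, ] <- cb
      out$contrast_tstat[i, ] <- cb / pmax(cse, .Machine$double.eps)
    }
  }
  class(out) <- "glm_fit"
  out
}

#' Finite impulse response (FIR) fit
#'
#' Fits the TENT-basis GLM and reshapes the task coefficients into one
#' response-over-time curve per condition per voxel, in percent signal
#' change per lag. No assumption is made about response shape.
#'
#' @inheritParams glsq_fit
#' @param schedule stimulus schedule.
#' @param tent_window_s estimation window in seconds from onset.
#' @param drift_order Legendre drift order.
#' @return list of class `fir_fit`: `curves` (named list, condition ->
#'   lags x V matrix), `lags_s`, plus the underlying `glm_fit`.
#' @export
fir_fit <- function(series, schedule, tent_window_s = 21.6, drift_order = 1,
                    noise_model = "ols") {
  s <- if (is.matrix(series)) NULL else as_series(series)
  Tn <- if (is.matrix(series)) nrow(series) else n_volumes(s)
  tr <- if (is.matrix(series)) attr(series, "tr_s") %||% 1 else s$tr_s
  des <- build_design(schedule, Tn, tr, basis = "tent",
                      drift_order = drift_order,
                      tent_window_s = tent_window_s)
  fit <- glsq_fit(series, des, noise_model)
  n_lags <- length(des$tent_lags)
  curves <- list()
  for (i in seq_along(des$conditions)) {
    rows <- (i - 1L) * n_lags + seq_len(n_lags)
    curves[[des$conditions[i]]] <- fit$beta[rows, , drop = FALSE]
  }
  structure(list(curves = curves, lags_s = des$tent_lags, fit = fit,
                 design = des),
            class = "fir_fit")
}
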