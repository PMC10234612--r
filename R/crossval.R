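#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the observed mean; may be
#' negative for predictions worse than the mean.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2).
#' @return scalar; `NA` with a warning when the observed series has zero
#'   variance.
#' @export
r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    warning("zero-variance observed series: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / sst
}

# Column-wise R^2 for T x V matrices (SS_tot about each column mean).
r2_columns <- function(obs, pred) {
  sst <- colSums(sweep(obs, 2, colMeans(obs))^2)
  ssr <- colSums((obs - pred)^2)
  out <- 1 - ssr / sst
  # numerically zero variance (sd below 1e-6 in scaled units) is undefined
  out[sst <= 1e-12 * (nrow(obs) - 1)] <- NA_real_
  out
}

# Polynomial detrending order rule: run duration in minutes minus one,
# rounded down and floored at 1.
drift_order_rule <- function(n_volumes, tr_s) {
  max(1L, floor(n_volumes * tr_s / 60 - 1))
}

# Project out Legendre drift (order per the duration rule) per run.
detrend_matrix <- function(Y, order) {
  L <- legendre_basis(nrow(Y), order)
  Y - L %*% qr.coef(qr(L), Y)
}

# Concatenated multi-run design: shared task columns, run-specific drift.
concat_design <- function(schedules, run_idx, n_volumes, tr_s, basis,
                          drift_order, tent_window_s = 21.6,
                          hrf_params = list()) {
  blocks <- lapply(run_idx, function(r)
    build_design(schedules[[r]], n_volumes, tr_s, basis = basis,
                 drift_order = drift_order, tent_window_s = tent_window_s,
                 hrf_params = hrf_params))
  n <- length(run_idx)
  p_task <- length(blocks[[1]]$task_cols)
  p_drift <- length(blocks[[1]]$drift_cols)
  X <- matrix(0, n * n_volumes, p_task + n * p_drift)
  for (i in seq_len(n)) {
    rows <- (i - 1) * n_volumes + seq_len(n_volumes)
    X[rows, seq_len(p_task)] <- blocks[[i]]$matrix[, blocks[[i]]$task_cols]
    X[rows, p_task + (i - 1) * p_drift + seq_len(p_drift)] <-
      blocks[[i]]$matrix[, blocks[[i]]$drift_cols]
  }
  list(X = X, task_cols = seq_len(p_task), block = blocks[[1]])
}

#' Leave-one-out cross-validated R^2 map under a canonical HRF model
#'
#' For each held-out run, a canonical-HRF GLM is fitted to the remaining
#' runs (concatenated, run-wise drift); the estimated task component
#' predicts the held-out run, and R^2 is computed per voxel against the
#' polynomial-detrended held-out data. The fold-average map is the
#' voxel-selection map for the FIR cross-validation.
#'
#' @param runs list of N >= 2 scaled runs (matching grids).
#' @param schedules one schedule or a list of length N.
#' @param tr_s TR override for plain arrays.
#' @param drift_order `NULL`: run-duration rule.
#' @param hrf_params canonical HRF parameters.
#' @return 3D array of fold-averaged R^2.
#' @export
loo_canonical_r2_map <- function(runs, schedules, tr_s = NULL,
                                 drift_order = NULL, hrf_params = list()) {
  N <- length(runs)
  stopifnot(N >= 2)
  if (is.data.frame(schedules)) schedules <- rep(list(schedules), N)
  if (length(schedules) != N) stop("need one schedule per run")
  s1 <- as_series(runs[[1]])
  tr <- tr_s %||% s1$tr_s
  Tn <- n_volumes(s1)
  dims <- grid_dims(s1)
  ord <- drift_order %||% drift_order_rule(Tn, tr)
  Ys <- lapply(runs, function(r) t(series_matrix(as_series(r), "real")))
  acc <- 0
  for (h in seq_len(N)) {
    train <- setdiff(seq_len(N), h)
    des <- concat_design(schedules, train, Tn, tr, "canonical", ord,
                         hrf_params = hrf_params)
    Ytr <- do.call(rbind, Ys[train])
    beta <- qr.coef(qr(des$X), Ytr)
    des_h <- build_design(schedules[[h]], Tn, tr, basis = "canonical",
                          drift_order = ord, hrf_params = hrf_params)
    Xt <- des_h$matrix[, des_h$task_cols, drop = FALSE]
    pred <- detrend_matrix(Xt %*% beta[des$task_cols, , drop = FALSE], ord)
    obs <- detrend_matrix(Ys[[h]], ord)
    acc <- acc + r2_columns(obs, pred)
  }
  array(acc / N, dims)
}

#' Exhaustive leave-p-out FIR cross-validation
#'
#' For every training subset of `N - P` runs, the full FIR (TENT) model is
#' fitted on the concatenated training runs of the *training* data variant;
#' its response estimates predict each held-out run of the *test* variant.
#' Per-voxel R^2 against the detrended test data is averaged over voxels
#' passing each threshold on the selection map, then over held-out runs,
#' and finally summarized (mean and standard error) over all C(N, P)
#' subsets. Train and test sets may be different processings (e.g.
#' denoised vs standard) of the same session.
#'
#' @param train_runs,test_runs lists of N runs each, matching grids and
#'   schedules.
#' @param schedules one schedule or list of length N.
#' @param p_values held-out run counts (default 1..N-1).
#' @param thresholds selection-map thresholds (R^2 units, default 0.15).
#' @param mask_map 3D selection map, e.g. [loo_canonical_r2_map()] on the
#'   standard data.
#' @param tent_window_s FIR window, seconds.
#' @param tr_s TR override for plain arrays.
#' @param train_label,test_label labels stored in the output table.
#' @return data.frame of class `crossval_table`: one row per (P,
#'   threshold): `train_source`, `test_source`, `p_out`, `n_train`,
#'   `threshold`, `mean_r2`, `se_r2`, `n_perm`.
#' @export
lpo_fir_crossval <- function(train_runs, test_runs, schedules,
                             p_values = NULL, thresholds = 0.15,
                             mask_map = NULL, tent_window_s = 21.6,
                             tr_s = NULL, train_label = "train",
                             test_label = "test") {
  N <- length(train_runs)
  stopifnot(length(test_runs) == N, N >= 2)
  if (is.data.frame(schedules)) schedules <- rep(list(schedules), N)
  s1 <- as_series(train_runs[[1]])
  tr <- tr_s %||% s1$tr_s
  Tn <- n_volumes(s1)
  if (is.null(p_values)) p_values <- seq_len(N - 1)
  if (any(p_values < 1 | p_values > N - 1)) stop("P must be in 1..N-1")
  ord <- drift_order_rule(Tn, tr)
  Ytr_all <- lapply(train_runs, function(r)
    t(series_matrix(as_series(r), "real")))
  Yte_all <- lapply(test_runs, function(r)
    t(series_matrix(as_series(r), "real")))
  if (is.null(mask_map)) mask_map <- array(1, grid_dims(s1))
  mvec <- as.vector(mask_map)
  sel <- lapply(thresholds, function(th) which(mvec >= th))
  if (any(!vapply(sel, length, integer(1))))
    stop("a threshold selects no voxels")

  rows <- list()
  for (P in p_values) {
    n_train <- N - P
    subsets <- utils::combn(N, n_train)
    agg <- matrix(NA_real_, ncol(subsets), length(thresholds))
    for (si in seq_len(ncol(subsets))) {
      train <- subsets[, si]
      des <- concat_design(schedules, train, Tn, tr, "tent", ord,
                           tent_window_s = tent_window_s)
      beta <- qr.coef(qr(des$X),
                      do.call(rbind, Ytr_all[train]))
      held <- setdiff(seq_len(N), train)
      per_thr <- matrix(NA_real_, length(held), length(thresholds))
      for (hi in seq_along(held)) {
        h <- held[hi]
        des_h <- build_design(schedules[[h]], Tn, tr, basis = "tent",
                              drift_order = ord,
                              tent_window_s = tent_window_s)
        Xt <- des_h$matrix[, des_h$task_cols, drop = FALSE]
        pred <- detrend_matrix(Xt %*% beta[des$task_cols, , drop = FALSE],
                               ord)
        obs <- detrend_matrix(Yte_all[[h]], ord)
        r2v <- r2_columns(obs, pred)
        for (ti in seq_along(thresholds))
          per_thr[hi, ti] <- mean(r2v[sel[[ti]]], na.rm = TRUE)
      }
      agg[si, ] <- colMeans(per_thr)
    }
    for (ti in seq_along(thresholds)) {
      rows[[length(rows) + 1L]] <- data.frame(
        train_source = train_label, test_source = test_label,
        p_out = P, n_train = n_train, threshold = thresholds[ti],
        mean_r2 = mean(agg[, ti]),
        se_r2 = sd(agg[, ti]) / sqrt(nrow(agg)),
        n_perm = nrow(agg), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("crossval_table", class(out))
  out
}

#' Equivalent-runs readout
#'
#' Smallest number of standard training runs whose mean cross-validated R^2
#' matches or exceeds that of a single denoised training run (both
#' predicting standard data).
#'
#' @param standard_table `crossval_table` for standard->standard.
#' @param denoised_table `crossval_table` for denoised->standard (uses its
#'   `n_train == 1` row).
#' @param threshold selection threshold to read out at.
#' @return integer count, or `Inf` if never reached.
#' @export
equivalent_runs <- function(standard_table, denoised_table,
                            threshold = 0.15) {
  ref <- denoised_table$mean_r2[denoised_table$n_train == 1 &
                                  denoised_table$threshold == threshold]
  stopifnot(length(ref) == 1)
  st <- standard_table[standard_table$threshold == threshold, ]
  st <- st[order(st$n_train), ]
  hit <- which(st$mean_r2 >= ref)
  if (!length(hit)) Inf else st$n_train[hit[1]]
}
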