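# Neural tracking of acoustics: band predictors, multivariate temporal
# response functions by L1 coordinate boosting, unique-variance
# partitioning (delta r) and ROI scoring.

#' Band envelope and onset predictors
#'
#' Waveform mode (a numeric vector plus \code{fs_audio}): a 4th-order
#' Butterworth band-pass bank at log-spaced centers between 0.02 and
#' 5 kHz extracts band envelopes (rectify + 30 Hz low-pass), which are
#' power-law compressed with exponent 0.6, summed into
#' \code{n_bands} log-spaced bands and resampled to the EEG rate.
#' Synthetic mode (a band-series matrix at the EEG rate, e.g. from
#' \code{\link{make_band_predictors}}): the envelopes pass through
#' unchanged. Onset series are the half-wave-rectified first
#' differences of the band envelopes.
#'
#' @param x waveform vector or 8 x N (or 16 x N envelope+onset) matrix.
#' @param fs_audio waveform sampling rate (>= 10 kHz; waveform mode only).
#' @param fs_eeg EEG sampling rate (Hz).
#' @param n_bands number of output bands.
#' @param band_lims frequency limits (Hz) of the log-spaced bands.
#' @param exponent compressive exponent applied to waveform envelopes.
#' @return object of class \code{predictor_set}: \code{env},
#'   \code{ons} (n_bands x N, nonnegative), \code{fs}, \code{band_edges}.
#' @export
derive_predictors <- function(x, fs_audio = NULL, fs_eeg = 128,
                              n_bands = 8, band_lims = c(20, 5000),
                              exponent = 0.6) {
  if (is.matrix(x)) {
    if (nrow(x) == 2 * n_bands) {
      env <- x[seq_len(n_bands), , drop = FALSE]
      ons <- x[n_bands + seq_len(n_bands), , drop = FALSE]
    } else if (nrow(x) == n_bands) {
      env <- x
      ons <- t(apply(env, 1, function(e) pmax(c(0, diff(e)), 0)))
    } else {
      stopf("band-series input must have %d or %d rows", n_bands, 2 * n_bands)
    }
  } else {
    if (is.null(fs_audio) || fs_audio < 10000)
      stopf("waveform mode needs fs_audio >= 10 kHz")
    if (band_lims[2] >= fs_audio / 2)
      stopf("band edge %g Hz is outside Nyquist (%g Hz)",
            band_lims[2], fs_audio / 2)
    n_sub <- 4L * n_bands
    edges <- exp(seq(log(band_lims[1]), log(band_lims[2]),
                     length.out = n_sub + 1))
    lp <- signal::butter(4, 30 / (fs_audio / 2), type = "low")
    t_audio <- (seq_along(x) - 1) / fs_audio
    n_out <- floor(length(x) / fs_audio * fs_eeg)
    t_out <- (seq_len(n_out) - 1) / fs_eeg
    sub_env <- matrix(0, n_sub, n_out)
    for (b in seq_len(n_sub)) {
      bp <- signal::butter(4, c(edges[b], edges[b + 1]) / (fs_audio / 2),
                           type = "pass")
      bandsig <- signal::filter(bp, x)
      e <- as.numeric(signal::filter(lp, abs(bandsig)))
      e <- pmax(e, 0)^exponent
      sub_env[b, ] <- stats::approx(t_audio, e, xout = t_out, rule = 2)$y
    }
    env <- matrix(0, n_bands, n_out)
    for (b in seq_len(n_bands))
      env[b, ] <- colSums(sub_env[(b - 1) * 4 + 1:4, , drop = FALSE])
    ons <- t(apply(env, 1, function(e) pmax(c(0, diff(e)), 0)))
  }
  rownames(env) <- sprintf("env%02d", seq_len(n_bands))
  rownames(ons) <- sprintf("ons%02d", seq_len(n_bands))
  out <- list(env = env, ons = ons, fs = fs_eeg,
              band_edges = exp(seq(log(band_lims[1]), log(band_lims[2]),
                                   length.out = n_bands + 1)))
  class(out) <- "predictor_set"
  out
}

# Lagged design matrix: column (p-1)*L + l holds predictor p delayed by
# lag_idx[l] samples (zero-padded).
lagged_design <- function(pred, lag_idx) {
  P <- nrow(pred); N <- ncol(pred); L <- length(lag_idx)
  X <- matrix(0, N, P * L)
  cn <- character(P * L)
  for (p in seq_len(P)) for (l in seq_len(L)) {
    lag <- lag_idx[l]
    col <- (p - 1L) * L + l
    if (lag >= 0) {
      if (lag < N) X[(lag + 1L):N, col] <- pred[p, seq_len(N - lag)]
    } else {
      if (-lag < N) X[seq_len(N + lag), col] <- pred[p, (1L - lag):N]
    }
    cn[col] <- sprintf("%s@%d", rownames(pred)[p], lag)
  }
  colnames(X) <- cn
  X
}

#' Multivariate temporal response functions by L1 coordinate boosting
#'
#' Estimates, per electrode, the kernel mapping the lagged band
#' predictors to the EEG. Kernels start at zero; at each step the
#' single (band, lag) coordinate whose fixed-size increment most
#' reduces the training L1 error (selected through the L1 subgradient
#' correlation, then verified by an exact error evaluation) is applied.
#' Boosting stops per electrode when an increment no longer improves
#' the training error or when the validation L1 error has not improved
#' for \code{patience} steps; the kernel checkpoint with the best
#' validation error is kept. Cross-validation follows contiguous
#' segment blocks: per fold, the test block is held out, one rotating
#' training segment serves as validation, and the fold kernel predicts
#' the held-out EEG; prediction accuracy r is the Pearson correlation
#' between predicted and observed EEG per electrode, averaged over
#' folds.
#'
#' @param eeg E x N recording (microvolt).
#' @param pred P x N predictor matrix (rows named).
#' @param fs sampling rate (Hz).
#' @param segments data.frame (start_s, end_s) of the story segments.
#' @param lags kernel lag range in s, default c(-0.1, 0.5).
#' @param folds number of cross-validation folds.
#' @param step_frac increment size as a fraction of the response/
#'   predictor scale ratio.
#' @param max_steps cap on boosting steps per fold.
#' @param patience validation patience (steps).
#' @param basis_s width (s) of the Hamming basis window: each boosting
#'   increment adds a smooth bump of this width along the lag axis
#'   rather than a single-sample spike (0 disables). Implemented by
#'   boosting on window-smoothed predictors and convolving the
#'   coefficient kernel back with the window.
#' @return object of class \code{trf_model}: \code{kernels}
#'   (P x L x E, fold-averaged), \code{r} (per electrode, fold-averaged),
#'   \code{r_folds}, \code{lag_s}, \code{folds}, \code{zero_flag}.
#' @export
boost_trf <- function(eeg, pred, fs, segments, lags = c(-0.1, 0.5),
                      folds = 5, step_frac = 0.005, max_steps = 500,
                      patience = 10, basis_s = 0.05) {
  E <- nrow(eeg); N <- ncol(eeg)
  stopifnot(ncol(pred) == N)
  n_seg <- nrow(segments)
  if (n_seg < folds) stopf("need at least %d segments for %d folds", folds, folds)
  lag_idx <- round(lags[1] * fs):round(lags[2] * fs)
  L <- length(lag_idx)
  P <- nrow(pred)
  # Basis smoothing: boost on window-smoothed predictors; the selected
  # coefficients then expand to smooth bumps on the lag axis.
  basis_n <- if (basis_s > 0) max(1L, round(basis_s * fs)) else 1L
  if (basis_n > 1L) {
    w <- signal::hamming(basis_n)
    w <- w / sum(w)
    ctr <- floor((basis_n + 1) / 2)
    pred_b <- t(apply(pred, 1, function(x) {
      y <- stats::filter(x, w, method = "convolution", sides = 2)
      y[is.na(y)] <- 0
      as.numeric(y)
    }))
    rownames(pred_b) <- rownames(pred)
    Bl <- matrix(0, L, L)                  # lag-axis expansion matrix
    for (l in seq_len(L)) {
      lp <- l + seq_len(basis_n) - ctr
      ok <- lp >= 1 & lp <= L
      Bl[lp[ok], l] <- w[ok]
    }
  } else {
    pred_b <- pred
    Bl <- diag(L)
  }
  X <- lagged_design(pred_b, lag_idx)
  seg_rows <- lapply(seq_len(n_seg), function(s) {
    (floor(segments$start_s[s] * fs) + 1L):min(floor(segments$end_s[s] * fs), N)
  })
  fold_of_seg <- sort(rep_len(seq_len(folds), n_seg))
  kern_sum <- matrix(0, P * L, E)
  r_folds <- matrix(NA_real_, folds, E)
  zero_flag <- rep(FALSE, E)
  for (f in seq_len(folds)) {
    test_seg <- which(fold_of_seg == f)
    nontest <- setdiff(seq_len(n_seg), test_seg)
    val_seg <- nontest[((f - 1L) %% length(nontest)) + 1L]
    train_seg <- setdiff(nontest, val_seg)
    itr <- unlist(seg_rows[train_seg])
    iva <- unlist(seg_rows[val_seg])
    ite <- unlist(seg_rows[test_seg])
    Xtr <- X[itr, , drop = FALSE]
    Xva <- X[iva, , drop = FALSE]
    col_sd <- apply(Xtr, 2, stats::sd)
    dead <- col_sd == 0                      # all-zero predictors
    col_sd[dead] <- 1
    H <- matrix(0, P * L, E)
    Hbest <- H
    Ytr <- t(eeg[, itr, drop = FALSE])
    Yva <- t(eeg[, iva, drop = FALSE])
    Rtr <- Ytr
    Rva <- Yva
    tr_err <- colMeans(abs(Rtr))
    va_err <- colMeans(abs(Rva))
    best_va <- va_err
    fails <- integer(E)
    active <- rep(TRUE, E)
    y_sd <- apply(Ytr, 2, stats::sd)
    steps <- 0L
    while (any(active) && steps < max_steps) {
      steps <- steps + 1L
      act <- which(active)
      Sg <- crossprod(Xtr, sign(Rtr[, act, drop = FALSE]))  # (P*L) x n_act
      Sg[dead, ] <- 0
      gain <- abs(Sg) / col_sd
      for (k in seq_along(act)) {
        e <- act[k]
        j <- which.max(gain[, k])
        if (gain[j, k] == 0) { active[e] <- FALSE; next }
        d <- step_frac * y_sd[e] / col_sd[j] * sign(Sg[j, k])
        new_r <- Rtr[, e] - d * Xtr[, j]
        new_err <- mean(abs(new_r))
        if (new_err >= tr_err[e]) { active[e] <- FALSE; next }
        H[j, e] <- H[j, e] + d
        Rtr[, e] <- new_r
        tr_err[e] <- new_err
        Rva[, e] <- Rva[, e] - d * Xva[, j]
        va_err[e] <- mean(abs(Rva[, e]))
        if (va_err[e] < best_va[e]) {
          best_va[e] <- va_err[e]
          Hbest[, e] <- H[, e]
          fails[e] <- 0L
        } else {
          fails[e] <- fails[e] + 1L
          if (fails[e] >= patience) active[e] <- FALSE
        }
      }
    }
    Yte_hat <- X[ite, , drop = FALSE] %*% Hbest
    Yte <- t(eeg[, ite, drop = FALSE])
    for (e in seq_len(E)) {
      if (all(Hbest[, e] == 0) || stats::sd(Yte_hat[, e]) == 0) {
        r_folds[f, e] <- 0
        zero_flag[e] <- TRUE
      } else {
        r_folds[f, e] <- stats::cor(Yte_hat[, e], Yte[, e])
      }
    }
    kern_sum <- kern_sum + Hbest
  }
  # design columns were ordered (p-1)*L + l; expand coefficient kernels
  # through the basis window
  coef <- array(kern_sum / folds, c(L, P, E))
  for (p in seq_len(P)) for (e in seq_len(E))
    coef[, p, e] <- Bl %*% coef[, p, e]
  kernels <- aperm(coef, c(2, 1, 3))
  dimnames(kernels) <- list(rownames(pred), NULL, rownames(eeg))
  out <- list(kernels = kernels, r = colMeans(r_folds),
              r_folds = r_folds, lag_s = lag_idx / fs, folds = folds,
              zero_flag = zero_flag, predictors = rownames(pred))
  class(out) <- "trf_model"
  out
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("Boosting TRF: %d predictors x %d lags x %d electrodes, %d folds, mean r = %.4f\n",
              dim(x$kernels)[1], dim(x$kernels)[2], dim(x$kernels)[3],
              x$folds, mean(x$r)))
  invisible(x)
}

#' Unique predictor contribution to tracking accuracy
#'
#' Per-electrode difference in cross-validated prediction accuracy
#' between a full model and a model with one predictor family left out.
#'
#' @param full,reduced \code{\link{boost_trf}} models on the same EEG
#'   with the same fold geometry.
#' @return named numeric vector of per-electrode delta r.
#' @export
delta_r <- function(full, reduced) {
  if (full$folds != reduced$folds ||
      !identical(dim(full$kernels)[3], dim(reduced$kernels)[3]))
    stopf("full and reduced models must share folds and electrodes")
  full$r - reduced$r
}

#' Full/reduced TRF fits and unique-variance partitioning
#'
#' Fits the full model (envelope + onset), the two reduced models, and
#' returns the per-electrode delta r of each predictor family.
#'
#' @param eeg E x N recording.
#' @param predictors a \code{\link{derive_predictors}} set.
#' @param fs,segments,... passed to \code{\link{boost_trf}}.
#' @return list: \code{full}, \code{no_env}, \code{no_ons} models,
#'   \code{delta_env}, \code{delta_ons}.
#' @export
tracking_delta_r <- function(eeg, predictors, fs, segments, ...) {
  full <- boost_trf(eeg, rbind(predictors$env, predictors$ons), fs,
                    segments, ...)
  no_env <- boost_trf(eeg, predictors$ons, fs, segments, ...)
  no_ons <- boost_trf(eeg, predictors$env, fs, segments, ...)
  list(full = full, no_env = no_env, no_ons = no_ons,
       delta_env = delta_r(full, no_env),
       delta_ons = delta_r(full, no_ons))
}

#' ROI definition and per-participant tracking scores
#'
#' Pools all participants' delta-r topographies, finds the electrodes
#' with significantly greater-than-zero delta r (one-tailed one-sample
#' cluster-mass permutation test), and scores each participant as the
#' mean delta r over that region of interest.
#'
#' @param delta_mat participants x electrodes matrix of delta r.
#' @param adjacency electrode adjacency (see
#'   \code{\link{electrode_adjacency}}).
#' @param alpha corrected cluster significance level.
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list: \code{roi} (electrode indices; empty flagged),
#'   \code{scores} (per participant; NA when the ROI is empty),
#'   \code{cluster_test}.
#' @export
roi_score <- function(delta_mat, adjacency, alpha = 0.05,
                      n_perm = 10000, seed = 1L) {
  if (nrow(delta_mat) < 8)
    stopf("ROI definition needs >= 8 participants pooled across groups")
  ct <- cluster_permutation_test(delta_mat, "one_sample",
                                 adjacency = adjacency, n_perm = n_perm,
                                 seed = seed)
  roi <- significant_sites(ct, alpha)   # one-tailed: all clusters positive
  scores <- if (length(roi)) rowMeans(delta_mat[, roi, drop = FALSE])
            else rep(NA_real_, nrow(delta_mat))
  list(roi = roi, empty = length(roi) == 0, scores = scores,
       cluster_test = ct)
}
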