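# Reference-based attribution of classifier decisions to electrodes x
# time, and the dispersion / peak-latency statistics derived from it.

#' Attribute a classifier decision to the input
#'
#' Backpropagates the pre-soft-max output of the target phoneme to the
#' input through the trained network, producing an E x T contribution
#' matrix: positive and negative entries are evidence for and against
#' the target, zero is irrelevance. The default rule is a rescale-style
#' reference backpropagation against the all-zero reference input (the
#' natural rest point of band-passed, baseline-free EEG): linear stages
#' propagate through their weights, and each nonlinearity multiplies by
#' the ratio of its output difference to its input difference relative
#' to the reference. This construction satisfies the completeness axiom
#' -- the contributions sum to the difference between the target's
#' pre-soft-max output at the input and at the reference -- which is
#' verified numerically on every call (a violation signals an
#' implementation bug and raises an error). A gradient-times-input rule
#' is available as a fallback; the two agree exactly on linear networks.
#'
#' @param model a trained network (one fold model of
#'   \code{\link{train_eval_cv}} run with \code{keep_models = TRUE}).
#' @param x input matrix E x T (standardized as during training).
#' @param target integer class index or label.
#' @param rule "rescale" (reference-based, default) or "gradxinput".
#' @param tol relative tolerance of the completeness check.
#' @return E x T contribution matrix with attribute \code{delta_logit}.
#' @export
attribute <- function(model, x, target, rule = c("rescale", "gradxinput"),
                      tol = 1e-3) {
  rule <- match.arg(rule)
  d <- model$dims
  stopifnot(nrow(x) == d$E, ncol(x) == d$Tn)
  if (is.character(target)) target <- match(target, model$labels)
  if (is.na(target) || target < 1 || target > d$K)
    stopf("target must be a class index in 1..%d or a known label", d$K)
  X <- array(x, c(1L, d$E, d$Tn))
  fw <- net_forward(model, X)
  onehot <- matrix(0, 1L, d$K)
  onehot[1, target] <- 1
  if (rule == "rescale") {
    ref <- net_forward(model, array(0, c(1L, d$E, d$Tn)))
    mult1 <- delta_ratio(fw$cache$ZbM, ref$cache$ZbM)
    mult2 <- delta_ratio(fw$cache$Z5, ref$cache$Z5)
  } else {
    mult1 <- elu_grad(fw$cache$ZbM)
    mult2 <- elu_grad(fw$cache$Z5)
  }
  bw <- net_backward(model, fw$cache, onehot, mult1, mult2,
                     want_param_grads = FALSE)
  contrib <- matrix(bw$dinput, d$E, d$Tn) * x     # x - reference, ref = 0
  if (rule == "rescale") {
    delta <- fw$logits[1, target] - ref$logits[1, target]
    err <- abs(sum(contrib) - delta) / max(abs(delta), 1e-8)
    if (abs(sum(contrib) - delta) > 1e-8 && err > tol)
      stopf("attribution completeness violated: sum %.6g vs output difference %.6g (relative error %.3g)",
            sum(contrib), delta, err)
    attr(contrib, "delta_logit") <- delta
  }
  contrib
}

# Finite-difference multiplier of the ELU nonlinearity between an input
# and its reference pre-activation; falls back to the local derivative
# where the difference vanishes.
delta_ratio <- function(zx, zref, eps = 1e-7) {
  dz <- zx - zref
  small <- abs(dz) < eps
  out <- (elu(zx) - elu(zref)) / dz
  out[small] <- elu_grad(zx)[small]
  out
}

# Attribute every test sample of a cv_result by its own test-fold model
# (no train/test leakage in relevance). Returns, per participant, the
# list of contribution matrices (one per decoded phoneme).
attribute_cv <- function(cv, rule = "rescale") {
  if (is.null(cv$models))
    stopf("run train_eval_cv with keep_models = TRUE before attribution")
  out <- list()
  for (i in seq_len(nrow(cv$samples))) {
    model <- cv$models[[cv$fold[i]]]
    m <- attribute(model, matrix(cv$X[i, , ], dim(cv$X)[2], dim(cv$X)[3],
                              dimnames = list(cv$electrodes, NULL)),
                   cv$y[i], rule = rule)
    id <- cv$samples$participant[i]
    out[[id]] <- c(out[[id]], list(m))
  }
  out
}

#' Relevance map of one participant
#'
#' Takes the absolute value of each contribution matrix, z-transforms it
#' over all its E x T entries (relative relevance within the matrix),
#' and averages the transformed matrices (across phonemes and
#' repetitions) into a single E x T map. Matrices with zero variance
#' carry no relative information and are excluded with a warning.
#'
#' @param mats list of E x T contribution matrices (see
#'   \code{\link{attribute}}).
#' @param fs sampling rate (Hz) of the PRP time axis.
#' @return object of class \code{relevance_map}: \code{scores} (E x T),
#'   \code{fs}, \code{n_matrices} averaged.
#' @export
relevance_map <- function(mats, fs) {
  zs <- list()
  for (m in mats) {
    a <- abs(m)
    s <- stats::sd(a)
    if (!is.finite(s) || s == 0) {
      warnf("a contribution matrix has zero variance; excluded from the relevance map")
      next
    }
    zs[[length(zs) + 1L]] <- (a - mean(a)) / s
  }
  if (length(zs) == 0)
    stopf("no contribution matrix with nonzero variance; relevance map undefined")
  out <- list(scores = Reduce(`+`, zs) / length(zs), fs = fs,
              n_matrices = length(zs))
  class(out) <- "relevance_map"
  out
}

#' Relevance dispersion
#'
#' Time-average of the relevance scores per electrode, then the variance
#' of these E values across electrodes (denominator E - 1). Smaller
#' dispersion indicates more spatially distributed relevance.
#'
#' @param map a \code{\link{relevance_map}}.
#' @return nonnegative variance (unitless).
#' @export
dispersion <- function(map) {
  em <- rowMeans(map$scores)
  if (length(em) < 2) stopf("dispersion needs at least 2 electrodes")
  stats::var(em)
}

#' Relevance peak latency
#'
#' Averages relevance over electrodes at each time point and returns the
#' latency (ms after PRP onset) at which the mean relevance is maximal;
#' ties resolve to the earliest time point (flagged).
#'
#' @param map a \code{\link{relevance_map}}.
#' @return latency in ms with attribute \code{tie} (logical).
#' @export
peak_latency <- function(map) {
  tc <- colMeans(map$scores)
  i <- which.max(tc)
  out <- 1000 * (i - 1) / map$fs
  attr(out, "tie") <- sum(tc == max(tc)) > 1
  out
}

#' Per-participant relevance summary table
#'
#' Builds one relevance map per participant from attribution matrices
#' (e.g. \code{repeat_protocol(..., keep_attributions = TRUE)}) and
#' tabulates dispersion and peak latency.
#'
#' @param attributions named list (participant -> list of contribution
#'   matrices).
#' @param fs sampling rate (Hz).
#' @return data.frame (id, dispersion, peak_latency_ms) plus a
#'   \code{maps} attribute holding the per-participant maps.
#' @export
relevance_table <- function(attributions, fs) {
  maps <- lapply(attributions, relevance_map, fs = fs)
  out <- data.frame(
    id = names(maps),
    dispersion = vapply(maps, dispersion, 0),
    peak_latency_ms = vapply(maps, function(m) as.numeric(peak_latency(m)), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "maps") <- maps
  out
}
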