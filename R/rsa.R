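# Representational similarity analysis: feature / neural / confusion
# RDMs, Spearman alignment, forward electrode selection, permutation
# testing and hierarchical clustering of phonemes.

new_rdm <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  if (max(abs(m - t(m))) > 1e-12) stopf("RDM must be symmetric")
  diag(m) <- 0
  if (any(m < 0)) stopf("RDM entries must be nonnegative")
  class(m) <- c("rdm", class(m))
  m
}

upper_tri <- function(m) m[upper.tri(m)]

#' Feature RDM from binary phonetic features
#'
#' Pairwise Euclidean distances between the phonemes' 0/1 feature
#' vectors, restricted to a feature subset.
#'
#' @param inventory a \code{\link{make_inventory}} table (or any object
#'   with a \code{features} 0/1 matrix).
#' @param feature_subset feature names to use (default: all).
#' @return K x K \code{rdm} matrix (symmetric, zero diagonal).
#' @export
feature_rdm <- function(inventory,
                        feature_subset = colnames(inventory$features)) {
  feats <- inventory$features
  unknown <- setdiff(feature_subset, colnames(feats))
  if (length(unknown))
    stopf("unknown feature name(s): %s", paste(unknown, collapse = ", "))
  if (length(feature_subset) == 0) stopf("feature subset must be non-empty")
  new_rdm(as.matrix(stats::dist(feats[, feature_subset, drop = FALSE])),
          rownames(feats))
}

#' Time-resolved neural RDMs from PRPs
#'
#' At each time step, the Euclidean distance between the electrode
#' vectors of every phoneme pair.
#'
#' @param prp_set a \code{\link{extract_prps}} result.
#' @param electrodes electrode names or indices to use (>= 1).
#' @return K x K x T array; each slice is a valid RDM.
#' @export
neural_rdm_series <- function(prp_set,
                              electrodes = rownames(prp_set$prps[[1]])) {
  if (length(electrodes) == 0) stopf("electrode subset must be non-empty")
  labels <- names(prp_set$prps)
  if (length(labels) < 3) stopf("need at least 3 phonemes")
  Tn <- ncol(prp_set$prps[[1]])
  K <- length(labels)
  out <- array(0, c(K, K, Tn), dimnames = list(labels, labels, NULL))
  # K x electrodes matrix per time step
  dat <- array(0, c(K, length(electrodes), Tn))
  for (i in seq_len(K))
    dat[i, , ] <- prp_set$prps[[i]][electrodes, , drop = FALSE]
  for (t in seq_len(Tn))
    out[, , t] <- as.matrix(stats::dist(dat[, , t, drop = TRUE]))
  out
}

spearman_rho <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(structure(0, degenerate = TRUE))
  stats::cor(a, b, method = "spearman")
}

#' Featural-neural alignment curve
#'
#' Spearman rank correlation between the strict upper triangles of each
#' time step's neural RDM and the feature RDM; higher rho means better
#' alignment of the neural dissimilarity structure with the phonetic
#' feature geometry. Time steps with a constant RDM are recorded as 0
#' (degenerate).
#'
#' @param neural K x K x T array from \code{\link{neural_rdm_series}}.
#' @param feature K x K feature \code{rdm} with matching labels.
#' @param fs sampling rate (Hz) to lay out the time axis; optional.
#' @return data.frame (time_s if fs given, rho, degenerate).
#' @export
alignment <- function(neural, feature, fs = NULL) {
  nl <- dimnames(neural)[[1]]
  if (!setequal(rownames(feature), nl))
    stopf("neural and feature RDM labels do not match")
  feature <- feature[nl, nl]                     # align label order
  fvec <- upper_tri(unclass(feature))
  Tn <- dim(neural)[3]
  rho <- numeric(Tn)
  degen <- logical(Tn)
  for (t in seq_len(Tn)) {
    r <- spearman_rho(upper_tri(neural[, , t]), fvec)
    rho[t] <- r
    degen[t] <- isTRUE(attr(r, "degenerate"))
  }
  out <- data.frame(rho = rho, degenerate = degen)
  if (!is.null(fs)) out <- cbind(time_s = (seq_len(Tn) - 1) / fs, out)
  out
}

#' Forward electrode selection for featural alignment
#'
#' Starting from the two most relevant electrodes, iteratively adds the
#' next electrode in the relevance ranking and recomputes the overall
#' alignment (mean rho over time and participants); stops the first time
#' the overall rho fails to strictly increase and returns the last
#' improving set. Deterministic.
#'
#' @param prp_sets list of PRP sets (one group).
#' @param ranked_electrodes electrode names ordered by decreasing
#'   relevance (e.g. from the group-mean relevance map).
#' @param feature feature \code{rdm}.
#' @return list: \code{electrodes}, \code{rho} (best overall), and the
#'   \code{trace} of overall rho per candidate set size.
#' @export
forward_select <- function(prp_sets, ranked_electrodes, feature) {
  if (length(ranked_electrodes) < 2)
    stopf("forward selection needs at least 2 ranked electrodes")
  overall <- function(els) {
    mean(vapply(prp_sets, function(ps)
      mean(alignment(neural_rdm_series(ps, els), feature)$rho), 0))
  }
  current <- ranked_electrodes[1:2]
  best <- overall(current)
  trace <- best
  for (j in seq_len(length(ranked_electrodes))[-(1:2)]) {
    cand <- ranked_electrodes[seq_len(j)]
    val <- overall(cand)
    trace <- c(trace, val)
    if (val > best) {
      current <- cand
      best <- val
    } else break
  }
  list(electrodes = current, rho = best, trace = trace)
}

#' RDM from a classifier confusion matrix
#'
#' Rows are normalized to conditional prediction probabilities, the
#' matrix is symmetrized, and dissimilarity is one minus similarity with
#' the diagonal forced to zero.
#'
#' @param confusion K x K matrix of counts (true x predicted).
#' @return K x K \code{rdm}.
#' @export
confusion_rdm <- function(confusion) {
  rs <- rowSums(confusion)
  if (any(rs == 0))
    stopf("confusion matrix has empty row(s): %s",
          paste(rownames(confusion)[rs == 0], collapse = ", "))
  P <- confusion / rs
  S <- (P + t(P)) / 2
  D <- 1 - S
  diag(D) <- 0
  new_rdm(D, rownames(confusion))
}

#' Permutation test of a group difference in confusion-RDM alignment
#'
#' The observed statistic is the difference in Spearman alignment
#' (confusion RDM vs feature RDM, strict upper triangle) between two
#' groups' confusion matrices. The null distribution is built by
#' independently shuffling the rows of both confusion matrices and
#' recomputing the difference. As printed in the source protocol, the
#' reported one-sided p is the proportion of null differences smaller
#' than the observed one, so both p near 0 and p near 1 are extreme
#' under the null.
#'
#' @param conf_a,conf_b confusion matrices with matching labels.
#' @param feature feature \code{rdm}.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param smoothing add-one smoothing of the p value (off by default,
#'   as printed).
#' @return list: \code{rho_a}, \code{rho_b}, \code{delta_rho}, \code{p},
#'   \code{n_perm}.
#' @export
permutation_rho_difference <- function(conf_a, conf_b, feature,
                                       n_perm = 5000, seed = 1L,
                                       smoothing = FALSE) {
  if (!identical(rownames(conf_a), rownames(conf_b)) ||
      !identical(rownames(conf_a), rownames(feature)))
    stopf("confusion matrices and feature RDM must share labels")
  if (n_perm < 100) warnf("n_perm = %d is very small", n_perm)
  fvec <- upper_tri(unclass(feature))
  rho_of <- function(cm) as.numeric(spearman_rho(upper_tri(unclass(confusion_rdm(cm))), fvec))
  rho_a <- rho_of(conf_a)
  rho_b <- rho_of(conf_b)
  obs <- rho_a - rho_b
  K <- nrow(conf_a)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    pa <- conf_a[sample.int(K), ]
    pb <- conf_b[sample.int(K), ]
    rownames(pa) <- rownames(conf_a)
    rownames(pb) <- rownames(conf_b)
    rho_of(pa) - rho_of(pb)
  }, 0))
  p <- if (smoothing) (sum(null < obs) + 1) / (n_perm + 1) else mean(null < obs)
  list(rho_a = rho_a, rho_b = rho_b, delta_rho = obs, p = p, n_perm = n_perm)
}

#' Hierarchical clustering of phonemes from PRPs
#'
#' Average-linkage agglomerative clustering of the phonemes on Euclidean
#' distances between PRPs flattened over (electrodes x window samples).
#'
#' @param prp_set a PRP set.
#' @param electrodes electrodes to include.
#' @param window time window (s) relative to PRP onset, default
#'   c(0, 0.35).
#' @return an \code{hclust} tree with phoneme labels.
#' @export
phoneme_dendrogram <- function(prp_set,
                               electrodes = rownames(prp_set$prps[[1]]),
                               window = c(0, 0.35)) {
  labels <- names(prp_set$prps)
  if (length(labels) < 3) stopf("need at least 3 phonemes")
  w <- prp_set$window
  if (window[1] < w[1] || window[2] > w[2])
    stopf("window [%g, %g] outside the PRP window [%g, %g]",
          window[1], window[2], w[1], w[2])
  i0 <- floor((window[1] - w[1]) * prp_set$fs) + 1L
  i1 <- floor((window[2] - w[1]) * prp_set$fs)
  feat <- t(vapply(labels, function(lab)
    as.vector(prp_set$prps[[lab]][electrodes, i0:i1, drop = FALSE]),
    numeric(length(electrodes) * (i1 - i0 + 1L))))
  stats::hclust(stats::dist(feat), method = "average")
}
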