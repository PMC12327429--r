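# Statistical layer: PRP separability F-curve, cluster-mass permutation
# tests, group tests, behavioral transforms, backward stepwise AIC
# regression and residual group analysis.

#' Phoneme separability F-curve
#'
#' At each time step and electrode, the one-way ratio of
#' between-phoneme to within-phoneme variability is computed with
#' phonemes as groups and participants as replicates; electrode ratios
#' are averaged into F(t). Higher values indicate greater category
#' separation. Points with zero within-phoneme variance are flagged
#' undefined (NaN), never silently zeroed.
#'
#' @param prp_sets list of PRP sets with identical labels (one group).
#' @return data.frame (time_s, F, undefined).
#' @export
separability_f <- function(prp_sets) {
  labels <- names(prp_sets[[1]]$prps)
  n <- length(prp_sets)
  if (n < 2) stopf("need at least 2 participants per phoneme")
  d <- dim(prp_sets[[1]]$prps[[1]])
  K <- length(labels)
  # participants x phonemes x electrodes x time
  A <- array(0, c(n, K, d[1], d[2]))
  for (i in seq_len(n)) for (k in seq_len(K)) {
    if (!identical(names(prp_sets[[i]]$prps), labels))
      stopf("participant %d has different phoneme labels", i)
    A[i, k, , ] <- prp_sets[[i]]$prps[[k]]
  }
  mean_k <- colMeans(A)                         # phoneme means: K x E x T
  grand <- colMeans(mean_k)                     # E x T
  ssb <- n * colSums(sweep(mean_k, c(2, 3), grand)^2)      # E x T
  ssw <- apply((A - rep(mean_k, each = n))^2, c(3, 4), sum)
  msb <- ssb / (K - 1)
  msw <- ssw / (K * (n - 1))
  Fmat <- msb / msw                             # E x T
  Fmat[msw == 0] <- NaN
  Fcurve <- colMeans(Fmat)
  data.frame(time_s = (seq_len(d[2]) - 1) / prp_sets[[1]]$fs,
             F = Fcurve, undefined = !is.finite(Fcurve))
}

#' Neighborhood structure of an electrode layout
#'
#' Electrodes within \code{factor} times the median nearest-neighbor
#' distance of each other are neighbors.
#'
#' @param layout E x 2 coordinate matrix.
#' @param factor distance multiplier.
#' @return E x E logical adjacency matrix (FALSE diagonal).
#' @export
electrode_adjacency <- function(layout, factor = 1.5) {
  D <- as.matrix(stats::dist(layout))
  diag(D) <- Inf
  med_nn <- stats::median(apply(D, 1, min))
  adj <- D <= factor * med_nn
  dimnames(adj) <- list(rownames(layout), rownames(layout))
  adj
}

# Connected components among the TRUE entries of `active` under `adj`.
connected_clusters <- function(active, adj) {
  idx <- which(active)
  if (length(idx) == 0) return(list())
  seen <- rep(FALSE, length(active))
  clusters <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v)
        which(adj[v, ] & active & !seen))))
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  clusters
}

# Mass-univariate t values per site. one_sample: t of the column means
# against zero; independent: Welch t between the rows of groups 1 and 2.
site_t <- function(data, groups = NULL) {
  if (is.null(groups)) {
    n <- nrow(data)
    m <- colMeans(data)
    se <- sqrt(apply(data, 2, stats::var) / n)
    list(t = m / se, df = rep(n - 1, ncol(data)))
  } else {
    a <- data[groups == 1L, , drop = FALSE]
    b <- data[groups == 2L, , drop = FALSE]
    va <- apply(a, 2, stats::var) / nrow(a)
    vb <- apply(b, 2, stats::var) / nrow(b)
    tt <- (colMeans(a) - colMeans(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (nrow(a) - 1) + vb^2 / (nrow(b) - 1))
    list(t = tt, df = df)
  }
}

#' Cluster-mass permutation test on topographies (or time courses)
#'
#' Mass-univariate t tests per site with a cluster-forming threshold at
#' uncorrected p <= 0.05, connected supra-threshold sites joined into
#' clusters under the adjacency, and a corrected p per cluster from the
#' permutation distribution of the maximum absolute cluster mass
#' (sign flips for the one-sample design, one-tailed; group-label
#' exchanges for the independent design, two-tailed). The largest
#' absolute t in each cluster (t_max) is reported as an effect-size
#' estimate.
#'
#' @param data n x S matrix (participants x sites); sites may be
#'   electrodes or time points.
#' @param design "one_sample" (test against zero, one-tailed positive)
#'   or "independent" (two-tailed Welch).
#' @param groups for the independent design, a vector of 1/2 group
#'   labels of length n.
#' @param adjacency S x S logical neighbor matrix (e.g.
#'   \code{\link{electrode_adjacency}}; a chain for time courses).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param alpha cluster-forming uncorrected threshold.
#' @return object of class \code{cluster_result}: list of clusters
#'   (sites, mass, sign, t_max, p), the t map, threshold, n_perm, seed.
#' @export
cluster_permutation_test <- function(data, design = c("one_sample", "independent"),
                                     groups = NULL, adjacency,
                                     n_perm = 10000, seed = 1L,
                                     alpha = 0.05) {
  design <- match.arg(design)
  S <- ncol(data)
  if (!identical(dim(adjacency), c(S, S)))
    stopf("adjacency must be %d x %d", S, S)
  comp_all <- connected_clusters(rep(TRUE, S), adjacency)
  if (length(comp_all) > 1)
    warnf("adjacency has %d disconnected components", length(comp_all))
  if (design == "one_sample") {
    if (nrow(data) < 4) stopf("need >= 4 participants")
    tails <- 1L
    st <- site_t(data)
    thr <- stats::qt(1 - alpha, st$df)
  } else {
    if (is.null(groups) || length(groups) != nrow(data))
      stopf("independent design needs a groups vector of length n")
    if (min(table(groups)) < 4) stopf("need >= 4 participants per group")
    tails <- 2L
    st <- site_t(data, groups)
    thr <- stats::qt(1 - alpha / 2, st$df)
  }
  obs <- t_clusters2(st$t, thr, adjacency, tails)
  null_max <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    if (design == "one_sample") {
      flips <- sample(c(-1, 1), nrow(data), replace = TRUE)
      stp <- site_t(data * flips)
    } else {
      stp <- site_t(data, sample(groups))
    }
    thrp <- stats::qt(1 - alpha / tails, stp$df)
    cl <- t_clusters2(stp$t, thrp, adjacency, tails)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, function(x) x$mass, 0)))
  }, 0))
  clusters <- lapply(obs, function(cl) {
    tt <- st$t[cl$sites]
    cl$t_max <- tt[which.max(abs(tt))]
    cl$p <- mean(null_max >= abs(cl$mass))
    cl$site_names <- colnames(data)[cl$sites]
    cl
  })
  out <- list(clusters = clusters, t = st$t, threshold = thr,
              design = design, n_perm = n_perm, seed = seed,
              alpha = alpha)
  class(out) <- "cluster_result"
  out
}

# Supra-threshold clusters of one t map and their masses; thr may be a
# per-site vector (Welch df varies by site).
t_clusters2 <- function(tt, thr, adj, tails) {
  out <- list()
  if (tails >= 1) {
    for (cl in connected_clusters(tt >= thr, adj))
      out[[length(out) + 1L]] <- list(sites = cl, mass = sum(tt[cl]), sign = 1L)
  }
  if (tails == 2) {
    for (cl in connected_clusters(tt <= -thr, adj))
      out[[length(out) + 1L]] <- list(sites = cl, mass = sum(tt[cl]), sign = -1L)
  }
  out
}

#' Significant sites of a cluster test
#'
#' @param x a \code{cluster_result}.
#' @param alpha corrected significance level.
#' @return integer vector of site indices in significant clusters.
#' @export
significant_sites <- function(x, alpha = 0.05) {
  sort(unique(unlist(lapply(x$clusters, function(cl)
    if (cl$p < alpha) cl$sites))))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test (%s, %d permutations): %d cluster(s)\n",
              x$design, x$n_perm, length(x$clusters)))
  for (cl in x$clusters)
    cat(sprintf("  %d sites, mass %.2f, t_max %.3f, p = %.4f\n",
                length(cl$sites), cl$mass, cl$t_max, cl$p))
  invisible(x)
}

#' Two-group tests
#'
#' Welch's unequal-variance t test (with Satterthwaite df, Cohen's d and
#' the 95% CI of the mean difference) or the Mann-Whitney U test with
#' tie-corrected normal approximation z (no continuity correction). U is
#' the number of (a, b) pairs with a > b (ties count 1/2).
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param kind "welch" or "mann_whitney".
#' @return list of statistic(s), p, and an effect descriptor.
#' @export
group_tests <- function(a, b, kind = c("welch", "mann_whitney")) {
  kind <- match.arg(kind)
  if (length(a) < 2 || length(b) < 2) stopf("each group needs n >= 2")
  degenerate <- stats::sd(c(a, b)) == 0
  if (kind == "welch") {
    if (degenerate)
      return(list(kind = kind, t = 0, df = length(a) + length(b) - 2, p = 1,
                  cohens_d = 0, ci = c(0, 0), degenerate = TRUE))
    tt <- stats::t.test(a, b, var.equal = FALSE)
    sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    list(kind = kind, t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, cohens_d = (mean(a) - mean(b)) / sp,
         ci = unname(tt$conf.int), degenerate = FALSE)
  } else {
    n1 <- length(a); n2 <- length(b)
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    N <- n1 + n2
    ties <- table(c(a, b))
    tie_term <- sum(ties^3 - ties)
    v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (v <= 0)
      return(list(kind = kind, U = U, z = 0, p = 1, degenerate = TRUE))
    z <- (U - n1 * n2 / 2) / sqrt(v)
    list(kind = kind, U = U, z = z, p = 2 * stats::pnorm(-abs(z)),
         degenerate = FALSE)
  }
}

#' Rationalized arcsine transform of a proportion-correct score
#'
#' Linearized arcsine units that stabilize variance near floor and
#' ceiling: \code{(146/pi) * (asin(sqrt(x/(n+1))) + asin(sqrt((x+1)/(n+1)))) - 23}.
#' Maps n/2 of n to exactly 50 and is strictly increasing in x.
#'
#' @param correct number correct (0..total).
#' @param total number of trials (>= 1).
#' @return score in rationalized arcsine units.
#' @export
rau <- function(correct, total) {
  if (total < 1 || any(correct < 0) || any(correct > total))
    stopf("need 0 <= correct <= total, total >= 1")
  th <- asin(sqrt(correct / (total + 1))) + asin(sqrt((correct + 1) / (total + 1)))
  (146 / pi) * th - 23
}

#' SNR loss from a words-in-noise score
#'
#' \code{26 - 0.4 * n} dB, where n is the number of words (of 70)
#' correctly identified; the SNR at which 50% recognition is reached.
#'
#' @param n_correct number correct, 0..70.
#' @return SNR loss in dB.
#' @export
snr_loss <- function(n_correct) {
  if (any(n_correct < 0) || any(n_correct > 70))
    stopf("n_correct must be in 0..70")
  26 - 0.4 * n_correct
}

#' Normalizing transform of an extended-high-frequency threshold
#'
#' Natural log of (threshold + 25) dB HL; the offset keeps the argument
#' positive for thresholds down to -25 dB HL.
#'
#' @param threshold_db threshold in dB HL (> -25).
#' @return transformed value.
#' @export
ehf_transform <- function(threshold_db) {
  if (any(threshold_db <= -25))
    stopf("threshold must exceed -25 dB HL")
  log(threshold_db + 25)
}

#' Above-chance test of decoding accuracy
#'
#' One-sample Wilcoxon signed-rank test of per-participant accuracies
#' against the uniform-guessing chance level 1/K, with the normal
#' approximation z.
#'
#' @param accuracies per-participant accuracy proportions.
#' @param n_classes number of decoded classes K.
#' @return list: \code{chance} (proportion), \code{V}, \code{z},
#'   \code{p} (two-sided).
#' @export
above_chance_test <- function(accuracies, n_classes) {
  chance <- 1 / n_classes
  wt <- stats::wilcox.test(accuracies, mu = chance, exact = FALSE,
                           correct = FALSE)
  d <- accuracies - chance
  d <- d[d != 0]
  n <- length(d)
  mu_v <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                  sum(ties^3 - ties) / 48)
  z <- if (sig_v > 0) (unname(wt$statistic) - mu_v) / sig_v else 0
  list(chance = chance, V = unname(wt$statistic), z = z, p = wt$p.value)
}

aic_of <- function(fit) {
  n <- length(fit$residuals)
  rss <- sum(fit$residuals^2)
  k <- length(stats::coef(fit)) - 1L          # fitted slopes
  n * log(rss / n) + 2 * (k + 1)
}

#' Backward stepwise regression by AIC
#'
#' z-scores the predictors, fits ordinary least squares, and repeatedly
#' removes the single predictor whose removal lowers
#' \code{AIC = n log(RSS/n) + 2(k+1)} the most, stopping when no removal
#' lowers it. Rows with missing values are dropped first (listwise).
#'
#' @param outcome numeric response.
#' @param predictors data.frame of candidate predictors.
#' @return object of class \code{stepwise_result}: \code{selected}
#'   names, \code{coefficients} table (beta, se, t, p) of the final
#'   refit, \code{aic}, \code{adj_r2}, \code{trace} data.frame
#'   (step, removed, aic), \code{n_dropped}.
#' @export
backward_stepwise <- function(outcome, predictors) {
  df <- data.frame(.y = outcome, predictors)
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  pnames <- names(predictors)
  if (nrow(df) < length(pnames) + 3)
    stopf("need n >= number of predictors + 3 (n = %d, p = %d)",
          nrow(df), length(pnames))
  for (p in pnames) df[[p]] <- as.numeric(scale(df[[p]]))
  X <- as.matrix(df[, pnames, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    qq <- qr(cbind(1, X))
    bad <- pnames[setdiff(seq_len(ncol(X)), qq$pivot[seq_len(qq$rank)] - 1L)]
    stopf("predictor table is rank deficient; collinear set includes: %s",
          paste(bad, collapse = ", "))
  }
  current <- pnames
  fit <- stats::lm(stats::reformulate(if (length(current)) current else "1",
                                      response = ".y"), data = df)
  trace <- data.frame(step = 0L, removed = "(none)", aic = aic_of(fit),
                      stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (length(current) == 0) break
    cand <- vapply(current, function(p) {
      rest <- setdiff(current, p)
      aic_of(stats::lm(stats::reformulate(if (length(rest)) rest else "1",
                                          response = ".y"), data = df))
    }, 0)
    if (min(cand) >= trace$aic[nrow(trace)]) break
    drop_p <- current[which.min(cand)]
    current <- setdiff(current, drop_p)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = drop_p,
                                     aic = min(cand)))
    fit <- stats::lm(stats::reformulate(if (length(current)) current else "1",
                                        response = ".y"), data = df)
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("beta", "se", "t", "p")
  out <- list(selected = current, coefficients = coefs,
              aic = trace$aic[nrow(trace)], adj_r2 = sm$adj.r.squared,
              trace = trace, n_dropped = n_dropped, fit = fit,
              data = df)
  class(out) <- "stepwise_result"
  out
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("Backward stepwise AIC regression: %d predictor(s) retained (AIC %.2f, adj R^2 %.3f)\n",
              length(x$selected), x$aic, x$adj_r2))
  if (length(x$selected)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Group comparison of regression residuals
#'
#' Fits the selected linear model on all participants pooled and
#' compares the residuals between two groups with Welch's t test: does
#' a group difference in the outcome survive after factoring out the
#' selected predictors?
#'
#' @param outcome numeric response.
#' @param predictors_selected data.frame of the selected predictors.
#' @param groups two-level factor/vector of group membership.
#' @return list: the Welch \code{test} (see \code{\link{group_tests}}),
#'   per-group residual means/sds, and the pooled fit.
#' @export
residual_group_test <- function(outcome, predictors_selected, groups) {
  df <- data.frame(.y = outcome, predictors_selected)
  for (p in names(predictors_selected))
    df[[p]] <- as.numeric(scale(df[[p]]))
  fit <- stats::lm(stats::reformulate(
    if (ncol(predictors_selected)) names(predictors_selected) else "1",
    response = ".y"), data = df)
  res <- stats::residuals(fit)
  gl <- unique(groups)
  if (length(gl) != 2) stopf("groups must have exactly 2 levels")
  a <- res[groups == gl[1]]
  b <- res[groups == gl[2]]
  list(test = group_tests(a, b, "welch"),
       summary = data.frame(group = as.character(gl),
                            mean = c(mean(a), mean(b)),
                            sd = c(stats::sd(a), stats::sd(b))),
       fit = fit)
}
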