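# Cross-validated phoneme decoding from PRPs.

# Assemble a (samples x E x T) array from a group's PRP sets. Each PRP
# matrix is standardized by its own mean and standard deviation, which
# removes amplitude confounds between participants and groups.
prp_dataset <- function(prp_sets, standardize = TRUE) {
  labels <- sort(unique(unlist(lapply(prp_sets, function(s) names(s$prps)))))
  samples <- do.call(rbind, lapply(prp_sets, function(s) {
    data.frame(participant = s$participant_id, label = names(s$prps),
               stringsAsFactors = FALSE)
  }))
  d <- dim(prp_sets[[1]]$prps[[1]])
  X <- array(0, c(nrow(samples), d[1], d[2]))
  k <- 0L
  for (s in prp_sets) for (lab in names(s$prps)) {
    k <- k + 1L
    m <- s$prps[[lab]]
    if (standardize) m <- (m - mean(m)) / stats::sd(m)
    X[k, , ] <- m
  }
  list(X = X, y = match(samples$label, labels), labels = labels,
       samples = samples, fs = prp_sets[[1]]$fs,
       electrodes = rownames(prp_sets[[1]]$prps[[1]]))
}

#' Shannon entropy of a prediction
#'
#' \eqn{H = -\sum p \log p} in nats, with \eqn{0 \log 0 = 0}.
#'
#' @param p probability vector (nonnegative, summing to 1 within 1e-6).
#' @return entropy in nats, in \eqn{[0, \log K]}.
#' @export
prediction_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stopf("p must be a probability vector (nonnegative, sum 1); sum was %.8f",
          sum(p))
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Chance level of uniform guessing
#'
#' @param n_classes number of classes.
#' @return accuracy of uniform guessing, in percent.
#' @export
chance_level <- function(n_classes) 100 / n_classes

# Stratified fold assignment: within each label, shuffled indices are
# dealt round-robin to folds from a random starting fold.
assign_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (k in unique(y)) {
      idx <- which(y == k)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(folds, 1)
      fold[idx] <- ((seq_along(idx) + start - 2L) %% folds) + 1L
    }
  })
  fold
}

#' Cross-validated training and evaluation of the PRP classifier
#'
#' Pools the (participant x phoneme) PRPs of one group, assigns them to
#' stratified test folds (each sample is tested exactly once), and per
#' fold trains the compact convolutional classifier on the remaining
#' data minus a random validation fraction, checkpointing at the lowest
#' validation loss. A prediction is correct when the highest-probability
#' phoneme (ties broken toward the lowest label index) matches the true
#' one; uncertainty is the Shannon entropy of the predicted
#' probabilities.
#'
#' @param prp_sets list of \code{\link{extract_prps}} results (one group).
#' @param spec a \code{\link{classifier_spec}}.
#' @param seed integer seed (fold assignment, initialization, shuffling
#'   and dropout streams all derive from it; results are reproducible).
#' @param keep_models keep the trained per-fold models and the
#'   standardized input array (needed for attribution).
#' @return object of class \code{cv_result}: \code{samples} data.frame
#'   (participant, label, predicted, correct, entropy), \code{probs}
#'   matrix, \code{labels}, \code{participant_summary} (mean accuracy
#'   and entropy per participant), \code{confusion} (true x predicted
#'   counts), \code{fold}, and optionally \code{models}, \code{X}.
#' @export
train_eval_cv <- function(prp_sets, spec = classifier_spec(), seed = 1L,
                          keep_models = FALSE) {
  ds <- prp_dataset(prp_sets)
  K <- length(ds$labels)
  if (K < 2) stopf("need at least 2 phoneme classes, got %d", K)
  cnt <- table(ds$y)
  if (any(cnt < 2))
    stopf("every phoneme needs >= 2 samples; too few for: %s",
          paste(ds$labels[as.integer(names(cnt))[cnt < 2]], collapse = ", "))
  n <- length(ds$y)
  folds <- spec$folds
  fold <- assign_folds(ds$y, folds, child_seed(seed, 1L, 51L))
  probs <- matrix(NA_real_, n, K, dimnames = list(NULL, ds$labels))
  models <- if (keep_models) vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(fold == f)
    if (length(test) == 0) next
    nontest <- which(fold != f)
    val <- NULL
    for (attempt in 1:2) {
      val <- with_seed(child_seed(seed, f, 53L + attempt), {
        sample(nontest, max(1L, round(spec$val_fraction * length(nontest))))
      })
      train <- setdiff(nontest, val)
      if (all(seq_len(K) %in% ds$y[train])) break
      if (attempt == 1)
        warnf("fold %d: validation draw left a phoneme absent from training; re-drawing once", f)
      else
        stopf("fold %d: a phoneme is absent from the training data", f)
    }
    model <- net_train(ds$X, ds$y, K, ds$fs, spec, train, val,
                       seed = child_seed(seed, f, 55L))
    model$labels <- ds$labels
    probs[test, ] <- net_predict(model, ds$X[test, , , drop = FALSE])
    if (keep_models) models[[f]] <- model
  }
  pred <- max.col(probs, ties.method = "first")
  entropy <- apply(probs, 1, prediction_entropy)
  samples <- data.frame(ds$samples,
                        predicted = ds$labels[pred],
                        correct = pred == ds$y,
                        entropy = entropy,
                        stringsAsFactors = FALSE)
  psum <- do.call(rbind, lapply(split(samples, samples$participant),
    function(g) data.frame(participant = g$participant[1],
                           accuracy = mean(g$correct),
                           entropy = mean(g$entropy),
                           n = nrow(g), stringsAsFactors = FALSE)))
  rownames(psum) <- NULL
  confusion <- table(factor(ds$labels[ds$y], levels = ds$labels),
                     factor(ds$labels[pred], levels = ds$labels))
  out <- list(samples = samples, probs = probs, labels = ds$labels,
              participant_summary = psum,
              confusion = unclass(as.matrix(confusion)),
              fold = fold, seed = seed, spec = spec)
  if (keep_models) {
    out$models <- models
    out$X <- ds$X
    out$y <- ds$y
    out$electrodes <- ds$electrodes
  }
  class(out) <- "cv_result"
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV result: %d samples, %d phonemes, accuracy %.3f, mean entropy %.3f nats (chance %.2f%%)\n",
              nrow(x$samples), length(x$labels), mean(x$samples$correct),
              mean(x$samples$entropy), chance_level(length(x$labels))))
  invisible(x)
}

#' Repeated decoding protocol with group-size balancing
#'
#' Repeats the full PRP-derivation + cross-validated decoding pipeline
#' \code{n_repeats} times with different seeds. At each repetition the
#' larger group is randomly subsampled to the smaller group's size, the
#' capped PRP instance subsets are re-drawn, and
#' \code{\link{train_eval_cv}} runs per group. Accuracy and entropy are
#' averaged over the repetitions in which a participant took part;
#' confusion matrices are summed within repetition and averaged across
#' repetitions.
#'
#' @param sessions_a,sessions_b lists of preprocessed sessions, one per
#'   group.
#' @param retained phoneme labels to decode (see
#'   \code{\link{select_phonemes}}).
#' @param spec a \code{\link{classifier_spec}}.
#' @param n_repeats number of repetitions.
#' @param root_seed integer; all repetition seeds derive from it.
#' @param cap,window passed to \code{\link{extract_prps}}.
#' @param keep_attributions also compute per-sample relevance
#'   attributions on each repetition's test-fold models (see
#'   \code{\link{relevance_map}}), returned per participant.
#' @return object of class \code{repeat_result} with
#'   \code{participant_table} (id, group, n_reps, accuracy, entropy),
#'   \code{confusion} (per-group repetition-averaged matrices),
#'   \code{per_rep} summaries and optionally \code{attributions}.
#' @export
repeat_protocol <- function(sessions_a, sessions_b, retained,
                            spec = classifier_spec(), n_repeats = 20,
                            root_seed = 1L, cap = 319,
                            window = c(0, 0.5),
                            keep_attributions = FALSE) {
  stopifnot(n_repeats >= 1)
  groups <- list(a = sessions_a, b = sessions_b)
  sizes <- vapply(groups, length, 0L)
  m <- min(sizes)
  acc <- list(); ent <- list(); nrep <- list()
  conf <- list(a = NULL, b = NULL)
  attributions <- list()
  per_rep <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    seed_r <- child_seed(root_seed, r, 61L)
    rep_sum <- list()
    for (gi in 1:2) {
      gname <- names(groups)[gi]
      sess <- groups[[gi]]
      if (length(sess) > m) {
        pick <- with_seed(child_seed(seed_r, gi, 62L),
                          sample.int(length(sess), m))
        sess <- sess[pick]
      }
      prps <- lapply(seq_along(sess), function(i)
        extract_prps(sess[[i]], retained, cap = cap, window = window,
                     seed = child_seed(seed_r, i, 63L + gi)))
      cv <- train_eval_cv(prps, spec, seed = child_seed(seed_r, gi, 66L),
                          keep_models = keep_attributions)
      for (i in seq_len(nrow(cv$participant_summary))) {
        id <- cv$participant_summary$participant[i]
        acc[[id]] <- c(acc[[id]], cv$participant_summary$accuracy[i])
        ent[[id]] <- c(ent[[id]], cv$participant_summary$entropy[i])
        nrep[[id]] <- (nrep[[id]] %||% 0L) + 1L
        attr(acc[[id]], "group") <- gname
      }
      conf[[gname]] <- if (is.null(conf[[gname]])) cv$confusion else
        conf[[gname]] + cv$confusion
      if (keep_attributions) {
        at <- attribute_cv(cv)
        for (id in names(at))
          attributions[[id]] <- c(attributions[[id]], at[[id]])
      }
      rep_sum[[gname]] <- mean(cv$samples$correct)
    }
    per_rep[[r]] <- rep_sum
  }
  ids <- names(acc)
  participant_table <- data.frame(
    id = ids,
    group = vapply(ids, function(id) attr(acc[[id]], "group"), ""),
    n_reps = vapply(ids, function(id) nrep[[id]], 0L),
    accuracy = vapply(ids, function(id) mean(acc[[id]]), 0),
    entropy = vapply(ids, function(id) mean(ent[[id]]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(participant_table = participant_table,
              confusion = lapply(conf, function(cm) cm / n_repeats),
              per_rep = per_rep, n_repeats = n_repeats,
              root_seed = root_seed)
  if (keep_attributions) out$attributions <- attributions
  class(out) <- "repeat_result"
  out
}

#' Correlation between per-phoneme accuracy and phoneme frequency
#'
#' Pearson correlation (with two-sided p) between the per-label decoding
#' accuracy of a \code{cv_result} and the labels' relative frequencies;
#' a check that decoding performance is not driven by how often a
#' phoneme occurred.
#'
#' @param cv a \code{\link{train_eval_cv}} result.
#' @param weights named numeric of label frequencies (names must cover
#'   the decoded labels).
#' @return list with \code{r}, \code{p}, \code{degenerate} flag.
#' @export
frequency_accuracy_check <- function(cv, weights) {
  acc <- tapply(cv$samples$correct, cv$samples$label, mean)
  if (length(acc) < 3) stopf("need at least 3 labels, got %d", length(acc))
  if (!all(names(acc) %in% names(weights)))
    stopf("weights are missing labels: %s",
          paste(setdiff(names(acc), names(weights)), collapse = ", "))
  freq <- weights[names(acc)]
  if (stats::sd(acc) == 0 || stats::sd(freq) == 0)
    return(list(r = 0, p = NA_real_, degenerate = TRUE))
  ct <- stats::cor.test(acc, freq)
  list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
}
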