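# Shared fixtures: tiny cohorts and PRP sets built in code.

tiny_config <- function(seed = 1L, n_per_group = 2, noise_sd = 8,
                        groups = list(A = list(alpha = 1, sigma = 0.6, tau_ms = 0),
                                      B = list(alpha = 0.4, sigma = 1, tau_ms = 80)),
                        n_segments = 2, segment_dur = 10, ...) {
  cohort_config(n_per_group = n_per_group, group_params = groups,
                n_electrodes = 8, fs = 128, n_segments = n_segments,
                segment_dur = segment_dur,
                inventory = make_inventory(6, 1, seed = 1L),
                noise_sd = noise_sd, seed = seed, ...)
}

# A noiseless, tracking-free session: recording is exactly the template
# stream.
clean_session <- function(seed = 1L, alpha = 1) {
  cfg <- tiny_config(seed = seed, noise_sd = 0,
                     groups = list(A = list(alpha = alpha, sigma = 1,
                                            tau_ms = 0)))
  cfg$kernel_gain <- c(envelope = 0, onset = 0)
  simulate_session(cfg, "A", participant_seed = seed)
}

# Synthetic PRP sets with known class structure: K phoneme means plus
# participant noise, bypassing the simulator (for decoder/RSA units).
toy_prp_sets <- function(n_participants = 4, K = 5, E = 6, Tn = 16,
                         noise = 0.1, fs = 128, seed = 1,
                         templates = NULL) {
  set.seed(seed)
  if (is.null(templates))
    templates <- lapply(seq_len(K), function(k) matrix(rnorm(E * Tn), E, Tn))
  labels <- sprintf("P%02d", seq_len(K))
  lapply(seq_len(n_participants), function(i) {
    prps <- lapply(templates, function(m) {
      mm <- m + noise * matrix(rnorm(E * Tn), E, Tn)
      rownames(mm) <- sprintf("E%02d", seq_len(E))
      mm
    })
    names(prps) <- labels
    out <- list(prps = prps, counts = stats::setNames(rep(10L, K), labels),
                n_dropped = 0L, selected = NULL, window = c(0, Tn / fs),
                fs = fs, participant_id = sprintf("S%02d", i), group = "A")
    class(out) <- "prp_set"
    out
  })
}

# Independent nearest-centroid classifier (leave-one-out), used as an
# oracle against the convolutional decoder on separable data.
centroid_loo_accuracy <- function(prp_sets) {
  ds <- prpdecode:::prp_dataset(prp_sets)
  n <- length(ds$y)
  K <- max(ds$y)
  correct <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    d2 <- vapply(seq_len(K), function(k) {
      idx <- tr[ds$y[tr] == k]
      cent <- apply(ds$X[idx, , , drop = FALSE], c(2, 3), mean)
      sum((ds$X[i, , ] - cent)^2)
    }, 0)
    correct[i] <- which.min(d2) == ds$y[i]
  }
  mean(correct)
}

# A small trained classifier with fold models retained, for attribution
# tests.
trained_toy_model <- function(seed = 3, n_participants = 4, K = 4,
                              E = 6, Tn = 16) {
  sets <- toy_prp_sets(n_participants = n_participants, K = K, E = E,
                       Tn = Tn, noise = 0.2, seed = seed)
  spec <- classifier_spec(folds = 4, max_epochs = 20, patience = 10)
  train_eval_cv(sets, spec, seed = seed, keep_models = TRUE)
}
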