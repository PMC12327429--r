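# Synthetic-data generator: inventory, sessions, cohorts.

test_that("inventory weights follow a Zipf law and cover all manner classes", {
  inv <- make_inventory(4, 0, seed = 1)
  expect_equal(unname(inv$weights), rep(0.25, 4))
  inv12 <- make_inventory(12, 1, seed = 2)
  expect_equal(unname(inv12$weights[1] / inv12$weights[2]), 2.0)
  expect_equal(sum(inv12$weights), 1, tolerance = 1e-12)
  # all four feature triples present
  expect_equal(nrow(unique(inv12$features)), 4)
  expect_true(all(inv12$features %in% c(0, 1)))
  # reproducibility
  expect_identical(make_inventory(31, 1.2, seed = 7),
                   make_inventory(31, 1.2, seed = 7))
  expect_error(make_inventory(3), "at least 4")
})

test_that("sessions are reproducible and structurally valid", {
  cfg <- tiny_config(seed = 42)
  s1 <- simulate_session(cfg, "A", participant_seed = 9)
  s2 <- simulate_session(cfg, "A", participant_seed = 9)
  expect_identical(s1, s2)
  expect_true(all(is.finite(s1$recording)))
  N <- ncol(s1$recording)
  expect_true(all(s1$annotations$onset_s >= 0 &
                    s1$annotations$onset_s < N / s1$fs))
  expect_true(all(s1$annotations$phoneme %in% cfg$inventory$labels))
  expect_true(all(s1$predictors >= 0))
  expect_error(simulate_session(cfg, "Z", 1), "unknown group")
})

test_that("with noise off the recording is the exact template + kernel stream", {
  cfg <- tiny_config(seed = 3, noise_sd = 0)
  s <- simulate_session(cfg, "A", participant_seed = 5)
  # rebuild the template stream from the truth block
  E <- cfg$n_electrodes
  Tn <- ncol(s$truth$templates[[1]])
  rec <- matrix(0, E + 2, ncol(s$recording))
  for (i in seq_len(nrow(s$annotations))) {
    idx <- floor(s$annotations$onset_s[i] * s$fs) + 1L
    if (idx + Tn - 1 <= ncol(rec))
      rec[1:E, idx:(idx + Tn - 1)] <- rec[1:E, idx:(idx + Tn - 1)] +
        s$truth$templates[[s$annotations$phoneme[i]]]
  }
  for (p in seq_len(nrow(s$predictors))) {
    conv_p <- prpdecode:::causal_filter(s$predictors[p, ],
                                        s$truth$kernel_courses[p, ])
    rec[1:E, ] <- rec[1:E, ] + outer(s$truth$kernel_gains, conv_p)
  }
  expect_lt(max(abs(rec - s$recording)), 1e-9)
})

test_that("alpha = 0 collapses all phoneme templates onto one shape", {
  cfg <- tiny_config(groups = list(G = list(alpha = 0, sigma = 1, tau_ms = 0)))
  s <- simulate_session(cfg, "G", participant_seed = 2)
  tt <- s$truth$templates
  devs <- vapply(tt, function(m) max(abs(m - tt[[1]])), 0)
  expect_true(all(devs < 1e-12))
})

test_that("a single clean instance round-trips through epoch extraction", {
  cfg <- tiny_config(noise_sd = 0, n_segments = 1, segment_dur = 5,
                     groups = list(A = list(alpha = 1, sigma = 1, tau_ms = 0)))
  cfg$kernel_gain <- c(envelope = 0, onset = 0)
  s <- simulate_session(cfg, "A", participant_seed = 4)
  lab <- s$annotations$phoneme[1]
  tmpl <- s$truth$templates[[lab]]
  Tn <- ncol(tmpl)
  # rebuild the session with exactly one instance of that phoneme
  s$recording[] <- 0
  onset <- 1.0
  idx <- floor(onset * s$fs) + 1L
  s$recording[seq_len(cfg$n_electrodes), idx:(idx + Tn - 1)] <- tmpl
  s$annotations <- data.frame(onset_s = onset, duration_s = 0.1,
                              phoneme = lab, stringsAsFactors = FALSE)
  s$recording <- s$recording[seq_len(cfg$n_electrodes), , drop = FALSE]
  ps <- extract_prps(s, lab, seed = 1)
  expect_equal(unname(ps$prps[[lab]]), unname(tmpl), tolerance = 1e-12)
  expect_equal(unname(ps$counts[lab]), 1L)
})

test_that("truth template geometry follows the phonetic features", {
  # templates as pure linear combinations of the feature courses
  cfg <- tiny_config(noise_sd = 0, unique_scale = 0,
                     groups = list(A = list(alpha = 1, sigma = 1, tau_ms = 0)))
  s <- simulate_session(cfg, "A", participant_seed = 8)
  K <- length(s$truth$templates)
  dmat <- matrix(0, K, K)
  for (i in 1:K) for (j in 1:K)
    dmat[i, j] <- sqrt(sum((s$truth$templates[[i]] - s$truth$templates[[j]])^2))
  frdm <- feature_rdm(cfg$inventory)
  ut <- upper.tri(dmat)
  expect_gt(cor(dmat[ut], unclass(frdm)[ut], method = "spearman"), 0.9)
})

test_that("cohort covariates attain their target correlations with alpha", {
  cs <- data.frame(name = c("c_pos", "c_null"), rho = c(0.8, 0),
                   nuisance = c(FALSE, TRUE), mean = c(0, 0), sd = c(1, 1))
  cfg <- cohort_config(
    n_per_group = 100,
    group_params = list(A = list(alpha = 1, sigma = 1, tau_ms = 0),
                        B = list(alpha = 0.5, sigma = 1, tau_ms = 0)),
    n_electrodes = 4, n_segments = 1, segment_dur = 1,
    inventory = make_inventory(4, 1, seed = 1), covariate_spec = cs,
    seed = 11)
  # only the covariate machinery matters here; skip the heavy signal
  # by drawing alphas and covariates exactly as simulate_session does
  part <- do.call(rbind, lapply(seq_len(200), function(k) {
    g <- if (k <= 100) "A" else "B"
    ps <- prpdecode:::child_seed(11, k, 20L)
    z <- prpdecode:::with_seed(prpdecode:::child_seed(ps, 1L, 1L), rnorm(1))
    alpha <- cfg$group_params[[g]]$alpha * exp(cfg$alpha_log_sd * z)
    cv <- prpdecode:::with_seed(prpdecode:::child_seed(ps, 5L, 5L), {
      mom <- prpdecode:::alpha_pooled_moments(cfg)
      s_i <- (alpha - mom$mean) / sqrt(mom$var)
      vapply(seq_len(nrow(cs)), function(j) {
        rho <- if (cs$nuisance[j]) 0 else cs$rho[j]
        cz <- rho * s_i + sqrt(1 - rho^2) * rnorm(1)
        cs$mean[j] + cs$sd[j] * cz
      }, 0)
    })
    data.frame(alpha = alpha, c_pos = cv[1], c_null = cv[2])
  }))
  expect_lt(abs(cor(part$alpha, part$c_pos) - 0.8), 0.1)
  expect_lt(abs(cor(part$alpha, part$c_null)), 0.3)
})

test_that("groups with higher alpha store higher alphas on average", {
  cfg <- tiny_config(seed = 5, n_per_group = 4, n_segments = 1,
                     segment_dur = 2)
  coh <- simulate_cohort(cfg)
  a <- with(coh$participants, tapply(alpha, group, mean))
  expect_gt(a[["A"]], a[["B"]])
  # full-cohort reproducibility
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$participants, coh2$participants)
})
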