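# Synthetic continuous-EEG cohort generator with known ground truth.
#
# Generative model per participant:
#   recording = phoneme-evoked stream + acoustic-tracking stream + noise
# The evoked template of phoneme p is
#   amp * ( C + alpha_i * a_e * (F_p + U_p) )
# where C is a common (phoneme-unspecific) component, F_p the sum of
# feature-indicator damped-oscillation components, U_p a phoneme-unique
# component, alpha_i the participant's distinctiveness realization, and
# a_e a spatial-spread attenuation (1 on the sigma*E most strongly
# weighted electrodes, 0.1 elsewhere). alpha = 0 therefore collapses all
# templates onto the common component. The tracking stream is the causal
# convolution of each band predictor with a separable kernel
# (lag course x electrode gain map). Noise is a mixture of white and
# 1/f-shaped Gaussian noise.

#' Default covariate specification for synthetic cohorts
#'
#' Per covariate: a target Pearson correlation with the participant-level
#' distinctiveness realization (alpha), a nuisance flag (nuisance
#' covariates are independent of alpha) and the output mean/sd. The
#' defaults emulate peripheral/cognitive measures: an ABR wave-I
#' amplitude proxy (positively coupled), a speech-in-noise SNR-loss proxy
#' (negatively coupled), and two cognitive scores left as nuisance.
#'
#' @return data.frame with columns name, rho, nuisance, mean, sd.
#' @export
default_covariates <- function() {
  data.frame(
    name     = c("abr_wave_i", "win_snr_loss", "moca", "ospan"),
    rho      = c(0.65, -0.5, 0, 0),
    nuisance = c(FALSE, FALSE, TRUE, TRUE),
    mean     = c(0.33, 6, 27.5, 40),
    sd       = c(0.17, 3, 1.8, 12),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic cohort
#'
#' @param n_per_group participants per group.
#' @param group_params named list (one entry per group) of lists with
#'   \code{alpha} (distinctiveness, >= 0), \code{sigma} (spatial spread,
#'   fraction of electrodes carrying the distinctive signal, in (0, 1])
#'   and \code{tau_ms} (latency shift, ms >= 0).
#' @param n_electrodes number of scalp electrodes E (>= 4); two mastoid
#'   channels are simulated in addition.
#' @param fs sampling rate in Hz.
#' @param n_segments,segment_dur number and duration (s) of story-like
#'   segments; the recording is their concatenation.
#' @param inventory a \code{\link{make_inventory}} table.
#' @param noise_sd noise standard deviation (microvolt).
#' @param pink_weight mixing weight of the 1/f noise component in [0, 1].
#' @param kernel_gain named numeric \code{c(envelope=, onset=)}: gain of
#'   the true acoustic-tracking kernels (microvolt per predictor unit);
#'   set both to 0 for a tracking-free cohort.
#' @param template_amp overall evoked-template amplitude (microvolt).
#' @param unique_scale amplitude of the phoneme-unique components
#'   relative to the feature-driven components (0 gives templates that
#'   are pure linear combinations of the feature courses).
#' @param alpha_log_sd log-scale spread of the per-participant alpha
#'   realizations around the group value.
#' @param covariate_spec data.frame as \code{\link{default_covariates}}.
#' @param seed root seed; all randomness in the cohort flows from it.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_group,
                          group_params,
                          n_electrodes = 16,
                          fs = 128,
                          n_segments = 5,
                          segment_dur = 36,
                          inventory = make_inventory(12, 1, seed = 1L),
                          noise_sd = 6,
                          pink_weight = 0.6,
                          kernel_gain = c(envelope = 0.2, onset = 0.3),
                          template_amp = 3,
                          unique_scale = 0.8,
                          alpha_log_sd = 0.15,
                          covariate_spec = default_covariates(),
                          seed = 1L) {
  if (n_electrodes < 4) stopf("n_electrodes must be >= 4")
  if (fs <= 0) stopf("fs must be positive")
  if (is.null(names(group_params)) || any(names(group_params) == ""))
    stopf("group_params must be a named list")
  for (g in names(group_params)) {
    p <- group_params[[g]]
    if (is.null(p$alpha) || p$alpha < 0) stopf("group '%s': alpha must be >= 0", g)
    if (is.null(p$sigma) || p$sigma <= 0 || p$sigma > 1)
      stopf("group '%s': sigma must be in (0, 1]", g)
    if (is.null(p$tau_ms)) group_params[[g]]$tau_ms <- 0
    if (group_params[[g]]$tau_ms < 0) stopf("group '%s': tau_ms must be >= 0", g)
  }
  if (any(abs(covariate_spec$rho) > 1))
    stopf("covariate target correlations must lie in [-1, 1]")
  validate_inventory(inventory)
  if (segment_dur < 0.7)
    stopf("segment_dur (%g s) too short to hold one 0.5 s epoch", segment_dur)
  cfg <- list(n_per_group = as.integer(n_per_group),
              group_params = group_params,
              n_electrodes = as.integer(n_electrodes),
              fs = fs,
              n_segments = as.integer(n_segments),
              segment_dur = segment_dur,
              inventory = inventory,
              noise_sd = noise_sd,
              pink_weight = pink_weight,
              kernel_gain = kernel_gain,
              template_amp = template_amp,
              unique_scale = unique_scale,
              alpha_log_sd = alpha_log_sd,
              covariate_spec = covariate_spec,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Gaussian bump on the unit disc, evaluated at scalp electrode positions.
disc_map <- function(layout_scalp, center, width) {
  d2 <- (layout_scalp[, 1] - center[1])^2 + (layout_scalp[, 2] - center[2])^2
  m <- exp(-d2 / (2 * width^2))
  m / max(m)
}

# Damped-oscillation time course, zero before its onset.
damped_course <- function(tt, f_hz, onset_s, decay_s) {
  u <- tt - onset_s
  ifelse(u >= 0, sin(2 * pi * f_hz * u) * exp(-u / decay_s), 0)
}

# Cohort-level generative quantities shared by all participants: feature
# components, common component, phoneme-unique components, kernel shapes.
# Deterministic function of the config (config seed only).
build_cohort_truth <- function(config) {
  E <- config$n_electrodes
  fs <- config$fs
  Tn <- round(0.5 * fs)
  tt <- (seq_len(Tn) - 1) / fs
  layout <- make_layout(E)
  scalp <- layout[seq_len(E), , drop = FALSE]
  feat_freq <- c(3, 5, 7)
  feat_onset <- c(0.05, 0.08, 0.11)
  feat_centers <- list(c(0, 0.45), c(-0.5, -0.15), c(0.5, -0.15))
  feat_comp <- lapply(1:3, function(f) {
    outer(disc_map(scalp, feat_centers[[f]], 0.55),
          damped_course(tt, feat_freq[f], feat_onset[f], 0.12))
  })
  common <- 0.6 * outer(disc_map(scalp, c(0, 0.15), 0.7),
                        damped_course(tt, 4, 0.03, 0.15))
  K <- length(config$inventory$labels)
  # Feature-driven part per phoneme.
  Fp <- lapply(seq_len(K), function(p) {
    x <- config$inventory$features[p, ]
    Reduce(`+`, feat_comp[which(x == 1)], accumulate = FALSE,
           init = matrix(0, E, Tn))
  })
  f_rms <- sqrt(mean(vapply(Fp, function(m) mean(m^2), 0)))
  # Phoneme-unique components: smooth random time course x smooth random map.
  Up <- with_seed(child_seed(config$seed, 0L, 12L), {
    win <- 0.5 * (1 - cos(2 * pi * seq_len(round(0.08 * fs)) /
                            (round(0.08 * fs) + 1)))
    win <- win / sum(win)
    taper <- exp(-((tt - 0.13) / 0.10)^2)   # aligned with the feature courses
    lapply(seq_len(K), function(p) {
      course <- causal_filter(stats::rnorm(Tn), win) * taper
      raw <- stats::rnorm(E)
      d2 <- as.matrix(stats::dist(scalp))^2
      map <- as.numeric(exp(-d2 / (2 * 0.4^2)) %*% raw)
      u <- outer(map / max(abs(map)), course)
      u * ((config$unique_scale %||% 0.8) * f_rms / sqrt(mean(u^2)))
    })
  })
  # Acoustic-tracking kernels: separable lag course x electrode gain map.
  lag_n <- round(0.25 * fs)
  lag_t <- (seq_len(lag_n) - 1) / fs
  env_course <- damped_course(lag_t, 4, 0.03, 0.07)
  ons_course <- damped_course(lag_t, 6, 0.02, 0.05)
  gain_map <- disc_map(scalp, c(0, 0.3), 0.6)
  courses <- rbind(
    matrix(rep(env_course, 8), nrow = 8, byrow = TRUE) *
      config$kernel_gain[["envelope"]],
    matrix(rep(ons_course, 8), nrow = 8, byrow = TRUE) *
      config$kernel_gain[["onset"]]
  )
  rownames(courses) <- c(sprintf("env%02d", 1:8), sprintf("ons%02d", 1:8))
  list(layout = layout, time = tt, n_time = Tn,
       feature_components = feat_comp, common = common,
       feature_part = Fp, unique_part = Up,
       kernel_courses = courses, kernel_gains = gain_map,
       kernel_lag_n = lag_n)
}

# Pooled moments of the alpha realizations across the configured groups
# (lognormal within group); used to standardize alpha for the covariate
# coupling so target correlations hold cohort-wide.
alpha_pooled_moments <- function(config) {
  s2 <- config$alpha_log_sd^2
  a <- vapply(config$group_params, function(p) p$alpha, 0)
  mu <- a * exp(s2 / 2)
  v <- a^2 * (exp(s2) - 1) * exp(s2)
  m <- mean(mu)
  list(mean = m, var = mean(v + mu^2) - m^2)
}

# 1/f-shaped ("pink") unit-variance Gaussian noise, one channel per
# column.
pink_noise_mat <- function(n, n_chan, fs) {
  z <- matrix(stats::rnorm(n * n_chan), n, n_chan)
  fr <- c(0, seq_len(n - 1)) * fs / n
  fr <- pmin(fr, fs - fr)          # two-sided frequency axis
  shape <- 1 / sqrt(pmax(fr, 0.5)) # 1/f power with a 0.5 Hz floor
  shape[1] <- 0                    # no DC
  x <- Re(stats::mvfft(stats::mvfft(z) * shape, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, stats::sd), `/`)
}

# Nonnegative band-envelope series (one per row): smoothed rectified
# noise, unit mean.
smooth_envelopes <- function(n, n_bands, fs) {
  w <- 0.5 * (1 - cos(2 * pi * seq_len(round(0.06 * fs)) /
                        (round(0.06 * fs) + 1)))
  raw <- abs(matrix(stats::rnorm(n * n_bands), n, n_bands))
  e <- filter_rows_fft(t(raw), w / sum(w))
  e / rowMeans(e)
}

#' Generate synthetic band predictors
#'
#' Eight nonnegative band-envelope series (smoothed rectified noise,
#' unit mean) and their half-wave-rectified first differences (band
#' onsets), at the EEG sampling rate.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @return 16 x n matrix with rownames env01..env08, ons01..ons08.
#' @export
make_band_predictors <- function(n, fs, seed = 1L) {
  env <- with_seed(seed, smooth_envelopes(n, 8, fs))
  ons <- t(apply(env, 1, function(e) pmax(c(0, diff(e)), 0)))
  pred <- rbind(env, ons)
  rownames(pred) <- c(sprintf("env%02d", 1:8), sprintf("ons%02d", 1:8))
  pred
}

#' Simulate one participant's continuous recording
#'
#' @param config a \code{\link{cohort_config}}.
#' @param group name of the group (must match \code{config$group_params}).
#' @param participant_seed integer seed for this participant's randomness.
#' @param alpha optional fixed distinctiveness realization; drawn from
#'   the group's lognormal law when NULL.
#' @param participant_id optional identifier string.
#' @return object of class \code{simulated_session} with elements
#'   \code{recording} ((E+2) x N microvolt matrix incl. mastoid rows
#'   M1/M2), \code{fs}, \code{layout}, \code{annotations} (onset_s,
#'   duration_s, phoneme), \code{segments}, \code{predictors} (16 x N),
#'   \code{covariates}, \code{group}, and a \code{truth} block holding
#'   every generative quantity (templates, kernels, alpha, ...).
#' @export
simulate_session <- function(config, group, participant_seed,
                             alpha = NULL, participant_id = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!group %in% names(config$group_params))
    stopf("unknown group '%s'", group)
  gp <- config$group_params[[group]]
  E <- config$n_electrodes
  fs <- config$fs
  N <- round(config$n_segments * config$segment_dur * fs)
  truth0 <- build_cohort_truth(config)
  Tn <- truth0$n_time

  z_i <- with_seed(child_seed(participant_seed, 1L, 1L), stats::rnorm(1))
  if (is.null(alpha)) alpha <- gp$alpha * exp(config$alpha_log_sd * z_i)

  # Spatial spread: keep the sigma*E electrodes with the largest
  # distinctive-part weights, attenuate the rest by 90%.
  dist_rms <- sqrt(Reduce(`+`, lapply(seq_along(truth0$feature_part),
    function(p) rowMeans((truth0$feature_part[[p]] + truth0$unique_part[[p]])^2))) /
      length(truth0$feature_part))
  keep_n <- min(E, max(1L, ceiling(gp$sigma * E)))
  atten <- rep(0.1, E)
  atten[order(dist_rms, decreasing = TRUE)[seq_len(keep_n)]] <- 1

  templates <- lapply(seq_along(config$inventory$labels), function(p) {
    config$template_amp *
      (truth0$common + alpha * atten *
         (truth0$feature_part[[p]] + truth0$unique_part[[p]]))
  })
  names(templates) <- config$inventory$labels

  # Annotations: phoneme instances tile each segment, inter-onset
  # intervals uniform on 50-250 ms (speech-like rate with overlapping
  # responses).
  ann <- with_seed(child_seed(participant_seed, 2L, 2L), {
    out <- list()
    for (s in seq_len(config$n_segments)) {
      t0 <- (s - 1) * config$segment_dur
      tmax <- t0 + config$segment_dur - 0.55
      onsets <- c()
      t <- t0 + 0.1
      while (t < tmax) {
        onsets <- c(onsets, t)
        t <- t + stats::runif(1, 0.05, 0.25)
      }
      dur <- c(diff(onsets), 0.1)
      lab <- sample(config$inventory$labels, length(onsets), replace = TRUE,
                    prob = config$inventory$weights)
      out[[s]] <- data.frame(onset_s = onsets, duration_s = dur,
                             phoneme = lab, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })

  tau_smp <- round(gp$tau_ms * fs / 1000)
  rec <- matrix(0, E + 2, N,
                dimnames = list(rownames(truth0$layout), NULL))
  for (i in seq_len(nrow(ann))) {
    idx <- floor(ann$onset_s[i] * fs) + 1L + tau_smp
    if (idx >= 1L && idx + Tn - 1L <= N) {
      rec[seq_len(E), idx:(idx + Tn - 1L)] <-
        rec[seq_len(E), idx:(idx + Tn - 1L)] + templates[[ann$phoneme[i]]]
    }
  }

  predictors <- make_band_predictors(N, fs,
                                     seed = child_seed(participant_seed, 4L, 4L))
  # Tracking stream: separable kernels sharing one electrode gain map ->
  # convolve every predictor with its lag course (batched FFT), sum the
  # convolved series, and scale into electrodes by the gain map.
  if (any(config$kernel_gain != 0)) {
    convs <- filter_rows_fft(predictors, truth0$kernel_courses)
    rec[seq_len(E), ] <- rec[seq_len(E), ] +
      outer(truth0$kernel_gains, colSums(convs))
  }

  if (config$noise_sd > 0) {
    w <- config$pink_weight
    nrm <- sqrt(w^2 + (1 - w)^2)
    noise <- with_seed(child_seed(participant_seed, 3L, 3L), {
      pink <- pink_noise_mat(N, E + 2, fs)
      white <- matrix(stats::rnorm(N * (E + 2)), N, E + 2)
      t((w * pink + (1 - w) * white) / nrm)
    })
    rec <- rec + config$noise_sd * noise
  }

  covariates <- draw_covariates(alpha, config,
                                seed = child_seed(participant_seed, 5L, 5L))

  # Full kernel array (predictor x lag x electrode), for the truth block.
  kern <- array(0, dim = c(nrow(predictors), truth0$kernel_lag_n, E),
                dimnames = list(rownames(predictors), NULL,
                                rownames(truth0$layout)[seq_len(E)]))
  for (p in seq_len(nrow(predictors)))
    kern[p, , ] <- outer(truth0$kernel_courses[p, ], truth0$kernel_gains)

  segs <- data.frame(start_s = (seq_len(config$n_segments) - 1) *
                       config$segment_dur,
                     end_s = seq_len(config$n_segments) * config$segment_dur)

  out <- list(recording = rec, fs = fs, layout = truth0$layout,
              annotations = ann, segments = segs, predictors = predictors,
              covariates = covariates, group = group,
              participant_id = participant_id %||% sprintf("P%09d", participant_seed),
              truth = list(templates = templates, kernels = kern,
                           kernel_courses = truth0$kernel_courses,
                           kernel_gains = truth0$kernel_gains,
                           alpha = alpha, alpha_group = gp$alpha,
                           sigma = gp$sigma, tau_ms = gp$tau_ms,
                           attenuation = atten, z_latent = z_i,
                           features = config$inventory$features),
              seed = participant_seed)
  class(out) <- "simulated_session"
  stopifnot(all(is.finite(out$recording)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw one participant's covariates given a distinctiveness realization
#'
#' Gaussian-copula-style coupling: the covariate is a weighted sum of
#' the cohort-standardized alpha (standardization uses the analytic
#' pooled moments of the configured groups) and independent noise, so
#' each non-nuisance covariate attains its target correlation with
#' alpha cohort-wide; nuisance covariates are independent of alpha.
#'
#' @param alpha the participant's distinctiveness realization.
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @return named numeric vector of covariate values.
#' @export
draw_covariates <- function(alpha, config, seed) {
  with_seed(seed, {
    mom <- alpha_pooled_moments(config)
    s_i <- if (mom$var > 0) (alpha - mom$mean) / sqrt(mom$var) else 0
    cs <- config$covariate_spec
    vals <- vapply(seq_len(nrow(cs)), function(j) {
      rho <- if (cs$nuisance[j]) 0 else cs$rho[j]
      cz <- rho * s_i + sqrt(1 - rho^2) * stats::rnorm(1)
      cs$mean[j] + cs$sd[j] * cz
    }, 0)
    stats::setNames(vals, cs$name)
  })
}

#' Draw a cohort's alpha realizations and covariates (no EEG synthesis)
#'
#' The participant-level half of \code{\link{simulate_cohort}}: group
#' alphas with lognormal participant variation plus coupled covariates,
#' without generating the recordings. Useful for studying the covariate
#' layer at larger n.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return data.frame (id, group, alpha, covariates ...).
#' @export
draw_cohort_covariates <- function(config) {
  rows <- list()
  k <- 0L
  for (g in names(config$group_params)) {
    for (i in seq_len(config$n_per_group)) {
      k <- k + 1L
      ps <- child_seed(config$seed, k, 20L)
      z <- with_seed(child_seed(ps, 1L, 1L), stats::rnorm(1))
      alpha <- config$group_params[[g]]$alpha *
        exp(config$alpha_log_sd * z)
      cv <- draw_covariates(alpha, config, child_seed(ps, 5L, 5L))
      rows[[k]] <- data.frame(id = sprintf("%s%02d", g, i), group = g,
                              alpha = alpha, as.data.frame(as.list(cv)),
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full cohort
#'
#' One \code{\link{simulate_session}} per participant per group, with
#' per-participant seeds split deterministically from the config's root
#' seed, alpha realizations drawn from each group's law and covariates
#' coupled to the pooled alpha realizations at their target correlations.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{simulated_cohort}: list with
#'   \code{sessions} (named list), \code{config} and a \code{participants}
#'   summary data.frame (id, group, alpha, covariates).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sessions <- list()
  k <- 0L
  for (g in names(config$group_params)) {
    for (i in seq_len(config$n_per_group)) {
      k <- k + 1L
      id <- sprintf("%s%02d", g, i)
      sessions[[id]] <- simulate_session(
        config, g, participant_seed = child_seed(config$seed, k, 20L),
        participant_id = id)
    }
  }
  cov_tab <- do.call(rbind, lapply(sessions, function(s)
    as.data.frame(as.list(s$covariates))))
  participants <- data.frame(
    id = names(sessions),
    group = vapply(sessions, function(s) s$group, ""),
    alpha = vapply(sessions, function(s) s$truth$alpha, 0),
    cov_tab, row.names = NULL, stringsAsFactors = FALSE)
  out <- list(sessions = sessions, config = config,
              participants = participants)
  class(out) <- "simulated_cohort"
  out
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("Simulated session %s (group %s): %d+2 channels x %d samples at %g Hz, %d phoneme instances, alpha = %.3f\n",
              x$participant_id, x$group, nrow(x$recording) - 2L,
              ncol(x$recording), x$fs, nrow(x$annotations), x$truth$alpha))
  invisible(x)
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d sessions in %d group(s), seed %d\n",
              length(x$sessions), length(x$config$group_params),
              x$config$seed))
  invisible(x)
}
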