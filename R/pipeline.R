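# End-to-end orchestration: simulate -> prp -> decode -> relevance ->
# rsa -> track -> stats, with seed management and a JSON run report.

#' Desk-scale default cohort configuration
#'
#' A CI-friendly cohort embodying the study's contrasts: group A
#' ("younger-like": distinctiveness alpha = 1, localized spread
#' sigma = 0.6, no latency shift) versus group B ("older-like":
#' alpha = 0.55, distributed sigma = 1, latency shift 80 ms), 10
#' participants per group, 16 electrodes, 12 phonemes, eight 24 s
#' segments at 128 Hz.
#'
#' @param seed root seed.
#' @param n_per_group participants per group.
#' @return a \code{\link{cohort_config}}.
#' @export
desk_config <- function(seed = 1L, n_per_group = 10) {
  cohort_config(
    n_per_group = n_per_group,
    group_params = list(
      A = list(alpha = 1.0, sigma = 0.6, tau_ms = 0),
      B = list(alpha = 0.55, sigma = 1.0, tau_ms = 80)),
    n_electrodes = 16, fs = 128, n_segments = 8, segment_dur = 24,
    inventory = make_inventory(12, 1, seed = 1L),
    seed = seed)
}

#' Full-scale cohort configuration
#'
#' The faithful-scale preset: 61 scalp electrodes, 31 phonemes, 20
#' participants per group, fifteen 70 s segments.
#'
#' @param seed root seed.
#' @return a \code{\link{cohort_config}}.
#' @export
full_scale_config <- function(seed = 1L) {
  cohort_config(
    n_per_group = 20,
    group_params = list(
      A = list(alpha = 1.0, sigma = 0.6, tau_ms = 0),
      B = list(alpha = 0.55, sigma = 1.0, tau_ms = 80)),
    n_electrodes = 61, fs = 128, n_segments = 15, segment_dur = 70,
    inventory = make_inventory(31, 1, seed = 1L),
    seed = seed)
}

#' Chain adjacency for time-course cluster tests
#' @param n number of time points.
#' @return n x n logical adjacency (neighboring samples).
#' @export
time_adjacency <- function(n) {
  adj <- abs(outer(seq_len(n), seq_len(n), `-`)) == 1
  adj
}

stage_deps <- c(prp = "simulate", decode = "prp", relevance = "decode",
                rsa = "prp", track = "simulate", stats = "decode")

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order
#' (simulate -> prp -> decode -> relevance -> rsa -> track -> stats),
#' writes each stage's outputs under \code{out_dir} and returns (and
#' writes) a machine-readable run report with the headline metrics.
#' Idempotent per (config, seed): re-running reproduces the outputs.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param stages subset of
#'   c("simulate","prp","decode","relevance","rsa","track","stats").
#' @param out_dir output directory.
#' @param seed root seed for all analysis randomness (simulation
#'   randomness is governed by \code{config$seed}).
#' @param spec classifier specification for the decoding stages.
#' @param n_repeats repetitions of the decoding protocol.
#' @param n_perm permutations for all permutation tests.
#' @param trf_max_steps boosting step cap for the tracking stage.
#' @param write_sessions write per-session files (recording, CSVs,
#'   truth) during the simulate stage.
#' @return the run report, invisibly (also written as report.json).
#' @export
run_pipeline <- function(config = desk_config(),
                         stages = c("simulate", "prp", "decode",
                                    "relevance", "rsa", "track", "stats"),
                         out_dir = tempfile("prprun"), seed = 1L,
                         spec = desk_classifier_spec(), n_repeats = 3,
                         n_perm = 500, trf_max_steps = 150,
                         write_sessions = TRUE) {
  all_stages <- c("simulate", "prp", "decode", "relevance", "rsa",
                  "track", "stats")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  for (st in stages) {
    dep <- stage_deps[st]
    if (!is.na(dep) && !dep %in% stages)
      stopf("stage '%s' requires stage '%s'; run it first", st, dep)
  }
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(schema = "prpdecode-report-1",
                 package_version = as.character(utils::packageVersion("prpdecode")),
                 seed = seed, config_seed = config$seed,
                 stages = stages, outputs = list(), metrics = list(),
                 timing_s = list())
  env <- new.env()
  tick <- function(st, code) {
    t0 <- Sys.time()
    force(code)
    report$timing_s[[st]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  if ("simulate" %in% stages) tick("simulate", {
    env$cohort <- simulate_cohort(config)
    if (write_sessions) {
      for (id in names(env$cohort$sessions))
        write_session(env$cohort$sessions[[id]],
                      file.path(out_dir, "sessions", id))
      report$outputs$sessions <- file.path(out_dir, "sessions")
    }
    utils::write.csv(env$cohort$participants,
                     file.path(out_dir, "participants.csv"),
                     row.names = FALSE)
    report$outputs$participants <- file.path(out_dir, "participants.csv")
  })

  if ("prp" %in% stages) tick("prp", {
    env$pre <- lapply(env$cohort$sessions, preprocess)
    ann_all <- do.call(rbind, lapply(env$cohort$sessions,
                                     function(s) s$annotations))
    env$retained <- select_phonemes(ann_all)
    env$prps <- lapply(env$pre, extract_prps, retained = env$retained,
                       seed = child_seed(seed, 1L, 70L))
    dir.create(file.path(out_dir, "prp"), showWarnings = FALSE)
    for (id in names(env$prps))
      write_prp_set(env$prps[[id]],
                    file.path(out_dir, "prp", paste0(id, ".bin")),
                    file.path(out_dir, "prp", paste0(id, ".json")))
    report$outputs$prp <- file.path(out_dir, "prp")
    report$metrics$retained_phonemes <- env$retained
  })

  by_group <- function(x) {
    grp <- vapply(env$cohort$sessions, function(s) s$group, "")
    split(x, grp)
  }

  if ("decode" %in% stages) tick("decode", {
    pg <- by_group(env$pre)
    env$rp <- repeat_protocol(pg[[1]], pg[[2]], env$retained, spec,
                              n_repeats = n_repeats,
                              root_seed = child_seed(seed, 2L, 71L),
                              keep_attributions = "relevance" %in% stages)
    dir.create(file.path(out_dir, "decode"), showWarnings = FALSE)
    utils::write.table(env$rp$participant_table,
                       file.path(out_dir, "decode", "participants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (g in names(env$rp$confusion))
      utils::write.csv(as.data.frame(env$rp$confusion[[g]]),
                       file.path(out_dir, "decode",
                                 sprintf("confusion_%s.csv", g)))
    pt <- env$rp$participant_table
    acc <- split(pt$accuracy, pt$group)
    ent <- split(pt$entropy, pt$group)
    report$outputs$decode <- file.path(out_dir, "decode")
    report$metrics$decode <- list(
      chance_pct = chance_level(length(env$retained)),
      mean_accuracy = lapply(acc, mean),
      mean_entropy = lapply(ent, mean),
      above_chance = lapply(acc, above_chance_test,
                            n_classes = length(env$retained)),
      accuracy_mw = group_tests(acc[[1]], acc[[2]], "mann_whitney")[c("U", "z", "p")],
      entropy_mw = group_tests(ent[[1]], ent[[2]], "mann_whitney")[c("U", "z", "p")])
    # per-phoneme accuracy vs frequency, from the averaged confusions
    cm <- Reduce(`+`, env$rp$confusion)
    pa <- diag(cm) / rowSums(cm)
    w <- config$inventory$weights[rownames(cm)]
    ct <- stats::cor.test(pa, w)
    report$metrics$decode$frequency_accuracy <-
      list(r = unname(ct$estimate), p = ct$p.value)
  })

  if ("relevance" %in% stages) tick("relevance", {
    env$rel <- relevance_table(env$rp$attributions,
                               fs = env$prps[[1]]$fs)
    grp <- vapply(env$rel$id, function(id)
      env$cohort$sessions[[id]]$group, "")
    env$rel$group <- grp
    dir.create(file.path(out_dir, "relevance"), showWarnings = FALSE)
    utils::write.table(env$rel,
                       file.path(out_dir, "relevance", "relevance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    disp <- split(env$rel$dispersion, grp)
    lat <- split(env$rel$peak_latency_ms, grp)
    # group contrast of time-averaged relevance topographies
    maps <- attr(env$rel, "maps")
    topo <- t(vapply(maps, function(m) rowMeans(m$scores),
                     numeric(nrow(maps[[1]]$scores))))
    adj <- electrode_adjacency(env$pre[[1]]$layout)
    ctst <- cluster_permutation_test(topo, "independent",
                                     groups = as.integer(factor(grp)),
                                     adjacency = adj, n_perm = n_perm,
                                     seed = child_seed(seed, 3L, 72L))
    report$outputs$relevance <- file.path(out_dir, "relevance")
    report$metrics$relevance <- list(
      mean_dispersion = lapply(disp, mean),
      dispersion_welch = group_tests(disp[[1]], disp[[2]], "welch")[c("t", "df", "p")],
      median_latency_ms = lapply(lat, stats::median),
      latency_mw = group_tests(lat[[1]], lat[[2]], "mann_whitney")[c("U", "z", "p")],
      topography_clusters = lapply(ctst$clusters, function(cl)
        list(n_sites = length(cl$sites), t_max = cl$t_max, p = cl$p)))
  })

  if ("rsa" %in% stages) tick("rsa", {
    dir.create(file.path(out_dir, "rsa"), showWarnings = FALSE)
    frdm <- feature_rdm(config$inventory)
    frdm <- frdm[env$retained, env$retained]
    frdm <- new_rdm(unclass(frdm), env$retained)
    write_rdm_csv(frdm, file.path(out_dir, "rsa", "feature_rdm.csv"))
    grp <- vapply(env$cohort$sessions, function(s) s$group, "")
    fs <- env$prps[[1]]$fs
    curves <- t(vapply(env$prps, function(ps)
      alignment(neural_rdm_series(ps), frdm)$rho,
      numeric(ncol(env$prps[[1]]$prps[[1]]))))
    for (g in unique(grp)) {
      tab <- data.frame(time_s = (seq_len(ncol(curves)) - 1) / fs,
                        t(curves[grp == g, , drop = FALSE]))
      utils::write.table(tab, file.path(out_dir, "rsa",
                                        sprintf("alignment_%s.tsv", g)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    ctst <- cluster_permutation_test(curves, "independent",
                                     groups = as.integer(factor(grp)),
                                     adjacency = time_adjacency(ncol(curves)),
                                     n_perm = n_perm,
                                     seed = child_seed(seed, 4L, 73L))
    sig <- significant_sites(ctst, 0.05)
    report$metrics$rsa <- list(
      mean_rho = lapply(split(rowMeans(curves), grp), mean),
      curve_clusters = lapply(ctst$clusters, function(cl)
        list(window_s = range((cl$sites - 1) / fs), t_max = cl$t_max,
             p = cl$p)),
      significant_window_s = if (length(sig)) range((sig - 1) / fs))
    if (!is.null(env$rp)) {
      pr <- permutation_rho_difference(env$rp$confusion[[1]],
                                       env$rp$confusion[[2]], frdm,
                                       n_perm = n_perm,
                                       seed = child_seed(seed, 5L, 74L))
      report$metrics$rsa$confusion_alignment <- pr
      jsonlite::write_json(pr, file.path(out_dir, "rsa", "confusion_rho.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    # forward electrode selection per group, ranked by relevance when
    # available, otherwise by PRP signal power
    for (g in unique(grp)) {
      sets <- env$prps[grp == g]
      rank_e <- if (!is.null(env$rel)) {
        maps <- attr(env$rel, "maps")[env$rel$group == g]
        gm <- Reduce(`+`, lapply(maps, function(m) rowMeans(m$scores))) /
          length(maps)
        names(sort(gm, decreasing = TRUE))
      } else {
        pw <- Reduce(`+`, lapply(sets, function(ps)
          rowMeans(Reduce(`+`, lapply(ps$prps, `^`, 2)))))
        names(sort(pw, decreasing = TRUE))
      }
      fsel <- forward_select(sets, rank_e, frdm)
      report$metrics$rsa[[sprintf("forward_selection_%s", g)]] <-
        list(n_electrodes = length(fsel$electrodes), rho = fsel$rho)
      # group-average PRPs for the dendrogram
      avg <- sets[[1]]
      for (lab in names(avg$prps))
        avg$prps[[lab]] <- Reduce(`+`, lapply(sets, function(s)
          s$prps[[lab]])) / length(sets)
      write_newick(phoneme_dendrogram(avg, fsel$electrodes),
                   file.path(out_dir, "rsa", sprintf("dendrogram_%s.nwk", g)))
    }
    report$outputs$rsa <- file.path(out_dir, "rsa")
  })

  if ("track" %in% stages) tick("track", {
    dir.create(file.path(out_dir, "track"), showWarnings = FALSE)
    ids <- names(env$cohort$sessions)
    dr_env <- NULL; dr_ons <- NULL
    for (id in ids) {
      s <- env$cohort$sessions[[id]]
      eeg <- preprocess(s)$recording
      ps <- derive_predictors(s$predictors, fs_eeg = s$fs)
      td <- tracking_delta_r(eeg, ps, s$fs, s$segments,
                             max_steps = trf_max_steps)
      dr_env <- rbind(dr_env, td$delta_env)
      dr_ons <- rbind(dr_ons, td$delta_ons)
    }
    rownames(dr_env) <- rownames(dr_ons) <- ids
    utils::write.table(data.frame(id = ids, dr_env),
                       file.path(out_dir, "track", "delta_r_envelope.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(id = ids, dr_ons),
                       file.path(out_dir, "track", "delta_r_onset.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    adj <- electrode_adjacency(env$cohort$sessions[[1]]$layout[
      seq_len(config$n_electrodes), ])
    grp <- vapply(env$cohort$sessions, function(s) s$group, "")
    env$track <- list()
    for (fam in c("envelope", "onset")) {
      dm <- if (fam == "envelope") dr_env else dr_ons
      roi <- roi_score(dm, adj, n_perm = n_perm,
                       seed = child_seed(seed, 6L, 75L))
      sc <- split(roi$scores, grp)
      env$track[[fam]] <- roi$scores
      gt <- cluster_permutation_test(dm, "independent",
                                     groups = as.integer(factor(grp)),
                                     adjacency = adj, n_perm = n_perm,
                                     seed = child_seed(seed, 7L, 76L))
      report$metrics$track[[fam]] <- list(
        roi_size = length(roi$roi), roi_empty = roi$empty,
        mean_score = lapply(sc, mean, na.rm = TRUE),
        group_clusters = lapply(gt$clusters, function(cl)
          list(n_sites = length(cl$sites), t_max = cl$t_max, p = cl$p)))
    }
    jsonlite::write_json(report$metrics$track,
                         file.path(out_dir, "track", "roi.json"),
                         auto_unbox = TRUE, digits = NA)
    report$outputs$track <- file.path(out_dir, "track")
  })

  if ("stats" %in% stages) tick("stats", {
    dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
    grp <- vapply(env$cohort$sessions, function(s) s$group, "")
    fc <- lapply(split(env$prps, grp), separability_f)
    for (g in names(fc))
      utils::write.table(fc[[g]], file.path(out_dir, "stats",
                                            sprintf("f_curve_%s.tsv", g)),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    report$metrics$stats <- list(
      f_curve_mean = lapply(fc, function(d) mean(d$F, na.rm = TRUE)))
    pt <- env$rp$participant_table
    cov <- env$cohort$participants
    cov <- cov[match(pt$id, cov$id), ]
    n_item <- round(stats::median(
      vapply(env$prps[pt$id], function(p) length(p$prps), 0L)))
    outcome <- rau(round(pt$accuracy * n_item), n_item)
    preds <- cov[, setdiff(names(cov), c("id", "group", "alpha")),
                 drop = FALSE]
    if (!is.null(env$track)) {
      # an empty ROI yields undefined scores; skip such predictors
      if (any(is.finite(env$track$envelope)))
        preds$tracking_envelope <- env$track$envelope[pt$id]
      if (any(is.finite(env$track$onset)))
        preds$tracking_onset <- env$track$onset[pt$id]
    }
    sw <- backward_stepwise(outcome, preds)
    rt <- residual_group_test(outcome,
                              preds[, sw$selected, drop = FALSE],
                              cov$group)
    report$metrics$stats$stepwise <- list(
      selected = sw$selected, aic = sw$aic, adj_r2 = sw$adj_r2)
    report$metrics$stats$residual_welch <- rt$test[c("t", "df", "p", "cohens_d")]
    utils::write.table(sw$trace, file.path(out_dir, "stats", "stepwise_trace.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$outputs$stats <- file.path(out_dir, "stats")
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(report)
}
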