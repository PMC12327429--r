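# On-disk formats: raw float64 recordings with JSON header sidecars,
# CSV annotations/predictors, JSON covariates/truth, labeled CSV RDMs,
# TSV tables and Newick trees.

write_matrix_bin <- function(m, path_bin, path_json, extra = list()) {
  con <- file(path_bin, "wb")
  on.exit(close(con))
  writeBin(as.vector(m), con, size = 8, endian = "little")
  hdr <- c(list(format = "float64-le-column-major",
                n_rows = nrow(m), n_cols = ncol(m),
                row_names = rownames(m)), extra)
  jsonlite::write_json(hdr, path_json, auto_unbox = TRUE, digits = NA)
}

read_matrix_bin <- function(path_bin, path_json) {
  hdr <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  con <- file(path_bin, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = hdr$n_rows * hdr$n_cols, size = 8,
               endian = "little")
  m <- matrix(v, hdr$n_rows, hdr$n_cols)
  if (!is.null(hdr$row_names)) rownames(m) <- hdr$row_names
  attr(m, "header") <- hdr
  m
}

#' Write a simulated session to disk
#'
#' Formats: the recording as raw float64 (column-major) with a JSON
#' header sidecar, annotations as UTF-8 CSV (onset_s, duration_s,
#' phoneme), predictors as a 16-column CSV at the EEG rate, covariates
#' and the generative truth as JSON.
#'
#' @param session a \code{\link{simulate_session}} result.
#' @param dir output directory (created).
#' @return the directory, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_bin(session$recording,
                   file.path(dir, "recording.bin"),
                   file.path(dir, "recording.json"),
                   extra = list(fs = session$fs, unit = "microvolt",
                                group = session$group,
                                participant_id = session$participant_id,
                                segments = session$segments,
                                layout = as.data.frame(session$layout)))
  utils::write.csv(session$annotations, file.path(dir, "annotations.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  pr <- as.data.frame(t(session$predictors))
  utils::write.csv(pr, file.path(dir, "predictors.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(session$covariates),
                       file.path(dir, "covariates.json"),
                       auto_unbox = TRUE, digits = NA)
  tr <- session$truth
  jsonlite::write_json(
    list(alpha = tr$alpha, alpha_group = tr$alpha_group,
         sigma = tr$sigma, tau_ms = tr$tau_ms,
         attenuation = tr$attenuation,
         templates = lapply(tr$templates, unclass),
         kernel_courses = tr$kernel_courses,
         kernel_gains = tr$kernel_gains,
         features = tr$features, seed = session$seed),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Read a session written by \code{\link{write_session}}
#' @param dir session directory.
#' @return a \code{simulated_session}-shaped list.
#' @export
read_session <- function(dir) {
  rec <- read_matrix_bin(file.path(dir, "recording.bin"),
                         file.path(dir, "recording.json"))
  hdr <- attr(rec, "header")
  attr(rec, "header") <- NULL
  ann <- utils::read.csv(file.path(dir, "annotations.csv"),
                         stringsAsFactors = FALSE)
  pred <- t(as.matrix(utils::read.csv(file.path(dir, "predictors.csv"))))
  cov <- unlist(jsonlite::read_json(file.path(dir, "covariates.json"),
                                    simplifyVector = TRUE))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  layout <- as.matrix(hdr$layout)
  rownames(layout) <- rownames(rec)
  out <- list(recording = rec, fs = hdr$fs, layout = layout,
              annotations = ann, segments = as.data.frame(hdr$segments),
              predictors = pred, covariates = cov, group = hdr$group,
              participant_id = hdr$participant_id, truth = truth,
              seed = truth$seed)
  class(out) <- "simulated_session"
  out
}

#' Write a PRP set (binary container + JSON header)
#' @param prp_set a \code{\link{extract_prps}} result.
#' @param path_bin,path_json output paths.
#' @export
write_prp_set <- function(prp_set, path_bin, path_json) {
  stacked <- do.call(rbind, prp_set$prps)
  con <- file(path_bin, "wb")
  writeBin(as.vector(stacked), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(
    list(format = "float64-le-column-major, phonemes stacked along rows",
         labels = names(prp_set$prps),
         n_electrodes = nrow(prp_set$prps[[1]]),
         electrodes = rownames(prp_set$prps[[1]]),
         n_time = ncol(prp_set$prps[[1]]),
         counts = as.list(prp_set$counts), window = prp_set$window,
         fs = prp_set$fs, participant_id = prp_set$participant_id,
         group = prp_set$group),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_bin)
}

#' Read a PRP set written by \code{\link{write_prp_set}}
#' @param path_bin,path_json input paths.
#' @return a \code{prp_set}.
#' @export
read_prp_set <- function(path_bin, path_json) {
  hdr <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  K <- length(hdr$labels)
  con <- file(path_bin, "rb")
  v <- readBin(con, "numeric", n = K * hdr$n_electrodes * hdr$n_time,
               size = 8, endian = "little")
  close(con)
  stacked <- matrix(v, K * hdr$n_electrodes, hdr$n_time)
  prps <- lapply(seq_len(K), function(k) {
    m <- stacked[(k - 1) * hdr$n_electrodes + seq_len(hdr$n_electrodes), ,
                 drop = FALSE]
    rownames(m) <- hdr$electrodes
    m
  })
  names(prps) <- hdr$labels
  out <- list(prps = prps, counts = unlist(hdr$counts), n_dropped = NA,
              selected = NULL, window = hdr$window, fs = hdr$fs,
              participant_id = hdr$participant_id, group = hdr$group)
  class(out) <- "prp_set"
  out
}

#' Write an RDM as labeled CSV
#' @param rdm an \code{rdm} matrix.
#' @param path output path.
#' @export
write_rdm_csv <- function(rdm, path) {
  utils::write.csv(as.data.frame(unclass(rdm)), path, row.names = TRUE)
  invisible(path)
}

#' Write a phoneme tree as Newick text
#' @param tree an \code{hclust} result (see
#'   \code{\link{phoneme_dendrogram}}).
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Read a plain-text key-value configuration file
#'
#' One \code{key = value} pair per line; \code{#} comments allowed.
#' Group parameters use dotted keys
#' (\code{group.<name>.alpha/sigma/tau_ms}); inventory parameters use
#' \code{inventory.n_phonemes/zipf_exponent/seed}; every other key maps
#' to a \code{\link{cohort_config}} argument (e.g. \code{n_per_group},
#' \code{n_electrodes}, \code{fs}, \code{n_segments},
#' \code{segment_dur}, \code{noise_sd}, \code{seed}).
#'
#' @param path file path.
#' @return a \code{cohort_config}.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stopf("malformed config line: '%s'", lines[bad][1])
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  num <- suppressWarnings(as.numeric(vals))
  groups <- list()
  inv_args <- list(n_phonemes = 12, zipf_exponent = 1, seed = 1L)
  args <- list()
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (parts[1] == "group" && length(parts) == 3) {
      groups[[parts[2]]][[parts[3]]] <- num[i]
    } else if (parts[1] == "inventory" && length(parts) == 2) {
      inv_args[[parts[2]]] <- num[i]
    } else {
      args[[keys[i]]] <- if (is.na(num[i])) vals[i] else num[i]
    }
  }
  if (length(groups) == 0)
    stopf("config defines no groups (group.<name>.alpha = ...)")
  args$group_params <- groups
  args$inventory <- do.call(make_inventory, inv_args)
  do.call(cohort_config, args)
}
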