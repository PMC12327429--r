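# Preprocessing and phoneme-related potential (PRP) derivation.

#' Design a minimum-phase causal FIR band-pass filter
#'
#' Windowed-sinc (Hamming) band-pass design converted to minimum phase
#' via the real-cepstrum method, so the filter is causal with the bulk of
#' its energy near zero delay. The coefficients are mean-corrected so the
#' DC gain is exactly zero.
#'
#' @param low,high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order linear-phase prototype order (even).
#' @return numeric vector of filter coefficients.
#' @export
design_bandpass <- function(low = 1, high = 15, fs = 128, order = 128) {
  if (high >= fs / 2) stopf("high edge must be below Nyquist (%g Hz)", fs / 2)
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  h <- minimum_phase(h)
  h - mean(h)                       # exact DC null
}

# Minimum-phase version of an FIR filter (same magnitude response),
# via folding of the real cepstrum.
minimum_phase <- function(h, nfft = 4096) {
  H <- abs(stats::fft(c(h, rep(0, nfft - length(h)))))
  H <- pmax(H, max(H) * 1e-8)
  cep <- Re(stats::fft(log(H), inverse = TRUE)) / nfft
  fold <- cep
  fold[2:(nfft / 2)] <- 2 * cep[2:(nfft / 2)]
  fold[(nfft / 2 + 2):nfft] <- 0
  hm <- Re(stats::fft(exp(stats::fft(fold)), inverse = TRUE)) / nfft
  hm[seq_along(h)]
}

#' Band-pass filter and mastoid re-referencing
#'
#' Applies a causal minimum-phase FIR band-pass (default 1-15 Hz) to
#' every channel and re-references by subtracting the average of the two
#' mastoid channels, which are then excluded from the output.
#'
#' @param session a \code{\link{simulate_session}} result, or any list
#'   with \code{recording} (channels x samples, rownames set), \code{fs}
#'   and \code{layout}.
#' @param low,high band edges (Hz).
#' @param mastoids character vector of the two mastoid channel names.
#' @param order FIR prototype order.
#' @return the session with filtered, re-referenced \code{recording}
#'   (mastoid rows dropped) and an attribute-style \code{preprocessed}
#'   flag.
#' @export
preprocess <- function(session, low = 1, high = 15,
                       mastoids = c("M1", "M2"), order = 128) {
  rec <- session$recording
  if (session$fs < 64) stopf("sampling rate must be >= 64 Hz")
  if (is.null(rownames(rec)) || !all(mastoids %in% rownames(rec)))
    stopf("mastoid channels %s not found in the recording; designate two mastoid channels",
          paste(mastoids, collapse = ", "))
  h <- design_bandpass(low, high, session$fs, order)
  filtered <- filter_rows_fft(rec, h)
  rownames(filtered) <- rownames(rec)
  ref <- colMeans(filtered[mastoids, , drop = FALSE])
  filtered <- sweep(filtered, 2, ref)
  keep <- setdiff(rownames(rec), mastoids)
  session$recording <- filtered[keep, , drop = FALSE]
  if (!is.null(session$layout))
    session$layout <- session$layout[setdiff(rownames(session$layout), mastoids), ,
                                     drop = FALSE]
  session$preprocessed <- TRUE
  session
}

#' Select phonemes by relative frequency
#'
#' Retains the labels whose instance count strictly exceeds
#' \code{min_fraction} of all instances (mirroring a ">1% of instances"
#' rule) and that are not explicitly excluded, in alphabetical order.
#'
#' @param annotations data.frame with a \code{phoneme} column.
#' @param min_fraction retention threshold as a fraction of all
#'   instances (strict inequality).
#' @param exclude character vector of labels to drop regardless of count.
#' @return character vector of retained labels, alphabetical.
#' @export
select_phonemes <- function(annotations, min_fraction = 0.01,
                            exclude = character()) {
  if (nrow(annotations) == 0) stopf("annotations are empty")
  counts <- table(annotations$phoneme)
  keep <- names(counts)[counts > min_fraction * sum(counts)]
  keep <- setdiff(keep, exclude)
  if (length(keep) == 0)
    stopf("no phoneme exceeds %g of %d instances after excluding {%s}",
          min_fraction, sum(counts), paste(exclude, collapse = ", "))
  sort(keep)
}

#' Extract phoneme-related potentials
#'
#' Epochs the recording at each instance of each retained phoneme over
#' \code{window} (half-open, relative to phoneme onset) and averages per
#' phoneme. Phonemes with more than \code{cap} complete instances are
#' averaged over a seeded uniform random subset of size \code{cap}
#' (without replacement), removing the frequency-driven SNR advantage of
#' common phonemes. Epochs running past the end of the recording are
#' dropped (counted).
#'
#' @param session preprocessed session (recording channels x samples).
#' @param retained character vector of labels to extract (see
#'   \code{\link{select_phonemes}}).
#' @param cap maximum number of instances entering one average.
#' @param window c(start, end) in s relative to onset; default c(0, 0.5).
#' @param seed integer seed for the subset draw.
#' @return object of class \code{prp_set}: list with \code{prps}
#'   (label -> E x T matrix), \code{counts}, \code{n_dropped},
#'   \code{selected} (annotation row indices averaged, per label),
#'   \code{window}, \code{fs}, \code{participant_id}, \code{group}.
#' @export
extract_prps <- function(session, retained, cap = 319,
                         window = c(0, 0.5), seed = 1L) {
  rec <- session$recording
  fs <- session$fs
  ann <- session$annotations
  Tn <- floor((window[2] - window[1]) * fs)
  N <- ncol(rec)
  missing_lab <- setdiff(retained, unique(ann$phoneme))
  if (length(missing_lab))
    stopf("retained labels not present in annotations: %s",
          paste(missing_lab, collapse = ", "))
  prps <- vector("list", length(retained))
  names(prps) <- retained
  counts <- integer(length(retained))
  names(counts) <- retained
  selected <- vector("list", length(retained))
  names(selected) <- retained
  n_dropped <- 0L
  for (lab in retained) {
    rows <- which(ann$phoneme == lab)
    idx0 <- floor(ann$onset_s[rows] * fs) + 1L + round(window[1] * fs)
    ok <- idx0 >= 1L & (idx0 + Tn - 1L) <= N
    n_dropped <- n_dropped + sum(!ok)
    rows <- rows[ok]
    idx0 <- idx0[ok]
    if (length(rows) == 0)
      stopf("phoneme '%s' has no complete epoch in [%g, %g) s", lab,
            window[1], window[2])
    if (length(rows) > cap) {
      pick <- with_seed(child_seed(seed, match(lab, retained), 7L),
                        sample.int(length(rows), cap))
      rows <- rows[pick]
      idx0 <- idx0[pick]
    }
    acc <- matrix(0, nrow(rec), Tn)
    for (j in seq_along(rows))
      acc <- acc + rec[, idx0[j]:(idx0[j] + Tn - 1L)]
    prps[[lab]] <- acc / length(rows)
    rownames(prps[[lab]]) <- rownames(rec)
    counts[lab] <- length(rows)
    selected[[lab]] <- rows
  }
  out <- list(prps = prps, counts = counts, n_dropped = n_dropped,
              selected = selected, window = window, fs = fs,
              participant_id = session$participant_id %||% "P1",
              group = session$group %||% NA_character_)
  class(out) <- "prp_set"
  out
}

#' @export
print.prp_set <- function(x, ...) {
  d <- dim(x$prps[[1]])
  cat(sprintf("PRP set %s: %d phonemes, %d electrodes x %d time points, counts %d..%d\n",
              x$participant_id, length(x$prps), d[1], d[2],
              min(x$counts), max(x$counts)))
  invisible(x)
}
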