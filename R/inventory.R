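#' Build a synthetic phoneme inventory with binary phonetic features
#'
#' Creates a table of phoneme labels, their binary phonetic-feature triples
#' ([syllabic], [sonorant], [continuant]) and Zipf-distributed relative
#' frequencies. The four manner classes implied by the feature triples --
#' vowels (1,1,1), approximants/nasals (0,1,1), fricatives (0,0,1) and
#' stops (0,0,0) -- are always all represented when \code{n_phonemes >= 4}.
#' Phoneme frequency in natural speech is highly skewed, which the Zipf
#' law emulates; the seed controls which manner class lands on which
#' frequency rank so that frequency and class are not confounded.
#'
#' @param n_phonemes number of phonemes (>= 4).
#' @param zipf_exponent exponent s of the Zipf law w_r proportional to
#'   r^(-s); 0 gives a flat distribution.
#' @param seed integer seed controlling the class-to-rank assignment.
#' @return an object of class \code{phoneme_inventory}: a list with
#'   \code{labels} (character), \code{features} (K x 3 0/1 matrix with
#'   columns syllabic, sonorant, continuant), \code{weights} (relative
#'   frequencies summing to 1) and \code{classes} (manner-class index).
#' @export
make_inventory <- function(n_phonemes, zipf_exponent = 1, seed = 1L) {
  if (!is.numeric(n_phonemes) || n_phonemes < 4)
    stopf("n_phonemes must be at least 4 (got %s); the four manner classes must all be representable",
          format(n_phonemes))
  n_phonemes <- as.integer(n_phonemes)
  feat_by_class <- rbind(
    vowel        = c(1, 1, 1),
    approx_nasal = c(0, 1, 1),
    fricative    = c(0, 0, 1),
    stop         = c(1, 1, 1) * 0
  )
  colnames(feat_by_class) <- c("syllabic", "sonorant", "continuant")
  # Cycle over the classes so all four appear, then shuffle the assignment
  # of classes to frequency ranks.
  classes <- rep_len(1:4, n_phonemes)
  classes <- with_seed(seed, {
    rest <- classes[-(1:4)]
    c(sample(1:4), rest[sample.int(length(rest))])
  })
  prefix <- c("V", "R", "F", "S")[classes]
  idx <- stats::ave(seq_len(n_phonemes), classes, FUN = seq_along)
  labels <- sprintf("%s%02d", prefix, idx)
  w <- seq_len(n_phonemes)^(-zipf_exponent)
  w <- w / sum(w)
  inv <- list(labels = labels,
              features = feat_by_class[classes, , drop = FALSE],
              weights = w,
              classes = classes)
  rownames(inv$features) <- labels
  names(inv$weights) <- labels
  class(inv) <- "phoneme_inventory"
  validate_inventory(inv)
  inv
}

validate_inventory <- function(inv) {
  if (anyDuplicated(inv$labels)) stopf("inventory labels must be unique")
  if (!all(inv$features %in% c(0, 1)))
    stopf("every feature value must be exactly 0 or 1")
  if (any(inv$weights <= 0) || abs(sum(inv$weights) - 1) > 1e-9)
    stopf("weights must be strictly positive and sum to 1")
  invisible(inv)
}

#' @export
print.phoneme_inventory <- function(x, ...) {
  cat(sprintf("Phoneme inventory: %d labels, weights %.3f .. %.3f\n",
              length(x$labels), max(x$weights), min(x$weights)))
  invisible(x)
}

#' Electrode layout on the unit disc
#'
#' Deterministic sunflower-spiral layout of \code{n} scalp electrodes on
#' the unit disc, mimicking an even cap montage. Two mastoid reference
#' positions are appended below the disc edge.
#'
#' @param n number of scalp electrodes.
#' @return matrix (n + 2) x 2 of x/y coordinates with rownames
#'   \code{E01..}, \code{M1}, \code{M2}.
#' @export
make_layout <- function(n) {
  i <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n)
  th <- i * golden
  xy <- cbind(x = r * cos(th), y = r * sin(th))
  xy <- rbind(xy, c(-1.05, -0.55), c(1.05, -0.55))
  rownames(xy) <- c(sprintf("E%02d", i), "M1", "M2")
  xy
}
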