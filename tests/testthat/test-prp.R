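# Preprocessing and PRP derivation.

test_that("the band-pass filter rejects DC and passes 8 Hz", {
  h <- design_bandpass(1, 15, fs = 128)
  y <- prpdecode:::causal_filter(rep(5, 1200), h)
  expect_lt(max(abs(y[(3 * length(h)):1200])), 0.01)
  x8 <- sin(2 * pi * 8 * (0:1199) / 128)
  y8 <- prpdecode:::causal_filter(x8, h)
  amp <- max(abs(y8[600:1100]))
  expect_lt(abs(amp - 1), 0.1)
  # 30 Hz well outside the band
  x30 <- sin(2 * pi * 30 * (0:1199) / 128)
  y30 <- prpdecode:::causal_filter(x30, h)
  expect_lt(max(abs(y30[600:1100])), 0.1)
})

test_that("preprocess re-references to the mastoids and drops them", {
  s <- clean_session(seed = 2)
  pp <- preprocess(s)
  expect_equal(nrow(pp$recording), nrow(s$recording) - 2)
  expect_false(any(c("M1", "M2") %in% rownames(pp$recording)))
  # identical channels re-reference to exactly zero
  s2 <- s
  s2$recording <- matrix(rep(s$recording[1, ], each = nrow(s$recording)),
                         nrow(s$recording), ncol(s$recording),
                         dimnames = dimnames(s$recording))
  pp2 <- preprocess(s2)
  expect_lt(max(abs(pp2$recording)), 1e-10)
  s3 <- s
  rownames(s3$recording) <- paste0("X", seq_len(nrow(s3$recording)))
  expect_error(preprocess(s3), "mastoid")
})

test_that("phoneme selection applies the strict frequency threshold", {
  ann <- data.frame(phoneme = rep(c("A", "B", "C"), c(50, 30, 20)))
  expect_equal(select_phonemes(ann, 0.01), c("A", "B", "C"))
  ann2 <- data.frame(phoneme = rep(c("A", "B", "C"), c(990, 9, 1)))
  expect_equal(select_phonemes(ann2, 0.01), "A")   # 0.9% is not > 1%
  ann3 <- data.frame(phoneme = rep(c("AH", "S", "T"), c(500, 300, 200)))
  expect_equal(select_phonemes(ann3, exclude = "AH"), c("S", "T"))
  expect_error(select_phonemes(ann2[0, , drop = FALSE]), "empty")
  expect_error(select_phonemes(ann, min_fraction = 0.99), "no phoneme")
})

test_that("PRP averaging is exact and epochs have the printed shape", {
  fs <- 128
  rec <- matrix(rnorm(4 * fs * 6), 4, fs * 6,
                dimnames = list(sprintf("E%02d", 1:4), NULL))
  sess <- list(recording = rec, fs = fs, participant_id = "P1",
               annotations = data.frame(
                 onset_s = c(1, 2.5, 4), duration_s = 0.1,
                 phoneme = c("X", "X", "Y"), stringsAsFactors = FALSE))
  ps <- extract_prps(sess, c("X", "Y"), seed = 1)
  expect_equal(ncol(ps$prps$X), 64)              # 0.5 s at 128 Hz
  i1 <- floor(1 * fs) + 1; i2 <- floor(2.5 * fs) + 1
  expect_equal(ps$prps$X,
               (rec[, i1:(i1 + 63)] + rec[, i2:(i2 + 63)]) / 2)
  # constant recording -> constant PRP
  sessc <- sess
  sessc$recording[] <- 3.25
  psc <- extract_prps(sessc, "X", seed = 1)
  expect_true(all(psc$prps$X == 3.25))
  # epoch past the end of the recording is dropped
  sesse <- sess
  sesse$annotations$onset_s[3] <- 5.9
  expect_error(extract_prps(sesse, "Y", seed = 1), "no complete epoch")
})

test_that("the instance cap draws a seeded subset whose plain average matches", {
  fs <- 128
  n_inst <- 40
  rec <- matrix(rnorm(2 * fs * 50), 2, fs * 50,
                dimnames = list(c("E01", "E02"), NULL))
  sess <- list(recording = rec, fs = fs, participant_id = "P1",
               annotations = data.frame(
                 onset_s = seq(1, 44, length.out = n_inst),
                 duration_s = 0.1, phoneme = "X",
                 stringsAsFactors = FALSE))
  ps <- extract_prps(sess, "X", cap = 15, seed = 7)
  expect_equal(unname(ps$counts["X"]), 15L)
  # brute-force average of the logged subset
  rows <- ps$selected$X
  idx0 <- floor(sess$annotations$onset_s[rows] * fs) + 1L
  acc <- Reduce(`+`, lapply(idx0, function(i) rec[, i:(i + 63)])) / 15
  expect_equal(ps$prps$X, acc, tolerance = 1e-12)
  # same seed, same subset; different seed, (almost surely) different
  ps2 <- extract_prps(sess, "X", cap = 15, seed = 7)
  expect_identical(ps$selected, ps2$selected)
})

test_that("PRP extraction is linear in the recording", {
  s <- clean_session(seed = 6)
  s$recording <- s$recording[1:8, , drop = FALSE]
  ret <- select_phonemes(s$annotations)
  p1 <- extract_prps(s, ret, seed = 1)
  s2 <- s
  s2$recording <- 2 * s$recording
  p2 <- extract_prps(s2, ret, seed = 1)
  for (lab in ret)
    expect_equal(p2$prps[[lab]], 2 * p1$prps[[lab]], tolerance = 1e-12)
})
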