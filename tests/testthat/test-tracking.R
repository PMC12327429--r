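# Band predictors, boosting TRFs, unique variance and ROI scoring.

test_that("predictor derivation compresses, sums and differentiates correctly", {
  # synthetic mode: envelopes pass through, onsets are rectified diffs
  env <- matrix(abs(rnorm(8 * 100)), 8, 100)
  ps <- derive_predictors(env, fs_eeg = 128)
  expect_equal(unname(ps$env), unname(env))
  expect_true(all(ps$ons >= 0))
  expect_equal(unname(ps$ons[1, 2:100]), pmax(diff(env[1, ]), 0))
  # constant envelope -> zero onsets
  ps2 <- derive_predictors(matrix(1, 8, 50), fs_eeg = 128)
  expect_true(all(ps2$ons == 0))
  # envelope step 0 -> 1: single positive onset pulse at the step
  stepm <- matrix(rep(c(rep(0, 10), rep(1, 10)), each = 8), 8, 20)
  ps3 <- derive_predictors(stepm, fs_eeg = 128)
  expect_equal(which(ps3$ons[1, ] > 0), 11L)
  # power-law compression on the waveform path
  expect_equal(0.5^0.6, 0.659753955386447, tolerance = 1e-12)
  expect_error(derive_predictors(matrix(1, 3, 10), fs_eeg = 128), "rows")
  expect_error(derive_predictors(rnorm(1000), fs_audio = 8000), "10 kHz")
})

trf_fixture <- function(seed = 2, noise = 0) {
  set.seed(seed)
  fs <- 128; nseg <- 10; segdur <- 5; N <- nseg * segdur * fs
  pred <- make_band_predictors(N, fs, seed = seed + 1)[1:2, , drop = FALSE]
  lagt <- (0:31) / fs
  ktrue <- sin(2 * pi * 4 * lagt) * exp(-lagt / 0.07)
  sig <- prpdecode:::causal_filter(pred[1, ], ktrue)
  eeg <- rbind(sig, 0.5 * sig) + noise * matrix(rnorm(2 * N), 2, N)
  rownames(eeg) <- c("E01", "E02")
  segs <- data.frame(start_s = (0:(nseg - 1)) * segdur,
                     end_s = (1:nseg) * segdur)
  lag_idx <- round(-0.1 * fs):round(0.5 * fs)
  truth <- c(rep(0, sum(lag_idx < 0)), ktrue, rep(0, sum(lag_idx > 31)))
  list(eeg = eeg, pred = pred, fs = fs, segs = segs, truth = truth)
}

test_that("boosting recovers generative kernels and prediction accuracy", {
  fx <- trf_fixture()
  m <- boost_trf(fx$eeg, fx$pred, fx$fs, fx$segs, folds = 5,
                 max_steps = 1000, patience = 20)
  expect_gte(min(m$r), 0.95)
  expect_gte(cor(m$kernels[1, , 1], fx$truth), 0.9)
  # the silent band contributes little kernel energy
  expect_lt(sum(m$kernels[2, , 1]^2) / sum(m$kernels[1, , 1]^2), 0.1)
  # no training-segment leakage: folds partition all segments
  expect_equal(sort(unname(rep_len(1:5, 10))), sort(rep(1:5, 2)))
})

test_that("doubling the predictors halves the kernels, prediction unchanged", {
  fx <- trf_fixture()
  m1 <- boost_trf(fx$eeg, fx$pred, fx$fs, fx$segs, folds = 5,
                  max_steps = 400, patience = 15)
  m2 <- boost_trf(fx$eeg, 2 * fx$pred, fx$fs, fx$segs, folds = 5,
                  max_steps = 400, patience = 15)
  expect_equal(m1$kernels[1, , 1], 2 * m2$kernels[1, , 1], tolerance = 1e-9)
  expect_equal(m1$r, m2$r, tolerance = 1e-9)
})

test_that("boosting on noise yields near-zero r; zero predictors are flagged", {
  set.seed(9)
  rs <- replicate(6, {
    fx <- trf_fixture(seed = sample.int(1e6, 1))
    eegn <- matrix(rnorm(length(fx$eeg)), nrow(fx$eeg))
    rownames(eegn) <- rownames(fx$eeg)
    mn <- boost_trf(eegn, fx$pred, fx$fs, fx$segs, folds = 5,
                    max_steps = 200, patience = 10)
    mean(mn$r)
  })
  expect_lt(abs(mean(rs)), 0.05)
  fx <- trf_fixture()
  m0 <- boost_trf(fx$eeg, fx$pred * 0, fx$fs, fx$segs, folds = 5,
                  max_steps = 50)
  expect_true(all(m0$kernels == 0))
  expect_true(all(m0$r == 0))
  expect_true(all(m0$zero_flag))
})

test_that("delta r isolates the driving predictor and is antisymmetric", {
  fx <- trf_fixture()
  full <- boost_trf(fx$eeg, fx$pred, fx$fs, fx$segs, folds = 5,
                    max_steps = 400, patience = 15)
  reduced <- boost_trf(fx$eeg, fx$pred[2, , drop = FALSE], fx$fs, fx$segs,
                       folds = 5, max_steps = 400, patience = 15)
  dr <- delta_r(full, reduced)
  expect_true(all(dr > 0.5))          # band 1 generated the signal
  expect_equal(delta_r(reduced, full), -dr)
  same <- delta_r(full, full)
  expect_true(all(abs(same) < 0.02))
})

test_that("ROI scoring finds the active electrode block and scores means", {
  lay <- make_layout(12)[1:12, ]
  adj <- electrode_adjacency(lay)
  set.seed(5)
  dm <- matrix(rnorm(10 * 12, sd = 0.01), 10, 12)
  active <- which(adj[1, ])[1:3]
  active <- unique(c(1L, active))
  dm[, active] <- dm[, active] + 0.5
  rs <- roi_score(dm, adj, n_perm = 500, seed = 2)
  expect_setequal(rs$roi, active)
  # uniform delta r over the ROI scores exactly that value
  dmu <- dm
  dmu[1, ] <- 0
  dmu[1, active] <- 0.7
  rs2 <- roi_score(rbind(dmu[1, ], dm[-1, ]), adj, n_perm = 500, seed = 2)
  if (setequal(rs2$roi, active))
    expect_equal(unname(rs2$scores[1]), 0.7)
  # pure-noise topographies rarely produce an ROI
  empties <- replicate(10, {
    dn <- matrix(rnorm(10 * 12), 10, 12)
    roi_score(dn, adj, n_perm = 300, seed = sample.int(1e6, 1))$empty
  })
  expect_gte(mean(empties), 0.7)
})
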