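# Convolutional decoder: entropy, folds, training, determinism.

test_that("prediction entropy has the exact closed-form values and bounds", {
  expect_equal(prediction_entropy(c(1, 0, 0)), 0)
  expect_equal(prediction_entropy(rep(1 / 31, 31)), log(31))
  expect_equal(prediction_entropy(c(0.5, 0.5, 0, 0)), log(2))
  expect_error(prediction_entropy(c(0.7, 0.2)), "sum")
  expect_error(prediction_entropy(c(1.2, -0.2)), "probability")
  expect_equal(chance_level(31), 100 / 31)
})

test_that("the compiled engine reproduces the R reference network exactly", {
  set.seed(4)
  spec <- classifier_spec(folds = 5, kernel2 = 5, pool1 = 2, pool2 = 2,
                          dropout = 0, batch_size = 64, max_epochs = 4)
  E <- 5; Tn <- 16; K <- 3; fs <- 32; n <- 24
  y <- rep(1:K, 8)
  X <- array(rnorm(n * E * Tn), c(n, E, Tn))
  model <- prpdecode:::net_init(E, Tn, K, fs, spec, seed = 2)
  fwR <- prpdecode:::net_forward(model, X)
  fwC <- prpdecode:::.cpp_net_forward(model, X)
  expect_lt(max(abs(fwR$logits - fwC$logits)), 1e-12)
  # full-batch, no-dropout training: identical parameter trajectories
  mR <- prpdecode:::net_train(X, y, K, fs, spec, 1:18, 19:24, seed = 7,
                              engine = "r")
  mC <- prpdecode:::net_train(X, y, K, fs, spec, 1:18, 19:24, seed = 7,
                              engine = "cpp")
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       mR$params, mC$params)), 1e-10)
})

test_that("network gradients match finite differences", {
  set.seed(1)
  spec <- classifier_spec(kernel2 = 5, pool1 = 2, pool2 = 2)
  E <- 4; Tn <- 12; K <- 3; fs <- 24; B <- 5
  model <- prpdecode:::net_init(E, Tn, K, fs, spec, seed = 3)
  X <- array(rnorm(B * E * Tn), c(B, E, Tn))
  y <- sample(1:K, B, TRUE)
  lossfun <- function(m)
    prpdecode:::cross_entropy(prpdecode:::net_forward(m, X)$probs, y)
  fw <- prpdecode:::net_forward(model, X)
  dlog <- fw$probs
  dlog[cbind(1:B, y)] <- dlog[cbind(1:B, y)] - 1
  dlog <- dlog / B
  bw <- prpdecode:::net_backward(model, fw$cache, dlog,
                                 prpdecode:::elu_grad(fw$cache$ZbM),
                                 prpdecode:::elu_grad(fw$cache$Z5))
  eps <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    ii <- sample(length(p), min(4, length(p)))
    num <- vapply(ii, function(i) {
      m2 <- model
      m2$params[[nm]][i] <- p[i] + eps
      l1 <- lossfun(m2)
      m2$params[[nm]][i] <- p[i] - eps
      (l1 - lossfun(m2)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(num - bw$grads[[nm]][ii]) / (abs(num) + 1e-8)), 1e-5)
  }
})

test_that("stratified folds cover every sample once and keep labels in training", {
  sets <- toy_prp_sets(n_participants = 5, K = 4, noise = 0.2)
  spec <- classifier_spec(folds = 5, max_epochs = 1)
  cv <- train_eval_cv(sets, spec, seed = 3)
  expect_equal(length(cv$fold), 20)
  expect_true(all(table(cv$fold) == 4))
  expect_false(any(is.na(cv$probs)))
  expect_true(all(abs(rowSums(cv$probs) - 1) < 1e-6))
  expect_true(all(cv$samples$entropy >= 0 &
                    cv$samples$entropy <= log(4) + 1e-9))
  # confusion row sums equal per-label test counts (each sample once)
  expect_true(all(rowSums(cv$confusion) == 5))
})

test_that("the decoder reaches the nearest-centroid oracle on separable data", {
  sets <- toy_prp_sets(n_participants = 6, K = 6, E = 10, Tn = 64,
                       noise = 0.05, fs = 128, seed = 8)
  expect_equal(centroid_loo_accuracy(sets), 1.0)
  spec <- classifier_spec(folds = 4, max_epochs = 150, patience = 15)
  cv <- train_eval_cv(sets, spec, seed = 5)
  expect_equal(mean(cv$samples$correct), 1.0)
})

test_that("decoding permuted labels sits in the chance band and runs are reproducible", {
  sets <- toy_prp_sets(n_participants = 6, K = 4, E = 6, Tn = 16,
                       noise = 0.1, seed = 12)
  # permute each participant's label assignment to break the structure
  set.seed(3)
  sets_perm <- lapply(sets, function(ps) {
    ps$prps <- ps$prps[sample(length(ps$prps))]
    names(ps$prps) <- sort(names(ps$prps))
    ps
  })
  spec <- classifier_spec(folds = 4, max_epochs = 30, patience = 10)
  cv <- train_eval_cv(sets_perm, spec, seed = 9)
  n <- nrow(cv$samples)
  band <- qbinom(c(0.005, 0.995), n, 1 / 4) / n
  acc <- mean(cv$samples$correct)
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
  cv2 <- train_eval_cv(sets_perm, spec, seed = 9)
  expect_identical(cv$samples, cv2$samples)
})

test_that("the repetition protocol balances group sizes and averages repetitions", {
  setsA <- toy_prp_sets(n_participants = 4, K = 4, noise = 0.1, seed = 1)
  setsB <- toy_prp_sets(n_participants = 3, K = 4, noise = 0.6, seed = 2)
  for (i in seq_along(setsB))
    setsB[[i]]$participant_id <- sprintf("T%02d", i)
  # repeat_protocol re-extracts PRPs from sessions, so wrap the toy PRPs
  # in minimal session objects
  mk_sess <- function(ps) {
    fs <- ps$fs; Tn <- ncol(ps$prps[[1]]); K <- length(ps$prps)
    N <- (K + 2) * Tn
    rec <- matrix(0, nrow(ps$prps[[1]]), N,
                  dimnames = list(rownames(ps$prps[[1]]), NULL))
    ann <- data.frame(onset_s = numeric(), duration_s = numeric(),
                      phoneme = character())
    for (k in seq_len(K)) {
      i0 <- (k - 1) * Tn + 1
      rec[, i0:(i0 + Tn - 1)] <- ps$prps[[k]]
      ann <- rbind(ann, data.frame(onset_s = (i0 - 1) / fs,
                                   duration_s = Tn / fs,
                                   phoneme = names(ps$prps)[k]))
    }
    list(recording = rec, fs = fs, annotations = ann,
         participant_id = ps$participant_id, group = ps$group)
  }
  sa <- lapply(setsA, mk_sess)
  sb <- lapply(setsB, mk_sess)
  spec <- classifier_spec(folds = 3, max_epochs = 10, patience = 5,
                          val_fraction = 0.2)
  rp <- repeat_protocol(sa, sb, names(setsA[[1]]$prps), spec,
                        n_repeats = 2, root_seed = 4,
                        window = c(0, ncol(setsA[[1]]$prps[[1]]) / setsA[[1]]$fs))
  pt <- rp$participant_table
  # group b participants appear in every repetition; one a is dropped
  expect_true(all(pt$n_reps[pt$group == "b"] == 2))
  expect_equal(sum(pt$n_reps[pt$group == "a"]), 2 * 3)
  expect_equal(sum(rp$confusion$a), 4 * 3)  # K x n per repetition, averaged
})

test_that("frequency-accuracy correlation matches the closed form", {
  cv <- list(samples = data.frame(
    label = rep(c("a", "b", "c"), each = 10),
    correct = c(rep(TRUE, 9), FALSE, rep(TRUE, 5), rep(FALSE, 5),
                TRUE, rep(FALSE, 9))))
  w <- c(a = 1, b = 2, c = 3)
  out <- frequency_accuracy_check(cv, w)
  expect_equal(out$r, -1, tolerance = 1e-12)
  cv2 <- list(samples = data.frame(label = rep(c("a", "b", "c"), each = 4),
                                   correct = TRUE))
  out2 <- frequency_accuracy_check(cv2, w)
  expect_equal(out2$r, 0)
  expect_true(out2$degenerate)
  expect_error(frequency_accuracy_check(
    list(samples = data.frame(label = c("a", "b"), correct = TRUE)), w),
    "3 labels")
})
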