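# Representational similarity analysis.

test_that("feature RDM distances are exact Euclidean feature distances", {
  inv <- list(features = rbind(a = c(1, 1, 1), b = c(0, 0, 0),
                               c = c(1, 0, 0), d = c(0, 1, 0)))
  colnames(inv$features) <- c("syllabic", "sonorant", "continuant")
  rdm <- feature_rdm(inv)
  expect_equal(rdm["a", "b"], sqrt(3), tolerance = 1e-12)
  expect_equal(rdm["c", "d"], sqrt(2), tolerance = 1e-12)
  expect_equal(rdm["a", "a"], 0)
  expect_true(isSymmetric(unclass(rdm)))
  expect_error(feature_rdm(inv, "voiced"), "unknown feature")
})

test_that("neural RDM series matches a brute-force pairwise loop", {
  sets <- toy_prp_sets(n_participants = 1, K = 4, E = 5, Tn = 6, noise = 0)
  ps <- sets[[1]]
  arr <- neural_rdm_series(ps)
  labs <- names(ps$prps)
  for (t in c(1, 4, 6)) {
    for (i in 1:4) for (j in 1:4) {
      d <- sqrt(sum((ps$prps[[i]][, t] - ps$prps[[j]][, t])^2))
      expect_equal(arr[i, j, t], d, tolerance = 1e-12)
    }
  }
  # one electrode, two phonemes: |a - b|
  ps2 <- ps
  ps2$prps <- lapply(ps$prps[1:3], function(m) m[1, , drop = FALSE])
  arr2 <- neural_rdm_series(ps2, electrodes = 1)
  expect_equal(arr2[1, 2, 3],
               unname(abs(ps2$prps[[1]][1, 3] - ps2$prps[[2]][1, 3])),
               tolerance = 1e-12)
  # identical PRPs -> all-zero RDMs
  ps3 <- ps
  for (k in seq_along(ps3$prps)) ps3$prps[[k]] <- ps3$prps[[1]]
  expect_true(all(neural_rdm_series(ps3) == 0))
})

test_that("alignment is 1 for matching RDMs, -1 for rank reversal, ~0 for noise", {
  inv <- make_inventory(8, 1, seed = 2)
  frdm <- feature_rdm(inv)
  K <- 8
  neural <- array(unclass(frdm), c(K, K, 2),
                  dimnames = list(inv$labels, inv$labels, NULL))
  a <- alignment(neural, frdm)
  expect_equal(a$rho, c(1, 1))
  rev_rdm <- max(frdm) + 0.5 - unclass(frdm)
  diag(rev_rdm) <- 0
  neural_rev <- array(rev_rdm, c(K, K, 1),
                      dimnames = list(inv$labels, inv$labels, NULL))
  expect_equal(alignment(neural_rev, frdm)$rho, -1)
  # constant RDM is degenerate, recorded as 0
  neural0 <- array(1, c(K, K, 1), dimnames = list(inv$labels, inv$labels, NULL))
  for (t in 1) diag(neural0[, , t]) <- 0
  a0 <- alignment(array(0, c(K, K, 1),
                        dimnames = list(inv$labels, inv$labels, NULL)), frdm)
  expect_equal(a0$rho, 0)
  expect_true(a0$degenerate)
  # Monte-Carlo null: independent random RDMs
  set.seed(5)
  K2 <- 12
  labs <- sprintf("L%02d", 1:K2)
  f2 <- matrix(runif(K2 * K2), K2, K2)
  f2 <- f2 + t(f2); diag(f2) <- 0
  f2 <- prpdecode:::new_rdm(f2, labs)
  rhos <- replicate(200, {
    m <- matrix(runif(K2 * K2), K2, K2)
    m <- m + t(m); diag(m) <- 0
    alignment(array(m, c(K2, K2, 1), dimnames = list(labs, labs, NULL)),
              f2)$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("confusion RDMs normalize, symmetrize and zero the diagonal", {
  ident <- diag(10, 4)
  rownames(ident) <- colnames(ident) <- letters[1:4]
  r <- confusion_rdm(ident)
  expect_true(all(r[upper.tri(r)] == 1))
  expect_true(all(diag(r) == 0))
  unif <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  ru <- confusion_rdm(unif)
  expect_true(all(abs(ru[upper.tri(ru)] - 0.75) < 1e-12))
  asym <- matrix(c(5, 1, 0, 0, 4, 2, 1, 1, 6), 3, 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  ra <- confusion_rdm(asym)
  expect_lt(max(abs(ra - t(ra))), 1e-12)
  zr <- asym; zr[2, ] <- 0
  expect_error(confusion_rdm(zr), "b")
})

test_that("the confusion-alignment permutation test is calibrated and deterministic", {
  inv <- make_inventory(8, 1, seed = 3)
  frdm <- feature_rdm(inv)
  set.seed(4)
  cm <- matrix(rpois(64, 5) + 1, 8, 8,
               dimnames = list(inv$labels, inv$labels))
  diag(cm) <- diag(cm) + 10
  r1 <- permutation_rho_difference(cm, cm, frdm, n_perm = 600, seed = 5)
  expect_equal(r1$delta_rho, 0)
  expect_gt(r1$p, 0.3)
  expect_lt(r1$p, 0.7)
  r2 <- permutation_rho_difference(cm, cm, frdm, n_perm = 600, seed = 5)
  expect_identical(r1$p, r2$p)
})

test_that("forward selection finds the informative electrodes and never regresses", {
  inv <- make_inventory(6, 1, seed = 2)
  frdm <- feature_rdm(inv)
  K <- 6; E <- 6; Tn <- 10
  # electrodes 1-2 carry feature geometry, the rest pure noise
  set.seed(9)
  feats <- inv$features
  templates <- lapply(seq_len(K), function(k) {
    m <- matrix(rnorm(E * Tn, sd = 3), E, Tn)
    m[1, ] <- feats[k, 1] * 2 + feats[k, 2]
    m[2, ] <- feats[k, 3] * 2 - feats[k, 2]
    m
  })
  sets <- toy_prp_sets(n_participants = 3, K = K, E = E, Tn = Tn,
                       noise = 0.05, templates = templates)
  sets <- lapply(sets, function(ps) {
    names(ps$prps) <- inv$labels
    ps
  })
  sel <- forward_select(sets, sprintf("E%02d", 1:6), frdm)
  expect_equal(sel$electrodes, c("E01", "E02"))
  # overall rho of the returned set is the running maximum of the trace
  expect_equal(sel$rho, max(sel$trace))
  # identical copies of one electrode: no strict improvement possible
  sets_same <- lapply(sets, function(ps) {
    ps$prps <- lapply(ps$prps, function(m) {
      m[2:E, ] <- matrix(m[1, ], E - 1, ncol(m), byrow = TRUE); m
    })
    ps
  })
  sel2 <- forward_select(sets_same, sprintf("E%02d", 1:6), frdm)
  expect_equal(length(sel2$electrodes), 2)
  # determinism
  sel3 <- forward_select(sets, sprintf("E%02d", 1:6), frdm)
  expect_identical(sel, sel3)
})

test_that("phoneme dendrograms have K leaves and split template families", {
  K <- 6; E <- 4; Tn <- 16
  fam <- rep(1:2, each = 3)
  base <- list(matrix(5, E, Tn), matrix(-5, E, Tn))
  set.seed(3)
  templates <- lapply(seq_len(K), function(k)
    base[[fam[k]]] + 0.2 * matrix(rnorm(E * Tn), E, Tn))
  sets <- toy_prp_sets(n_participants = 1, K = K, E = E, Tn = Tn,
                       noise = 0, templates = templates)
  tree <- phoneme_dendrogram(sets[[1]], window = c(0, Tn / 128))
  expect_s3_class(tree, "hclust")
  expect_equal(length(tree$labels), K)
  top_split <- stats::cutree(tree, 2)
  expect_equal(length(unique(top_split[fam == 1])), 1)
  expect_equal(length(unique(top_split[fam == 2])), 1)
  # identical PRPs -> all merge heights 0
  sets0 <- toy_prp_sets(n_participants = 1, K = 4, E = E, Tn = Tn, noise = 0,
                        templates = rep(list(matrix(1, E, Tn)), 4))
  tree0 <- phoneme_dendrogram(sets0[[1]], window = c(0, Tn / 128))
  expect_true(all(tree0$height < 1e-12))
})
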