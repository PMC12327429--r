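# Statistical layer.

test_that("separability F is ~1 under the null and large under separation", {
  # null: identical phoneme means, participant noise only
  set.seed(2)
  mk_sets <- function(sep) {
    templates <- lapply(1:4, function(k) matrix(sep * k, 3, 5))
    toy_prp_sets(n_participants = 6, K = 4, E = 3, Tn = 5, noise = 1,
                 templates = templates, seed = sample.int(1e6, 1))
  }
  f_null <- replicate(40, mean(separability_f(mk_sets(0))$F))
  expect_gt(mean(f_null), 0.8)
  expect_lt(mean(f_null), 1.2)
  f_sep <- mean(separability_f(mk_sets(10))$F)
  expect_gt(f_sep, 50)
  # all inputs identical -> within-variance zero, flagged undefined
  sets0 <- toy_prp_sets(n_participants = 3, K = 4, E = 3, Tn = 5, noise = 0)
  f0 <- separability_f(sets0)
  expect_true(all(f0$undefined))
})

test_that("cluster test flags a uniform effect and is deterministic", {
  lay <- make_layout(12)[1:12, ]
  adj <- electrode_adjacency(lay)
  set.seed(7)
  dat <- matrix(rnorm(10 * 12, mean = 2), 10, 12)
  ct <- cluster_permutation_test(dat, "one_sample", adjacency = adj,
                                 n_perm = 500, seed = 3)
  expect_equal(length(significant_sites(ct, 0.01)), 12)
  expect_equal(length(ct$clusters), 1)
  expect_lt(ct$clusters[[1]]$p, 0.01)
  ct2 <- cluster_permutation_test(dat, "one_sample", adjacency = adj,
                                  n_perm = 500, seed = 3)
  expect_identical(vapply(ct$clusters, `[[`, 0, "p"),
                   vapply(ct2$clusters, `[[`, 0, "p"))
  # independent design detects a group difference at a subset of sites
  datB <- matrix(rnorm(10 * 12), 10, 12)
  datB[, 1:4] <- datB[, 1:4] + 3
  ct3 <- cluster_permutation_test(rbind(dat * 0 + rnorm(120), datB),
                                  "independent",
                                  groups = rep(1:2, each = 10),
                                  adjacency = adj, n_perm = 500, seed = 4)
  expect_true(length(ct3$clusters) >= 1)
})

test_that("Welch and Mann-Whitney match reference implementations", {
  a <- c(1.2, 3.4, 2.2, 4.1, 2.8)
  b <- c(5.5, 4.8, 6.1, 5.0)
  w <- group_tests(a, b, "welch")
  ref <- t.test(a, b)
  expect_equal(w$t, unname(ref$statistic))
  expect_equal(w$p, ref$p.value)
  expect_equal(w$df, unname(ref$parameter))
  # exhaustive rank case: all of B exceeds A -> U = 0
  mw <- group_tests(1:3, 4:6, "mann_whitney")
  expect_equal(mw$U, 0)
  # z/p against wilcox.test's normal approximation (no continuity corr.)
  set.seed(1)
  x <- rnorm(12); y <- rnorm(15, 0.8)
  mw2 <- group_tests(x, y, "mann_whitney")
  ref2 <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mw2$U, unname(ref2$statistic))
  expect_equal(mw2$p, ref2$p.value, tolerance = 1e-10)
  # translation invariance
  mw3 <- group_tests(x + 100, y + 100, "mann_whitney")
  expect_equal(mw2$p, mw3$p)
  w2 <- group_tests(x + 100, y + 100, "welch")
  expect_equal(group_tests(x, y, "welch")$t, w2$t, tolerance = 1e-9)
})

test_that("behavioral transforms match their closed forms", {
  expect_equal(rau(50, 100), 50, tolerance = 1e-12)  # midpoint symmetry
  # direct evaluation of the published formula at the floor
  expect_equal(rau(0, 100),
               (146 / pi) * (asin(0) + asin(sqrt(1 / 101))) - 23,
               tolerance = 1e-12)
  k <- 0:99
  expect_true(all(diff(rau(k, 100)) > 0))            # strict monotonicity
  expect_error(rau(101, 100), "correct")
  expect_equal(snr_loss(0), 26)
  expect_equal(snr_loss(70), -2)
  expect_equal(snr_loss(54), 4.4)
  expect_error(snr_loss(71), "0..70")
  expect_equal(ehf_transform(-2.5), log(22.5))
  expect_equal(ehf_transform(0), log(25))
  expect_true(all(diff(ehf_transform(seq(-10, 40, 5))) > 0))
  expect_error(ehf_transform(-25), "-25")
})

test_that("backward stepwise recovers a real predictor and drops noise", {
  set.seed(11)
  hits <- 0L
  for (r in 1:40) {
    n <- 40
    x <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    names(x) <- paste0("x", 1:5)
    y <- 2 * x$x1 + rnorm(n)
    sw <- backward_stepwise(y, x)
    if ("x1" %in% sw$selected) hits <- hits + 1L
  }
  expect_gte(hits, 32)                 # >= 80% recovery
  # AIC trace decreases and the final AIC is its minimum
  set.seed(2)
  x <- as.data.frame(matrix(rnorm(200), 40, 5))
  names(x) <- paste0("x", 1:5)
  sw <- backward_stepwise(2 * x$x1 + rnorm(40), x)
  expect_true(all(diff(sw$trace$aic) < 0))
  expect_equal(sw$aic, min(sw$trace$aic))
  # deterministic
  sw2 <- backward_stepwise(sw$data$.y, x)
  expect_identical(sw$trace, sw2$trace)
  # agreement with stats::step under the same AIC definition
  df <- data.frame(.y = sw$data$.y, x)
  for (p in names(x)) df[[p]] <- as.numeric(scale(df[[p]]))
  ref <- stats::step(lm(.y ~ ., data = df), direction = "backward", trace = 0)
  expect_setequal(sw$selected,
                  setdiff(names(coef(ref)), "(Intercept)"))
  # rank-deficient table errors with the collinear predictor named
  xc <- x
  xc$x6 <- xc$x1 * 2
  expect_error(backward_stepwise(rnorm(40), xc), "rank deficient")
})

test_that("pure-noise predictors most often leave only the intercept", {
  set.seed(21)
  sizes <- replicate(120, {
    x <- as.data.frame(matrix(rnorm(40 * 4), 40, 4))
    names(x) <- paste0("x", 1:4)
    length(backward_stepwise(rnorm(40), x)$selected)
  })
  tab <- table(factor(sizes, levels = 0:4))
  expect_equal(unname(which.max(tab)), 1L)  # mode at zero predictors
})

test_that("the above-chance test detects accuracy above 1/K", {
  set.seed(3)
  acc <- runif(12, 0.2, 0.4)          # well above 1/12
  out <- above_chance_test(acc, 12)
  expect_lt(out$p, 0.01)
  expect_gt(out$z, 0)
  ref <- wilcox.test(acc, mu = 1 / 12, exact = FALSE, correct = FALSE)
  expect_equal(out$p, ref$p.value)
  null_acc <- 1 / 12 + rnorm(12, sd = 0.02)
  expect_gt(above_chance_test(null_acc, 12)$p, 0.001)
})

test_that("residual analysis removes covariate-carried group effects", {
  set.seed(31)
  # group effect fully mediated by the covariate
  n <- 30
  groups <- rep(c("A", "B"), each = n / 2)
  covar <- ifelse(groups == "A", 1, -1) + rnorm(n, sd = 0.3)
  y <- 2 * covar + rnorm(n, sd = 0.5)
  rt <- residual_group_test(y, data.frame(covar = covar), groups)
  expect_gt(rt$test$p, 0.05)
  # residuals of the pooled fit sum to zero
  expect_lt(abs(sum(residuals(rt$fit))), 1e-9)
  # group effect orthogonal to the covariate survives
  covar2 <- rnorm(n)
  y2 <- 2 * covar2 + ifelse(groups == "A", 1.5, 0) + rnorm(n, sd = 0.5)
  rt2 <- residual_group_test(y2, data.frame(covar = covar2), groups)
  expect_lt(rt2$test$p, 0.05)
})
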