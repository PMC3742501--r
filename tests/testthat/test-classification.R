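# Discriminant classification: Bayes-rule oracle, dummy coding, holdout,
# permutation and subject-permutation significance, MANOVA, accuracy curves.

test_that("the decision boundary bisects two equal-prior 1-D classes", {
  set.seed(21)
  x <- matrix(c(rnorm(50, -1, 0.3), rnorm(50, 1, 0.3)), ncol = 1)
  y <- rep(c("neg", "pos"), each = 50)
  fit <- lda_fit(x, y)                # equal n, so equal priors
  mid <- mean(fit$means)              # midpoint of the class means
  eps <- 1e-6
  expect_equal(lda_predict(fit, matrix(c(mid - eps, mid + eps), ncol = 1)),
               c("neg", "pos"))
  p_mid <- lda_predict(fit, matrix(mid, 1, 1), type = "posterior")
  expect_equal(unname(p_mid[1, 1]), 0.5, tolerance = 1e-9)
})

test_that("posteriors agree with the closed-form Gaussian oracle and MASS", {
  toy <- toy_classes(n_per = 15, p = 3, shift = 2, g = 3, seed = 22)
  fit <- lda_fit(toy$x, toy$y)
  post <- lda_predict(fit, toy$x, type = "posterior")
  oracle <- bayes_posterior_oracle(toy$x, fit$means, fit$cov, fit$prior)
  expect_equal(unname(post), unname(oracle), tolerance = 1e-12)
  m <- MASS::lda(toy$x, grouping = toy$y)
  pm <- predict(m, as.data.frame(toy$x))$posterior
  expect_equal(unname(post), unname(pm), tolerance = 1e-9)
  # training points in the separation limit are recovered
  far <- toy_classes(n_per = 10, p = 2, shift = 30, g = 3, seed = 23)
  ffit <- lda_fit(far$x, far$y)
  expect_equal(lda_predict(ffit, far$x), far$y)
})

test_that("singularity and dimension contracts are enforced", {
  toy <- toy_classes(n_per = 10, p = 2, g = 2, seed = 24)
  dup <- cbind(toy$x, toy$x[, 1])
  expect_error(lda_fit(dup, toy$y), "singular")
  # but a ridge rescues it
  expect_s3_class(lda_fit(dup, toy$y, ridge = 1e-8), "lda_model")
  fit <- lda_fit(toy$x, toy$y)
  expect_error(lda_predict(fit, matrix(0, 1, 5)), "dimension mismatch")
  expect_error(lda_fit(toy$x, c("a", rep("b", 19))), "fewer than 2")
})

test_that("exact score ties go to the class listed earlier", {
  # two classes mirrored about zero with equal priors: the origin is tied
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("a", "a", "b", "b")
  fit <- lda_fit(x, y, prior = "uniform")
  expect_equal(lda_predict(fit, matrix(0, 1, 1)), "a")
})

test_that("dummy coding matches the A/B/C convention", {
  m <- dummy_code_types(c("A", "B", "C", "C"))
  expect_equal(colnames(m), c("A", "B", "C"))
  expect_equal(unname(m[3, ]), c(0L, 0L, 1L))
  expect_equal(unname(rowSums(m)), rep(1, 4))
  expect_error(dummy_code_types(rep("A", 5)), "at least 2")
  expect_error(dummy_code_types(c("A", "D"), levels = c("A", "B")),
               "unseen")
})

test_that("holdout classification is deterministic and calibrated", {
  far <- toy_classes(n_per = 20, p = 2, shift = 20, g = 3, seed = 25)
  rep1 <- holdout_classification(far$x, far$y, seed = 9)
  expect_equal(rep1$percent_correct, 100)
  expect_equal(sum(rep1$confusion), rep1$n_validation)
  rep2 <- holdout_classification(far$x, far$y, seed = 9)
  expect_identical(rep1$confusion, rep2$confusion)
  # labels independent of features: the null accuracy sits slightly below
  # 50% (the validation half complements the calibration half), and the
  # package agrees with an independent MASS-based holdout on the same task
  set.seed(26)
  accs_pkg <- replicate(40, {
    x <- matrix(rnorm(160), 80, 2)
    y <- rep(c("a", "b"), 40)
    holdout_classification(x, y, seed = sample.int(1e6, 1))$percent_correct
  })
  accs_mass <- replicate(40, {
    x <- matrix(rnorm(160), 80, 2)
    colnames(x) <- c("v1", "v2")
    y <- factor(rep(c("a", "b"), 40))
    cal <- sample(80, 40)
    m <- MASS::lda(x[cal, ], grouping = y[cal])
    100 * mean(predict(m, as.data.frame(x[-cal, ]))$class == y[-cal])
  })
  se <- sqrt(var(accs_pkg) / 40 + var(accs_mass) / 40)
  expect_lt(abs(mean(accs_pkg) - mean(accs_mass)), 3 * se)
  expect_lt(mean(accs_pkg), 52)      # no optimistic bias under the null
  expect_error(holdout_classification(matrix(rnorm(10), 5),
                                      c("a", "a", "a", "a", "b")),
               "both halves")
})

test_that("permutation p-values respect their bounds and direction", {
  set.seed(27)
  x <- matrix(rnorm(120), 60, 2)
  y <- rep(c("a", "b"), 30)
  res <- permutation_significance(x, y, n_perm = 99, seed = 2)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  expect_equal(res$n_permutations, 99)
  expect_equal(res$chance_percent, mean(res$null_accuracy))
  # observed below the null median implies p > 0.5
  if (res$percent_correct < median(res$null_accuracy))
    expect_gt(res$p_value, 0.5)
  # strong class effect: small p
  far <- toy_classes(n_per = 25, p = 2, shift = 10, g = 2, seed = 28)
  sig <- permutation_significance(far$x, far$y, n_perm = 99, seed = 3)
  expect_equal(sig$p_value, 1 / 100)
  expect_error(permutation_significance(x, y, n_perm = 10), "99")
})

test_that("pdfa permutes subjects and enforces its contracts", {
  set.seed(29)
  # 4 subjects per class, strong class effect: significant
  n_subj <- 8; calls_per <- 6
  subj <- rep(paste0("s", 1:n_subj), each = calls_per)
  y <- rep(c("a", "b"), each = n_subj / 2 * calls_per)
  x <- matrix(rnorm(n_subj * calls_per * 2), ncol = 2) +
    ifelse(y == "a", 0, 6)
  res <- pdfa(x, y, subj, n_perm = 99, seed = 4)
  expect_lte(res$p_value, 0.05)
  expect_equal(res$n_subjects, 8)
  # a class with a single subject is unpermutable
  subj_bad <- c(rep("s1", 24), rep(paste0("t", 1:4), each = 6))
  expect_error(pdfa(x, y, subj_bad, n_perm = 99), "single subject")
  # subjects spanning two classes are split into subject-class pairs
  subj_span <- rep(paste0("s", 1:8), times = 6)   # every subject in both
  expect_message(pdfa(x, y, subj_span, n_perm = 99, seed = 5),
                 "subject-class pairs")
})

test_that("Wilks lambda matches the determinant-ratio oracle", {
  toy <- toy_classes(n_per = 30, p = 2, shift = 2, g = 2, seed = 30)
  mw <- manova_wilks(toy$x, toy$y)
  expect_equal(mw$wilks_lambda, wilks_oracle(toy$x, toy$y),
               tolerance = 1e-9)
  expect_lt(mw$p_value, 0.01)
  # identical class means: lambda near 1
  set.seed(31)
  x0 <- matrix(rnorm(200), 100, 2)
  mw0 <- manova_wilks(x0, rep(c("a", "b"), 50))
  expect_gt(mw0$wilks_lambda, 0.9)
  # separation limit: lambda near 0
  far <- toy_classes(n_per = 30, p = 2, shift = 50, g = 2, seed = 32)
  expect_lt(manova_wilks(far$x, far$y)$wilks_lambda, 0.01)
  expect_error(manova_wilks(matrix(rnorm(12), 4), c("a", "a", "b", "b")),
               "too few")
})

test_that("multi-call accuracy reaches 100% in the separation limit", {
  far <- toy_classes(n_per = 30, p = 2, shift = 25, g = 3, seed = 33)
  curve <- multi_call_accuracy(far$x, far$y, n_range = c(1, 3, 5),
                               inner = 4, outer = 4, seed = 6)
  expect_equal(curve$mean, rep(100, 3))
  expect_true(all(curve$ci_lo <= curve$mean & curve$mean <= curve$ci_hi))
})

test_that("small situations are excluded from the accuracy simulation", {
  set.seed(34)
  x <- matrix(rnorm(90), 45, 2)
  y <- c(rep("big1", 20), rep("big2", 20), rep("tiny", 5))
  expect_warning(curve <- multi_call_accuracy(x, y, n_range = c(1, 10),
                                              inner = 2, outer = 2,
                                              seed = 7),
                 "tiny")
  expect_equal(attr(curve, "n_situations"), 2)
})

test_that("type-proportion mode classifies through indicator averages", {
  # types deterministically indicate the situation
  set.seed(35)
  y <- rep(c("s1", "s2", "s3"), each = 30)
  types <- c(sample(c("A", "B"), 30, TRUE, c(0.9, 0.1)),
             sample(c("A", "B"), 30, TRUE, c(0.1, 0.9)),
             sample(c("C", "B"), 30, TRUE, c(0.9, 0.1)))
  curve <- multi_call_accuracy(types, y, n_range = c(2, 8), inner = 4,
                               outer = 4, seed = 8, mode = "types")
  expect_gt(curve$mean[2], curve$mean[1] - 10)  # no collapse with more calls
  expect_gt(curve$mean[2], 60)
})
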