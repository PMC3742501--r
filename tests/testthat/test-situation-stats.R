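# Situation-level statistics: profiles, Ward dendrograms, chi-square
# association with Pearson residuals, Spearman and quasi-binomial valence
# models, BH-FDR behaviour.

test_that("situation profiles equal group-by means / proportions", {
  calls <- simulate_calls(study_design(), seed = 41)
  prof <- situation_profiles(calls, "acoustic")
  for (s in c("CA", "IS")) {
    sub <- calls[calls$situation == s, feature_cols]
    expect_equal(unname(prof[s, ]), unname(colMeans(sub)),
                 tolerance = 1e-12)
  }
  proft <- situation_profiles(calls, "types")
  expect_equal(unname(rowSums(proft)), rep(1, 11), tolerance = 1e-9)
  one <- calls[c(1, 200), ]
  p1 <- situation_profiles(one, "acoustic")
  expect_equal(unname(p1[one$situation[1], "dur"]), one$dur[1])
})

test_that("ward dendrogram merges identical profiles first at height 0", {
  m <- rbind(A = c(0, 0), B = c(0, 0), C = c(5, 5))
  d <- ward_dendrogram(m, standardize = FALSE)
  expect_equal(d$merges$height[1], 0)
  first <- sort(-d$hclust$merge[1, ])
  expect_equal(d$hclust$labels[first], c("A", "B"))
  expect_match(d$newick, "A|B")
  dup <- m; rownames(dup) <- c("A", "A", "C")
  expect_error(ward_dendrogram(dup), "unique")
})

test_that("ward merge heights match the Lance-Williams hand computation", {
  set.seed(42)
  x <- matrix(rnorm(8), 4, 2, dimnames = list(LETTERS[1:4], NULL))
  d <- ward_dendrogram(x, standardize = FALSE)
  expect_equal(d$merges$height, ward_merge_heights_oracle(x),
               tolerance = 1e-9)
  # heights non-decreasing; cophenetic round trip reconstructs heights
  expect_true(all(diff(d$merges$height) >= -1e-12))
  coph <- as.matrix(stats::cophenetic(d$hclust))
  expect_equal(sort(unique(round(coph[upper.tri(coph)], 9))),
               sort(unique(round(d$merges$height, 9))))
})

test_that("gross-category blocks form the top-level clades when separated", {
  # situation profiles built as three tight blocks around the gross
  # categories: the 3-way cut of the dendrogram must recover the blocks
  sit <- piglet_situations()
  centre <- rbind(life_threat = c(0.05, 0.05, 0.10, 0.40, 0.40),
                  nursing     = c(0.10, 0.15, 0.60, 0.05, 0.10),
                  other       = c(0.45, 0.35, 0.15, 0.02, 0.03))
  set.seed(43)
  prof <- centre[sit$gross, ] + matrix(runif(55, 0, 0.02), 11, 5)
  prof <- prof / rowSums(prof)
  rownames(prof) <- sit$situation
  d <- ward_dendrogram(prof, standardize = FALSE)
  cut3 <- stats::cutree(d$hclust, k = 3)
  agreement <- table(gross_category(names(cut3)), cut3)
  expect_true(all(rowSums(agreement > 0) == 1))  # one clade per category
  expect_true(all(colSums(agreement > 0) == 1))  # one category per clade
})

test_that("chi-square association follows closed-form arithmetic", {
  tab <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("LF", "HF"),
                                                    c("s1", "s2")))
  res <- association_test(tab)
  expect_false(res$monte_carlo)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_equal(unname(abs(res$residuals)), matrix(sqrt(5), 2, 2),
               tolerance = 1e-12)
  expect_true(all(res$flag2) && !any(res$flag4))
  # independence: residuals all zero
  ind <- outer(c(30, 70), c(40, 60)) / 10
  res0 <- association_test(ind)
  expect_equal(max(abs(res0$residuals)), 0, tolerance = 1e-9)
  # residual conservation: sum of observed equals sum of expected
  expect_equal(sum(res$table),
               sum(outer(rowSums(res$table), colSums(res$table))) /
                 sum(res$table))
  expect_error(association_test(matrix(c(5, 5, 0, 0), 2)), "degenerate")
})

test_that("Monte-Carlo p agrees with the asymptotic p on large tables", {
  set.seed(44)
  big <- matrix(rpois(12, 40) + 20, 3, 4)
  asym <- stats::chisq.test(big, correct = FALSE)$p.value
  # force the Monte-Carlo path by calling on a scaled copy with a small cell
  res <- association_test(big, n_mc = 4000, seed = 9)
  if (res$monte_carlo) {
    expect_lt(abs(res$p_value - asym), 0.02)
  } else {
    expect_equal(res$p_value, asym, tolerance = 1e-12)
  }
  small <- matrix(c(3, 8, 9, 2, 7, 4), 2, 3)
  res_small <- association_test(small, n_mc = 4000, seed = 10)
  expect_true(res_small$monte_carlo)
  asym_small <- suppressWarnings(
    stats::chisq.test(small, correct = FALSE)$p.value)
  expect_lt(abs(res_small$p_value - asym_small), 0.05)
})

test_that("spearman valence correlations hit the closed-form extremes", {
  prof <- matrix(c(1:8, 8:1, c(2, 1, 4, 3, 6, 5, 8, 7)), 8, 3,
                 dimnames = list(paste0("S", 1:8),
                                 c("up", "down", "wiggle")))
  val <- stats::setNames(as.numeric(1:8), paste0("S", 1:8))
  res <- valence_feature_correlation(prof, val)
  expect_equal(res$estimate[res$variable == "up"], 1)
  expect_equal(res$estimate[res$variable == "down"], -1)
  # rho equals rank-then-pearson on random data
  set.seed(45)
  prof2 <- matrix(rnorm(44), 11, 4,
                  dimnames = list(paste0("S", 1:11), letters[1:4]))
  val2 <- stats::setNames(sample(1:11), paste0("S", 1:11))
  res2 <- valence_feature_correlation(prof2, val2)
  for (v in letters[1:4])
    expect_equal(res2$estimate[res2$variable == v],
                 cor(rank(prof2[, v]), rank(val2[rownames(prof2)])),
                 tolerance = 1e-12)
  # constant variable reported as missing with a note
  prof3 <- cbind(prof2, const = 1)
  res3 <- valence_feature_correlation(prof3, val2)
  expect_true(is.na(res3$estimate[res3$variable == "const"]))
  expect_match(res3$note[res3$variable == "const"], "constant")
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(46)
  prof <- matrix(rnorm(88), 11, 8,
                 dimnames = list(paste0("S", 1:11), feature_cols))
  val <- stats::setNames(sample(1:11), paste0("S", 1:11))
  res <- valence_feature_correlation(prof, val)
  ord <- order(res$p_value)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, stats::p.adjust(res$p_value, "BH"))
})

test_that("quasi-binomial regression recovers exact logistic structure", {
  v <- stats::setNames(as.numeric(1:11), paste0("S", 1:11))
  # proportions exactly on a logistic curve, huge totals -> near-exact slope
  b_true <- -0.4; a_true <- 1.5
  p <- plogis(a_true + b_true * v)
  totals <- rep(1e6, 11)
  counts <- cbind(T1 = round(p * totals), T2 = totals - round(p * totals))
  rownames(counts) <- names(v)
  res <- valence_type_regression(counts, v)
  expect_equal(res$estimate[res$type == "T1"], b_true, tolerance = 1e-3)
  expect_equal(res$df[1], 9)   # 11 situations, 2 parameters
  # constant proportion: slope indistinguishable from zero
  counts0 <- cbind(A = rep(30, 11), B = rep(70, 11))
  rownames(counts0) <- names(v)
  res0 <- valence_type_regression(counts0, v)
  expect_lt(abs(res0$estimate[res0$type == "A"]), 1e-9)
})

test_that("dispersion is near 1 for genuinely binomial data", {
  set.seed(47)
  v <- stats::setNames(as.numeric(1:11), paste0("S", 1:11))
  disp <- replicate(60, {
    p <- plogis(0.5 - 0.2 * v)
    k <- rbinom(11, 80, p)
    counts <- cbind(A = k, B = 80 - k)
    rownames(counts) <- names(v)
    valence_type_regression(counts, v)$dispersion[1]
  })
  expect_lt(abs(mean(disp) - 1), 3 * sd(disp) / sqrt(60))
})
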