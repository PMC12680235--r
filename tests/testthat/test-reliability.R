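test_that("mutual information matches hand-computed plug-in values", {
  # constant scores carry no information
  expect_identical(as.numeric(mutual_information(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))), 0)
  # perfect dependence with balanced labels: MI = H(Y) = ln 2
  expect_equal(as.numeric(mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))),
               log(2), tolerance = 1e-12)
  # joint counts [[2,1],[1,2]] against the independent 2x2 oracle
  scores <- c(0, 0, 0, 1, 1, 1)
  labels <- c(0, 0, 1, 0, 1, 1)
  expect_equal(as.numeric(mutual_information(scores, labels)),
               mi_oracle_2x2(rbind(c(2, 1), c(1, 2))), tolerance = 1e-12)
  # constant labels are flagged degenerate
  r <- mutual_information(c(0.1, 0.9), c(1, 1))
  expect_identical(as.numeric(r), 0)
  expect_identical(attr(r, "degenerate"), "constant_labels")
  expect_error(mutual_information(1:3, c(0, 1)), "equal length")
})

test_that("patch-probability channels binarize at one half", {
  # all probabilities above the median but below 0.5 on one side
  s <- c(0.1, 0.2, 0.6, 0.7)
  l <- c(0, 0, 1, 1)
  expect_equal(as.numeric(mutual_information(s, l, channel = "patch_prob")),
               log(2))
  # shifted: every probability < 0.5 makes the split degenerate
  expect_identical(as.numeric(mutual_information(s / 10, l, channel = "patch_prob")), 0)
})

test_that("spearman correlation uses mid-ranks", {
  expect_equal(as.numeric(spearman_cor(c(0, 0, 1, 1), c(0, 0, 1, 1))), 1)
  expect_equal(as.numeric(spearman_cor(c(1, 1, 0, 0), c(0, 0, 1, 1))), -1)
  expect_equal(as.numeric(spearman_cor(1:4, c(0, 0, 1, 1))), 2 / sqrt(5),
               tolerance = 1e-12)
  r <- spearman_cor(rep(1, 4), c(0, 1, 0, 1))
  expect_identical(as.numeric(r), 0)
  expect_identical(attr(r, "degenerate"), "zero_variance")
})

test_that("average precision matches the threshold-sum definition", {
  expect_equal(as.numeric(auprc(c(0.9, 0.8, 0.7), c(1, 1, 0))), 1)
  expect_equal(as.numeric(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1))), 1 / 2 + 1 / 3,
               tolerance = 1e-12)
  # tied scores are a single threshold
  expect_equal(as.numeric(auprc(c(0.5, 0.5, 0.1), c(1, 0, 0))), 0.5)
  expect_identical(attr(auprc(c(1, 2), c(1, 1)), "degenerate"), "no_negatives")
})

test_that("a random scorer attains AUPRC near prevalence and vanishing MI", {
  set.seed(20)
  prev <- 0.2; n <- 200
  labels <- c(rep(1, n * prev), rep(0, n * (1 - prev)))
  ap <- replicate(2000, as.numeric(auprc(runif(n), labels)))
  expect_lt(abs(mean(ap) - prev), 0.03)   # finite-n AP bias is upward
  mi <- replicate(500, as.numeric(mutual_information(runif(n), labels)))
  expect_lt(mean(mi), 0.01)
  rs <- replicate(500, as.numeric(spearman_cor(runif(n), labels)))
  expect_lt(abs(mean(rs)), 0.01)
})

test_that("all metrics are invariant to strictly increasing transforms", {
  set.seed(21)
  s <- runif(60); l <- rbinom(60, 1, 0.3)
  f <- function(x) exp(3 * x) + x   # strictly increasing
  expect_equal(as.numeric(mutual_information(f(s), l)),
               as.numeric(mutual_information(s, l)))
  expect_equal(as.numeric(spearman_cor(f(s), l)), as.numeric(spearman_cor(s, l)))
  expect_equal(as.numeric(auprc(f(s), l)), as.numeric(auprc(s, l)))
})

test_that("a label-perfect scorer achieves the theoretical optima", {
  set.seed(22)
  l <- rbinom(80, 1, 0.25)
  expect_equal(as.numeric(auprc(l, l)), 1)
  expect_equal(as.numeric(spearman_cor(l, l)), 1)
  p <- mean(l)
  expect_equal(as.numeric(mutual_information(l, l)),
               -p * log(p) - (1 - p) * log(1 - p), tolerance = 1e-12)
})

test_that("slide-set evaluation excludes ROI-free slides and aggregates", {
  s1 <- c(0.9, 0.1, 0.2); l1 <- c(1, 0, 0)
  s2 <- c(0.3, 0.8, 0.6, 0.1); l2 <- c(0, 1, 1, 0)
  s3 <- c(0.5, 0.5); l3 <- c(0, 0)          # no ROI: excluded
  r <- evaluate_reliability(list(s1, s2, s3), list(l1, l2, l3))
  expect_identical(r$n_slides_used, 2L)
  expect_equal(r$auprc, mean(c(as.numeric(auprc(s1, l1)), as.numeric(auprc(s2, l2)))))
  expect_equal(r$spearman, mean(c(as.numeric(spearman_cor(s1, l1)),
                                  as.numeric(spearman_cor(s2, l2)))))
  # single retained slide: both aggregations reduce to the plain metrics
  for (agg in c("per_slide_mean", "pooled")) {
    r1 <- evaluate_reliability(list(s1, s3), list(l1, l3), aggregation = agg)
    expect_equal(r1$auprc, as.numeric(auprc(s1, l1)))
    expect_equal(r1$mi, as.numeric(mutual_information(s1, l1)))
  }
  # pooled equals the metric on concatenated vectors
  rp <- evaluate_reliability(list(s1, s2), list(l1, l2), aggregation = "pooled")
  expect_equal(rp$auprc, as.numeric(auprc(c(s1, s2), c(l1, l2))))
  expect_equal(rp$mi, as.numeric(mutual_information(c(s1, s2), c(l1, l2))))
  expect_error(evaluate_reliability(list(s3), list(l3)), "no ROI slides")
})

test_that("patch score sets feed evaluation directly", {
  ss <- list(patch_score_set("a", c(0.7, 0.2, 0.1), "attention"),
             patch_score_set("b", c(0.1, 0.9), "patch_prob"))
  r <- evaluate_reliability(ss, list(c(1, 0, 0), c(0, 1)), model_id = "m", seed = 3L)
  expect_identical(r$model_id, "m")
  expect_equal(r$auprc, 1)
})
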