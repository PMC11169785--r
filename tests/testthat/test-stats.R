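test_that("finite chance level matches the binomial construction and its limits", {
  # explicit CDF-summation oracle
  oracle <- function(n, c, a) {
    for (k in 0:n) {
      if (sum(dbinom(0:(k - 1), n, 1 / c)) >= 1 - a) return(k / n)
    }
    1
  }
  expect_equal(finite_chance_level(100, 2, 0.05), oracle(100, 2, 0.05))
  expect_equal(finite_chance_level(20, 3, 0.05), oracle(20, 3, 0.05))
  expect_lt(abs(finite_chance_level(1e6, 2, 0.05) - 0.5), 0.002)

  # decreasing staircase: upticks bounded by one binomial count, always > 1/2
  ns <- seq(10, 500, 10)
  th <- vapply(ns, finite_chance_level, numeric(1), n_classes = 2)
  expect_true(all(diff(th) <= 1 / ns[-1] + 1e-12))
  expect_lt(th[length(th)], th[1])
  expect_true(all(th > 0.5))
})

test_that("accuracy and mean-difference t-tests match the closed form", {
  expect_equal(ttest_accuracy(c(0.5, 0.5, 0.5), 0.5), 1)
  p <- ttest_accuracy(c(0.6, 0.7, 0.8), 0.5)
  tstat <- (0.7 - 0.5) / (0.1 / sqrt(3))
  expect_equal(p, 2 * pt(-tstat, df = 2), tolerance = 1e-12)
  expect_lt(ttest_accuracy(rep(0.9, 35) + seq(-1, 1, length.out = 35) * 1e-4, 0.5), 1e-10)

  expect_equal(ttest_meandiff(c(-1, 1)), 1)
  expect_lt(ttest_meandiff(rnorm(35, 5, 0.1)), 0.01)
  expect_error(ttest_meandiff(1), class = "ecog_input_error")
  expect_true(is.na(ttest_accuracy(rep(0.8, 5), 0.5)))
})

test_that("BH step-up matches the formula, p.adjust, and brute force", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.5), alpha = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10), 0.05)))

  brute <- function(p, a) {
    n <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- 0
    for (i in seq_len(n)) if (ps[i] <= i / n * a) k <- i
    if (k == 0) return(rep(FALSE, n))
    p <= ps[k]
  }
  set.seed(20)
  for (i in 1:1000) {
    p <- runif(sample(3:25, 1))^sample(1:3, 1)
    a <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, a), brute(p, a))
  }
  # agreement with stats::p.adjust rejection set
  set.seed(21)
  p <- runif(40)^2
  expect_identical(bh_fdr(p, 0.05), p.adjust(p, "BH") <= 0.05)
  # invariant to input order
  expect_identical(bh_fdr(rev(p), 0.05), rev(bh_fdr(p, 0.05)))
})

test_that("joint significance needs both families and above-chance direction", {
  res <- data.frame(roi = "r", band = c("b1", "b2", "b3"),
                    p_acc = c(1e-6, 1e-6, 0.5),
                    p_diff = c(1e-6, 0.8, 1e-6),
                    mean_acc = c(0.8, 0.8, 0.5))
  out <- joint_significance(res, chance = 0.6, alpha = 0.05)
  expect_equal(out$sig_joint, c(TRUE, FALSE, FALSE))
  # accuracy significantly *below* chance must not count
  res2 <- data.frame(roi = "r", band = "b", p_acc = 1e-8, p_diff = 1e-8,
                     mean_acc = 0.4)
  expect_false(joint_significance(res2, chance = 0.6, alpha = 0.05)$sig_joint)
})

test_that("two-way ANOVA matches a hand sum-of-squares decomposition", {
  d <- expand.grid(roi = c("r1", "r2"), band = c("b1", "b2"), rep = 1:3)
  set.seed(30)
  d$accuracy <- 0.6 + 0.1 * (d$roi == "r2") + rnorm(nrow(d), 0, 0.05)
  res <- anova_roi_band(d)

  # textbook SS decomposition on the balanced 2 x 2 x 3 design
  g <- mean(d$accuracy)
  mr <- tapply(d$accuracy, d$roi, mean)
  mb <- tapply(d$accuracy, d$band, mean)
  mc <- tapply(d$accuracy, interaction(d$roi, d$band), mean)
  ss_r <- 6 * sum((mr - g)^2)
  ss_b <- 6 * sum((mb - g)^2)
  ss_c <- 3 * sum((mc - g)^2)
  ss_i <- ss_c - ss_r - ss_b
  ss_e <- sum((d$accuracy - mc[interaction(d$roi, d$band)])^2)
  expect_equal(res$f_roi, (ss_r / 1) / (ss_e / 8), tolerance = 1e-8)
  expect_equal(res$f_interaction, (ss_i / 1) / (ss_e / 8), tolerance = 1e-8)

  # all-equal accuracies: no effects
  d0 <- d; d0$accuracy <- 0.5
  res0 <- anova_roi_band(d0)
  expect_equal(res0$f_roi, 0)
  expect_equal(res0$f_band, 0)

  d1 <- d[d$roi == "r1" | d$band == "b1", ]
  expect_error(anova_roi_band(d1[!(d1$roi == "r1" & d1$band == "b2"), ]),
               class = "ecog_input_error")
})

test_that("an injected ROI effect is detected by the ANOVA but a null band is not", {
  set.seed(31)
  pr <- pb <- numeric(10)
  for (i in 1:10) {
    d <- expand.grid(roi = paste0("r", 1:4), band = paste0("b", 1:3), rep = 1:10)
    d$accuracy <- 0.6 + 0.1 * (d$roi == "r1") + rnorm(nrow(d), 0, 0.08)
    res <- anova_roi_band(d)
    pr[i] <- res$p_roi; pb[i] <- res$p_band
  }
  expect_lt(median(pr), 0.01)
  expect_gt(median(pb), 0.05)
})
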