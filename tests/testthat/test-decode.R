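test_that("buffered folds exclude neighbours of the test fold", {
  sch <- make_folds(70, 7, 1)
  expect_equal(sch$train_folds[[4]], c(1, 2, 6, 7))
  expect_equal(sch$train_folds[[1]], 3:7)
  sch0 <- make_folds(70, 7, 0)
  expect_equal(sch0$train_folds[[4]], c(1:3, 5:7))
  expect_error(make_folds(10, 7, 1), class = "ecog_input_error")

  # buffer validity: min temporal gap between train and test >= a fold span
  sch2 <- make_folds(500, 7, 1)
  min_size <- min(lengths(sch2$folds))
  for (k in 1:7) {
    te <- sch2$folds[[k]]
    tr <- unlist(sch2$folds[sch2$train_folds[[k]]])
    expect_gte(min(abs(outer(tr, te, "-"))), min_size)
  }
})

test_that("balance_classes downsamples every class to the minimum count", {
  labs <- rep(c("A", "B"), times = c(10, 6))
  out <- balance_classes(seq_along(labs), labs, seed = 1)
  expect_equal(as.numeric(table(labs[out])), c(6, 6))

  bal <- balance_classes(1:12, rep(c("A", "B"), 6), seed = 2)
  expect_setequal(bal, 1:12)

  labs3 <- rep(c("A", "B", "C"), times = c(9, 6, 3))
  out3 <- balance_classes(seq_along(labs3), labs3, seed = 3)
  expect_equal(as.numeric(table(labs3[out3])), c(3, 3, 3))
  expect_identical(out3, balance_classes(seq_along(labs3), labs3, seed = 3))
  expect_error(balance_classes(1:6, rep("A", 6), classes = c("A", "B")),
               class = "ecog_input_error")
})

test_that("z-scoring is independent per split with sample-SD convention", {
  z <- zscore_split(matrix(c(1, 2, 3)), matrix(c(4, 5, 6, 7)))
  expect_equal(as.numeric(z$train), c(-1, 0, 1))
  z2 <- zscore_split(matrix(c(1, 2, 3)), matrix(c(4, 5, 6, 7) + 100))
  expect_equal(z$test, z2$test)
  expect_warning(zc <- zscore_split(matrix(c(1, 1, 1)), matrix(c(1, 2, 3))))
  expect_equal(as.numeric(zc$train), c(0, 0, 0))
  expect_error(zscore_split(matrix(1), matrix(1:2)), class = "ecog_input_error")
})

test_that("shared-covariance LDA recovers means and the midpoint boundary", {
  set.seed(10)
  x <- matrix(c(rnorm(200, 0), rnorm(200, 2)), ncol = 1)
  lab <- rep(c("a", "b"), each = 200)
  fit <- fit_lda_shared(x, lab)
  expect_equal(predict(fit, matrix(c(0.9, 1.1), ncol = 1)), c("a", "b"))
  expect_equal(predict(fit, matrix(mean(fit$means), ncol = 1)), "a")  # tie -> first

  # identical class means give chance-level held-out accuracy
  set.seed(11)
  xt <- matrix(rnorm(4000), ncol = 2)
  lt <- rep(c("a", "b"), 1000)
  f0 <- fit_lda_shared(xt[1:1000, ], lt[1:1000])
  acc <- mean(predict(f0, xt[1001:2000, ]) == lt[1001:2000])
  expect_gt(acc, 0.42)
  expect_lt(acc, 0.58)

  # parameter recovery at n = 5000
  set.seed(12)
  mu <- rbind(c(0, 0), c(1, -1))
  xl <- rbind(matrix(rnorm(5000 * 2), ncol = 2),
              matrix(rnorm(5000 * 2), ncol = 2) + rep(mu[2, ], each = 5000))
  ll <- rep(c("a", "b"), each = 5000)
  fr <- fit_lda_shared(xl, ll)
  expect_lt(max(abs(fr$means - mu)), 0.1)
})

test_that("predict_lda equals Gaussian-density classification", {
  set.seed(13)
  p <- 3
  x <- matrix(rnorm(60 * p), ncol = p)
  lab <- sample(c("a", "b", "c"), 60, replace = TRUE)
  fit <- fit_lda_shared(x, lab)
  xs <- matrix(rnorm(100 * p), ncol = p)
  Sinv <- solve(fit$cov)
  dens <- sapply(fit$classes, function(cl) {
    mu <- fit$means[cl, ]
    apply(xs, 1, function(v) {
      -0.5 * t(v - mu) %*% Sinv %*% (v - mu) +
        log(fit$priors[match(cl, fit$classes)])
    })
  })
  expect_equal(predict(fit, xs), fit$classes[max.col(dens, ties.method = "first")])
})

test_that("evaluate_feature recovers a planted feature-level effect with the right sign", {
  fx <- feature_fixture(n_blocks = 60,
                        shifts = data.frame(roi = "roiA", band = "highgamma",
                                            delta = 1),
                        seed = 5)
  ev <- evaluate_feature(fx$table, fx$assignment, "roiA", "highgamma",
                         class_pair = c("Talking", "WatchingTV"), seed = 1)
  chance <- finite_chance_level(round(median(ev$n_test)))
  expect_gt(mean(ev$accuracy), chance)
  expect_true(all(ev$mean_diff > 0))
  md <- attr(ev, "mean_diff_by_electrode")
  expect_equal(ncol(md), 3)
  expect_equal(rowMeans(md), ev$mean_diff)

  # a null feature stays near chance
  ev0 <- evaluate_feature(fx$table, fx$assignment, "roiB", "alpha", seed = 1)
  expect_lt(mean(ev0$accuracy), chance + 0.1)
  expect_gt(mean(ev0$accuracy), 1 - chance - 0.1)
})

test_that("label permutation stays at chance (no leakage through the protocol)", {
  fx <- feature_fixture(n_blocks = 60,
                        shifts = data.frame(roi = "roiA", band = "highgamma",
                                            delta = 1),
                        seed = 6)
  accs <- vapply(1:10, function(s) {
    tab <- fx$table
    set.seed(s)
    perm <- sample(60)
    tab$labels <- rep(fx$labels$labels[perm], each = 12)
    mean(evaluate_feature(tab, fx$assignment, "roiA", "highgamma", seed = s)$accuracy)
  }, numeric(1))
  expect_gt(t.test(accs, mu = 0.5)$p.value, 0.01)
})

test_that("multiclass decoding separates constructed signatures and degrades to chance", {
  fx <- feature_fixture(
    n_blocks = 60, states = c("Talking", "WatchingTV", "UsingElectronics"),
    shifts = NULL, seed = 7)
  bin_lab <- fx$table$labels
  # give each state its own band signature across all electrodes
  for (st in list(c("Talking", "theta"), c("WatchingTV", "alpha"),
                  c("UsingElectronics", "beta"))) {
    bd <- match(st[2], fx$table$bands$name)
    fx$table$values[bin_lab == st[1], , bd] <-
      fx$table$values[bin_lab == st[1], , bd] + 1.2
  }
  mc <- evaluate_multiclass(fx$table, fx$assignment,
                            classes = c("Talking", "WatchingTV", "UsingElectronics"),
                            seed = 2)
  expect_gt(mean(mc$accuracy), finite_chance_level(round(median(mc$n_test)), 3))

  # shuffled labels: accuracy near 1/3
  tabs <- fx$table
  set.seed(3)
  tabs$labels <- sample(tabs$labels)
  mcs <- evaluate_multiclass(tabs, fx$assignment,
                             classes = c("Talking", "WatchingTV", "UsingElectronics"),
                             seed = 2)
  expect_lt(abs(mean(mcs$accuracy) - 1 / 3), 0.12)
})

test_that("incremental ROI curves are flat for redundant regions and rise for independent ones", {
  # only roiA informative: adding noise ROIs does not help
  fx <- feature_fixture(n_blocks = 60,
                        rois = list(roiA = 3, roiB = 3, roiC = 3),
                        shifts = data.frame(roi = "roiA", band = "highgamma",
                                            delta = 0.8),
                        seed = 8)
  cv <- incremental_roi_curve(fx$table, fx$assignment, "highgamma", seed = 1)
  expect_equal(cv$roi_added[1], "roiA")
  expect_lt(max(abs(cv$test_accuracy[-1] - cv$test_accuracy[1])), 0.05)

  # two independently informative ROIs: combining adds accuracy
  fx2 <- feature_fixture(n_blocks = 60,
                         rois = list(roiA = 3, roiB = 3),
                         shifts = data.frame(roi = c("roiA", "roiB"),
                                             band = "highgamma",
                                             delta = c(0.55, 0.55)),
                         seed = 9)
  cv2 <- incremental_roi_curve(fx2$table, fx2$assignment, "highgamma", seed = 1)
  expect_gt(cv2$test_accuracy[2], cv2$test_accuracy[1] + 0.03)

  # single retained ROI degenerates to a length-1 curve
  fx1 <- feature_fixture(n_blocks = 20, rois = list(roiA = 3), seed = 10)
  cv1 <- incremental_roi_curve(fx1$table, fx1$assignment, "alpha", seed = 1)
  expect_equal(nrow(cv1), 1)
})
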