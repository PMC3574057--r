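# feature frame where the label depends only on the named columns
toy_examples <- function(n = 400, seed = 31, driver = "height_pct",
                         beta = 3, noise = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(stats::rnorm(n * 16), n, 16,
                            dimnames = list(NULL, FEATURE_NAMES)))
  x$high_cpg <- as.integer(x$high_cpg > 1)
  x$low_cpg <- as.integer(x$low_cpg > 1)
  lp <- rowSums(as.matrix(x[, driver, drop = FALSE])) * beta +
    stats::rnorm(n, 0, noise)
  y <- factor(ifelse(lp > 0, "common", "specific"),
              levels = c("common", "specific"))
  list(x = x, y = y)
}

test_that("overlap labelling marks common peaks and matches the scan oracle", {
  set.seed(32)
  a <- rand_peaks(50, span = 5000)
  expect_true(all(label_by_overlap(a, a) == "common"))
  expect_true(all(label_by_overlap(a, a[0, ]) == "specific"))
  b <- rand_peaks(50, span = 5000, prefix = "t")
  lab <- label_by_overlap(a, b)
  for (i in seq_len(50)) {
    expect_identical(lab[i] == "common",
                     bf_count_overlapping(a[i, , drop = FALSE], b) == 1L)
  }
})

test_that("height percentiles use average ranks out of 100", {
  expect_equal(height_percentiles(7), 100)
  expect_equal(height_percentiles(10 * (1:10)), 10 * (1:10))
  expect_equal(height_percentiles(rep(5, 4)), rep(62.5, 4))
  set.seed(33)
  h <- sample.int(50, 200, replace = TRUE)
  p <- height_percentiles(h)
  expect_true(all(p >= 0 & p <= 100))
  expect_equal(p, rank(h) / 200 * 100)
})

test_that("ROC score is the rank statistic of the decision values", {
  y <- factor(rep(c("common", "specific"), each = 5),
              levels = c("common", "specific"))
  expect_equal(roc_auc(c(6:10, 1:5), y), 1)
  expect_equal(roc_auc(c(1:5, 6:10), y), 0)
  expect_equal(roc_auc(rep(1, 10), y), 0.5)
  pts <- roc_points(c(6:10, 1:5), y)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_equal(pts$fpr[nrow(pts)], 1)
})

test_that("stratified folds preserve class proportions within one example", {
  set.seed(34)
  y <- factor(sample(c("common", "specific"), 317, TRUE, prob = c(0.3, 0.7)))
  folds <- stratified_folds(y, k = 10, seed = 5)
  tab <- table(folds, y)
  expect_true(all(apply(tab, 2, function(cl) diff(range(cl)) <= 1)))
  expect_identical(folds, stratified_folds(y, k = 10, seed = 5))
  expect_false(identical(folds, stratified_folds(y, k = 10, seed = 6)))
  expect_error(stratified_folds(factor(rep("common", 30),
                                       levels = c("common", "specific")),
                                k = 10), "k examples")
})

test_that("the linear SVM separates a separable height rule perfectly", {
  ex <- toy_examples(noise = 0)  # label = sign of height_pct, no noise
  cv <- specificity_cv(ex$x, ex$y, model = "height", k = 10, seed = 1)
  expect_equal(cv$mean_auc, 1, tolerance = 1e-9)
  # determinism: identical folds and scores on the same seed
  cv2 <- specificity_cv(ex$x, ex$y, model = "height", k = 10, seed = 1)
  expect_identical(cv$fold_auc, cv2$fold_auc)
  # fitted object round trip
  fit <- specificity_fit(ex$x, ex$y, features = "height_pct")
  expect_s3_class(fit, "specificity_fit")
  dec <- predict(fit, ex$x)
  expect_gt(roc_auc(dec, ex$y), 0.99)
  expect_gt(coef(fit)["height_pct"], 0)
  cls <- predict(fit, ex$x, type = "class")
  expect_gt(mean(cls == ex$y), 0.99)
})

test_that("random labels give chance-level ROC", {
  set.seed(35)
  ex <- toy_examples(n = 2000)
  y_perm <- sample(ex$y)
  cv <- specificity_cv(ex$x, y_perm, model = "svm", k = 10, seed = 2)
  expect_lt(abs(cv$mean_auc - 0.5), 0.05)
})

test_that("the feature groups partition the 16 features", {
  expect_setequal(unlist(FEATURE_GROUPS), FEATURE_NAMES)
  expect_identical(length(unlist(FEATURE_GROUPS)), 16L)
  reduced <- setdiff(FEATURE_NAMES,
                     c(FEATURE_GROUPS$Height, FEATURE_GROUPS$Cluster))
  expect_setequal(unlist(specpeak:::SUPER_GROUPS), reduced)
})

test_that("group elimination isolates the generative feature group", {
  ex <- toy_examples(n = 600, driver = "height_pct", beta = 3, noise = 0.5)
  el <- feature_group_elimination(ex$x, ex$y, k = 5, seed = 3)
  expect_lt(el$delta_auc[el$group == "Height"], -0.05)
  others <- el$delta_auc[!el$group %in% "Height"]
  expect_true(all(abs(others) < 0.05))
  # removing a constant feature group barely moves the score
  x_const <- ex$x
  x_const$phylop <- 0
  el2 <- feature_group_elimination(x_const, ex$y, k = 5, seed = 3)
  expect_lt(abs(el2$delta_auc[el2$group == "PhyloP"]), 0.01)
})

test_that("supergroup elimination flags the generative context group", {
  ex <- toy_examples(n = 600, driver = "chromatin_diff", beta = 3,
                     noise = 0.5)
  el <- grouped_elimination_reduced(ex$x, ex$y, k = 5, seed = 4)
  drop <- el$delta_auc[el$group == "cell_type_specific"]
  expect_lt(drop, -0.05)
  expect_true(all(el$delta_auc[el$group != "cell_type_specific"] > drop))
})

test_that("high-and-clustered subset equals the brute-force filter", {
  set.seed(36)
  pct <- stats::runif(500, 0, 100)
  ctf <- sample.int(8, 500, replace = TRUE)
  sub <- high_clustered_subset(pct, ctf)
  thr <- stats::quantile(ctf, 0.8, type = 1, names = FALSE)
  expect_identical(sub$cluster_threshold, thr)
  expect_identical(sub$index, which(pct >= 90 & ctf >= thr))
  degen <- high_clustered_subset(pct, rep(3L, 500))
  expect_true(degen$degenerate)
})

test_that("cross-cell-type evaluation with identical contexts matches CV", {
  ex <- toy_examples(n = 800, noise = 0.8, seed = 37)
  cv <- specificity_cv(ex$x, ex$y, model = "height", k = 10, seed = 5)
  xc <- cross_celltype_evaluation(ex$x, ex$y, ex$x, ex$y, model = "height",
                                  k = 10, seed = 5)
  expect_equal(xc$mean_auc, cv$mean_auc, tolerance = 1e-9)
  expect_error(cross_celltype_evaluation(ex$x, ex$y, ex$x[1:10, ],
                                         ex$y[1:10]),
               "same reference peaks")
})

test_that("hpp uses height, conservation and motif score when available", {
  ex <- toy_examples(n = 300, seed = 38)
  expect_setequal(specificity_cv(ex$x, ex$y, model = "hpp", k = 5,
                                 seed = 1)$features,
                  c("height_pct", "phylop"))
  x2 <- ex$x
  x2$pwm_score <- stats::rnorm(300)
  expect_setequal(specificity_cv(x2, ex$y, model = "hpp", k = 5,
                                 seed = 1)$features,
                  c("height_pct", "phylop", "pwm_score"))
  # TFs without a PWM: all-NA column is dropped silently
  x3 <- ex$x
  x3$pwm_score <- NA_real_
  expect_setequal(specificity_cv(x3, ex$y, model = "hpp", k = 5,
                                 seed = 1)$features,
                  c("height_pct", "phylop"))
})
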