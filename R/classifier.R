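#' Classifiers of peak cell-type specificity
#'
#' A peak in the reference cell type is labelled `common` when it overlaps a
#' same-TF peak in the comparison cell type by at least one base, else
#' `specific`. Three soft-margin linear SVM models predict that label: the
#' full model on the 16-feature set, `height` on the peak-height percentile
#' alone, and `hpp` on height, conservation and PWM score. Performance is
#' the area under the ROC curve of the decision values, estimated by
#' stratified k-fold cross-validation.
#'
#' @name classifier
NULL

#' The 16 classifier features, in canonical order
#' @export
FEATURE_NAMES <- c("height_pct", "length", "promoter", "tss_dist",
                   "cluster_tfs", "cluster_avg_height",
                   "chromatin_avg", "chromatin_diff",
                   "h3k4me3_avg", "h3k4me3_diff",
                   "h3k27me3_avg", "h3k27me3_diff",
                   "cpg_freq", "high_cpg", "low_cpg", "phylop")

#' Feature groups for group-wise elimination
#' @export
FEATURE_GROUPS <- list(
  Height = "height_pct", Length = "length", Promoter = "promoter",
  `TSS dist` = "tss_dist", Cluster = c("cluster_tfs", "cluster_avg_height"),
  Chromatin = c("chromatin_avg", "chromatin_diff"),
  H3K4me3 = c("h3k4me3_avg", "h3k4me3_diff"),
  H3K27me3 = c("h3k27me3_avg", "h3k27me3_diff"),
  CpG = c("cpg_freq", "high_cpg", "low_cpg"), PhyloP = "phylop")

# After removing height and clustering, the remaining 13 features are
# grouped into: cell-type specific context, promoter/sequence-associated
# (length included so the groups partition the remainder), conservation.
SUPER_GROUPS <- list(
  cell_type_specific = c("chromatin_avg", "chromatin_diff", "h3k4me3_avg",
                         "h3k4me3_diff", "h3k27me3_avg", "h3k27me3_diff"),
  promoter_sequence = c("length", "promoter", "tss_dist", "cpg_freq",
                        "high_cpg", "low_cpg"),
  conservation = "phylop")

#' Label reference peaks by overlap with a comparison set
#'
#' @param reference,comparison peak frames for the same TF in two cell
#'   types.
#' @return factor along `reference` rows with levels `common`, `specific`.
#' @export
label_by_overlap <- function(reference, comparison) {
  factor(ifelse(overlaps_any(reference, comparison), "common", "specific"),
         levels = c("common", "specific"))
}

#' Peak-height percentiles
#'
#' Average-rank percentile of each height within its (TF, cell type) set:
#' `rank / n * 100`, ties sharing the average rank. A single peak gets 100.
#'
#' @param heights numeric vector of peak heights.
#' @return numeric vector in `[0, 100]`.
#' @export
height_percentiles <- function(heights) {
  rank(heights, ties.method = "average") / length(heights) * 100
}

#' Area under the ROC curve from decision values
#'
#' Rank statistic (Mann-Whitney) on continuous scores; ties get average
#' ranks.
#'
#' @param scores decision values, larger = more positive.
#' @param labels factor or character labels.
#' @param positive the positive class (default `"common"`).
#' @return numeric AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "common") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("ROC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from decision values
#'
#' @inheritParams roc_auc
#' @return `data.frame(fpr, tpr)` sorted from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels, positive = "common") {
  ord <- order(scores, decreasing = TRUE)
  pos <- (labels == positive)[ord]
  tpr <- c(0, cumsum(pos) / sum(pos))
  fpr <- c(0, cumsum(!pos) / sum(!pos))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Stratified fold assignment
#'
#' Examples of each class are shuffled with the seed and dealt round-robin
#' over k folds, so class proportions per fold differ by at most one
#' example.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold index (1..k) per example.
#' @export
stratified_folds <- function(labels, k = 10, seed = 1L) {
  if (min(table(labels)) < k) stop("need at least k examples per class")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    i <- which(labels == cls)
    folds[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  folds
}

# z-score standardisation fitted on training rows; constant columns get
# scale 1 so they pass through as zeros.
.fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

.apply_scaler <- function(x, sc) {
  scale(x, center = sc$center, scale = sc$scale)
}

#' Fit a linear specificity classifier
#'
#' Standardises the features (z-scores fitted on the training data) and
#' fits a soft-margin linear-kernel SVM with cost `cost`. Classes are
#' weighted inversely to their frequencies: common and specific peaks are
#' rarely balanced, and an unweighted SVM on overlapping classes can
#' collapse onto the majority class (weight vector at numerical zero with
#' arbitrary sign), which destroys the ranking the ROC score needs. The
#' model keeps the scaler so prediction applies the training-fold
#' standardisation.
#'
#' @param x numeric feature matrix or data.frame.
#' @param y factor with levels `common`, `specific` (both present).
#' @param features columns of `x` to use (default all).
#' @param cost soft-margin cost parameter C (default 1).
#' @return object of class `specificity_fit`.
#' @export
specificity_fit <- function(x, y, features = colnames(x), cost = 1) {
  x <- as.matrix(as.data.frame(x)[, features, drop = FALSE])
  y <- factor(y, levels = c("common", "specific"))
  if (nlevels(droplevels(y)) < 2L) stop("training data must contain both classes")
  sc <- .fit_scaler(x)
  xs <- .apply_scaler(x, sc)
  cw <- length(y) / (2 * table(y))
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = cw)
  dv1 <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                             decision.values = TRUE), "decision.values")
  pos_class <- strsplit(colnames(dv1)[1], "/", fixed = TRUE)[[1]][1]
  structure(list(svm = fit, scaler = sc, features = features, cost = cost,
                 pos_class = pos_class, n = nrow(x), class_counts = table(y)),
            class = "specificity_fit")
}

#' @export
print.specificity_fit <- function(x, ...) {
  cat("Linear SVM peak-specificity classifier\n")
  cat("  features:", length(x$features), "| cost:", x$cost,
      "| n =", x$n, sprintf("(common %d / specific %d)\n",
                            x$class_counts["common"], x$class_counts["specific"]))
  invisible(x)
}

#' Decision values or class predictions
#'
#' Decision values are oriented so that larger values indicate the `common`
#' class.
#'
#' @param object a [specificity_fit()].
#' @param newdata feature matrix or data.frame covering the fit's features.
#' @param type `"decision"` (default) or `"class"`.
#' @param ... unused.
#' @return numeric decision values or a factor.
#' @export
predict.specificity_fit <- function(object, newdata,
                                    type = c("decision", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  xs <- .apply_scaler(x, object$scaler)
  pr <- stats::predict(object$svm, xs, decision.values = TRUE)
  if (type == "class") return(pr)
  dv <- attr(pr, "decision.values")
  # positive raw decision values favour the class named first in the
  # "a/b" column label, recorded at fit time
  as.numeric(dv[, 1]) * if (object$pos_class == "common") 1 else -1
}

#' Feature weights of the linear decision function
#'
#' @param object a [specificity_fit()].
#' @param ... unused.
#' @return named numeric vector of weights on the standardised features,
#'   oriented so positive weights push towards `common`.
#' @export
coef.specificity_fit <- function(object, ...) {
  w <- drop(t(object$svm$coefs) %*% object$svm$SV)
  sgn <- if (object$pos_class == "common") 1 else -1
  stats::setNames(as.numeric(w) * sgn, object$features)
}

# Feature sets of the three published model variants.
.model_features <- function(model, available) {
  switch(model,
    svm = FEATURE_NAMES,
    height = "height_pct",
    hpp = intersect(c("height_pct", "phylop", "pwm_score"), available),
    stop("unknown model: ", model))
}

#' Stratified k-fold cross-validation of a specificity model
#'
#' Per fold the features are standardised on the training fold, a linear
#' SVM is fitted, decision values are scored on the held-out fold, and the
#' ROC score (AUC) is recorded. The `hpp` model silently drops the
#' `pwm_score` column when it is absent or all-NA (TFs without an available
#' PWM).
#'
#' @param x feature data.frame (16 canonical features, plus optionally
#'   `pwm_score`).
#' @param y labels (`common`/`specific`).
#' @param model `"svm"`, `"height"` or `"hpp"`; ignored when `features` is
#'   given.
#' @param features explicit feature subset overriding `model`.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param cost SVM cost.
#' @return object of class `specificity_cv`: `fold_auc`, `mean_auc`,
#'   `decision` (pooled out-of-fold decision values), `roc` curve points,
#'   `model`, `features`, `k`, `seed`.
#' @export
specificity_cv <- function(x, y, model = c("svm", "height", "hpp"),
                           features = NULL, k = 10, seed = 1L, cost = 1) {
  x <- as.data.frame(x)
  y <- factor(y, levels = c("common", "specific"))
  if (is.null(features)) {
    model <- match.arg(model)
    avail <- names(x)[vapply(x, function(v) !all(is.na(v)), logical(1))]
    features <- .model_features(model, avail)
  } else model <- "custom"
  folds <- stratified_folds(y, k = k, seed = seed)
  dec <- numeric(length(y))
  auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- specificity_fit(x[tr, , drop = FALSE], y[tr], features = features,
                           cost = cost)
    dec[!tr] <- predict(fit, x[!tr, , drop = FALSE])
    auc[f] <- roc_auc(dec[!tr], y[!tr])
  }
  structure(list(fold_auc = auc, mean_auc = mean(auc), decision = dec,
                 roc = roc_points(dec, y), model = model, features = features,
                 k = k, seed = seed, n = length(y),
                 class_counts = table(y)),
            class = "specificity_cv")
}

#' @export
print.specificity_cv <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV (%s model): mean ROC score %.3f\n",
              x$k, x$model, x$mean_auc))
  invisible(x)
}

#' @export
summary.specificity_cv <- function(object, ...) {
  cat(sprintf("%d-fold stratified CV, %s model (%d features), n = %d\n",
              object$k, object$model, length(object$features), object$n))
  cat(sprintf("  mean ROC score %.3f (sd %.3f)\n", object$mean_auc,
              stats::sd(object$fold_auc)))
  cat("  per-fold:", paste(sprintf("%.3f", object$fold_auc), collapse = " "),
      "\n")
  invisible(object)
}

#' @export
plot.specificity_cv <- function(x, ...) {
  plot(x$roc$fpr, x$roc$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate",
       main = sprintf("ROC (%s), score %.3f", x$model, x$mean_auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Feature-group elimination
#'
#' Removes one feature group at a time and reports the change in mean
#' cross-validated ROC score relative to the full model (negative values
#' mean the group helped). The same seed is used throughout so every run
#' shares fold assignments.
#'
#' @param x feature data.frame.
#' @param y labels.
#' @param groups named list of feature-name vectors (default
#'   [FEATURE_GROUPS]).
#' @param base_features features of the reference model (default the 16).
#' @param k,seed,cost as in [specificity_cv()].
#' @return `data.frame(group, mean_auc, delta_auc)` plus attribute
#'   `base_auc`.
#' @export
feature_group_elimination <- function(x, y, groups = FEATURE_GROUPS,
                                      base_features = FEATURE_NAMES,
                                      k = 10, seed = 1L, cost = 1) {
  base <- specificity_cv(x, y, features = base_features, k = k, seed = seed,
                         cost = cost)
  rows <- lapply(names(groups), function(g) {
    keep <- setdiff(base_features, groups[[g]])
    cv <- specificity_cv(x, y, features = keep, k = k, seed = seed, cost = cost)
    data.frame(group = g, mean_auc = cv$mean_auc,
               delta_auc = cv$mean_auc - base$mean_auc)
  })
  out <- do.call(rbind, rows)
  attr(out, "base_auc") <- base$mean_auc
  out
}

#' Supergroup elimination on the reduced feature set
#'
#' Removes peak height and the clustering features, then eliminates the
#' three remaining supergroups (cell-type specific context,
#' promoter/sequence-associated, conservation) one at a time.
#'
#' @inheritParams feature_group_elimination
#' @return as [feature_group_elimination()].
#' @export
grouped_elimination_reduced <- function(x, y, k = 10, seed = 1L, cost = 1) {
  reduced <- setdiff(FEATURE_NAMES,
                     c(FEATURE_GROUPS$Height, FEATURE_GROUPS$Cluster))
  feature_group_elimination(x, y, groups = SUPER_GROUPS,
                            base_features = reduced, k = k, seed = seed,
                            cost = cost)
}

#' High and clustered peak subset
#'
#' Peaks among the 10% highest (height percentile >= `height_min`) that also
#' sit in the top 20% largest clusters (distinct-TF count at or above the
#' 80th percentile of cluster sizes).
#'
#' @param height_pct per-peak height percentiles.
#' @param cluster_tfs per-peak distinct-TF cluster sizes.
#' @param height_min percentile cutoff (default 90).
#' @param cluster_quantile cluster-size quantile cutoff (default 0.8).
#' @return list: `index` (selected rows), `cluster_threshold` (absolute
#'   distinct-TF cutoff used), `degenerate` (TRUE when all cluster sizes are
#'   equal).
#' @export
high_clustered_subset <- function(height_pct, cluster_tfs, height_min = 90,
                                  cluster_quantile = 0.8) {
  thr <- stats::quantile(cluster_tfs, cluster_quantile, names = FALSE, type = 1)
  list(index = which(height_pct >= height_min & cluster_tfs >= thr),
       cluster_threshold = thr,
       degenerate = stats::sd(cluster_tfs) == 0)
}

#' Cross-cell-type evaluation protocol
#'
#' Stratified k-fold over the reference peaks. Training folds carry labels
#' and context features derived from the first comparison cell type; the
#' held-out fold is relabelled and recontextualised against a different
#' comparison cell type, so no peak appears in both a train and a test set
#' and the cell-type specific features come from different cell types in
#' train and test.
#'
#' @param x_train feature data.frame in the training context (reference vs
#'   comparison cell type B).
#' @param y_train labels vs cell type B.
#' @param x_test feature data.frame for the same reference peaks in the
#'   test context (vs cell type C).
#' @param y_test labels vs cell type C.
#' @param model,features,k,seed,cost as in [specificity_cv()].
#' @return a `specificity_cv` object (fold AUCs measured on the
#'   test-context folds).
#' @export
cross_celltype_evaluation <- function(x_train, y_train, x_test, y_test,
                                      model = c("svm", "height", "hpp"),
                                      features = NULL, k = 10, seed = 1L,
                                      cost = 1) {
  x_train <- as.data.frame(x_train); x_test <- as.data.frame(x_test)
  if (nrow(x_train) != nrow(x_test))
    stop("train and test contexts must describe the same reference peaks")
  y_train <- factor(y_train, levels = c("common", "specific"))
  y_test <- factor(y_test, levels = c("common", "specific"))
  if (is.null(features)) {
    model <- match.arg(model)
    avail <- names(x_train)[vapply(x_train, function(v) !all(is.na(v)),
                                   logical(1))]
    features <- .model_features(model, avail)
  } else model <- "custom"
  folds <- stratified_folds(y_train, k = k, seed = seed)
  dec <- numeric(length(y_test))
  auc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- specificity_fit(x_train[tr, , drop = FALSE], y_train[tr],
                           features = features, cost = cost)
    dec[!tr] <- predict(fit, x_test[!tr, , drop = FALSE])
    auc[f] <- roc_auc(dec[!tr], y_test[!tr])
  }
  structure(list(fold_auc = auc, mean_auc = mean(auc), decision = dec,
                 roc = roc_points(dec, y_test), model = model,
                 features = features, k = k, seed = seed, n = length(y_test),
                 class_counts = table(y_test), protocol = "cross_celltype"),
            class = "specificity_cv")
}
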