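# Cross-validation harness and threshold-free metrics.

#' Stratified k-fold assignment
#'
#' Random reshuffle followed by k near-equal folds, stratified by label so
#' every fold carries the class proportions of the whole set. The same
#' assignment is shared by every model of an experiment (blocking
#' requirement of the Friedman test).
#'
#' @param y Label vector (its length sets n).
#' @param k Fold count.
#' @param seed Integer seed.
#' @return Integer vector of fold indices 1..k.
#' @export
make_folds <- function(y, k = 10, seed = 1L) {
  n <- length(y)
  stopifnot(n >= k, k >= 2)
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k))
    if (length(unique(y[fold != f])) < 2)
      stop("a class is absent from the training split of fold ", f)
  fold
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: ties contribute half. Equals the
#' trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric decision values (larger = more positive).
#' @param labels Binary labels (0/1 or the two-level equivalent).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as_pm1(labels) == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes are required for the AUROC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision, recall and F-measure at a threshold
#'
#' @param scores Decision values.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0, the signed-SVM
#'   convention; use 0.5 for probabilistic scores).
#' @return Tibble: precision, recall, f_measure, and a
#'   `no_positive_predictions` flag (precision reported as 0 in that case).
#' @export
prf <- function(scores, labels, threshold = 0) {
  y <- as_pm1(labels) == 1
  if (all(y) || !any(y)) stop("both classes are required")
  pred <- scores > threshold
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  flag <- (tp + fp) == 0
  precision <- if (flag) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f_measure = f,
                 no_positive_predictions = flag)
}

#' Empirical ROC curve
#'
#' @param scores Decision values.
#' @param labels Binary labels.
#' @return Tibble of (fpr, tpr) points from (0,0) to (1,1).
#' @export
roc_curve <- function(scores, labels) {
  y <- as_pm1(labels) == 1
  ord <- order(-scores)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  # collapse score ties to one operating point
  keep <- c(diff(scores[ord]) != 0, TRUE)
  tibble::tibble(fpr = c(0, fp[keep] / sum(!y)),
                 tpr = c(0, tp[keep] / sum(y)))
}

#' Vertically averaged ROC curve
#'
#' Averages TPR over curves on a fixed grid of 101 FPR points, treating
#' each curve as a right-continuous staircase.
#'
#' @param curves List of (fpr, tpr) tibbles from [roc_curve()].
#' @param grid_points Grid size (default 101).
#' @return Tibble (fpr, tpr).
#' @export
mean_roc <- function(curves, grid_points = 101) {
  stopifnot(length(curves) >= 1)
  grid <- seq(0, 1, length.out = grid_points)
  tprs <- vapply(curves, function(cv) {
    vapply(grid, function(g) max(cv$tpr[cv$fpr <= g]), numeric(1))
  }, numeric(grid_points))
  tibble::tibble(fpr = grid, tpr = rowMeans(as.matrix(tprs)))
}

#' Evaluate a set of models on shared folds
#'
#' Runs every model on the same stratified fold assignment and collects
#' per-fold AUROC, precision, recall, F-measure, selected-feature count
#' and the ROC curve — the complete blocked results matrix consumed by
#' [decision_workflow()].
#'
#' @param table Feature table (raw, unstandardized).
#' @param models Named list of model functions; each is called as
#'   `fn(X_train, y_train, X_test, groups)` and must return a list with
#'   `scores` (test decision values) and `n_features`.
#' @param k Fold count.
#' @param seed Fold seed.
#' @param scaling `"global"` (whole-table z-scoring first, as the study
#'   did) or `"per-fold"` (train statistics applied to the test rows).
#' @param groups Feature grouping (default from the inventory intersected
#'   with the table columns).
#' @return Tibble of class `fold_results`: model, fold, auroc, precision,
#'   recall, f_measure, n_features, roc (list-column).
#' @export
evaluate_models <- function(table, models, k = 10, seed = 1L,
                            scaling = c("global", "per-fold"),
                            groups = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(length(models) >= 1, !is.null(names(models)))
  if (is.null(groups)) {
    inv <- feature_inventory()
    present <- inv[inv$name %in% names(table), ]
    groups <- split(present$name, present$group)[unique(present$group)]
  }
  folds <- make_folds(table$label, k = k, seed = seed)
  if (scaling == "global") table_g <- standardize(table, "global")
  out <- list()
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    tab <- if (scaling == "global") table_g else
      standardize(table, "per-fold", train_rows = tr)
    feats <- unlist(groups, use.names = FALSE)
    Xtr <- as.matrix(tab[tr, feats]); Xte <- as.matrix(tab[te, feats])
    ytr <- tab$label[tr]; yte <- tab$label[te]
    for (mname in names(models)) {
      res <- models[[mname]](Xtr, ytr, Xte, groups)
      p <- prf(res$scores, yte)
      out[[length(out) + 1]] <- tibble::tibble(
        model = mname, fold = f,
        auroc = auroc(res$scores, yte),
        precision = p$precision, recall = p$recall, f_measure = p$f_measure,
        n_features = res$n_features,
        roc = list(roc_curve(res$scores, yte)))
    }
  }
  structure(dplyr::bind_rows(out), class = c("fold_results", "tbl_df", "tbl",
                                             "data.frame"))
}
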