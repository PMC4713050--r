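# Feature-selection multiple kernel learning (FSMKL): per-group class
# alignment ranking, a bank of kernels over nested ranked-feature prefixes,
# sparse SimpleMKL-style weight learning, and importance reporting.

#' Rank the features of one group by class alignment
#'
#' Scores every feature by the absolute point-biserial correlation with the
#' binary label and sorts by decreasing score, ties broken by inventory
#' (input) order. Constant features score 0.
#'
#' @param table Feature table with a `label` column.
#' @param features Character vector of feature columns to rank (one group).
#' @return Tibble: feature, score, rank.
#' @export
rank_features <- function(table, features) {
  y <- table$label
  if (length(unique(y)) < 2) stop("both classes are required to rank features")
  score <- vapply(features, function(f) {
    v <- suppressWarnings(stats::cor(table[[f]], y))
    if (is.na(v)) 0 else abs(v)
  }, numeric(1))
  ord <- order(-score, seq_along(features))
  tibble::tibble(feature = features[ord], score = unname(score[ord]),
                 rank = seq_along(features))
}

#' Build the FSMKL kernel bank
#'
#' One kernel per (texture group, ranked-prefix size, kernel family and
#' hyperparameter). Prefix sizes are capped at the group size and
#' deduplicated. Gaussian widths default to low values scaled by the
#' prefix size: `gamma_scales / k`. Gram matrices are computed lazily by
#' [fsmkl_train()] on the requested rows; the bank stores the standardized
#' feature matrix and the kernel specs.
#'
#' @param table Standardized feature table with a `label` column.
#' @param groups Named list: group -> character vector of its features, in
#'   inventory order (see [feature_groups()]).
#' @param subset_sizes Prefix sizes per group; `Inf` means the whole group.
#' @param families Kernel families for every (group, prefix).
#' @param gamma_scales Low gaussian width multipliers (divided by the
#'   prefix size).
#' @param rankings Optional precomputed rankings (named list of
#'   [rank_features()] tibbles); computed from `table` if missing.
#' @return List of class `kernel_bank`: specs tibble, feature matrix `X`,
#'   labels `y`.
#' @export
build_kernel_bank <- function(table, groups,
                              subset_sizes = c(1, 2, 3, 5, 8, 13, Inf),
                              families = c("polynomial-1", "polynomial-2",
                                           "gaussian"),
                              gamma_scales = c(0.01, 0.1, 1),
                              rankings = NULL) {
  if (nrow(table) == 0) stop("empty feature table")
  if (is.null(rankings))
    rankings <- lapply(groups, function(fs) rank_features(table, fs))
  specs <- list()
  for (g in names(groups)) {
    ranked <- rankings[[g]]$feature
    ks <- unique(pmin(subset_sizes, length(ranked)))
    for (k in ks) {
      subset <- ranked[seq_len(k)]
      for (fam in families) {
        if (fam == "gaussian") {
          for (gs in gamma_scales)
            specs[[length(specs) + 1]] <- tibble::tibble(
              group = g, k = k, features = list(subset), family = fam,
              gamma = gs / k)
        } else {
          specs[[length(specs) + 1]] <- tibble::tibble(
            group = g, k = k, features = list(subset), family = fam,
            gamma = NA_real_)
        }
      }
    }
  }
  specs <- dplyr::bind_rows(specs)
  specs$kernel_id <- seq_len(nrow(specs))
  X <- as.matrix(table[unique(unlist(groups))])
  structure(list(specs = specs, X = X, y = table$label, rankings = rankings),
            class = "kernel_bank")
}

# Gram matrices of every kernel spec on the given rows, trace-normalized to
# mean diagonal 1 (so heterogeneous families are on a comparable scale).
# Returns list(grams, factors).
bank_grams <- function(bank, rows) {
  n <- length(rows)
  grams <- vector("list", nrow(bank$specs))
  factors <- numeric(nrow(bank$specs))
  for (m in seq_len(nrow(bank$specs))) {
    sp <- bank$specs[m, ]
    K <- kernel_gram(bank$X[rows, sp$features[[1]], drop = FALSE],
                     family = sp$family, gamma = sp$gamma)
    f <- n / sum(diag(K))
    grams[[m]] <- K * f
    factors[m] <- f
  }
  list(grams = grams, factors = factors)
}

#' Train FSMKL by SimpleMKL-style alternating optimization
#'
#' Minimizes the regularized MKL objective over simplex-constrained kernel
#' weights `d`: for fixed `d` the SVM dual is solved on
#' `K(d) = sum d_m K_m`; `d` is then updated by a reduced-gradient descent
#' step with a halving line search. Iterates until the weight change falls
#' below `tol`. Weights below `clamp` are zeroed and the remainder
#' renormalized before a final SVM solve.
#'
#' @param bank A `kernel_bank`.
#' @param rows Row indices to train on (default all).
#' @param C Soft-margin constant.
#' @param tol Convergence tolerance on `max |delta d|`.
#' @param max_iter Maximum outer iterations.
#' @param clamp Sparsity threshold on the weights.
#' @param svm_eps KKT tolerance of the inner SVM solves.
#' @return List of class `fsmkl_fit`: weights `d`, dual coefficients,
#'   bias, training rows, objective log, convergence flag.
#' @export
fsmkl_train <- function(bank, rows = NULL, C = 10, tol = 1e-3, max_iter = 40,
                        clamp = 1e-4, svm_eps = 1e-4) {
  stopifnot(inherits(bank, "kernel_bank"), C > 0)
  if (is.null(rows)) rows <- seq_along(bank$y)
  y <- as_pm1(bank$y[rows])
  bg <- bank_grams(bank, rows)
  Ks <- bg$grams
  M <- length(Ks)
  d <- rep(1 / M, M)
  obj_log <- numeric(0)
  converged <- FALSE
  sol <- smo_solve(combine_kernels(Ks, d), y, C, svm_eps)
  J <- sol$objective
  obj_log <- J
  for (it in seq_len(max_iter)) {
    v <- sol$alpha * y
    grad <- -0.5 * kernel_quadforms(Ks, v)   # dJ/dd_m at the dual optimum
    mu <- which.max(d)
    red <- grad - grad[mu]
    D <- -red
    D[d <= 0 & red > 0] <- 0
    D[mu] <- -sum(D[-mu])
    if (max(abs(D)) < 1e-12) { converged <- TRUE; break }
    neg <- which(D < 0)
    step <- min(1, if (length(neg)) min(-d[neg] / D[neg]) else 1)
    improved <- FALSE
    for (ls in 1:12) {
      d_try <- pmax(d + step * D, 0)
      d_try <- d_try / sum(d_try)
      sol_try <- smo_solve(combine_kernels(Ks, d_try), y, C, svm_eps)
      if (sol_try$objective < J - 1e-10) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    delta <- max(abs(d_try - d))
    d <- d_try; sol <- sol_try; J <- sol_try$objective
    obj_log <- c(obj_log, J)
    if (delta < tol) { converged <- TRUE; break }
  }
  d_pre <- d
  d[d < clamp] <- 0
  if (sum(d) == 0) d[which.max(d_pre)] <- 1  # degenerate guard
  d <- d / sum(d)
  sol <- smo_solve(combine_kernels(Ks, d), y, C, svm_eps)
  structure(list(d = d, alpha = sol$alpha, b = sol$b, y = y, rows = rows,
                 factors = bg$factors, C = C, objective = sol$objective,
                 objective_log = obj_log, converged = converged,
                 specs = bank$specs),
            class = "fsmkl_fit")
}

#' Decision values of a trained FSMKL model
#'
#' `f(x) = sum_i alpha_i y_i sum_m d_m K_m(x_i, x) + b`, with test kernels
#' computed against the training rows under the training specs and
#' normalization factors.
#'
#' @param model An `fsmkl_fit`.
#' @param bank The `kernel_bank` the model was trained from.
#' @param rows Row indices of the test samples in the bank, or `NULL` to
#'   score external data in `newX`.
#' @param newX Optional matrix of new samples (standardized, same columns
#'   as the bank's feature matrix).
#' @return Tibble: score, label (0/1 by the sign of the score).
#' @export
fsmkl_predict <- function(model, bank, rows = NULL, newX = NULL) {
  stopifnot(inherits(model, "fsmkl_fit"), inherits(bank, "kernel_bank"))
  if (!identical(model$specs$kernel_id, bank$specs$kernel_id) ||
      !identical(model$specs$family, bank$specs$family))
    stop("kernel specs of model and bank do not match")
  if (is.null(rows) && is.null(newX)) stop("give `rows` or `newX`")
  Xte <- if (is.null(newX)) bank$X[rows, , drop = FALSE] else {
    if (!identical(colnames(newX), colnames(bank$X)))
      stop("`newX` columns must match the bank feature matrix")
    as.matrix(newX)
  }
  Xtr <- bank$X[model$rows, , drop = FALSE]
  f <- numeric(nrow(Xte))
  v <- model$alpha * model$y
  for (m in which(model$d > 0)) {
    sp <- bank$specs[m, ]
    Kc <- kernel_gram(Xtr[, sp$features[[1]], drop = FALSE],
                      Xte[, sp$features[[1]], drop = FALSE],
                      family = sp$family, gamma = sp$gamma) * model$factors[m]
    f <- f + model$d[m] * as.numeric(crossprod(Kc, v))
  }
  f <- f + model$b
  tibble::tibble(score = f, label = as.integer(f > 0))
}

#' Kernel and feature importance of an FSMKL model
#'
#' Kernels sorted by weight with cumulative share; per-feature importance
#' aggregated as the sum of the weights of the kernels containing the
#' feature (reported raw and normalized to share of total); selected
#' features are the union over non-zero-weight kernels.
#'
#' @param model An `fsmkl_fit`.
#' @return List of class `fsmkl_importance`: `kernels` tibble (rank, group,
#'   subset size, family, weight, cumulative share), `features` tibble
#'   (feature, n_kernels, importance, share), `selected` character vector.
#' @export
report_importance <- function(model) {
  stopifnot(inherits(model, "fsmkl_fit"))
  specs <- model$specs
  ord <- order(-model$d, specs$kernel_id)
  kern <- tibble::tibble(
    rank = seq_along(ord), kernel_id = specs$kernel_id[ord],
    group = specs$group[ord], k = specs$k[ord], family = specs$family[ord],
    gamma = specs$gamma[ord], weight = model$d[ord],
    cumulative = cumsum(model$d[ord]) / sum(model$d))
  active <- which(model$d > 0)
  feats <- unlist(lapply(active, function(m)
    stats::setNames(rep(model$d[m], length(specs$features[[m]])),
                    specs$features[[m]])))
  imp <- tapply(feats, names(feats), sum)
  nker <- tapply(feats, names(feats), length)
  features <- tibble::tibble(feature = names(imp),
                             n_kernels = as.integer(nker),
                             importance = as.numeric(imp),
                             share = as.numeric(imp) / sum(imp))
  features <- dplyr::arrange(features, dplyr::desc(.data$importance))
  structure(list(kernels = kern, features = features,
                 selected = features$feature),
            class = "fsmkl_importance")
}

#' Choose the FSMKL soft-margin constant by inner cross-validation
#'
#' Grid-searches `C` by stratified inner-fold AUROC.
#'
#' @param bank A `kernel_bank`.
#' @param rows Training rows.
#' @param C_grid Candidate values.
#' @param inner_k Inner fold count.
#' @param seed Seed for the inner fold split.
#' @param ... Passed to [fsmkl_train()].
#' @return The selected `C`.
#' @export
fsmkl_select_c <- function(bank, rows = seq_along(bank$y),
                           C_grid = c(0.1, 1, 10, 100), inner_k = 5,
                           seed = 1L, ...) {
  y <- bank$y[rows]
  folds <- make_folds(y, k = inner_k, seed = seed)
  perf <- vapply(C_grid, function(C) {
    mean(vapply(seq_len(inner_k), function(f) {
      tr <- rows[folds != f]; te <- rows[folds == f]
      fit <- fsmkl_train(bank, rows = tr, C = C, ...)
      auroc(fsmkl_predict(fit, bank, rows = te)$score, bank$y[te])
    }, numeric(1)))
  }, numeric(1))
  C_grid[which.max(perf)]
}

#' @export
tidy.fsmkl_fit <- function(x, ...) report_importance(x)$kernels

#' @export
glance.fsmkl_fit <- function(x, ...) {
  tibble::tibble(n_kernels_total = length(x$d),
                 n_kernels_active = sum(x$d > 0),
                 n_features_selected = length(report_importance(x)$selected),
                 objective = x$objective,
                 iterations = length(x$objective_log),
                 converged = x$converged, C = x$C)
}

#' Grouping of inventory features by texture family
#'
#' @param inventory Tibble from [feature_inventory()].
#' @return Named list: group -> character vector of feature names.
#' @export
feature_groups <- function(inventory = feature_inventory()) {
  split(inventory$name, inventory$group)[unique(inventory$group)]
}
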