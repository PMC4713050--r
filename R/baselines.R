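# Reference classifiers: Gaussian naive Bayes, RBF SVM with grid search,
# SVM-RFE, GA/PSO feature-mask wrappers and group-wise MKL.  Each also has a
# `model_*()` constructor returning the `fn(Xtr, ytr, Xte, groups)` closure
# consumed by evaluate_models().

#' Gaussian naive Bayes
#'
#' Per-class Gaussian likelihoods under conditional feature independence.
#' Scores are posterior log-odds of the positive class.
#'
#' @param X Numeric feature matrix.
#' @param y Binary labels.
#' @return List of class `nb_fit`.
#' @export
train_naive_bayes <- function(X, y) {
  X <- as.matrix(X)
  yy <- as_pm1(y)
  if (length(unique(yy)) < 2) stop("both classes are required")
  eps <- 1e-9 * max(colMeans(X^2) - colMeans(X)^2, 1e-12)
  stats_for <- function(cl) {
    Z <- X[yy == cl, , drop = FALSE]
    mu <- colMeans(Z)
    v <- colMeans((Z - rep(mu, each = nrow(Z)))^2)  # ML variance: invariant
    list(mu = mu, v = v + eps,                      # under sample duplication
         logprior = log(nrow(Z) / nrow(X)))
  }
  structure(list(pos = stats_for(1L), neg = stats_for(-1L)),
            class = "nb_fit")
}

#' @rdname train_naive_bayes
#' @param fit An `nb_fit`.
#' @export
nb_score <- function(fit, X) {
  X <- as.matrix(X)
  ll <- function(s) rowSums(stats::dnorm(X, rep(s$mu, each = nrow(X)),
                                         rep(sqrt(s$v), each = nrow(X)),
                                         log = TRUE)) + s$logprior
  ll(fit$pos) - ll(fit$neg)
}

# inner-CV AUROC of an SVM on a precomputed Gram (folds fixed by caller)
inner_cv_auroc <- function(K, y, C, folds, eps = 1e-4) {
  mean(vapply(sort(unique(folds)), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) return(NA_real_)
    fit <- ksvm_fit(K[tr, tr, drop = FALSE], y[tr], C, eps)
    auroc(ksvm_decision(fit, K[tr, te, drop = FALSE]), y[te])
  }, numeric(1)), na.rm = TRUE)
}

#' RBF SVM with (C, gamma) grid search
#'
#' Soft-margin SVM with a Gaussian kernel; `C` and `gamma` are chosen by
#' stratified inner-fold AUROC.
#'
#' @param X,y Training data.
#' @param C_grid Box-constraint candidates.
#' @param gamma_scales Width candidates, divided by `ncol(X)`.
#' @param inner_k Inner fold count.
#' @param seed Inner-fold seed.
#' @return List of class `svm_rbf_fit` (keeps the training matrix).
#' @export
train_svm <- function(X, y, C_grid = c(0.1, 1, 10, 100),
                      gamma_scales = c(0.1, 1, 10), inner_k = 3, seed = 1L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("both classes are required")
  D2 <- pairwise_sqdist(X)
  folds <- make_folds(y, k = inner_k, seed = seed)
  best <- NULL
  for (gs in gamma_scales) {
    g <- gs / ncol(X)
    K <- exp(-g * D2)
    for (C in C_grid) {
      a <- inner_cv_auroc(K, y, C, folds)
      if (is.null(best) || a > best$auroc)
        best <- list(auroc = a, C = C, gamma = g, K = K)
    }
  }
  fit <- ksvm_fit(best$K, y, best$C)
  structure(list(svm = fit, X = X, gamma = best$gamma, C = best$C,
                 inner_auroc = best$auroc),
            class = "svm_rbf_fit")
}

#' @rdname train_svm
#' @param fit An `svm_rbf_fit`.
#' @param newX Matrix of new samples.
#' @export
svm_score <- function(fit, newX) {
  Kc <- kernel_gram(fit$X, as.matrix(newX), "gaussian", fit$gamma)
  ksvm_decision(fit$svm, Kc)
}

#' SVM-RFE: recursive feature elimination by squared SVM weights
#'
#' Trains a linear SVM, removes the `ceil(step_fraction * remaining)`
#' features with smallest `w_i^2` (one at a time below `switch_at`
#' features), and repeats down to one feature. The returned subset is the
#' elimination depth with the best stratified inner-fold AUROC.
#'
#' @param X,y Training data (standardized).
#' @param step_fraction Fraction of remaining features removed per
#'   iteration.
#' @param inner_k Inner fold count for depth selection.
#' @param C Soft-margin constant of the elimination SVMs.
#' @param switch_at Remaining-feature count below which elimination is
#'   one-at-a-time.
#' @param seed Inner-fold seed.
#' @return List of class `svm_rfe_fit`: `ranking` (all features, best
#'   first), `selected` (the chosen subset), `mask` (logical over
#'   columns), `path` tibble (depth, n_features, inner AUROC).
#' @export
svm_rfe <- function(X, y, step_fraction = 0.1, inner_k = 3, C = 10,
                    switch_at = 30, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 1, step_fraction > 0, step_fraction < 1)
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(p))
  folds <- make_folds(y, k = inner_k, seed = seed)
  yy <- as_pm1(y)
  G <- tcrossprod(X) + 1              # linear kernel, maintained incrementally
  surviving <- seq_len(p)
  eliminated <- integer(0)
  subsets <- list(surviving)
  while (length(surviving) > 1) {
    fit <- ksvm_fit(G, yy, C)
    w <- as.numeric(crossprod(X[, surviving, drop = FALSE], fit$alpha * fit$y))
    nrem <- if (length(surviving) > switch_at)
      ceiling(step_fraction * length(surviving)) else 1L
    nrem <- min(nrem, length(surviving) - 1L)   # guard: keep >= 1 feature
    drop_idx <- order(w^2)[seq_len(nrem)]
    dropped <- surviving[drop_idx]
    G <- G - tcrossprod(X[, dropped, drop = FALSE])
    eliminated <- c(dropped, eliminated)        # first-eliminated = worst
    surviving <- surviving[-drop_idx]
    subsets[[length(subsets) + 1]] <- surviving
  }
  ranking <- c(surviving, eliminated)           # best first
  path <- purrr::map_dfr(seq_along(subsets), function(s) {
    cols <- subsets[[s]]
    Ks <- tcrossprod(X[, cols, drop = FALSE]) + 1
    tibble::tibble(depth = s, n_features = length(cols),
                   inner_auroc = inner_cv_auroc(Ks, yy, C, folds))
  })
  best_depth <- path$depth[which.max(path$inner_auroc)]
  selected <- subsets[[best_depth]]
  mask <- seq_len(p) %in% selected
  structure(list(ranking = feats[ranking], selected = feats[selected],
                 mask = mask, path = path, C = C),
            class = "svm_rfe_fit")
}

# shared fitness for the GA/PSO wrappers: inner-CV AUROC of a linear SVM on
# the masked features (folds fixed once per search); memoised on the mask
make_mask_fitness <- function(X, y, folds, C = 1, eps = 1e-4) {
  yy <- as_pm1(y)
  cache <- new.env(parent = emptyenv())
  function(mask) {
    key <- paste(which(mask), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    K <- tcrossprod(X[, mask, drop = FALSE]) + 1
    v <- inner_cv_auroc(K, yy, C, folds, eps)
    cache[[key]] <- v
    v
  }
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1)] <- TRUE
  mask
}

#' Bio-inspired wrapper feature selection (GA / PSO)
#'
#' Searches binary feature masks maximizing the stratified inner-fold
#' AUROC of a linear SVM. The GA uses tournament selection, uniform
#' crossover, bit-flip mutation and one elite; the PSO uses SPSO-style
#' velocities thresholded through a sigmoid into binary positions.
#' Zero-feature candidates are repaired by setting one random bit.
#'
#' @param X,y Training data (standardized).
#' @param engine `"GA"` or `"PSO"`.
#' @param population Individuals / particles.
#' @param iterations Generations / iterations.
#' @param crossover,mutation GA operator rates (`mutation = NULL` means
#'   `1/p`).
#' @param inertia,c1,c2 PSO velocity coefficients.
#' @param inner_k,C Fitness SVM settings.
#' @param seed Integer seed (full run is reproducible).
#' @return List of class `wrapper_fit`: `mask`, `selected`, `fitness`,
#'   `trace` tibble (iteration, best fitness so far).
#' @export
wrapper_search <- function(X, y, engine = c("GA", "PSO"),
                           population = if (engine == "GA") 50 else 40,
                           iterations = 100, crossover = 0.8,
                           mutation = NULL, inertia = 0.721,
                           c1 = 1.193, c2 = 1.193,
                           inner_k = 3, C = 1, seed = 1L) {
  engine <- match.arg(engine)
  X <- as.matrix(X)
  p <- ncol(X)
  feats <- colnames(X); if (is.null(feats)) feats <- paste0("f", seq_len(p))
  if (is.null(mutation)) mutation <- 1 / p
  folds <- make_folds(y, k = inner_k, seed = seed)
  set.seed(as.integer(seed))
  fitness <- make_mask_fitness(X, y, folds, C)
  pop <- matrix(stats::runif(population * p) < 0.5, population, p)
  pop <- t(apply(pop, 1, repair_mask))
  fit <- apply(pop, 1, fitness)
  gbest_i <- which.max(fit)
  gbest <- pop[gbest_i, ]; gbest_fit <- fit[gbest_i]
  trace <- numeric(iterations)
  if (engine == "PSO") {
    V <- matrix(stats::rnorm(population * p, 0, 1), population, p)
    pbest <- pop; pbest_fit <- fit
  }
  for (it in seq_len(iterations)) {
    if (engine == "GA") {
      elite <- pop[which.max(fit), ]
      newpop <- matrix(FALSE, population, p)
      newpop[1, ] <- elite
      for (i in 2:population) {
        pick <- function() {
          cand <- sample.int(population, 2)
          pop[cand[which.max(fit[cand])], ]
        }
        a <- pick(); b <- pick()
        child <- if (stats::runif(1) < crossover)
          ifelse(stats::runif(p) < 0.5, a, b) else a
        flip <- stats::runif(p) < mutation
        child[flip] <- !child[flip]
        newpop[i, ] <- repair_mask(child)
      }
      pop <- newpop
      fit <- apply(pop, 1, fitness)
    } else {
      for (i in seq_len(population)) {
        V[i, ] <- inertia * V[i, ] +
          c1 * stats::runif(p) * (pbest[i, ] - pop[i, ]) +
          c2 * stats::runif(p) * (gbest - pop[i, ])
        pop[i, ] <- repair_mask(stats::runif(p) < 1 / (1 + exp(-V[i, ])))
      }
      fit <- apply(pop, 1, fitness)
      better <- fit > pbest_fit
      pbest[better, ] <- pop[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
    }
    if (max(fit) > gbest_fit) {
      gbest_i <- which.max(fit)
      gbest <- pop[gbest_i, ]; gbest_fit <- fit[gbest_i]
    }
    trace[it] <- gbest_fit
  }
  structure(list(mask = gbest, selected = feats[gbest], fitness = gbest_fit,
                 trace = tibble::tibble(iteration = seq_len(iterations),
                                        best_fitness = trace),
                 engine = engine),
            class = "wrapper_fit")
}

#' Group-wise multiple kernel learning
#'
#' The FSMKL trainer applied to a bank holding one kernel per texture
#' group and kernel family (each kernel spanning all features of its
#' group), reporting the dominant group.
#'
#' @param table Standardized feature table with a `label` column.
#' @param groups Named list group -> feature names.
#' @param families,gamma_scales Kernel families and gaussian widths.
#' @param ... Passed to [fsmkl_train()].
#' @return An `fsmkl_fit` with attribute `dominant_group`.
#' @export
group_mkl <- function(table, groups,
                      families = c("polynomial-1", "polynomial-2", "gaussian"),
                      gamma_scales = c(0.01, 0.1, 1), ...) {
  bank <- build_kernel_bank(table, groups, subset_sizes = Inf,
                            families = families, gamma_scales = gamma_scales)
  fit <- fsmkl_train(bank, ...)
  gw <- tapply(fit$d, bank$specs$group, sum)
  attr(fit, "dominant_group") <- names(gw)[which.max(gw)]
  attr(fit, "bank") <- bank
  fit
}

# ---- harness model constructors --------------------------------------------

as_table <- function(X, y) {
  tb <- tibble::as_tibble(as.data.frame(X, check.names = FALSE))
  tb$label <- y
  tb
}

#' Model constructors for the evaluation harness
#'
#' Each returns a closure `fn(Xtr, ytr, Xte, groups)` yielding `scores` on
#' the test rows and the selected-feature count, as required by
#' [evaluate_models()].
#'
#' @param ... Passed to the underlying trainer.
#' @param engine Wrapper engine, `"GA"` or `"PSO"`.
#' @param subset_sizes FSMKL ranked-prefix sizes per group.
#' @param C FSMKL soft-margin constant.
#' @return A model function.
#' @name model_constructors
NULL

#' @rdname model_constructors
#' @export
model_nb <- function(...) function(Xtr, ytr, Xte, groups) {
  fit <- train_naive_bayes(Xtr, ytr, ...)
  list(scores = nb_score(fit, Xte), n_features = ncol(Xtr), fit = fit)
}

#' @rdname model_constructors
#' @export
model_svm <- function(...) function(Xtr, ytr, Xte, groups) {
  fit <- train_svm(Xtr, ytr, ...)
  list(scores = svm_score(fit, Xte), n_features = ncol(Xtr), fit = fit)
}

#' @rdname model_constructors
#' @export
model_svm_rfe <- function(...) function(Xtr, ytr, Xte, groups) {
  fit <- svm_rfe(Xtr, ytr, ...)
  sel <- fit$selected
  K <- tcrossprod(Xtr[, sel, drop = FALSE]) + 1
  svm <- ksvm_fit(K, ytr, fit$C)
  Kc <- tcrossprod(Xtr[, sel, drop = FALSE], Xte[, sel, drop = FALSE]) + 1
  list(scores = ksvm_decision(svm, Kc), n_features = length(sel), fit = fit)
}

#' @rdname model_constructors
#' @export
model_wrapper <- function(engine, ...) function(Xtr, ytr, Xte, groups) {
  fit <- wrapper_search(Xtr, ytr, engine = engine, ...)
  sel <- which(fit$mask)
  K <- tcrossprod(Xtr[, sel, drop = FALSE]) + 1
  svm <- ksvm_fit(K, ytr, 1)
  Kc <- tcrossprod(Xtr[, sel, drop = FALSE], Xte[, sel, drop = FALSE]) + 1
  list(scores = ksvm_decision(svm, Kc), n_features = length(sel), fit = fit)
}

#' @rdname model_constructors
#' @export
model_group_mkl <- function(...) function(Xtr, ytr, Xte, groups) {
  fit <- group_mkl(as_table(Xtr, ytr), groups, ...)
  bank <- attr(fit, "bank")
  pred <- fsmkl_predict(fit, bank, newX = Xte)
  list(scores = pred$score,
       n_features = length(report_importance(fit)$selected), fit = fit)
}

#' @rdname model_constructors
#' @export
model_fsmkl <- function(subset_sizes = c(1, 2, 3, 5, 8, 13, Inf), C = 10,
                        ...) function(Xtr, ytr, Xte, groups) {
  bank <- build_kernel_bank(as_table(Xtr, ytr), groups,
                            subset_sizes = subset_sizes)
  fit <- fsmkl_train(bank, C = C, ...)
  pred <- fsmkl_predict(fit, bank, newX = Xte)
  list(scores = pred$score,
       n_features = length(report_importance(fit)$selected), fit = fit)
}
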