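# Nonparametric model-selection statistics: normality and homoscedasticity
# gatekeeping, Friedman omnibus with the Iman-Davenport F extension, the
# Finner step-down post hoc adjustment, and a Wilcoxon signed-rank
# tie-break on selected-feature counts.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around the Royston AS R94 algorithm (`stats::shapiro.test`)
#' with an explicit guard against constant input.
#'
#' @param x Numeric sample, 3 <= n <= 5000.
#' @return List: `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  stopifnot(length(x) >= 3, length(x) <= 5000)
  if (stats::var(x) == 0) stop("Shapiro-Wilk is undefined for constant input")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Bartlett homoscedasticity test
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values and positive variance).
#' @return List: `K2`, `df`, `p`.
#' @export
bartlett <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  if (any(vapply(groups, stats::var, numeric(1)) == 0))
    stop("Bartlett's test requires positive variance in every group")
  ht <- stats::bartlett.test(groups)
  list(K2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Friedman test with the Iman-Davenport extension
#'
#' Ranks the `k` treatments within each of the `n` blocks (rank 1 = best,
#' i.e. largest value; ties get average ranks) and computes
#' `chisq = 12n/(k(k+1)) (sum R_j^2 - k(k+1)^2/4)` over the average ranks
#' `R_j`, then the Iman-Davenport statistic
#' `F = (n-1) chisq / (n(k-1) - chisq)` referred to an F distribution with
#' `(k-1, (k-1)(n-1))` degrees of freedom. Optionally an exact permutation
#' p-value for the chi-square statistic by enumerating all within-block
#' rank permutations (small matrices only).
#'
#' @param M Numeric matrix, blocks (folds) x treatments (models);
#'   higher values are better.
#' @param p_method `"iman-davenport"` (default) or `"permutation"`.
#' @return List of class `friedman_id`: average ranks, `chisq`, `f_stat`,
#'   `df1`, `df2`, `p`, and `degenerate` flag (infinite F).
#' @export
friedman_imandavenport <- function(M, p_method = c("iman-davenport",
                                                   "permutation")) {
  p_method <- match.arg(p_method)
  M <- as.matrix(M)
  if (any(is.na(M))) stop("the results matrix must be complete")
  n <- nrow(M); k <- ncol(M)
  stopifnot(n >= 2, k >= 2)
  ranks <- t(apply(M, 1, function(row) rank(-row)))
  R <- colMeans(ranks)
  chisq_of <- function(Rbar) 12 * n / (k * (k + 1)) *
    (sum(Rbar^2) - k * (k + 1)^2 / 4)
  chisq <- chisq_of(R)
  degenerate <- abs(chisq - n * (k - 1)) < 1e-12
  f_stat <- if (degenerate) Inf else (n - 1) * chisq / (n * (k - 1) - chisq)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  p <- if (p_method == "iman-davenport") {
    if (degenerate) 0 else stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  } else {
    perms <- all_permutations(k)
    if (nrow(perms)^n > 2e6) stop("permutation p-value is limited to tiny matrices")
    idx <- rep(1L, n)
    count <- 0L; total <- 0L
    repeat {
      Rp <- colMeans(perms[idx, , drop = FALSE])
      if (chisq_of(Rp) >= chisq - 1e-12) count <- count + 1L
      total <- total + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(perms)) break
        idx[j] <- 1L; j <- j + 1L
      }
      if (j > n) break
    }
    count / total
  }
  structure(list(ranks = tibble::tibble(treatment = colnames(M) %||%
                                          paste0("T", seq_len(k)),
                                        mean_rank = unname(R)),
                 chisq = chisq, f_stat = f_stat, df1 = df1, df2 = df2,
                 p = p, n = n, k = k, degenerate = degenerate,
                 p_method = p_method),
            class = "friedman_id")
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind_pos <- function(row) append(row, k, after = pos - 1)
    t(apply(sub, 1, cbind_pos))
  }))
}

#' Finner step-down post hoc comparison against a control
#'
#' For each treatment `i` versus the control:
#' `z_i = (R_i - R_control) / sqrt(k(k+1)/(6n))`, two-sided normal raw
#' p-values, comparisons ordered by ascending raw p (tied raw p share the
#' smaller index), adjusted
#' `p~_(j) = max_{i<=j} (1 - (1 - p_(i))^{(k-1)/i})` capped at 1, and
#' critical scores `c_i = 1 - (1 - alpha)^{i/(k-1)}`. The step-down pass
#' rejects while the raw p-value does not exceed its critical score.
#'
#' @param ranks Named numeric vector of average ranks (one per treatment).
#' @param n Number of blocks the ranks were averaged over.
#' @param control Control treatment name; default the best (lowest) rank.
#' @param alpha Significance level.
#' @return List of class `finner_result`: `comparisons` tibble (treatment,
#'   mean_rank, z, p_raw, p_adjusted, finner_score, reject; ascending raw
#'   p), `control`, `alpha`.
#' @export
finner_posthoc <- function(ranks, n, control = NULL, alpha = 0.05) {
  k <- length(ranks)
  stopifnot(k >= 2, !is.null(names(ranks)))
  if (is.null(control)) control <- names(ranks)[which.min(ranks)]
  if (!control %in% names(ranks)) stop("unknown control treatment")
  others <- setdiff(names(ranks), control)
  m <- k - 1
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (ranks[others] - ranks[[control]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  ord <- order(p_raw)
  sorted <- p_raw[ord]
  shared_idx <- match(sorted, sorted)        # tied raw p -> smaller index
  adj_sorted <- cummax(pmin(1, 1 - (1 - sorted)^(m / shared_idx)))
  scores <- 1 - (1 - alpha)^(seq_len(m) / m)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (sorted[i] <= scores[i]) reject_sorted[i] <- TRUE else break
  }
  comparisons <- tibble::tibble(
    treatment = others[ord], mean_rank = unname(ranks[others][ord]),
    z = unname(z[ord]), p_raw = unname(sorted),
    p_adjusted = unname(adj_sorted), finner_score = scores,
    reject = reject_sorted)
  structure(list(comparisons = comparisons, control = control,
                 alpha = alpha, n = n, k = k),
            class = "finner_result")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped. The statistic is the positive-rank sum
#' `V`. For n <= 25 the two-sided p-value is exact, from the tie-aware
#' distribution of `V` over all sign assignments (dynamic programme on
#' doubled ranks); above that a normal approximation with tie-corrected
#' variance is used.
#'
#' @param a,b Paired numeric vectors of equal length >= 3.
#' @return List: `statistic` (V), `p`, `n_effective`, `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = 1, n_effective = 0L,
                all_zero = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))           # doubled ranks are integers
    counts <- 1                              # distribution of 2V over 0..sum(r2)
    for (ri in r2) {
      new <- c(counts, rep(0, ri))
      new[(ri + 1):(ri + length(counts))] <-
        new[(ri + 1):(ri + length(counts))] + counts
      counts <- new
    }
    total <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(counts[seq_len(v2 + 1)]) / total
    p_ge <- sum(counts[(v2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = V, p = p, n_effective = n, all_zero = FALSE)
}

#' Model-selection decision workflow
#'
#' The full comparison pipeline over a blocked fold-results set: normality
#' (Shapiro-Wilk) and homoscedasticity (Bartlett) checks as narrative
#' gatekeeping, Friedman + Iman-Davenport omnibus, Finner post hoc with
#' the top-ranked model as control, and — when two or more models are not
#' separated — a pairwise Wilcoxon signed-rank tie-break on per-fold
#' selected-feature counts, the leaner model winning.
#'
#' @param results A `fold_results` tibble from [evaluate_models()] (needs
#'   model, fold, the metric column, n_features).
#' @param metric Metric column used for ranking (default `"auroc"`).
#' @param alpha Significance level.
#' @return List of class `model_comparison`.
#' @export
decision_workflow <- function(results, metric = "auroc", alpha = 0.05) {
  needed <- c("model", "fold", metric, "n_features")
  stopifnot(all(needed %in% names(results)))
  M <- tidyr::pivot_wider(results[c("model", "fold", metric)],
                          names_from = "model",
                          values_from = dplyr::all_of(metric))
  M <- as.matrix(M[order(M$fold), -1])
  if (any(is.na(M))) stop("incomplete results matrix: every model needs every fold")
  sw <- tryCatch(shapiro_wilk(as.vector(M)), error = function(e) NULL)
  bt <- tryCatch(bartlett(asplit(M, 2)), error = function(e) NULL)
  fr <- friedman_imandavenport(M)
  ranks <- stats::setNames(fr$ranks$mean_rank, fr$ranks$treatment)
  fp <- finner_posthoc(ranks, n = fr$n, alpha = alpha)
  finalists <- c(fp$control,
                 fp$comparisons$treatment[!fp$comparisons$reject])
  winner <- fp$control
  wilcoxon <- NULL
  if (length(finalists) >= 2) {
    nf <- function(m) {
      sub <- results[results$model == m, ]
      sub$n_features[order(sub$fold)]
    }
    rows <- purrr::map_dfr(setdiff(finalists, fp$control), function(m) {
      wt <- wilcoxon_signed_rank(nf(fp$control), nf(m))
      tibble::tibble(model_a = fp$control, model_b = m,
                     statistic = wt$statistic, p = wt$p,
                     median_a = stats::median(nf(fp$control)),
                     median_b = stats::median(nf(m)))
    })
    wilcoxon <- rows
    leaner <- rows[rows$p < alpha & rows$median_b < rows$median_a, ]
    if (nrow(leaner) > 0)
      winner <- leaner$model_b[which.min(leaner$median_b)]
  }
  structure(list(metric = metric, matrix = M, shapiro = sw, bartlett = bt,
                 friedman = fr, finner = fp, wilcoxon = wilcoxon,
                 finalists = finalists, winner = winner, alpha = alpha),
            class = "model_comparison")
}

#' @export
tidy.model_comparison <- function(x, ...) x$finner$comparisons

#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    winner = x$winner, n_finalists = length(x$finalists),
    friedman_chisq = x$friedman$chisq, iman_davenport_f = x$friedman$f_stat,
    df1 = x$friedman$df1, df2 = x$friedman$df2, p_omnibus = x$friedman$p,
    shapiro_w = if (is.null(x$shapiro)) NA_real_ else x$shapiro$W,
    shapiro_p = if (is.null(x$shapiro)) NA_real_ else x$shapiro$p,
    bartlett_k2 = if (is.null(x$bartlett)) NA_real_ else x$bartlett$K2,
    bartlett_p = if (is.null(x$bartlett)) NA_real_ else x$bartlett$p)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison on", x$metric, "over", x$friedman$n, "folds\n")
  cat("Average ranks (1 = best):\n")
  r <- x$friedman$ranks[order(x$friedman$ranks$mean_rank), ]
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-16s %.2f\n", r$treatment[i], r$mean_rank[i]))
  cat(sprintf("Iman-Davenport F(%d, %d) = %.2f, p = %.3g\n",
              x$friedman$df1, x$friedman$df2, x$friedman$f_stat,
              x$friedman$p))
  cat("Finner post hoc, control =", x$finner$control, "\n")
  print(as.data.frame(x$finner$comparisons), digits = 3)
  if (!is.null(x$wilcoxon)) {
    cat("Feature-count tie-break (Wilcoxon signed-rank):\n")
    print(as.data.frame(x$wilcoxon), digits = 3)
  }
  cat("Winner:", x$winner, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
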