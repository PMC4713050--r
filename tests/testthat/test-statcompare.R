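test_that("Shapiro-Wilk wrapper: reference behaviour and guards", {
  set.seed(14)
  x <- rnorm(80)
  sw <- shapiro_wilk(x)
  expect_gt(sw$p, 0.05)
  expect_lte(sw$W, 1)
  bim <- c(rep(0, 40), rep(1, 40)) + rnorm(80, 0, 1e-3)
  expect_lt(shapiro_wilk(bim)$p, 1e-3)
  expect_error(shapiro_wilk(rep(2, 10)), "constant")
})

test_that("Bartlett test: degrees of freedom and textbook oracle", {
  groups <- lapply(1:8, function(i) rnorm(10, sd = i))
  b <- bartlett(groups)
  expect_equal(b$df, 7)
  g2 <- list(c(1, 2, 3, 4), c(2, 4, 6, 9))
  b2 <- bartlett(g2)
  # explicit textbook formula
  ni <- lengths(g2); k <- 2; N <- sum(ni)
  s2 <- vapply(g2, var, numeric(1))
  sp2 <- sum((ni - 1) * s2) / (N - k)
  K2 <- ((N - k) * log(sp2) - sum((ni - 1) * log(s2))) /
    (1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1)))
  expect_equal(b2$K2, K2, tolerance = 1e-12)
  expect_equal(b2$p, pchisq(K2, 1, lower.tail = FALSE), tolerance = 1e-12)
  ident <- bartlett(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$K2, 0, tolerance = 1e-12)
  expect_equal(ident$p, 1)
  expect_error(bartlett(list(c(1, 1), c(1, 2))), "variance")
})

test_that("Friedman + Iman-Davenport: ranks, dfs, degenerate and oracle", {
  set.seed(2)
  M <- matrix(rnorm(80), 10, 8)
  fr <- friedman_imandavenport(M)
  expect_equal(c(fr$df1, fr$df2), c(7, 63))
  expect_equal(sum(fr$ranks$mean_rank), 8 * 9 / 2, tolerance = 1e-12)
  # agrees with the base-R Friedman chi-square
  ref <- friedman.test(M)
  expect_equal(fr$chisq, unname(ref$statistic), tolerance = 1e-10)
  ident <- friedman_imandavenport(matrix(rep(1:5, 3), 5, 3))
  expect_equal(ident$chisq, 0)
  expect_equal(ident$f_stat, 0)
  # fully consistent ordering -> chisq = n(k-1), infinite F with flag
  M3 <- matrix(rep(c(3, 2, 1), each = 4), 4, 3)
  dg <- friedman_imandavenport(M3)
  expect_true(dg$degenerate)
  expect_equal(dg$f_stat, Inf)
  # permutation p on a 3x3 matrix equals exhaustive enumeration
  M33 <- matrix(c(1, 2, 3, 2, 3, 1, 3, 1, 2), 3, 3)
  pp <- friedman_imandavenport(M33, p_method = "permutation")
  # oracle: enumerate all (3!)^3 within-block orderings from scratch
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stat <- function(R) 12 * 3 / (3 * 4) * (sum(colMeans(R)^2) - 3 * 16 / 4)
  obs <- stat(t(apply(M33, 1, function(r) rank(-r))))
  cnt <- 0; tot <- 0
  for (a in perms) for (b in perms) for (cc in perms) {
    tot <- tot + 1
    if (stat(rbind(a, b, cc)) >= obs - 1e-12) cnt <- cnt + 1
  }
  expect_equal(pp$p, cnt / tot, tolerance = 1e-12)
})

test_that("Finner critical scores and adjustment follow the closed forms", {
  ranks <- setNames(c(1.3, 1.7, 3, 4.1, 5.9, 5.9, 6.7, 7.4), paste0("m", 1:8))
  fp <- finner_posthoc(ranks, n = 10, alpha = 0.05)
  expect_equal(fp$control, "m1")
  k <- 8
  expect_equal(fp$comparisons$finner_score,
               1 - (1 - 0.05)^(seq_len(k - 1) / (k - 1)), tolerance = 1e-12)
  expect_equal(fp$comparisons$finner_score[k - 1], 0.05)
  expect_true(all(diff(fp$comparisons$finner_score) > 0))
  # z statistic closed form
  se <- sqrt(k * (k + 1) / (6 * 10))
  expect_equal(fp$comparisons$z,
               sort(ranks[-1] - 1.3, decreasing = TRUE) / se,
               ignore_attr = TRUE, tolerance = 1e-12)
  # adjusted p monotone and >= raw
  expect_true(all(diff(fp$comparisons$p_adjusted) >= 0))
  expect_true(all(fp$comparisons$p_adjusted >= fp$comparisons$p_raw - 1e-15))
})

test_that("tied raw p-values share the smaller Finner exponent index", {
  ranks <- setNames(c(1, 3, 3, 5), c("ctl", "a", "b", "c"))
  fp <- finner_posthoc(ranks, n = 10, control = "ctl")
  cmp <- fp$comparisons                 # row 1 is "c"; rows 2-3 are the tie
  expect_equal(cmp$p_raw[2], cmp$p_raw[3])
  expect_equal(cmp$p_adjusted[2], cmp$p_adjusted[3])
  m <- 3
  shared <- max(1 - (1 - cmp$p_raw[1])^(m / 1),
                1 - (1 - cmp$p_raw[2])^(m / 2))
  expect_equal(cmp$p_adjusted[2], shared, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank: exact enumeration oracle and edge cases", {
  a <- c(5, 5, 5); b <- c(5, 5, 5)
  w0 <- wilcoxon_signed_rank(a, b)
  expect_true(w0$all_zero)
  expect_equal(w0$p, 1)
  a <- c(3.1, 1.2, 5.3, 0.4, 2.2, 7.9)
  b <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  wt <- wilcoxon_signed_rank(a, b)
  d <- a - b; r <- rank(abs(d)); V <- sum(r[d > 0])
  # oracle: all 2^6 sign assignments
  vals <- apply(expand.grid(rep(list(c(0, 1)), 6)), 1,
                function(s) sum(r * s))
  p_or <- min(1, 2 * min(mean(vals <= V), mean(vals >= V)))
  expect_equal(wt$statistic, V)
  expect_equal(wt$p, p_or, tolerance = 1e-12)
  # matches base R where no ties and no zeros
  ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(wt$statistic, unname(ref$statistic))
  expect_equal(wt$p, ref$p.value, tolerance = 1e-12)
  # extreme shift reaches the exact minimum two-sided p for n = 6
  wmax <- wilcoxon_signed_rank(a + 100, b)
  expect_equal(wmax$p, 2 / 2^6, tolerance = 1e-12)
  # ties in |d| are handled exactly
  wtie <- wilcoxon_signed_rank(c(2, 4, 1, 9, 7), c(1, 3, 2, 4, 6))
  expect_true(wtie$p >= 0 && wtie$p <= 1)
})

test_that("decision workflow: trivial winner and feature-count tie-break", {
  folds <- 1:10
  mk <- function(model, auc, nf) tibble::tibble(model = model, fold = folds,
                                                auroc = auc, n_features = nf)
  # one model strictly best in every fold
  res <- dplyr::bind_rows(mk("best", 0.95 + 0.001 * folds, 10),
                          mk("mid", 0.80 + 0.001 * folds, 20),
                          mk("bad", 0.60 + 0.001 * folds, 30))
  wf <- decision_workflow(res)
  expect_equal(wf$winner, "best")
  expect_true(all(wf$finner$comparisons$reject))
  # two tied top models, one leaner in every fold
  set.seed(6)
  top <- 0.9 + 0.005 * rnorm(10)
  res2 <- dplyr::bind_rows(
    tibble::tibble(model = "fat", fold = folds, auroc = top, n_features = 40),
    tibble::tibble(model = "lean", fold = folds, auroc = top,
                   n_features = 12),
    mk("bad", 0.55 + 0.002 * folds, 30))
  wf2 <- decision_workflow(res2)
  expect_true(all(c("fat", "lean") %in% wf2$finalists))
  expect_equal(wf2$winner, "lean")
  expect_error(decision_workflow(res[-1, ]), "incomplete")
})

test_that("workflow reproduces a hand-traced synthetic 8-model comparison", {
  set.seed(42)
  k <- 8; n <- 10
  base <- seq(0.95, 0.60, length.out = k)
  M <- sapply(base, function(b) b + rnorm(n, 0, 0.01))
  colnames(M) <- paste0("mod", 1:k)
  res <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(M), fold = 1:n), -fold,
    names_to = "model", values_to = "auroc")
  res$n_features <- 5
  wf <- decision_workflow(res)
  # hand trace: ranks per fold, chi-square, Iman-Davenport F
  R <- colMeans(t(apply(M, 1, function(r) rank(-r))))
  chi <- 12 * n / (k * (k + 1)) * (sum(R^2) - k * (k + 1)^2 / 4)
  Fid <- (n - 1) * chi / (n * (k - 1) - chi)
  expect_equal(wf$friedman$chisq, chi, tolerance = 1e-12)
  expect_equal(wf$friedman$f_stat, Fid, tolerance = 1e-12)
  expect_equal(wf$friedman$p, pf(Fid, 7, 63, lower.tail = FALSE),
               tolerance = 1e-12)
  # Finner adjustment recomputed by hand from the raw p-values
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (R[-1] - R[1]) / se
  praw <- sort(2 * pnorm(-abs(z)))
  idx <- match(praw, praw)
  adj <- cummax(pmin(1, 1 - (1 - praw)^((k - 1) / idx)))
  expect_equal(wf$finner$comparisons$p_adjusted, unname(adj),
               tolerance = 1e-12)
  expect_equal(wf$winner, "mod1")
  gl <- glance(wf)
  expect_equal(gl$df1, 7); expect_equal(gl$df2, 63)
})
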