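toy_groups <- function(p_signal = 1, p_noise = 9) {
  list(Signal = paste0("f", seq_len(p_signal)),
       Noise = paste0("f", p_signal + seq_len(p_noise)))
}

test_that("class-alignment ranking matches a brute-force correlation oracle", {
  tb <- tibble::tibble(label = c(0L, 0L, 0L, 1L, 1L, 1L),
                       a = c(0, 0, 0, 1, 1, 1),       # identical to the label
                       b = c(5, 5, 5, 5, 5, 5),       # constant
                       c = c(1, 3, 2, 4, 6, 5),
                       d = c(6, 4, 5, 3, 1, 2))
  r <- rank_features(tb, c("a", "b", "c", "d"))
  expect_equal(r$feature[1], "a")
  expect_equal(r$score[1], 1)
  expect_equal(r$feature[4], "b")                     # constant ranks last
  expect_equal(r$score[4], 0)
  oracle <- vapply(c("a", "b", "c", "d"), function(f) {
    v <- suppressWarnings(abs(cor(tb[[f]], tb$label))); if (is.na(v)) 0 else v
  }, numeric(1))
  expect_equal(r$feature, names(sort(-oracle)))
  expect_error(rank_features(tb[tb$label == 1, ], c("a", "c")), "classes")
})

test_that("kernel bank: product count, capping and PSD Gram matrices", {
  tb <- toy_table(n = 30, p_signal = 2, p_noise = 16, seed = 11)
  groups <- list(A = paste0("f", 1:6), B = paste0("f", 7:12),
                 C = paste0("f", 13:18))
  # 3 groups x 3 sizes x (2 poly + 3 gaussian widths) = 45; here use 6
  # groups is 3 -> spec arithmetic scales: sizes {1,2,3} and 5 combos
  bank <- build_kernel_bank(tb, groups, subset_sizes = c(1, 2, 3))
  expect_equal(nrow(bank$specs), 3 * 3 * 5)
  small <- build_kernel_bank(tb, list(G = paste0("f", 1:2)),
                             subset_sizes = c(2, 5, 10),
                             families = "polynomial-1")
  expect_equal(nrow(small$specs), 1)                  # capped and deduplicated
  expect_equal(small$specs$k, 2)
  bg <- geltexture:::bank_grams(bank, seq_len(30))
  for (K in bg$grams) {
    expect_equal(K, t(K), tolerance = 1e-10)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  expect_error(build_kernel_bank(tb[0, ], groups), "empty")
})

test_that("a one-kernel bank reduces FSMKL to a plain SVM", {
  for (s in 1:20) {
    tb <- toy_table(n = 24, p_signal = 1, p_noise = 3, sep = 1.5, seed = 200 + s)
    bank <- build_kernel_bank(tb, list(G = paste0("f", 1:4)),
                              subset_sizes = Inf, families = "gaussian",
                              gamma_scales = 0.4)
    fit <- fsmkl_train(bank, C = 1)
    expect_equal(fit$d, 1)
    K <- geltexture:::bank_grams(bank, seq_len(24))$grams[[1]]
    svm <- ksvm_fit(K, tb$label, C = 1, eps = 1e-4)
    dec_mkl <- fsmkl_predict(fit, bank, rows = 1:24)$score
    dec_svm <- ksvm_decision(svm, K)
    expect_equal(dec_mkl, dec_svm, tolerance = 1e-6)
  }
})

test_that("weights stay on the simplex and the objective is monotone", {
  tb <- toy_table(n = 40, p_signal = 1, p_noise = 9, sep = 2, seed = 7)
  bank <- build_kernel_bank(tb, toy_groups(), subset_sizes = c(1, 3, Inf))
  fit <- fsmkl_train(bank, C = 10)
  expect_equal(sum(fit$d), 1, tolerance = 1e-8)
  expect_true(all(fit$d >= 0))
  expect_true(all(diff(fit$objective_log) <= 1e-8))
})

test_that("planted signal concentrates the kernel weights", {
  tb <- toy_table(n = 200, p_signal = 1, p_noise = 24, sep = 4, seed = 31)
  groups <- list(Signal = "f1", NoiseA = paste0("f", 2:9),
                 NoiseB = paste0("f", 10:17), NoiseC = paste0("f", 18:25))
  bank <- build_kernel_bank(tb, groups, subset_sizes = c(1, 2, 3, 5, 8))
  expect_gte(nrow(bank$specs), 50)
  fit <- fsmkl_train(bank, C = 1)
  has_signal <- vapply(bank$specs$features, function(f) "f1" %in% f, logical(1))
  expect_gte(sum(fit$d[has_signal]), 0.9)
  # sparsity: most of the weight sits on few kernels
  w <- sort(fit$d, decreasing = TRUE)
  expect_gte(sum(w[seq_len(min(10, length(w)))]), 0.8)
})

test_that("prediction matches a dense double-loop re-evaluation", {
  tb <- toy_table(n = 40, p_signal = 1, p_noise = 5, sep = 2, seed = 13)
  groups <- toy_groups(1, 5)
  bank <- build_kernel_bank(tb, groups, subset_sizes = c(1, 2))
  fit <- fsmkl_train(bank, rows = 1:30, C = 1)
  pred <- fsmkl_predict(fit, bank, rows = 31:40)
  # dense oracle: explicit loops over support vectors and kernels
  X <- bank$X
  f_oracle <- vapply(31:40, function(t) {
    acc <- 0
    for (m in which(fit$d > 0)) {
      sp <- bank$specs[m, ]
      for (ii in seq_along(fit$rows)) {
        xi <- X[fit$rows[ii], sp$features[[1]]]
        xt <- X[t, sp$features[[1]]]
        kv <- switch(sp$family,
                     "polynomial-1" = sum(xi * xt) + 1,
                     "polynomial-2" = (sum(xi * xt) + 1)^2,
                     "gaussian" = exp(-sp$gamma * sum((xi - xt)^2)))
        acc <- acc + fit$d[m] * fit$alpha[ii] * fit$y[ii] * kv * fit$factors[m]
      }
    }
    acc + fit$b
  }, numeric(1))
  expect_equal(pred$score, f_oracle, tolerance = 1e-8)
  # training points reproduce their training decision values
  tr_pred <- fsmkl_predict(fit, bank, rows = 1:30)
  K <- Reduce(`+`, Map(`*`, geltexture:::bank_grams(bank, 1:30)$grams,
                       fit$d))
  expect_equal(tr_pred$score,
               as.numeric(crossprod(K, fit$alpha * fit$y)) + fit$b,
               tolerance = 1e-8)
  expect_error(fsmkl_predict(fit, bank), "rows|newX")
})

test_that("importance report: hand-built three-kernel arithmetic", {
  tb <- toy_table(n = 20, p_signal = 2, p_noise = 3, seed = 3)
  bank <- build_kernel_bank(tb, list(A = paste0("f", 1:2),
                                     B = paste0("f", 3:5)),
                            subset_sizes = c(1, 2),
                            families = "polynomial-1")
  fit <- fsmkl_train(bank, C = 1)
  expect_equal(nrow(bank$specs), 4)
  # overwrite with hand weights over known subsets
  fit$d <- c(0.5, 0.3, 0.2, 0)
  rep_ <- report_importance(fit)
  expect_equal(rep_$kernels$weight, c(0.5, 0.3, 0.2, 0))
  expect_equal(rep_$kernels$cumulative, c(0.5, 0.8, 1, 1))
  subs <- bank$specs$features[1:3]
  imp_oracle <- tapply(
    unlist(Map(function(s, w) setNames(rep(w, length(s)), s),
               subs, c(0.5, 0.3, 0.2))),
    unlist(subs), sum)
  got <- setNames(rep_$features$importance, rep_$features$feature)
  expect_equal(unname(got[names(imp_oracle)]), as.numeric(imp_oracle),
               tolerance = 1e-12)
  expect_setequal(rep_$selected, unique(unlist(subs)))
  # selected-feature count equals the union cardinality
  expect_equal(length(rep_$selected), length(unique(unlist(subs))))
  single <- fit; single$d <- c(1, 0, 0, 0)
  expect_equal(report_importance(single)$kernels$cumulative[1], 1)
})

test_that("tidy and glance views expose the fit summary", {
  tb <- toy_table(n = 30, p_signal = 1, p_noise = 4, seed = 9)
  bank <- build_kernel_bank(tb, toy_groups(1, 4), subset_sizes = c(1, Inf))
  fit <- fsmkl_train(bank, C = 1)
  td <- tidy(fit)
  expect_true(all(c("group", "k", "family", "weight", "cumulative") %in%
                  names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_kernels_total, length(fit$d))
  expect_true(gl$n_kernels_active >= 1)
})
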