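test_that("quantization maps the stated formula and falls back sanely", {
  lv <- function(g) quantize(matrix(g), Ng = 4)$levels[1, 1]
  expect_equal(lv(255), 4)
  expect_equal(lv(0), 1)
  expect_equal(lv(64), 2)
  expect_warning(q <- quantize(matrix(rep(100, 9), 3), Ng = 8,
                               normalization = "percentile-1-99"),
                 "falling back")
  expect_true(all(q$levels >= 1 & q$levels <= 8))
  # monotone in the source grey level
  g <- 0:255
  l <- floor(g * 64 / 256) + 1
  expect_true(all(diff(l) >= 0))
})

test_that("histogram features match hand computation and stay ordered", {
  px <- matrix(c(rep(100, 8), rep(200, 8)), 4)
  h <- histogram_features(px)
  expect_equal(unname(h[c("Mean", "Variance", "Skewness")]), c(150, 2500, 0))
  const <- histogram_features(matrix(7, 3, 3))
  expect_equal(unname(const), c(7, 0, 0, 0, 7, 7, 7, 7, 7))
  r <- random_roi(12, 12, seed = 4)
  hr <- histogram_features(r)
  pcs <- hr[c("Perc.01%", "Perc.10%", "Perc.50%", "Perc.90%", "Perc.99%")]
  expect_true(all(diff(pcs) >= 0))
})

test_that("gradient features: ramps, constants and isotropy", {
  const <- gradient_features(matrix(5, 5, 5))
  expect_equal(unname(const), rep(0, 5))
  ramp_h <- matrix(rep(1:5, each = 5), 5)           # value = column index
  gh <- gradient_features(ramp_h)
  expect_equal(unname(gh[c("GrMean", "GrVariance", "GrNonZeros")]), c(2, 0, 1))
  gv <- gradient_features(t(ramp_h))
  expect_equal(unname(gh), unname(gv))              # magnitude is isotropic
  tiny <- matrix(1:4, 2)
  expect_error(gradient_features(tiny), "small|interior")
})

test_that("GLCM is normalized, symmetric-accumulated and matches examples", {
  const <- quantize(matrix(128, 4, 4), Ng = 4)
  p <- glcm(const, 1, 0)
  expect_equal(sum(p), 1)
  expect_equal(p[3, 3], 1)                          # 128 -> level 3
  chk <- matrix(rep(c(0, 255), 8), 4)[1:4, 1:4]     # two-level checkerboard
  chk <- outer(1:4, 1:4, function(r, c) ifelse((r + c) %% 2 == 0, 0, 255))
  q <- quantize(chk, Ng = 2)
  p2 <- glcm(q, 1, 0)
  expect_equal(p2[1, 2], 0.5)
  expect_equal(p2[2, 1], 0.5)
  expect_error(glcm(quantize(matrix(1, 1, 1), Ng = 2), 3, 0), "pairs")
})

test_that("Haralick features: closed-form cases and bounds", {
  const <- glcm(quantize(matrix(128, 4, 4), Ng = 4), 1, 0)
  f <- glcm_features(const)
  expect_equal(unname(f[c("InvDfMom", "Contrast", "AngScMom", "Entropy")]),
               c(1, 0, 1, 0))
  chk <- outer(1:4, 1:4, function(r, c) ifelse((r + c) %% 2 == 0, 0, 255))
  f2 <- glcm_features(glcm(quantize(chk, Ng = 2), 1, 0))
  expect_equal(unname(f2[c("InvDfMom", "Contrast", "AngScMom")]),
               c(0.5, 1, 0.5))
  for (s in 1:5) {
    p <- glcm(quantize(random_roi(10, 10, seed = s), Ng = 16), 1, 45)
    ff <- glcm_features(p)
    expect_gt(ff[["InvDfMom"]], 0); expect_lte(ff[["InvDfMom"]], 1)
    expect_lte(ff[["AngScMom"]], 1)
  }
})

test_that("run-length features reproduce hand-enumerated runs", {
  q <- quantize(matrix(128, 4, 4), Ng = 4)
  f <- rlm_features(q, "horizontal")
  expect_equal(unname(f), c(4 / 16 / 4, 16, 4, 4, 0.25))
  alt <- matrix(rep(c(0, 255), 8), 4, byrow = TRUE)
  alt <- outer(1:4, 1:4, function(r, c) ifelse(c %% 2 == 0, 255, 0))
  fa <- rlm_features(quantize(alt, Ng = 2), "horizontal")
  expect_equal(unname(fa[c(1, 2, 5)]), c(1, 1, 1))
  for (dir in c("horizontal", "vertical", "45", "135")) {
    fr <- rlm_features(quantize(random_roi(9, 9, 0.8, seed = 2), Ng = 8), dir)
    expect_gt(fr[[5]], 0); expect_lte(fr[[5]], 1)
  }
})

test_that("AR model: degenerate input and oracle equivalence", {
  const <- ar_features(matrix(9, 6, 6))
  expect_equal(as.numeric(const), rep(0, 5))
  expect_true(attr(const, "degenerate"))
  set.seed(31)
  # strongly left-correlated field: theta1 should dominate
  m <- matrix(0, 20, 20)
  m[, 1] <- rnorm(20)
  for (c in 2:20) m[, c] <- 0.95 * m[, c - 1] + rnorm(20, 0, 0.05)
  f <- ar_features(m * 30 + 128)
  expect_gt(f[["Teta1"]], 0.6)
  expect_gt(abs(f[["Teta1"]]), max(abs(f[c("Teta2", "Teta3", "Teta4")])))
})

test_that("every feature family agrees with its brute-force oracle", {
  for (s in 1:20) {
    px <- random_roi(16, 16, mask_frac = if (s %% 2) 1 else 0.85, seed = 100 + s)
    expect_equal(unname(histogram_features(px)), oracle_histogram(px),
                 tolerance = 1e-9)
    expect_equal(unname(gradient_features(px)), oracle_gradient(px),
                 tolerance = 1e-9)
    q <- quantize(px, Ng = 8)
    for (off in list(c(1, 0), c(2, 45), c(1, 90), c(3, 135))) {
      sh <- geltexture:::glcm_shift(off[1], off[2])
      p <- glcm(q, off[1], off[2])
      expect_equal(p, oracle_glcm(q$levels, 8, sh[1], sh[2]), tolerance = 1e-12)
      expect_equal(unname(glcm_features(p)), unname(oracle_haralick(p)),
                   tolerance = 1e-9)
    }
    steps <- list(horizontal = c(0, 1), vertical = c(1, 0),
                  `45` = c(-1, 1), `135` = c(1, 1))
    for (dir in names(steps))
      expect_equal(unname(rlm_features(q, dir)),
                   unname(oracle_rlm(q$levels, steps[[dir]][1],
                                     steps[[dir]][2])),
                   tolerance = 1e-9)
    expect_equal(unname(ar_features(px))[1:5], as.vector(oracle_ar(px)),
                 tolerance = 1e-9)
    w <- wavelet_features(px)
    o <- oracle_haar_energies(px)
    expect_equal(w[names(o)], o, tolerance = 1e-9)
  }
})

test_that("wavelet energies: constants, shift invariance, small crops", {
  w <- wavelet_features(matrix(50, 16, 16))
  detail <- w[grep("LH|HL|HH", names(w))]
  expect_equal(unname(detail), rep(0, length(detail)))
  px <- random_roi(16, 16, seed = 77)
  w1 <- wavelet_features(px)
  w2 <- wavelet_features(px + 40)
  detail_names <- grep("LH|HL|HH", names(w1), value = TRUE)
  expect_equal(w1[detail_names], w2[detail_names], tolerance = 1e-9)
  small <- wavelet_features(random_roi(4, 4, seed = 1))
  expect_true(all(is.na(small[c("WavEnLL_s3", "WavEnLL_s4")])))
  expect_error(wavelet_features(matrix(1)), "2x2")
})

test_that("the default inventory has 274 uniquely named, grouped features", {
  inv <- feature_inventory()
  expect_equal(nrow(inv), 274)
  expect_false(any(duplicated(inv$name)))
  expect_setequal(unique(inv$group),
                  c("Histogram", "Gradient", "GLCM", "RLM", "ARModel",
                    "Wavelet"))
  counts <- table(inv$group)
  expect_equal(unname(counts[c("Histogram", "Gradient", "GLCM", "RLM",
                               "ARModel", "Wavelet")]),
               c(9L, 5L, 220L, 20L, 5L, 15L), ignore_attr = TRUE)
})

test_that("full extraction is deterministic and respects pixel permutation", {
  px <- random_roi(18, 18, seed = 12)
  v1 <- extract_features(px)
  v2 <- extract_features(px)
  expect_identical(v1, v2)
  expect_length(v1, 274)
  expect_true(all(is.finite(v1)))
  # permuting pixel positions keeps the histogram, changes the GLCM
  set.seed(5)
  perm <- matrix(sample(px), nrow(px))
  vp <- extract_features(perm)
  hist_names <- feature_inventory()$name[feature_inventory()$group == "Histogram"]
  expect_equal(v1[hist_names], vp[hist_names])
  glcm_idm <- "S(1,0)InvDfMom"
  expect_false(isTRUE(all.equal(v1[[glcm_idm]], vp[[glcm_idm]])))
})

test_that("noise regions are more homogeneous than spots (GLCM IDM)", {
  ds <- generate_dataset(gel_config(images = 2, width = 512, height = 512,
                                    spots_per_image = 25, noise_per_image = 25),
                         seed = 21)
  idm <- vapply(seq_len(nrow(ds$rois)), function(k) {
    px <- geltexture:::roi_pixels(ds$images[[ds$rois$image_id[k]]], ds$rois[k, ])
    glcm_features(glcm(quantize(px), 4, 0))[["InvDfMom"]]
  }, numeric(1))
  lab <- ds$rois$label
  expect_gt(mean(idm[lab == "noise"]), mean(idm[lab == "spot"]))
})
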