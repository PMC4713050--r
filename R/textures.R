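# Texture feature families over masked regions of interest.
#
# Every operation takes a ROI as a numeric matrix covering its bounding box
# with NA outside the mask.  Pairwise (GLCM) and run (RLM) statistics use
# only elements fully inside the mask; the AR model and wavelet energies
# operate on the bounding-box crop with mask holes filled by the in-mask
# mean.

# ---- helpers ---------------------------------------------------------------

pop_moments <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  list(mean = m, var = m2,
       skew = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
       kurt = if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0)
}

# nearest-rank percentile on sorted values
nearest_rank <- function(sorted_x, q) sorted_x[pmax(1L, ceiling(q * length(sorted_x)))]

entropy0 <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

#' Quantize a ROI to Ng grey levels
#'
#' Maps in-mask grey level `g` to `floor((g - lo) * Ng / (hi - lo + 1)) + 1`
#' clipped to `[1, Ng]`. The reference range `(lo, hi)` is the full 8-bit
#' range, a three-sigma window around the ROI mean, or the 1st/99th
#' nearest-rank percentiles. A degenerate window falls back to full range
#' with a warning.
#'
#' @param px ROI matrix (NA outside the mask).
#' @param Ng Number of grey levels (>= 2).
#' @param normalization One of `"full-range"`, `"three-sigma"`,
#'   `"percentile-1-99"`.
#' @return A list with `levels` (integer matrix, NA outside mask) and `Ng`.
#' @export
quantize <- function(px, Ng = 64L,
                     normalization = c("full-range", "three-sigma",
                                       "percentile-1-99")) {
  normalization <- match.arg(normalization)
  x <- px[!is.na(px)]
  stopifnot(Ng >= 2, length(x) > 0)
  lims <- switch(normalization,
    "full-range" = c(0, 255),
    "three-sigma" = {
      m <- mean(x); s <- stats::sd(x)
      c(m - 3 * s, m + 3 * s)
    },
    "percentile-1-99" = {
      sx <- sort(x)
      c(nearest_rank(sx, 0.01), nearest_rank(sx, 0.99))
    })
  if (lims[2] <= lims[1]) {
    warning("degenerate normalization window; falling back to full range")
    lims <- c(0, 255)
  }
  lev <- floor((px - lims[1]) * Ng / (lims[2] - lims[1] + 1)) + 1
  lev <- pmin(pmax(lev, 1), Ng)
  list(levels = lev, Ng = as.integer(Ng))
}

# ---- histogram -------------------------------------------------------------

#' First-order (histogram) features of a ROI
#'
#' Population moments and nearest-rank percentiles of the raw in-mask grey
#' levels: Mean, Variance, Skewness, Kurtosis (excess; 0 on degenerate
#' input) and the 1/10/50/90/99 percentiles.
#'
#' @param px ROI matrix (NA outside the mask).
#' @return Named numeric vector of 9 features.
#' @export
histogram_features <- function(px) {
  x <- px[!is.na(px)]
  stopifnot(length(x) >= 1)
  m <- pop_moments(x)
  sx <- sort(x)
  c(Mean = m$mean, Variance = m$var, Skewness = m$skew, Kurtosis = m$kurt,
    "Perc.01%" = nearest_rank(sx, 0.01), "Perc.10%" = nearest_rank(sx, 0.10),
    "Perc.50%" = nearest_rank(sx, 0.50), "Perc.90%" = nearest_rank(sx, 0.90),
    "Perc.99%" = nearest_rank(sx, 0.99))
}

# ---- absolute gradient -----------------------------------------------------

#' Absolute-gradient features of a ROI
#'
#' Central-difference gradient magnitudes
#' `sqrt((I(r,c+1)-I(r,c-1))^2 + (I(r+1,c)-I(r-1,c))^2)` over interior
#' pixels (all four neighbours in-mask): moments plus the fraction of
#' interior pixels with nonzero magnitude.
#'
#' @param px ROI matrix (NA outside the mask).
#' @return Named numeric vector: GrMean, GrVariance, GrSkewness,
#'   GrKurtosis, GrNonZeros.
#' @export
gradient_features <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 3 || nc < 3) stop("ROI too small for gradient features")
  ctr <- px[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  dx <- px[2:(nr - 1), 3:nc, drop = FALSE] - px[2:(nr - 1), 1:(nc - 2), drop = FALSE]
  dy <- px[3:nr, 2:(nc - 1), drop = FALSE] - px[1:(nr - 2), 2:(nc - 1), drop = FALSE]
  mag <- sqrt(dx^2 + dy^2)
  mag[is.na(ctr)] <- NA
  g <- mag[!is.na(mag)]
  if (length(g) == 0) stop("ROI has no interior pixels for gradient features")
  m <- pop_moments(g)
  c(GrMean = m$mean, GrVariance = m$var, GrSkewness = m$skew,
    GrKurtosis = m$kurt, GrNonZeros = mean(g > 0))
}

# ---- grey-level co-occurrence ----------------------------------------------

# canonical offsets: distance d along direction theta, as a (dr, dc) shift
glcm_shift <- function(d, theta) {
  switch(as.character(theta),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135"))
}

# Mazda-style offset label S(dx,dy)
glcm_offset_name <- function(d, theta) {
  switch(as.character(theta),
         "0" = sprintf("S(%d,0)", d), "90" = sprintf("S(0,%d)", d),
         "45" = sprintf("S(%d,%d)", d, d), "135" = sprintf("S(%d,-%d)", d, d))
}

#' Grey-level co-occurrence matrix of a quantized ROI
#'
#' Counts in-mask pixel pairs at distance `d` along direction `theta`
#' (degrees), accumulated symmetrically, normalized to sum 1.
#'
#' @param q Result of [quantize()].
#' @param d Pixel distance (>= 1).
#' @param theta Direction: 0, 45, 90 or 135 degrees.
#' @return Ng x Ng matrix summing to 1.
#' @export
glcm <- function(q, d, theta) {
  stopifnot(d >= 1)
  sh <- glcm_shift(as.integer(d), theta)
  lev <- q$levels; Ng <- q$Ng
  nr <- nrow(lev); nc <- ncol(lev)
  rlo <- max(1, 1 - sh[1]); rhi <- min(nr, nr - sh[1])
  clo <- max(1, 1 - sh[2]); chi <- min(nc, nc - sh[2])
  if (rlo > rhi || clo > chi)
    stop(sprintf("no valid pixel pairs for offset d=%d theta=%d", d, theta))
  r1 <- rlo:rhi
  c1 <- clo:chi
  i <- lev[r1, c1, drop = FALSE]
  j <- lev[r1 + sh[1], c1 + sh[2], drop = FALSE]
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok))
    stop(sprintf("no valid pixel pairs for offset d=%d theta=%d", d, theta))
  counts <- tabulate((i[ok] - 1L) * Ng + j[ok], nbins = Ng * Ng)
  p <- matrix(counts, Ng, Ng, byrow = TRUE)
  p <- p + t(p)                      # symmetric accumulation
  p / sum(p)
}

#' Haralick features of a co-occurrence matrix
#'
#' Eleven second-order statistics of a normalized symmetric GLCM
#' (natural logarithms, 0 log 0 := 0). The inverse difference moment is
#' `sum p(i,j) / (1 + (i-j)^2)`.
#'
#' @param p Normalized co-occurrence matrix.
#' @param prefix Offset label prepended to each feature name (e.g.
#'   `"S(4,0)"`); `""` for bare names.
#' @return Named numeric vector of 11 features.
#' @export
glcm_features <- function(p, prefix = "") {
  Ng <- nrow(p)
  i <- row(p); j <- col(p)
  px_ <- rowSums(p)
  mu <- sum(seq_len(Ng) * px_)
  sg2 <- sum((seq_len(Ng) - mu)^2 * px_)
  # p_{x+y}, k = 2..2Ng and p_{x-y}, k = 0..Ng-1
  psum <- vapply(2:(2 * Ng), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(Ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * Ng); kd <- 0:(Ng - 1)
  sum_avg <- sum(ks * psum)
  dif_avg <- sum(kd * pdif)
  corr <- if (sg2 > 0) (sum(i * j * p) - mu^2) / sg2 else 0
  out <- c(AngScMom = sum(p^2),
           Contrast = sum((i - j)^2 * p),
           Correlat = corr,
           SumOfSqs = sum((i - mu)^2 * p),
           InvDfMom = sum(p / (1 + (i - j)^2)),
           SumAverg = sum_avg,
           SumVarnc = sum((ks - sum_avg)^2 * psum),
           SumEntrp = entropy0(psum),
           Entropy = entropy0(p),
           DifVarnc = sum((kd - dif_avg)^2 * pdif),
           DifEntrp = entropy0(pdif))
  if (nzchar(prefix)) names(out) <- paste0(prefix, names(out))
  out
}

# ---- run-length matrix -----------------------------------------------------

rlm_direction_suffix <- c(horizontal = "H", vertical = "V",
                          `45` = "45", `135` = "135")

# maximal-run sequences of a level matrix along a direction; NA breaks runs
rlm_lines <- function(lev, direction) {
  nr <- nrow(lev); nc <- ncol(lev)
  switch(direction,
    horizontal = lapply(seq_len(nr), function(r) lev[r, ]),
    vertical = lapply(seq_len(nc), function(c) lev[, c]),
    # 45 degrees: up-right, lines of constant r + c traversed with c rising
    `45` = {
      idx <- row(lev) + col(lev)
      lapply(split(lev[order(idx, -row(lev))], sort(idx)), identity)
    },
    # 135 degrees: down-right, lines of constant r - c
    `135` = {
      idx <- row(lev) - col(lev)
      lapply(split(lev[order(idx, row(lev))], sort(idx)), identity)
    },
    stop("unknown run direction"))
}

#' Run-length features of a quantized ROI
#'
#' Galloway statistics of the run-length matrix along one direction:
#' short- and long-run emphasis, grey-level and run-length non-uniformity,
#' and the fraction of runs per in-mask pixel.
#'
#' @param q Result of [quantize()].
#' @param direction `"horizontal"`, `"vertical"`, `"45"` or `"135"`.
#' @return Named numeric vector of 5 features, suffixed by direction.
#' @export
rlm_features <- function(q, direction = c("horizontal", "vertical",
                                          "45", "135")) {
  direction <- match.arg(direction)
  lev <- q$levels
  npix <- sum(!is.na(lev))
  if (npix == 0) stop("empty ROI")
  lens <- integer(0); vals <- integer(0)
  for (line in rlm_lines(lev, direction)) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    lens <- c(lens, r$lengths[keep]); vals <- c(vals, r$values[keep])
  }
  R <- length(lens)
  glev <- tapply(rep(1L, R), factor(vals), sum)          # runs per grey level
  rlen <- tapply(rep(1L, R), factor(lens), sum)          # runs per length
  out <- c(sum(1 / lens^2) / R,
           sum(as.numeric(lens)^2) / R,
           sum(as.numeric(glev)^2) / R,
           sum(as.numeric(rlen)^2) / R,
           R / npix)
  names(out) <- paste0(c("ShrtREmp", "LngREmph", "GLevNonU", "RLNonUni",
                         "Fraction"),
                       "_", rlm_direction_suffix[[direction]])
  out
}

# ---- autoregressive model --------------------------------------------------

#' Autoregressive-model features of a ROI
#'
#' Least-squares fit of the zero-mean intensity as a weighted sum of the
#' west, north, north-west and north-east neighbours:
#' `s(r,c) = th1 s(r,c-1) + th2 s(r-1,c) + th3 s(r-1,c-1) + th4 s(r-1,c+1) + e`.
#' Sigma is the root-mean-square residual. Rank-deficient designs (e.g. a
#' constant ROI) return all zeros with attribute `degenerate = TRUE`.
#'
#' @param px ROI matrix (NA outside the mask). Holes are filled with the
#'   in-mask mean before fitting.
#' @return Named numeric vector: Teta1..Teta4, Sigma.
#' @export
ar_features <- function(px) {
  mu <- mean(px, na.rm = TRUE)
  s <- px; s[is.na(s)] <- mu
  s <- s - mu
  valid <- !is.na(px)
  nr <- nrow(s); nc <- ncol(s)
  if (nr < 2 || nc < 3) stop("ROI too small for the AR model")
  rr <- 2:nr; cc <- 2:(nc - 1)
  tgt_ok <- valid[rr, cc, drop = FALSE] &
    valid[rr, cc - 1, drop = FALSE] & valid[rr - 1, cc, drop = FALSE] &
    valid[rr - 1, cc - 1, drop = FALSE] & valid[rr - 1, cc + 1, drop = FALSE]
  if (sum(tgt_ok) < 5) stop("fewer than 5 pixels with all AR neighbours in-mask")
  yv <- s[rr, cc, drop = FALSE][tgt_ok]
  X <- cbind(s[rr, cc - 1, drop = FALSE][tgt_ok],
             s[rr - 1, cc, drop = FALSE][tgt_ok],
             s[rr - 1, cc - 1, drop = FALSE][tgt_ok],
             s[rr - 1, cc + 1, drop = FALSE][tgt_ok])
  out <- c(Teta1 = 0, Teta2 = 0, Teta3 = 0, Teta4 = 0, Sigma = 0)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  th <- qr.coef(qrX, yv)
  e <- yv - X %*% th
  out[1:4] <- th
  out[5] <- sqrt(mean(e^2))
  attr(out, "degenerate") <- FALSE
  out
}

# ---- wavelet ---------------------------------------------------------------

# one orthonormal Haar analysis step; pads odd dimensions by edge replication
haar_step <- function(m) {
  if (nrow(m) %% 2 == 1) m <- rbind(m, m[nrow(m), ])
  if (ncol(m) %% 2 == 1) m <- cbind(m, m[, ncol(m)])
  od <- seq(1, ncol(m), by = 2); ev <- od + 1
  L <- (m[, od, drop = FALSE] + m[, ev, drop = FALSE]) / sqrt(2)  # along rows
  H <- (m[, od, drop = FALSE] - m[, ev, drop = FALSE]) / sqrt(2)
  od <- seq(1, nrow(m), by = 2); ev <- od + 1
  list(LL = (L[od, , drop = FALSE] + L[ev, , drop = FALSE]) / sqrt(2),
       HL = (L[od, , drop = FALSE] - L[ev, , drop = FALSE]) / sqrt(2),
       LH = (H[od, , drop = FALSE] + H[ev, , drop = FALSE]) / sqrt(2),
       HH = (H[od, , drop = FALSE] - H[ev, , drop = FALSE]) / sqrt(2))
}

#' Haar wavelet subband energies of a ROI
#'
#' Orthonormal Haar decomposition of the bounding-box crop (mask holes
#' filled with the in-mask mean; odd dimensions edge-padded). The energy of
#' a subband is the mean squared coefficient. Scales beyond what the crop
#' supports are returned as NA.
#'
#' @param px ROI matrix (NA outside the mask).
#' @param scales Deepest scale to attempt (default 4).
#' @return Named numeric vector `WavEnLL_s1 ... WavEnHH_s<scales>`.
#' @export
wavelet_features <- function(px, scales = 4L) {
  if (nrow(px) < 2 || ncol(px) < 2) stop("ROI bounding box smaller than 2x2")
  mu <- mean(px, na.rm = TRUE)
  m <- px; m[is.na(m)] <- mu
  out <- stats::setNames(
    rep(NA_real_, 4L * scales),
    as.vector(vapply(seq_len(scales), function(s)
      paste0("WavEn", c("LL", "LH", "HL", "HH"), "_s", s), character(4))))
  for (s in seq_len(scales)) {
    if (nrow(m) < 2 || ncol(m) < 2) break
    sub <- haar_step(m)
    for (b in c("LL", "LH", "HL", "HH"))
      out[paste0("WavEn", b, "_s", s)] <- mean(sub[[b]]^2)
    m <- sub$LL
  }
  out
}

# ---- inventory and full extraction -----------------------------------------

#' The default texture feature inventory
#'
#' Enumerates the 274 features emitted per ROI, with their family tags:
#' 9 histogram, 5 gradient, 11 Haralick statistics x 20 GLCM offsets
#' (d = 1..5 by 0/45/90/135 degrees), 5 run-length statistics x 4
#' directions, 5 autoregressive parameters, and 15 Haar subband energies
#' (scales 1-4, omitting the scale-1 approximation energy, which is
#' dominated by the DC term already carried by the histogram mean).
#'
#' @param scales Wavelet scale count (default 4).
#' @return Tibble with columns `name` and `group`.
#' @export
feature_inventory <- function(scales = 4L) {
  glcm_names <- as.vector(vapply(1:5, function(d)
    vapply(c(0, 45, 90, 135), function(th)
      paste0(glcm_offset_name(d, th),
             c("AngScMom", "Contrast", "Correlat", "SumOfSqs", "InvDfMom",
               "SumAverg", "SumVarnc", "SumEntrp", "Entropy", "DifVarnc",
               "DifEntrp")),
      character(11)),
    character(44)))
  rlm_names <- as.vector(vapply(c("H", "V", "45", "135"), function(sfx)
    paste0(c("ShrtREmp", "LngREmph", "GLevNonU", "RLNonUni", "Fraction"),
           "_", sfx), character(5)))
  wav_names <- as.vector(vapply(seq_len(scales), function(s)
    paste0("WavEn", c("LL", "LH", "HL", "HH"), "_s", s), character(4)))
  wav_names <- setdiff(wav_names, "WavEnLL_s1")
  tibble::tibble(
    name = c(names(histogram_features(matrix(1:9, 3))),
             c("GrMean", "GrVariance", "GrSkewness", "GrKurtosis",
               "GrNonZeros"),
             glcm_names, rlm_names,
             c("Teta1", "Teta2", "Teta3", "Teta4", "Sigma"), wav_names),
    group = c(rep("Histogram", 9), rep("Gradient", 5),
              rep("GLCM", length(glcm_names)), rep("RLM", length(rlm_names)),
              rep("ARModel", 5), rep("Wavelet", length(wav_names))))
}

#' Extract every inventory feature from one ROI
#'
#' Runs all six feature families and returns one value per inventory
#' entry, in inventory order.
#'
#' @param px ROI matrix (NA outside the mask).
#' @param inventory Tibble from [feature_inventory()].
#' @param Ng Grey levels for quantization (GLCM/RLM).
#' @param normalization Quantization window mode, see [quantize()].
#' @return Named numeric vector, `nrow(inventory)` long.
#' @export
extract_features <- function(px, inventory = feature_inventory(),
                             Ng = 64L, normalization = "full-range") {
  q <- quantize(px, Ng, normalization)
  vals <- c(histogram_features(px), gradient_features(px))
  for (d in 1:5)
    for (th in c(0, 45, 90, 135))
      vals <- c(vals, glcm_features(glcm(q, d, th), glcm_offset_name(d, th)))
  for (dir in c("horizontal", "vertical", "45", "135"))
    vals <- c(vals, rlm_features(q, dir))
  vals <- c(vals, ar_features(px), wavelet_features(px))
  missing <- setdiff(inventory$name, names(vals))
  if (length(missing))
    stop("inventory features not computed: ", paste(missing, collapse = ", "))
  vals[inventory$name]
}
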