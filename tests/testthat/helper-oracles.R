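# Independent brute-force oracles.  These deliberately use naive double
# loops and closed forms, not the package's vectorized code paths.

# random masked ROI: integer grey levels, optional irregular mask
random_roi <- function(nr = 16, nc = 16, mask_frac = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  px <- matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc)
  if (mask_frac < 1) {
    hole <- sample(nr * nc, round((1 - mask_frac) * nr * nc))
    px[hole] <- NA
  }
  px * 1.0
}

oracle_histogram <- function(px) {
  x <- px[!is.na(px)]
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n; m4 <- sum((x - m)^4) / n
  pc <- function(q) sort(x)[max(1, ceiling(q * n))]
  c(m, m2, if (m2 > 0) m3 / m2^1.5 else 0, if (m2 > 0) m4 / m2^2 - 3 else 0,
    pc(.01), pc(.1), pc(.5), pc(.9), pc(.99))
}

oracle_gradient <- function(px) {
  g <- c()
  for (r in 2:(nrow(px) - 1)) for (c in 2:(ncol(px) - 1)) {
    vals <- c(px[r, c], px[r, c - 1], px[r, c + 1], px[r - 1, c], px[r + 1, c])
    if (any(is.na(vals))) next
    g <- c(g, sqrt((px[r, c + 1] - px[r, c - 1])^2 +
                   (px[r + 1, c] - px[r - 1, c])^2))
  }
  n <- length(g); m <- sum(g) / n
  m2 <- sum((g - m)^2) / n
  c(m, m2, if (m2 > 0) sum((g - m)^3) / n / m2^1.5 else 0,
    if (m2 > 0) sum((g - m)^4) / n / m2^2 - 3 else 0, sum(g > 0) / n)
}

# naive symmetric co-occurrence counts by scanning every pixel pair
oracle_glcm <- function(lev, Ng, dr, dc) {
  p <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(lev))) for (c in seq_len(ncol(lev))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nrow(lev) || c2 < 1 || c2 > ncol(lev)) next
    i <- lev[r, c]; j <- lev[r2, c2]
    if (is.na(i) || is.na(j)) next
    p[i, j] <- p[i, j] + 1
    p[j, i] <- p[j, i] + 1
  }
  p / sum(p)
}

oracle_haralick <- function(p) {
  Ng <- nrow(p)
  asm <- ctr <- idm <- ent <- ssq <- 0
  mu_x <- 0
  for (i in 1:Ng) for (j in 1:Ng) mu_x <- mu_x + i * p[i, j]
  for (i in 1:Ng) for (j in 1:Ng) {
    asm <- asm + p[i, j]^2
    ctr <- ctr + (i - j)^2 * p[i, j]
    idm <- idm + p[i, j] / (1 + (i - j)^2)
    ssq <- ssq + (i - mu_x)^2 * p[i, j]
    if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
  }
  sg2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) sg2 <- sg2 + (i - mu_x)^2 * p[i, j]
  cor_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) cor_num <- cor_num + i * j * p[i, j]
  corr <- if (sg2 > 0) (cor_num - mu_x^2) / sg2 else 0
  psum <- rep(0, 2 * Ng); pdif <- rep(0, Ng)
  for (i in 1:Ng) for (j in 1:Ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  savg <- sum((1:(2 * Ng)) * psum)
  svar <- sum(((1:(2 * Ng)) - savg)^2 * psum)
  sent <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  davg <- sum((0:(Ng - 1)) * pdif)
  dvar <- sum(((0:(Ng - 1)) - davg)^2 * pdif)
  dent <- -sum(pdif[pdif > 0] * log(pdif[pdif > 0]))
  c(AngScMom = asm, Contrast = ctr, Correlat = corr, SumOfSqs = ssq,
    InvDfMom = idm, SumAverg = savg, SumVarnc = svar, SumEntrp = sent,
    Entropy = ent, DifVarnc = dvar, DifEntrp = dent)
}

# naive run extraction by explicit walking along a direction
oracle_rlm <- function(lev, step_r, step_c) {
  nr <- nrow(lev); nc <- ncol(lev)
  starts <- list()
  for (r in 1:nr) for (c in 1:nc) {
    pr <- r - step_r; pc <- c - step_c
    if (pr < 1 || pr > nr || pc < 1 || pc > nc) starts[[length(starts) + 1]] <- c(r, c)
  }
  lens <- c(); vals <- c()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lev[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1
      } else {
        if (!is.na(cur)) { lens <- c(lens, len); vals <- c(vals, cur) }
        cur <- v; len <- 1
      }
      r <- r + step_r; c <- c + step_c
    }
    if (!is.na(cur)) { lens <- c(lens, len); vals <- c(vals, cur) }
  }
  R <- length(lens)
  np <- sum(!is.na(lev))
  gl <- tapply(rep(1, R), vals, sum); rl <- tapply(rep(1, R), lens, sum)
  c(sum(1 / lens^2) / R, sum(lens^2) / R, sum(gl^2) / R, sum(rl^2) / R, R / np)
}

# AR fit through the explicit normal equations
oracle_ar <- function(px) {
  mu <- mean(px, na.rm = TRUE)
  s <- px; s[is.na(s)] <- mu; s <- s - mu
  valid <- !is.na(px)
  X <- NULL; yv <- c()
  for (r in 2:nrow(s)) for (c in 2:(ncol(s) - 1)) {
    if (!valid[r, c] || !valid[r, c - 1] || !valid[r - 1, c] ||
        !valid[r - 1, c - 1] || !valid[r - 1, c + 1]) next
    X <- rbind(X, c(s[r, c - 1], s[r - 1, c], s[r - 1, c - 1], s[r - 1, c + 1]))
    yv <- c(yv, s[r, c])
  }
  th <- solve(t(X) %*% X, t(X) %*% yv)
  e <- yv - X %*% th
  c(th, sqrt(mean(e^2)))
}

# Haar analysis via explicit orthonormal filter matrices
haar_matrices <- function(k) {
  if (k %% 2 == 1) k <- k + 1
  L <- matrix(0, k / 2, k); H <- matrix(0, k / 2, k)
  for (i in seq_len(k / 2)) {
    L[i, 2 * i - 1] <- L[i, 2 * i] <- 1 / sqrt(2)
    H[i, 2 * i - 1] <- 1 / sqrt(2); H[i, 2 * i] <- -1 / sqrt(2)
  }
  list(L = L, H = H)
}

oracle_haar_energies <- function(px, scales = 4) {
  mu <- mean(px, na.rm = TRUE)
  m <- px; m[is.na(m)] <- mu
  out <- c()
  for (s in seq_len(scales)) {
    if (nrow(m) < 2 || ncol(m) < 2) break
    mm <- m
    if (nrow(mm) %% 2 == 1) mm <- rbind(mm, mm[nrow(mm), ])
    if (ncol(mm) %% 2 == 1) mm <- cbind(mm, mm[, ncol(mm)])
    Fr <- haar_matrices(nrow(mm)); Fc <- haar_matrices(ncol(mm))
    LL <- Fr$L %*% mm %*% t(Fc$L); LH <- Fr$L %*% mm %*% t(Fc$H)
    HL <- Fr$H %*% mm %*% t(Fc$L); HH <- Fr$H %*% mm %*% t(Fc$H)
    v <- c(mean(LL^2), mean(LH^2), mean(HL^2), mean(HH^2))
    names(v) <- paste0("WavEn", c("LL", "LH", "HL", "HH"), "_s", s)
    out <- c(out, v)
    m <- LL
  }
  out
}

# AUROC by exhaustive concordant / tied pair counting
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# small standardized two-class feature table with planted signal
toy_table <- function(n = 60, p_signal = 1, p_noise = 9, sep = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * (p_signal + p_noise)), n)
  for (j in seq_len(p_signal)) X[, j] <- X[, j] + sep * y
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  tb <- tibble::as_tibble(as.data.frame(X))
  tb$label <- y
  standardize(tb, "global")
}
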