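# Kernel computations and the soft-margin SVM on a precomputed Gram matrix.
# The dual is solved by the SMO routine in src/smo.cpp.

pairwise_sqdist <- function(X, Z = NULL) {
  if (is.null(Z)) Z <- X
  sx <- rowSums(X^2); sz <- rowSums(Z^2)
  d2 <- outer(sx, sz, "+") - 2 * tcrossprod(X, Z)
  pmax(d2, 0)
}

#' Kernel (Gram) matrix between two sample sets
#'
#' Supported families: `polynomial-1` (linear, `x.z + 1`), `polynomial-2`
#' (`(x.z + 1)^2`) and `gaussian` (`exp(-gamma ||x-z||^2)`).
#'
#' @param X,Z Numeric matrices (rows = samples). `Z = NULL` means `X`.
#' @param family Kernel family.
#' @param gamma Gaussian width (required for `gaussian`).
#' @return `nrow(X)` x `nrow(Z)` kernel matrix.
#' @export
kernel_gram <- function(X, Z = NULL,
                        family = c("polynomial-1", "polynomial-2", "gaussian"),
                        gamma = NULL) {
  family <- match.arg(family)
  X <- as.matrix(X); if (!is.null(Z)) Z <- as.matrix(Z)
  switch(family,
         "polynomial-1" = tcrossprod(X, if (is.null(Z)) X else Z) + 1,
         "polynomial-2" = (tcrossprod(X, if (is.null(Z)) X else Z) + 1)^2,
         "gaussian" = {
           if (is.null(gamma) || gamma <= 0) stop("gaussian kernel needs gamma > 0")
           exp(-gamma * pairwise_sqdist(X, Z))
         })
}

# y in {0,1} or {-1,+1} -> +/-1 integer
as_pm1 <- function(y) {
  u <- sort(unique(y))
  if (length(u) != 2) stop("labels must contain exactly two classes")
  ifelse(y == u[2], 1L, -1L)
}

#' Train a soft-margin SVM on a precomputed kernel
#'
#' @param K Training Gram matrix.
#' @param y Binary labels (0/1 or -1/+1; the larger value is the positive
#'   class).
#' @param C Box constraint.
#' @param eps KKT tolerance of the SMO solver.
#' @return List of class `ksvm_fit`: alpha, b, y (+/-1), objective,
#'   iterations, converged.
#' @export
ksvm_fit <- function(K, y, C = 1, eps = 1e-5) {
  yy <- as_pm1(y)
  sol <- smo_solve(as.matrix(K), yy, C, eps)
  structure(list(alpha = sol$alpha, b = sol$b, y = yy,
                 objective = sol$objective, iterations = sol$iterations,
                 converged = sol$converged, C = C),
            class = "ksvm_fit")
}

#' Decision values of a kernel SVM
#'
#' @param fit A `ksvm_fit`.
#' @param K_cross Kernel matrix between training rows and new rows
#'   (`n_train` x `n_new`).
#' @return Numeric decision values (positive = positive class).
#' @export
ksvm_decision <- function(fit, K_cross) {
  as.numeric(crossprod(K_cross, fit$alpha * fit$y)) + fit$b
}
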