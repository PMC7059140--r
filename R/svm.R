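#' Fit a binary RBF-kernel support vector machine
#'
#' Soft-margin C-SVM with Gaussian kernel
#' \eqn{K(x, z) = \exp(-\|x - z\|^2 / (2\sigma^2))}, solved in the dual by
#' sequential minimal optimisation (compiled, deterministic working-set
#' selection). Intended for the small balanced per-term training sets used
#' throughout; the full kernel matrix is materialised.
#'
#' @param x Numeric matrix (rows = samples).
#' @param y Labels coercible to -1/+1 (logical, 0/1 or -1/+1).
#' @param sigma Kernel width (> 0).
#' @param C Soft-margin cost (default 1).
#' @param tol KKT tolerance (default 1e-3).
#' @param max_passes Full no-change passes before stopping (default 5).
#' @param max_iter Hard cap on pair updates (default `300 * nrow(x)`).
#' @return An object of class `kcml_svm` with elements `x`, `y`, `alpha`,
#'   `b`, `sigma`, `C`.
#' @export
rbf_svm <- function(x, y, sigma, C = 1, tol = 1e-3, max_passes = 5,
                    max_iter = 300L * nrow(x)) {
  x <- as.matrix(x)
  y <- as_pm1(y)
  stopifnot(length(y) == nrow(x), sigma > 0, C > 0)
  if (length(unique(y)) < 2) abort("rbf_svm: need both classes in training data")
  D2 <- pairwise_sqdist(x)
  K <- rbf_kernel_from_d2(D2, sigma)
  fit <- smo_train_kernel(K, as.integer(y), C, tol, as.integer(max_passes),
                          as.integer(max_iter))
  structure(list(x = x, y = y, alpha = fit$alpha, b = fit$b, sigma = sigma,
                 C = C, iter = fit$iter),
            class = "kcml_svm")
}

as_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1L, -1L))
  y <- as.integer(y)
  if (all(y %in% c(0L, 1L))) return(ifelse(y == 1L, 1L, -1L))
  if (all(y %in% c(-1L, 1L))) return(y)
  abort("labels must be logical, 0/1 or -1/+1")
}

#' @param object A `kcml_svm`.
#' @param newdata Numeric matrix of rows to score.
#' @param ... Unused.
#' @return `predict()` returns the signed decision values (distance to the
#'   boundary in kernel space, up to margin normalisation); positive values
#'   are predicted members of the positive class.
#' @rdname rbf_svm
#' @export
predict.kcml_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sv <- which(object$alpha != 0)
  if (length(sv) == 0) return(rep(object$b, nrow(newdata)))
  D2 <- cross_sqdist(newdata, object$x[sv, , drop = FALSE])
  K <- rbf_kernel_from_d2(D2, object$sigma)
  drop(K %*% (object$alpha[sv] * object$y[sv])) + object$b
}

#' @export
print.kcml_svm <- function(x, ...) {
  cat(sprintf("<kcml_svm> n=%d, sigma=%.4g, C=%.3g, support vectors=%d\n",
              nrow(x$x), x$sigma, x$C, sum(x$alpha != 0)))
  invisible(x)
}

# Stratified fold assignment (0-based, for the compiled CV loop):
# deterministic given the current RNG state.
stratified_folds <- function(y, nfold) {
  y <- as_pm1(y)
  fold <- integer(length(y))
  for (cl in c(-1L, 1L)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfold) - 1L, length(idx)))
  }
  fold
}

# Mean CV F-score of an RBF SVM on a squared-distance matrix.
cv_fscore <- function(D2, y, fold, nfold, sigma, C = 1, tol = 1e-3,
                      max_passes = 3, max_iter = 20L * nrow(D2)) {
  cv_fscore_d2(D2, as.integer(as_pm1(y)), as.integer(fold),
               as.integer(nfold), sigma, C, tol, as.integer(max_passes),
               as.integer(max_iter))
}
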