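#' @keywords internal
"_PACKAGE"

#' @importFrom stats cov density median pchisq quantile rgamma rnorm runif
#'   rWishart sd var cor model.matrix setNames
#' @importFrom utils read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw rows from a zero-mean multivariate normal
#'
#' Eigen-decomposition based sampler so that positive semi-definite matrices
#' with exact zero eigenvalues (e.g. a degenerate all-zero covariance) are
#' valid inputs. Draws are filled row-wise from a single `rnorm()` call, so
#' the values consumed from the RNG stream depend only on `n` and
#' `ncol(sigma)` -- this keeps seeds portable across parameter values.
#'
#' @param n number of independent rows to draw.
#' @param sigma covariance matrix (t x t, symmetric PSD).
#' @return an `n x t` numeric matrix.
#' @keywords internal
rmvn0 <- function(n, sigma) {
  sigma <- as.matrix(sigma)
  t <- ncol(sigma)
  if (t == 0L || n == 0L) return(matrix(0, n, t))
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  rt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  z <- matrix(rnorm(n * t), nrow = n, ncol = t, byrow = TRUE)
  z %*% rt
}

#' Check symmetry and positive semi-definiteness
#'
#' @param m matrix to check.
#' @param name label used in the error message.
#' @param tol relative tolerance on the smallest eigenvalue.
#' @return invisibly `TRUE`; errors otherwise, reporting the offending matrix
#'   and its smallest eigenvalue.
#' @keywords internal
check_psd <- function(m, name = "covariance matrix", tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop(sprintf("%s must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lo <- min(ev)
  if (lo < -tol * max(1, max(abs(ev)))) {
    stop(sprintf("%s is not positive semi-definite (smallest eigenvalue %.6g)",
                 name, lo), call. = FALSE)
  }
  invisible(TRUE)
}

#' Project a symmetric matrix onto the PSD cone
#'
#' Eigenvalues below `floor` times the mean diagonal are raised to that floor,
#' keeping the matrix invertible for use in mixed-model equations.
#'
#' @param m symmetric matrix.
#' @param floor relative eigenvalue floor.
#' @return list with `mat` (projected matrix) and `projected` (logical).
#' @keywords internal
psd_project <- function(m, floor = 1e-8) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  lo <- floor * max(mean(diag(m)), .Machine$double.eps)
  if (min(ev$values) >= lo) return(list(mat = m, projected = FALSE))
  lam <- pmax(ev$values, lo)
  list(mat = ev$vectors %*% (lam * t(ev$vectors)), projected = TRUE)
}

logdet <- function(m) {
  determinant(as.matrix(m), logarithm = TRUE)$modulus[[1]]
}

#' Labels for the distinct entries of a symmetric trait covariance matrix
#' @keywords internal
vech_labels <- function(prefix, traits) {
  t <- length(traits)
  idx <- which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
  sprintf("%s[%s,%s]", prefix, traits[idx[, 2]], traits[idx[, 1]])
}

vech <- function(m) m[lower.tri(m, diag = TRUE)]

unvech <- function(v, t) {
  m <- matrix(0, t, t)
  m[lower.tri(m, diag = TRUE)] <- v
  m + t(m) - diag(diag(m), t)
}
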