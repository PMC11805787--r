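# Small shared numerical helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Sample skewness and excess kurtosis
#'
#' Moment-based sample skewness (g1) and excess kurtosis (g2), the statistics
#' conventionally screened against |skew| < 2 and |kurtosis| < 4 as an
#' approximate-normality check for individual-difference measures.
#'
#' @param x Numeric vector.
#' @return For `sample_skewness` the g1 statistic; for `sample_kurtosis` the
#'   excess kurtosis g2 (0 for a normal distribution).
#' @export
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

#' @rdname sample_skewness
#' @export
sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^4) / s2^2 - 3
}

#' Nearest positive semi-definite repair of a symmetric matrix
#'
#' Eigenvalue clipping: negative eigenvalues are set to a small floor and the
#' matrix is reassembled. When `corr = TRUE` the result is rescaled to unit
#' diagonal so it remains a correlation matrix.
#'
#' @param mat Symmetric numeric matrix.
#' @param corr Rescale to unit diagonal afterwards?
#' @param eps Eigenvalue floor.
#' @return A positive semi-definite matrix of the same dimension.
#' @export
nearest_psd <- function(mat, corr = FALSE, eps = 1e-10) {
  mat <- (mat + t(mat)) / 2
  e <- eigen(mat, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  out <- (out + t(out)) / 2
  if (corr) {
    d <- sqrt(diag(out))
    out <- out / tcrossprod(d)
    diag(out) <- 1
  }
  out
}

is_psd <- function(mat, tol = -1e-8) {
  all(eigen((mat + t(mat)) / 2, symmetric = TRUE, only.values = TRUE)$values > tol)
}

# Multivariate normal draws via Cholesky (eigen fallback for semi-definite input).
draw_mvn <- function(n, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  z <- matrix(stats::rnorm(n * p), n, p)
  if (is.null(ch)) {
    e <- eigen(sigma, symmetric = TRUE)
    ch <- t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), p))
  }
  sweep(z %*% ch, 2, mu, `+`)
}

#' Convert a Spearman rank correlation to the Gaussian-copula Pearson scale
#'
#' For a bivariate normal, the Spearman correlation is (6/pi) asin(rho/2); the
#' inverse map 2 sin(pi rho_s / 6) gives the latent Pearson correlation to use
#' in a Gaussian copula so the generated data attain a target rank correlation.
#'
#' @param rho_s Spearman correlation(s) in \[-1, 1\].
#' @return Pearson correlation(s) on the latent normal scale.
#' @export
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)
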