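# Internal numerical helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Check symmetry and positive definiteness of a covariance matrix.
#' @noRd
check_spd <- function(sigma, name = "sigma", sym_tol = 1e-10) {
  if (!is.matrix(sigma) || nrow(sigma) != ncol(sigma)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(sigma - t(sigma))) > sym_tol * max(1, max(abs(sigma)))) {
    stop(sprintf("'%s' is not symmetric", name), call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf("'%s' is not positive definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(TRUE)
}

# Draw n rows from N(mu, sigma) by Cholesky factorisation.
#' @noRd
rmvn <- function(n, mu, sigma) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(z %*% chol(sigma), 2, mu, `+`)
}

# Squared Mahalanobis distances of rows of x from mu under sigma,
# via one Cholesky factorisation.
#' @noRd
mahalanobis_sq <- function(x, mu, sigma_chol) {
  y <- sweep(x, 2, mu)
  w <- backsolve(sigma_chol, t(y), transpose = TRUE)
  colSums(w^2)
}

# Derive m reproducible sub-seeds from the current RNG state.
#' @noRd
draw_seeds <- function(m) sample.int(.Machine$integer.max - 1L, m)

#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is_scalar_number(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
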