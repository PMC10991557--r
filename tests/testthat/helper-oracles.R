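# Independent oracles and fixture builders used across the suite.

# A niche_posterior whose K draws are all the same fixed (mu, sigma):
# useful for checking overlap and size against closed forms.
make_fixed_posterior <- function(mu, sigma, K = 50, group = "fixed") {
  d <- length(mu)
  if (!is.matrix(sigma)) sigma <- diag(sigma, d)
  axis_names <- paste0("axis", seq_len(d))
  mu_draws <- matrix(mu, K, d, byrow = TRUE,
                     dimnames = list(NULL, axis_names))
  sigma_draws <- array(sigma, c(d, d, K),
                       dimnames = list(axis_names, axis_names, NULL))
  structure(list(group = group, axis_names = axis_names, mu = mu_draws,
                 sigma = sigma_draws, K = as.integer(K), n = NA_integer_,
                 d = d, seed = NULL),
            class = "niche_posterior")
}

# A niche_posterior built from explicit centroid draws (covariances fixed).
make_posterior_from_mu <- function(mu_draws, sigma = NULL, group = "g") {
  mu_draws <- as.matrix(mu_draws)
  d <- ncol(mu_draws)
  K <- nrow(mu_draws)
  if (is.null(sigma)) sigma <- diag(d)
  axis_names <- colnames(mu_draws)
  if (is.null(axis_names)) {
    axis_names <- paste0("axis", seq_len(d))
    colnames(mu_draws) <- axis_names
  }
  sigma_draws <- array(sigma, c(d, d, K),
                       dimnames = list(axis_names, axis_names, NULL))
  structure(list(group = group, axis_names = axis_names, mu = mu_draws,
                 sigma = sigma_draws, K = K, n = NA_integer_, d = d,
                 seed = NULL),
            class = "niche_posterior")
}

# Brute-force Layman metrics on one centroid matrix (S x d), O(S^2) pairwise
# loops, independent of the package implementation.
brute_layman <- function(centroids) {
  s <- nrow(centroids)
  com <- colMeans(centroids)
  cd <- mean(apply(centroids, 1, function(r) sqrt(sum((r - com)^2))))
  nn <- numeric(s)
  for (i in seq_len(s)) {
    best <- Inf
    for (j in seq_len(s)) {
      if (i == j) next
      dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      if (dij < best) best <- dij
    }
    nn[i] <- best
  }
  nnd <- mean(nn)
  list(cd = cd, nnd = nnd,
       sdnnd = sqrt(mean((nn - nnd)^2)),
       range_per_axis = apply(centroids, 2, max) - apply(centroids, 2, min))
}

# Numeric-integration oracle for directional overlap with fixed parameters:
# P(X in ellipse(mu_onto, sigma_onto, alpha)) for X ~ N(mu_from, sigma_from),
# in 1 or 2 dimensions.
numeric_overlap <- function(mu_from, sigma_from, mu_onto, sigma_onto,
                            alpha = 0.95, grid_n = 600) {
  d <- length(mu_from)
  c2 <- qchisq(alpha, df = d)
  if (d == 1) {
    half <- sqrt(c2 * sigma_onto[1])
    return(pnorm(mu_onto[1] + half, mu_from[1], sqrt(sigma_from[1])) -
             pnorm(mu_onto[1] - half, mu_from[1], sqrt(sigma_from[1])))
  }
  stopifnot(d == 2)
  # integrate the bivariate normal density over the ellipse on a fine grid
  half <- sqrt(c2 * diag(sigma_onto))
  xs <- seq(mu_onto[1] - half[1], mu_onto[1] + half[1], length.out = grid_n)
  ys <- seq(mu_onto[2] - half[2], mu_onto[2] + half[2], length.out = grid_n)
  dx <- xs[2] - xs[1]
  dy <- ys[2] - ys[1]
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  so_inv <- solve(sigma_onto)
  dev_o <- sweep(pts, 2, mu_onto)
  inside <- rowSums((dev_o %*% so_inv) * dev_o) <= c2
  sf_inv <- solve(sigma_from)
  dev_f <- sweep(pts, 2, mu_from)
  dens <- exp(-0.5 * rowSums((dev_f %*% sf_inv) * dev_f)) /
    (2 * pi * sqrt(det(sigma_from)))
  sum(dens[inside]) * dx * dy
}

# Multivariate-normal sampler for building test data (independent of the
# package's internal sampler).
rmvn_test <- function(n, mu, sigma) {
  d <- length(mu)
  ev <- eigen(sigma, symmetric = TRUE)
  a <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) %*% t(ev$vectors)
  sweep(matrix(rnorm(n * d), n, d) %*% a, 2, mu, `+`)
}

# A small complete synthetic dataset for IO / filtering tests.
small_dataset <- function(seed = 11, n = c(10L, 10L)) {
  specs <- list(
    species_spec("sp_a", n[1], latent_mean = c(0, 0, 0, 0, 0)),
    species_spec("sp_b", n[2], latent_mean = c(1, 0, 1, 0.5, 0)))
  generate_community(specs, seed = seed)
}
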