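# Conjugate posterior sampling, ellipsoid volume, Monte-Carlo overlap.

test_that("posterior draws match the conjugate analytic moments", {
  set.seed(61)
  x <- matrix(rnorm(500), ncol = 1)
  p <- sample_posterior(x, K = 20000, seed = 62, group = "norm1d")
  n <- nrow(x)
  xbar <- mean(x)
  S <- sum((x - xbar)^2)
  # E[mu | X] = xbar; allow sampling + MC slack
  mc_se <- sd(p$mu) / sqrt(p$K)
  expect_lt(abs(mean(p$mu) - xbar), 4 * (sd(x) / sqrt(n) + mc_se))
  # E[Sigma | X] = S / (n - 1 - d - 1) for the IW(S, n - 1) posterior
  expect_lt(abs(mean(p$sigma) - S / (n - 3)) / (S / (n - 3)), 0.05)
  # every covariance draw symmetric positive definite
  expect_true(all(apply(p$sigma, 3, function(s) s > 0)))
})

test_that("posterior sampling is deterministic given the seed and proper", {
  set.seed(63)
  x <- matrix(rnorm(60), ncol = 3)
  a <- sample_posterior(x, K = 50, seed = 7)
  b <- sample_posterior(x, K = 50, seed = 7)
  expect_identical(a$mu, b$mu)
  expect_identical(a$sigma, b$sigma)
  c_ <- sample_posterior(x, K = 50, seed = 8)
  expect_false(isTRUE(all.equal(a$mu, c_$mu)))
  # propriety boundary: d = 5 needs n >= 7
  x5 <- matrix(rnorm(30), ncol = 5)
  expect_error(sample_posterior(x5, K = 10, group = "tiny"),
               "insufficient samples.*tiny")
  expect_silent(sample_posterior(matrix(rnorm(35), ncol = 5), K = 10))
})

test_that("niche size matches closed forms and scales with determinant", {
  # d = 2, Sigma = I: area of the 95% circle is pi * chi2_{2,0.95}
  expect_equal(niche_size(diag(2), 0.95), pi * qchisq(0.95, 2),
               tolerance = 1e-12)
  # d = 1: interval length 2 * z_{0.975}
  expect_equal(niche_size(matrix(1), 0.95), 2 * qnorm(0.975),
               tolerance = 1e-12)
  # determinant homogeneity: c^2 Sigma -> c^d V, exactly
  set.seed(64)
  a <- matrix(rnorm(9), 3)
  sigma <- crossprod(a) + diag(3)
  for (cc in c(0.5, 2, 3)) {
    expect_equal(niche_size(cc^2 * sigma, 0.9),
                 cc^3 * niche_size(sigma, 0.9), tolerance = 1e-10)
  }
  expect_error(niche_size(matrix(c(1, 2, 2, 1), 2), 0.95), "positive definite")
  expect_error(niche_size(diag(2), 1.2), "alpha")
})

test_that("overlap of a fixed region onto itself equals alpha", {
  set.seed(65)
  for (d in c(1, 3)) {
    a <- matrix(rnorm(d * d), d)
    sigma <- crossprod(a) + diag(d)
    p <- make_fixed_posterior(rnorm(d), sigma, K = 10)
    ov <- niche_overlap(p, p, alpha = 0.95, n_mc = 5000, seed = 66)
    tol <- 3 * sqrt(0.95 * 0.05 / (5000 * 10))
    expect_lt(abs(ov$mean - 0.95), tol)
    expect_true(all(ov$overlap_draws >= 0 & ov$overlap_draws <= 1))
  }
})

test_that("overlap matches the normal-CDF and numeric-integration oracles", {
  # 1D: from N(0,1) onto the 95% region of N(2,1)
  from <- make_fixed_posterior(0, matrix(1), K = 40)
  onto <- make_fixed_posterior(2, matrix(1), K = 40, group = "onto")
  ov <- niche_overlap(from, onto, alpha = 0.95, n_mc = 10000, seed = 67)
  expected <- pnorm(2 + qnorm(0.975)) - pnorm(2 - qnorm(0.975))
  expect_equal(expected, 0.48403, tolerance = 1e-4)  # oracle sanity
  expect_lt(abs(ov$mean - expected), 0.01)
  # 2D: correlated covariances, numeric integration oracle
  sf <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  so <- matrix(c(0.7, -0.2, -0.2, 1.2), 2)
  from2 <- make_fixed_posterior(c(0, 0), sf, K = 40)
  onto2 <- make_fixed_posterior(c(1, 0.5), so, K = 40, group = "onto")
  ov2 <- niche_overlap(from2, onto2, alpha = 0.95, n_mc = 10000, seed = 68)
  expect_lt(abs(ov2$mean - numeric_overlap(c(0, 0), sf, c(1, 0.5), so)), 0.01)
  # disjoint supports
  far <- make_fixed_posterior(c(1e6, 0), diag(2), K = 10, group = "far")
  near <- make_fixed_posterior(c(0, 0), diag(2), K = 10)
  expect_equal(niche_overlap(near, far, n_mc = 500, seed = 69)$mean, 0)
  # axis mismatch is an error
  p3 <- make_fixed_posterior(c(0, 0, 0), diag(3))
  expect_error(niche_overlap(from2, p3), "axis")
})

test_that("inflating the target covariance never decreases overlap", {
  set.seed(70)
  from <- make_fixed_posterior(c(0, 1), diag(2), K = 20)
  means <- vapply(c(1, 1.5, 2, 4), function(f) {
    onto <- make_fixed_posterior(c(1, 0), f * diag(2), K = 20, group = "onto")
    niche_overlap(from, onto, n_mc = 4000, seed = 71)$mean
  }, numeric(1))
  expect_true(all(diff(means) >= -0.01))
})

test_that("posterior concentrates on the truth as n grows", {
  set.seed(72)
  mu_true <- c(1, -2)
  sigma_true <- matrix(c(2, 0.5, 0.5, 1), 2)
  errs <- vapply(c(50, 500, 5000), function(n) {
    # average centroid error over replicates so the ~1/sqrt(n) trend is
    # visible through sampling noise
    mean(replicate(5, {
      x <- rmvn_test(n, mu_true, sigma_true)
      p <- sample_posterior(x, K = 1000)
      sqrt(sum((colMeans(p$mu) - mu_true)^2))
    }))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  # niche-size mode within 5% of the true-Sigma size at n = 5000
  x <- rmvn_test(5000, mu_true, sigma_true)
  p <- sample_posterior(x, K = 5000, seed = 73)
  sz <- niche_size_draws(p, 0.95)
  expect_lt(abs(density_mode(sz) - niche_size(sigma_true, 0.95)) /
              niche_size(sigma_true, 0.95), 0.05)
})

test_that("niche_fit groups, reports non-estimable species, has methods", {
  d <- complete_case_filter(default_community(seed = 7))
  sp <- build_dimension_space(d, "2D")
  fit <- niche_fit(sp, K = 300, seed = 74)
  expect_s3_class(fit, "niche_fit")
  expect_length(fit$posteriors, 5L)
  expect_identical(fit$axis_names, c("PC1-Css", "PC1-Nss"))
  cf <- coef(fit)
  expect_equal(dim(cf), c(5L, 2L))
  summ <- summary(fit)
  expect_s3_class(summ, "summary.niche_fit")
  expect_true(all(summ$q05 <= summ$q95))
  expect_true(all(summ$mode > 0))
  sim <- simulate(fit, nsim = 10, seed = 75)
  expect_equal(nrow(sim), 50L)
  expect_output(print(fit), "Groups")
  # formula interface
  df <- data.frame(a = rnorm(40), b = rnorm(40),
                   g = rep(c("x", "y"), each = 20))
  ff <- niche_fit(cbind(a, b) ~ g, data = df, K = 100, seed = 76)
  expect_setequal(names(ff$posteriors), c("x", "y"))
  # a species below the propriety bound (n < d + 2 = 4 in 2D) is flagged
  tiny <- rbind(sp$coords, sp$coords[1:3, ] + 100)
  grp <- c(sp$species, rep("tiny_sp", 3))
  fit2 <- niche_fit(tiny, group = grp, K = 100, seed = 77)
  expect_identical(fit2$not_estimable, "tiny_sp")
  expect_true("tiny_sp" %in% summary(fit2)$group)
})
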