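# Bhattacharyya coefficients, the centroid-difference probability, group
# comparison assembly, and the two-period temporal analysis.

test_that("bhattacharyya hits its boundary and closed-form cases", {
  set.seed(91)
  a <- rnorm(5000)
  expect_equal(bhattacharyya(a, a), 1, tolerance = 1e-12)
  expect_equal(bhattacharyya(1:100, 201:300), 0)
  # equal-variance normals: BC = exp(-delta^2 / 8)
  x <- rnorm(100000)
  y <- rnorm(100000, 2)
  expect_lt(abs(bhattacharyya(x, y, 100) - exp(-0.5)), 0.02)
  # symmetry is exact (shared binning)
  expect_identical(bhattacharyya(x, y, 100), bhattacharyya(y, x, 100))
  # bin-count sensitivity is mild on smooth posteriors
  expect_lt(abs(bhattacharyya(x, y, 50) - bhattacharyya(x, y, 200)), 0.03)
  # degenerate union range -> 1 by convention
  expect_equal(bhattacharyya(rep(2, 5), rep(2, 9)), 1)
  expect_error(bhattacharyya(numeric(0), 1), "non-empty")
  expect_error(bhattacharyya(1, 2, n_bins = 1), "n_bins")
})

test_that("centroid-difference test matches hand enumeration and limits", {
  # K = 4 in 1D, all a-draws 0 and b-draws 5: every indicator fires
  res <- centroid_difference_test(matrix(0, 4, 1), matrix(5, 4, 1), seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$centroid_distance, 5)
  # tight posteriors 10 units apart
  set.seed(92)
  a <- matrix(rnorm(2000, sd = 0.01), ncol = 2)
  b <- matrix(rnorm(2000, 10, sd = 0.01), ncol = 2)
  expect_gt(centroid_difference_test(a, b, seed = 2)$p, 0.999)
  # identical generating distributions: conservative in 2D
  p_null <- replicate(10, {
    centroid_difference_test(matrix(rnorm(4000), ncol = 2),
                             matrix(rnorm(4000), ncol = 2))$p
  })
  expect_true(all(p_null < 0.2))
  expect_error(centroid_difference_test(matrix(0, 2, 1), matrix(0, 2, 1)),
               "4 draws")
  # odd K is truncated to even rather than failing
  expect_silent(centroid_difference_test(matrix(rnorm(5), 5, 1),
                                         matrix(rnorm(5), 5, 1), seed = 3))
})

test_that("centroid-difference test is invariant to common rigid motions", {
  set.seed(93)
  a <- matrix(rnorm(1000), ncol = 2)
  b <- matrix(rnorm(1000, 1), ncol = 2)
  base <- centroid_difference_test(a, b, seed = 5)
  q <- qr.Q(qr(matrix(rnorm(4), 2)))
  shift <- c(100, -40)
  a2 <- sweep(a %*% q, 2, shift, `+`)
  b2 <- sweep(b %*% q, 2, shift, `+`)
  moved <- centroid_difference_test(a2, b2, seed = 5)
  expect_equal(moved$p, base$p, tolerance = 1e-10)
  expect_equal(moved$centroid_distance, base$centroid_distance,
               tolerance = 1e-10)
})

test_that("compare_groups assembles coherent self and planted comparisons", {
  set.seed(94)
  x <- rmvn_test(40, rep(0, 2), diag(2))
  p <- sample_posterior(x, K = 2000, seed = 95, group = "self")
  self_cmp <- compare_groups(p, p, seed = 96)
  expect_true(all(self_cmp$bc_per_axis == 1))
  expect_gt(self_cmp$bc_size, 0.98)
  expect_lt(self_cmp$p_centroid_diff, 0.15)
  expect_equal(self_cmp$centroid_distance, 0)

  # two groups separated by 10 posterior sds on axis 3 only
  sd_mu <- 0.05
  mu_a <- matrix(rnorm(5 * 4000, sd = sd_mu), ncol = 5)
  mu_b <- matrix(rnorm(5 * 4000, sd = sd_mu), ncol = 5)
  mu_b[, 3] <- mu_b[, 3] + 10 * sd_mu
  pa <- make_posterior_from_mu(mu_a, diag(5), group = "a")
  pb <- make_posterior_from_mu(mu_b, diag(5), group = "b")
  cmp <- compare_groups(pa, pb, sizes_a = rep(1, 4000), sizes_b = rep(1, 4000),
                        seed = 97)
  expect_true(all(cmp$bc_per_axis[c(1, 2, 4, 5)] > 0.9))
  expect_lt(cmp$bc_per_axis[3], 0.05)
  expect_error(compare_groups(pa, make_fixed_posterior(0, matrix(1))), "axis")
})

test_that("temporal analysis respects the period boundary and exchangeability", {
  # null period effect: periods exchangeable, centroids indistinct
  spec <- species_spec("corm", 40, latent_mean = c(0.5, 0.5, 0.5, 0.5, 0),
                       period_shift = rep(0, 5), period_cov_scale = 1,
                       year_range = c(1970L, 2006L))
  d <- generate_community(list(spec), seed = 101)
  ta <- temporal_analysis(d, "corm", approaches = "2D", K = 3000,
                          n_mc = 500, seed = 102)
  expect_true(ta$results[["2D"]]$estimable)
  expect_lt(ta$tests$p[1], 0.15)
  expect_gt(ta$overlap$overlap_mean[1], 0.6)
  expect_gt(ta$overlap$overlap_mean[2], 0.6)
  # the year split drives the period sample counts
  expect_equal(unname(ta$results[["2D"]]$n["period1"]),
               sum(d$year >= 1970 & d$year <= 1989))
  expect_equal(unname(ta$results[["2D"]]$n["period2"]),
               sum(d$year >= 1990 & d$year <= 2006))
})

test_that("a shrunken late-period niche is detected in every approach", {
  spec <- species_spec("shrink", 60, latent_mean = c(0.5, 0.5, 0.5, 0.5, 0),
                       period_shift = rep(0, 5), period_cov_scale = 0.25,
                       year_range = c(1970L, 2006L))
  filler <- species_spec("filler", 20, latent_mean = c(-2, 0, -2, 0, 1))
  d <- generate_community(list(spec, filler), seed = 103)
  ta <- temporal_analysis(d, "shrink", approaches = c("2D", "3D", "5D"),
                          K = 2000, n_mc = 400, seed = 104)
  for (app in c("2D", "3D", "5D")) {
    sz <- ta$sizes[ta$sizes$approach == app, ]
    expect_lt(sz$mode[sz$period == "period2"], sz$mode[sz$period == "period1"])
    ov <- ta$overlap[ta$overlap$approach == app, ]
    expect_gt(ov$overlap_mean[ov$from == "period2"],
              ov$overlap_mean[ov$from == "period1"])
  }
})

test_that("temporal analysis flags starved approaches and is deterministic", {
  # only 5 late-period samples: 5D (needs 7) must be non-estimable, 2D fine
  spec <- species_spec("sparse", 25, latent_mean = rep(0, 5),
                       year_range = c(1970L, 1989L))
  late <- species_spec("sparse_late", 5, latent_mean = rep(0, 5),
                       year_range = c(1995L, 2000L))
  d1 <- generate_community(list(spec), seed = 105)
  d2 <- generate_community(list(late), seed = 106)
  d2$species <- "sparse"
  d2$sample_id <- paste0("late_", seq_len(nrow(d2)))
  d <- isotope_dataset(rbind(d1, d2))
  ta <- temporal_analysis(d, "sparse", approaches = c("2D", "5D"),
                          K = 1000, n_mc = 300, seed = 107)
  expect_true(ta$results[["2D"]]$estimable)
  expect_false(ta$results[["5D"]]$estimable)
  expect_true(all(is.na(ta$sizes$mode[ta$sizes$approach == "5D"])))
  # determinism of the emitted tables
  tb <- temporal_analysis(d, "sparse", approaches = c("2D", "5D"),
                          K = 1000, n_mc = 300, seed = 107)
  expect_identical(ta$sizes, tb$sizes)
  expect_identical(ta$tests, tb$tests)
  expect_identical(ta$overlap, tb$overlap)
  expect_error(temporal_analysis(d, "absent", K = 1000, seed = 1),
               "not present")
  expect_error(period_split(c(1970, 1995), c(1990, 2006)), "overlap")
})
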