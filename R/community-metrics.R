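# Layman community metrics generalized to n dimensions, computed on the
# posterior centroid draws of every species and summarised over draws.

#' Kernel-density mode of a draw vector
#'
#' Mode of a Gaussian kernel density (Silverman's rule-of-thumb bandwidth)
#' evaluated on a 512-point grid over the draw range. A constant vector
#' returns that constant.
#'
#' @param draws Numeric vector.
#' @return The abscissa of the density maximum.
#' @export
density_mode <- function(draws) {
  if (!length(draws)) stop("empty draws", call. = FALSE)
  if (length(draws) == 1L || stats::sd(draws) == 0) return(draws[1])
  dd <- stats::density(draws, bw = "nrd0", n = 512)
  dd$x[which.max(dd$y)]
}

#' Summarise a posterior draw vector
#'
#' Two summary conventions: `mode_q05_q95` (kernel-density mode with 5% and
#' 95% quantiles, the convention used for niche sizes) and `mean_q025_q975`
#' (mean with 2.5% and 97.5% quantiles, used for community metrics).
#' Quantiles use the standard linear-interpolation estimator
#' ([stats::quantile()] type 7).
#'
#' @param draws Numeric vector, length >= 2 (length 1 is degenerate but
#'   allowed for constants).
#' @param summary_kind `"mode_q05_q95"` or `"mean_q025_q975"`.
#' @return A one-row data frame: `center`, `lower`, `upper`, `kind`.
#' @export
summarize_posterior <- function(draws,
                                summary_kind = c("mode_q05_q95",
                                                 "mean_q025_q975")) {
  summary_kind <- match.arg(summary_kind)
  if (!length(draws)) stop("empty draws", call. = FALSE)
  if (summary_kind == "mode_q05_q95") {
    q <- stats::quantile(draws, c(0.05, 0.95), names = FALSE)
    data.frame(center = density_mode(draws), lower = q[1], upper = q[2],
               kind = summary_kind, stringsAsFactors = FALSE)
  } else {
    q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    data.frame(center = mean(draws), lower = q[1], upper = q[2],
               kind = summary_kind, stringsAsFactors = FALSE)
  }
}

# Layman metrics for one fixed set of centroids (S x d matrix).
# Centroid distance (CD): mean Euclidean distance of species centroids to
# their unweighted mean; NND: mean nearest-neighbour distance; SDNND:
# population standard deviation of the nearest distances; range per axis.
#' @noRd
layman_once <- function(centroids) {
  s <- nrow(centroids)
  com <- colMeans(centroids)
  cd <- mean(sqrt(rowSums(sweep(centroids, 2, com)^2)))
  dmat <- as.matrix(stats::dist(centroids))
  diag(dmat) <- Inf
  nn <- apply(dmat, 1, min)
  nnd <- mean(nn)
  sdnnd <- sqrt(mean((nn - nnd)^2))
  rng <- apply(centroids, 2, max) - apply(centroids, 2, min)
  list(cd = cd, nnd = nnd, sdnnd = sdnnd, range_per_axis = rng)
}

#' n-dimensional Layman community metrics over posterior draws
#'
#' For each posterior draw k, takes the k-th centroid of every species and
#' computes: CD, the mean Euclidean distance of species centroids to the
#' unweighted community centroid (species spread); NND, the mean
#' nearest-neighbour distance among species centroids (species packing);
#' SDNND, the population standard deviation of those nearest distances
#' (packing evenness); and the per-axis centroid range. Summaries are the
#' posterior mean with 2.5% and 97.5% quantiles.
#'
#' @param x A `niche_fit` or a list of `niche_posterior` objects with
#'   identical axes and draw counts (>= 2 species).
#' @return A `layman_draws` list: `draws` (data frame with one row per
#'   posterior draw: `cd`, `nnd`, `sdnnd`, one `range_*` column per axis),
#'   `summary` (per-metric mean/q025/q975), `species`, `axis_names`.
#' @export
layman_metrics <- function(x) {
  posteriors <- if (inherits(x, "niche_fit")) x$posteriors else x
  if (!is.list(posteriors) || length(posteriors) < 2L) {
    stop("at least two species posteriors are required", call. = FALSE)
  }
  lapply(posteriors, function(p) {
    if (!inherits(p, "niche_posterior")) {
      stop("x must be a niche_fit or a list of niche_posterior objects",
           call. = FALSE)
    }
  })
  axes <- posteriors[[1]]$axis_names
  K <- posteriors[[1]]$K
  for (p in posteriors) {
    if (!identical(p$axis_names, axes)) stop("axis names differ", call. = FALSE)
    if (p$K != K) stop("posterior draw counts differ", call. = FALSE)
  }
  s <- length(posteriors)
  d <- length(axes)
  # mu_arr[k, axis, species]
  mu_arr <- array(unlist(lapply(posteriors, function(p) p$mu)), c(K, d, s))
  mu_of <- function(j) array(mu_arr[, , j], c(K, d))
  # community centroid per draw: K x d
  com <- array(apply(mu_arr, c(1, 2), mean), c(K, d))
  cd <- rowMeans(vapply(seq_len(s), function(j) {
    sqrt(rowSums((mu_of(j) - com)^2))
  }, numeric(K)))
  # pairwise distances per draw, vectorised over draws
  pair_d <- array(Inf, c(K, s, s))
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      dij <- sqrt(rowSums((mu_of(i) - mu_of(j))^2))
      pair_d[, i, j] <- dij
      pair_d[, j, i] <- dij
    }
  }
  nn <- vapply(seq_len(s), function(j) {
    do.call(pmin, lapply(seq_len(s)[-j], function(i) pair_d[, j, i]))
  }, numeric(K))
  nnd <- rowMeans(nn)
  sdnnd <- sqrt(rowMeans((nn - nnd)^2))
  rng <- vapply(seq_len(d), function(a) {
    m <- matrix(mu_arr[, a, ], K, s)
    apply(m, 1, max) - apply(m, 1, min)
  }, numeric(K))
  colnames(rng) <- paste0("range_", axes)
  draws <- data.frame(cd = cd, nnd = nnd, sdnnd = sdnnd)
  draws <- cbind(draws, as.data.frame(rng))
  summ <- do.call(rbind, lapply(names(draws), function(m) {
    cbind(metric = m, summarize_posterior(draws[[m]], "mean_q025_q975"))
  }))
  rownames(summ) <- NULL
  structure(list(draws = draws, summary = summ,
                 species = names(posteriors), axis_names = axes, K = K),
            class = "layman_draws")
}

#' @export
print.layman_draws <- function(x, digits = 4, ...) {
  cat("Layman community metrics over", x$K, "posterior draws (",
      length(x$species), "species,", length(x$axis_names), "axes )\n")
  print.data.frame(x$summary, digits = digits, row.names = FALSE)
  invisible(x)
}
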