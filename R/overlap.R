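# Directional Monte-Carlo niche overlap: the probability that an individual
# of group A falls inside group B's alpha-probability niche region,
# propagated over paired posterior draws.

#' Directional niche overlap between two posteriors
#'
#' For each paired posterior draw k, estimates the probability that a point
#' drawn from `from`'s normal (mu_from_k, Sigma_from_k) falls inside `onto`'s
#' alpha-probability ellipsoid \{x : (x - mu_onto_k)' Sigma_onto_k^-1
#' (x - mu_onto_k) <= qchisq(alpha, d)\}, using `n_mc` Monte-Carlo points.
#' The measure is directional: overlap of A onto B generally differs from
#' B onto A.
#'
#' @param from,onto `niche_posterior` objects with matching axes and draw
#'   counts.
#' @param alpha Probability mass defining the `onto` niche region
#'   (default 0.95).
#' @param n_mc Monte-Carlo points per posterior draw (>= 100, default 1000).
#' @param seed Optional integer seed.
#' @return An `overlap_result`: list with `from_group`, `onto_group`,
#'   `alpha`, `overlap_draws` (K probabilities in \[0, 1\]), and summary
#'   statistics `mean`, `mode`, `q025`, `q975`.
#' @export
niche_overlap <- function(from, onto, alpha = 0.95, n_mc = 1000, seed = NULL) {
  stopifnot(inherits(from, "niche_posterior"), inherits(onto, "niche_posterior"))
  if (!identical(from$axis_names, onto$axis_names)) {
    stop("axis names of 'from' and 'onto' posteriors do not match", call. = FALSE)
  }
  if (from$K != onto$K) stop("posterior draw counts differ", call. = FALSE)
  if (n_mc < 100) stop("n_mc must be >= 100", call. = FALSE)
  set_seed_if(seed)
  d <- from$d
  K <- from$K
  thresh <- stats::qchisq(alpha, df = d)
  draws <- numeric(K)
  for (k in seq_len(K)) {
    x <- rmvn(n_mc, from$mu[k, ], from$sigma[, , k])
    r_onto <- chol(onto$sigma[, , k])
    md <- mahalanobis_sq(x, onto$mu[k, ], r_onto)
    draws[k] <- mean(md <= thresh)
  }
  structure(list(from_group = from$group, onto_group = onto$group,
                 alpha = alpha, n_mc = as.integer(n_mc),
                 overlap_draws = draws,
                 mean = mean(draws), mode = density_mode(draws),
                 q025 = unname(stats::quantile(draws, 0.025)),
                 q975 = unname(stats::quantile(draws, 0.975))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Directional niche overlap %s -> %s (alpha = %.2f)\n",
              x$from_group, x$onto_group, x$alpha))
  cat(sprintf("  posterior mean %.3f, mode %.3f, 95%% CrI [%.3f, %.3f]\n",
              x$mean, x$mode, x$q025, x$q975))
  invisible(x)
}

#' All directional pairwise overlaps of a fitted model
#'
#' Runs [niche_overlap()] for every ordered pair of estimable groups.
#'
#' @param fit A `niche_fit`.
#' @param alpha Probability mass of the target niche region.
#' @param n_mc Monte-Carlo points per posterior draw.
#' @param seed Optional integer seed (pair sub-seeds derived from it).
#' @return Data frame with one row per directed pair: `from`, `onto`,
#'   `mean`, `mode`, `q025`, `q975` (probabilities in \[0, 1\]).
#' @export
pairwise_overlap <- function(fit, alpha = 0.95, n_mc = 1000, seed = NULL) {
  stopifnot(inherits(fit, "niche_fit"))
  groups <- names(fit$posteriors)
  pairs <- expand.grid(from = groups, onto = groups,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$onto, , drop = FALSE]
  set_seed_if(seed)
  sub_seeds <- if (is.null(seed)) rep(list(NULL), nrow(pairs)) else
    as.list(draw_seeds(nrow(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ov <- niche_overlap(fit$posteriors[[pairs$from[i]]],
                        fit$posteriors[[pairs$onto[i]]],
                        alpha = alpha, n_mc = n_mc, seed = sub_seeds[[i]])
    data.frame(from = pairs$from[i], onto = pairs$onto[i],
               mean = ov$mean, mode = ov$mode, q025 = ov$q025,
               q975 = ov$q975, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
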