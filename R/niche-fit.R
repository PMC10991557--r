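# Bayesian multivariate-normal niche model. Under the non-informative prior
# p(mu, Sigma) proportional to |Sigma|^-(d+1)/2, the posterior given n
# observations with sample mean xbar and centred sum-of-squares S is
#   Sigma | X ~ Inverse-Wishart(scale = S, dof = n - 1)
#   mu | Sigma, X ~ Normal(xbar, Sigma / n)
# which is the conjugate posterior conventionally used for isotopic niche
# regions.

#' Posterior draws of a group's niche centroid and covariance
#'
#' Draws `K` independent (mu, Sigma) pairs from the non-informative conjugate
#' posterior of a multivariate normal fitted to one group's coordinates:
#' Sigma from an inverse-Wishart with scale the centred sum-of-squares matrix
#' and n - 1 degrees of freedom (sampled via [stats::rWishart()] on the
#' precision scale), then mu given Sigma from a normal centred on the sample
#' mean with covariance Sigma / n.
#'
#' @param coords Numeric n x d matrix of one group's niche coordinates.
#' @param K Number of posterior draws (default 10000).
#' @param seed Integer seed; identical coords and seed reproduce the draws.
#' @param group Group label carried in the result (used in error messages).
#' @return A `niche_posterior`: list with `group`, `axis_names`, `mu`
#'   (K x d), `sigma` (d x d x K), `K`, `n`, `seed`.
#' @export
sample_posterior <- function(coords, K = 10000, seed = NULL, group = "group") {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- ncol(coords)
  if (n < d + 2) {
    stop(sprintf(paste0("insufficient samples for a proper %d-dimensional",
                        " posterior in group '%s' (n = %d, need >= %d)"),
                 d, group, n, d + 2), call. = FALSE)
  }
  stopifnot(K >= 1)
  axis_names <- colnames(coords) %||% paste0("axis", seq_len(d))
  set_seed_if(seed)
  xbar <- colMeans(coords)
  S <- crossprod(sweep(coords, 2, xbar))
  # Sigma^-1 ~ Wishart(n - 1, S^-1)  <=>  Sigma ~ IW(S, n - 1)
  W <- stats::rWishart(K, df = n - 1, Sigma = chol2inv(chol(S)))
  mu <- matrix(NA_real_, K, d, dimnames = list(NULL, axis_names))
  sigma <- array(NA_real_, c(d, d, K),
                 dimnames = list(axis_names, axis_names, NULL))
  z <- matrix(stats::rnorm(K * d), K, d)
  for (k in seq_len(K)) {
    sig <- chol2inv(chol(W[, , k]))
    sig <- (sig + t(sig)) / 2
    sigma[, , k] <- sig
    mu[k, ] <- xbar + drop(z[k, ] %*% chol(sig)) / sqrt(n)
  }
  structure(list(group = group, axis_names = axis_names, mu = mu,
                 sigma = sigma, K = as.integer(K), n = n, d = d,
                 seed = seed),
            class = "niche_posterior")
}

#' @export
print.niche_posterior <- function(x, ...) {
  cat("Niche posterior for '", x$group, "': ", x$K, " draws in ",
      x$d, "-D (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Fit Bayesian multivariate-normal niche models per group
#'
#' The central fitting function. For each group (species, or species-period)
#' it draws `K` posterior (centroid, covariance) pairs under the
#' non-informative conjugate prior (see [sample_posterior()]). Groups with
#' too few samples for a proper d-dimensional posterior (n < d + 2) are
#' reported as not estimable rather than silently regularised.
#'
#' @param x A `dimension_space` (groups taken from its species labels), a
#'   formula of the form `cbind(axis1, axis2, ...) ~ group` evaluated in
#'   `data`, or a numeric coordinate matrix.
#' @param ... Passed on to methods.
#' @return A `niche_fit` object: list of `niche_posterior`s (`posteriors`),
#'   with `axis_names`, `K`, `seed`, the group sample sizes (`n`), any
#'   `not_estimable` groups, and the grouped coordinates (`coords`).
#' @seealso [summary.niche_fit()], [pairwise_overlap()], [layman_metrics()],
#'   [compare_groups()]
#' @examples
#' eggs <- default_community(seed = 1)
#' space <- build_dimension_space(complete_case_filter(eggs), "2D")
#' fit <- niche_fit(space, K = 500, seed = 1)
#' summary(fit)
#' @export
niche_fit <- function(x, ...) UseMethod("niche_fit")

#' @rdname niche_fit
#' @param group Character or factor vector of group labels, one per row of
#'   the coordinate matrix.
#' @param K Posterior draws per group (default 10000; published analyses of
#'   this kind typically use 100000).
#' @param seed Integer seed; per-group sub-seeds are derived from it.
#' @export
niche_fit.default <- function(x, group, K = 10000, seed = NULL, ...) {
  coords <- as.matrix(x)
  stopifnot(length(group) == nrow(coords))
  group <- as.character(group)
  set_seed_if(seed)
  groups <- unique(group)
  sub_seeds <- if (is.null(seed)) rep(list(NULL), length(groups)) else
    as.list(draw_seeds(length(groups)))
  posteriors <- list()
  not_estimable <- character(0)
  n_by_group <- integer(0)
  coords_by_group <- list()
  d <- ncol(coords)
  for (i in seq_along(groups)) {
    g <- groups[i]
    xg <- coords[group == g, , drop = FALSE]
    n_by_group[g] <- nrow(xg)
    coords_by_group[[g]] <- xg
    if (nrow(xg) < d + 2) {
      not_estimable <- c(not_estimable, g)
    } else {
      posteriors[[g]] <- sample_posterior(xg, K = K, seed = sub_seeds[[i]],
                                          group = g)
    }
  }
  if (!length(posteriors)) {
    stop("no group has enough samples for a proper posterior", call. = FALSE)
  }
  structure(list(posteriors = posteriors,
                 axis_names = colnames(coords) %||% paste0("axis", seq_len(d)),
                 d = d, K = as.integer(K), seed = seed,
                 n = n_by_group, not_estimable = not_estimable,
                 coords = coords_by_group,
                 approach = NULL,
                 call = match.call()),
            class = "niche_fit")
}

#' @rdname niche_fit
#' @export
niche_fit.dimension_space <- function(x, K = 10000, seed = NULL, ...) {
  fit <- niche_fit.default(x$coords, group = x$species, K = K, seed = seed)
  fit$approach <- x$approach
  fit$call <- match.call()
  fit
}

#' @rdname niche_fit
#' @param formula A formula `cbind(axis1, ...) ~ group`.
#' @param data Data frame in which the formula is evaluated.
#' @export
niche_fit.formula <- function(x, data, K = 10000, seed = NULL, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  if (is.null(dim(y))) y <- matrix(y, dimnames = list(NULL, deparse(x[[2]])))
  g <- mf[[2]]
  fit <- niche_fit.default(y, group = g, K = K, seed = seed)
  fit$call <- match.call()
  fit
}

#' @export
print.niche_fit <- function(x, ...) {
  cat("Bayesian multivariate-normal niche model",
      if (!is.null(x$approach)) paste0("(", x$approach, " space)"), "\n")
  cat("Axes:", paste(x$axis_names, collapse = ", "), "\n")
  cat("Groups (n):",
      paste(sprintf("%s (%d)", names(x$n), x$n), collapse = ", "), "\n")
  cat("Posterior draws per group:", x$K, "\n")
  if (length(x$not_estimable)) {
    cat("Not estimable (n < d + 2):",
        paste(x$not_estimable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior-mean centroids
#'
#' @param object A `niche_fit`.
#' @param ... Unused.
#' @return Matrix of posterior-mean centroid coordinates, one row per group.
#' @export
coef.niche_fit <- function(object, ...) {
  t(vapply(object$posteriors, function(p) colMeans(p$mu),
           numeric(object$d)))
}

#' Posterior niche-size summary
#'
#' Computes the posterior distribution of each group's niche hypervolume
#' (the alpha-probability ellipsoid volume, see [niche_size()]) and
#' summarises it by its kernel-density mode and quantiles.
#'
#' @param object A `niche_fit`.
#' @param alpha Probability mass enclosed by the niche region (default 0.95).
#' @param ... Unused.
#' @return A `summary.niche_fit` data frame with one row per group:
#'   `group`, `n`, `mode`, `q05`, `q95`, `mean`, `q025`, `q975`.
#' @export
summary.niche_fit <- function(object, alpha = 0.95, ...) {
  rows <- lapply(names(object$posteriors), function(g) {
    sz <- niche_size_draws(object$posteriors[[g]], alpha = alpha)
    q <- stats::quantile(sz, c(0.05, 0.95, 0.025, 0.975), names = FALSE)
    data.frame(group = g, n = object$n[[g]],
               mode = density_mode(sz), q05 = q[1], q95 = q[2],
               mean = mean(sz), q025 = q[3], q975 = q[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (length(object$not_estimable)) {
    ne <- data.frame(group = object$not_estimable,
                     n = as.integer(object$n[object$not_estimable]),
                     mode = NA_real_, q05 = NA_real_, q95 = NA_real_,
                     mean = NA_real_, q025 = NA_real_, q975 = NA_real_,
                     stringsAsFactors = FALSE)
    out <- rbind(out, ne)
  }
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "approach") <- object$approach
  class(out) <- c("summary.niche_fit", "data.frame")
  out
}

#' @export
print.summary.niche_fit <- function(x, digits = 4, ...) {
  cat("Posterior niche size (", 100 * attr(x, "alpha"),
      "% ellipsoid volume)", sep = "")
  if (!is.null(attr(x, "approach"))) cat(", ", attr(x, "approach"), " space", sep = "")
  cat("\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Simulate from the posterior predictive distribution
#'
#' For each requested point, picks a posterior draw uniformly at random and
#' samples one observation from the corresponding multivariate normal —
#' i.e. draws from each group's posterior predictive distribution.
#'
#' @param object A `niche_fit`.
#' @param nsim Points per group.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `group` and one column per axis.
#' @export
simulate.niche_fit <- function(object, nsim = 1, seed = NULL, ...) {
  set_seed_if(seed)
  out <- lapply(names(object$posteriors), function(g) {
    p <- object$posteriors[[g]]
    ks <- sample.int(p$K, nsim, replace = TRUE)
    pts <- t(vapply(ks, function(k) {
      p$mu[k, ] + drop(stats::rnorm(p$d) %*% chol(p$sigma[, , k]))
    }, numeric(p$d)))
    colnames(pts) <- p$axis_names
    cbind(data.frame(group = g, stringsAsFactors = FALSE), as.data.frame(pts))
  })
  do.call(rbind, out)
}

#' Plot a fitted niche model
#'
#' Scatterplot of the raw coordinates on two chosen axes with each group's
#' posterior-mean alpha-probability ellipse.
#'
#' @param x A `niche_fit`.
#' @param axes Length-2 integer or character selection of axes (ignored for
#'   one-dimensional fits).
#' @param alpha Ellipse probability mass.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.niche_fit <- function(x, axes = c(1, 2), alpha = 0.95, ...) {
  groups <- names(x$coords)
  cols <- seq_along(groups)
  names(cols) <- groups
  if (x$d == 1L) {
    all_pts <- do.call(rbind, lapply(groups, function(g)
      cbind(x$coords[[g]][, 1], match(g, groups))))
    graphics::plot(all_pts[, 1], all_pts[, 2], col = all_pts[, 2], pch = 19,
                   xlab = x$axis_names[1], ylab = "group", yaxt = "n", ...)
    graphics::axis(2, at = seq_along(groups), labels = groups, las = 1)
    return(invisible(x))
  }
  pts <- do.call(rbind, lapply(groups, function(g) x$coords[[g]][, axes,
                                                                 drop = FALSE]))
  graphics::plot(pts, col = rep(cols, vapply(x$coords, nrow, 1L)), pch = 19,
                 xlab = x$axis_names[axes][1], ylab = x$axis_names[axes][2],
                 ...)
  theta <- seq(0, 2 * pi, length.out = 181)
  r <- sqrt(stats::qchisq(alpha, df = 2))
  for (g in names(x$posteriors)) {
    p <- x$posteriors[[g]]
    mu <- colMeans(p$mu)[axes]
    sig <- apply(p$sigma, c(1, 2), mean)[axes, axes]
    ell <- sweep(r * cbind(cos(theta), sin(theta)) %*% chol(sig), 2, mu, `+`)
    graphics::lines(ell, col = cols[[g]])
  }
  graphics::legend("topright", legend = groups, col = cols, pch = 19,
                   cex = 0.8, bty = "n")
  invisible(x)
}
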