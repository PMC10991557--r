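# Niche size: volume of the alpha-probability ellipsoid of a multivariate
# normal,
#   V = [2 pi^(d/2) / (d Gamma(d/2))] * (chi2_{d,alpha})^(d/2) * |Sigma|^(1/2)
# i.e. the volume of the unit d-ball scaled by the ellipsoid semi-axes.

#' Volume of the alpha-probability niche ellipsoid
#'
#' For a multivariate normal with covariance `sigma`, the niche region at
#' probability `alpha` is the central ellipsoid containing `alpha` of the
#' probability mass; its volume is
#' `2 pi^(d/2) / (d Gamma(d/2)) * qchisq(alpha, d)^(d/2) * sqrt(det(sigma))`,
#' in axis units to the power d.
#'
#' @param sigma d x d positive-definite covariance matrix (a scalar is
#'   treated as a 1x1 matrix).
#' @param alpha Probability mass in (0, 1), default 0.95.
#' @return The hypervolume (scalar).
#' @examples
#' niche_size(diag(2))            # pi * qchisq(0.95, 2) ~ 18.82
#' @export
niche_size <- function(sigma, alpha = 0.95) {
  if (!is.matrix(sigma)) sigma <- matrix(sigma, 1, 1)
  check_spd(sigma, "sigma", sym_tol = 1e-8)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  d <- nrow(sigma)
  unit_ball <- 2 * pi^(d / 2) / (d * gamma(d / 2))
  unit_ball * stats::qchisq(alpha, df = d)^(d / 2) *
    sqrt(det(sigma))
}

#' Posterior draws of niche size
#'
#' Applies [niche_size()] to every posterior covariance draw.
#'
#' @param posterior A `niche_posterior` (see [sample_posterior()]).
#' @param alpha Probability mass, default 0.95.
#' @return Numeric vector of K hypervolumes.
#' @export
niche_size_draws <- function(posterior, alpha = 0.95) {
  stopifnot(inherits(posterior, "niche_posterior"))
  d <- posterior$d
  unit_ball <- 2 * pi^(d / 2) / (d * gamma(d / 2))
  scale <- unit_ball * stats::qchisq(alpha, df = d)^(d / 2)
  dets <- apply(posterior$sigma, 3, det)
  scale * sqrt(dets)
}
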