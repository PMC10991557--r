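# Synthetic multi-species isotope communities with planted latent niche
# structure. Each species occupies a multivariate-normal region on five
# latent axes (carbon source, secondary carbon, nitrogen baseline, trophic
# nitrogen, sulphur); a fixed loading map projects latent positions onto the
# 21 observed tracers with additive Gaussian noise.

latent_axes <- c("c_source", "c_secondary", "n_baseline", "n_trophic", "sulphur")

#' Specify one synthetic species
#'
#' Describes a species' latent niche: its centroid and covariance on the five
#' latent axes (`c_source`, `c_secondary`, `n_baseline`, `n_trophic`,
#' `sulphur`, unitless latent scale), its sample count and collection-year
#' range, and an optional second-period effect (a centroid shift plus a
#' covariance scale factor applied to samples collected in the later period).
#'
#' @param name Species label.
#' @param n_samples Number of samples (>= 0).
#' @param latent_mean Numeric 5-vector: latent centroid.
#' @param latent_cov 5x5 symmetric positive-definite latent covariance.
#' @param year_range Inclusive integer pair of collection years.
#' @param period_shift Optional 5-vector added to `latent_mean` for samples
#'   in the second period.
#' @param period_cov_scale Optional positive scalar multiplying `latent_cov`
#'   in the second period (values < 1 shrink the niche).
#' @param site Site label attached to every sample.
#' @return A `species_spec` list.
#' @export
species_spec <- function(name, n_samples, latent_mean,
                         latent_cov = diag(0.25, 5),
                         year_range = c(1970L, 2006L),
                         period_shift = NULL, period_cov_scale = NULL,
                         site = "synthetic_site") {
  stopifnot(is.character(name), length(name) == 1L,
            is_scalar_number(n_samples), n_samples >= 0,
            is.numeric(latent_mean), length(latent_mean) == 5L,
            length(year_range) == 2L, year_range[1] <= year_range[2])
  check_spd(latent_cov, "latent_cov")
  if (!is.null(period_shift)) {
    stopifnot(is.numeric(period_shift), length(period_shift) == 5L)
  }
  if (!is.null(period_cov_scale)) {
    if (!is_scalar_number(period_cov_scale) || period_cov_scale <= 0) {
      stop("period_cov_scale must be a positive scalar", call. = FALSE)
    }
  }
  structure(list(name = name, n_samples = as.integer(n_samples),
                 latent_mean = stats::setNames(as.numeric(latent_mean), latent_axes),
                 latent_cov = latent_cov,
                 year_range = as.integer(year_range),
                 period_shift = period_shift,
                 period_cov_scale = period_cov_scale,
                 site = site),
            class = "species_spec")
}

#' Map latent niche axes to observed tracers
#'
#' The loading matrix sends the five latent axes to the 21 observed tracers
#' (ten amino-acid delta13C, ten amino-acid delta15N, bulk delta34S, in that
#' order) as `loading %*% latent + intercepts + noise`. Bulk delta13C and
#' delta15N are generated afterwards as weighted means of the amino-acid
#' values plus independent noise, planting the proxy correlations the
#' dimension-validation step looks for.
#'
#' @param loading 21x5 numeric matrix.
#' @param intercepts Numeric 21-vector (permil).
#' @param noise_sd Numeric 21-vector of non-negative tracer noise SDs (permil).
#' @param bulk_c_weights,bulk_n_weights Numeric 10-vectors summing to 1;
#'   weights of the amino acids in the bulk values.
#' @param bulk_noise_sd Length-2 vector: noise SD of bulk delta13C and
#'   delta15N (permil).
#' @return A `tracer_map` list.
#' @export
tracer_map <- function(loading, intercepts, noise_sd,
                       bulk_c_weights = rep(0.1, 10),
                       bulk_n_weights = rep(0.1, 10),
                       bulk_noise_sd = c(0.3, 0.3)) {
  stopifnot(is.matrix(loading), nrow(loading) == 21L, ncol(loading) == 5L,
            is.numeric(intercepts), length(intercepts) == 21L,
            is.numeric(noise_sd), length(noise_sd) == 21L,
            length(bulk_c_weights) == 10L, length(bulk_n_weights) == 10L,
            length(bulk_noise_sd) == 2L, all(bulk_noise_sd >= 0))
  if (any(noise_sd < 0)) stop("noise_sd must be elementwise >= 0", call. = FALSE)
  if (abs(sum(bulk_c_weights) - 1) > 1e-10 || abs(sum(bulk_n_weights) - 1) > 1e-10) {
    stop("bulk weights must sum to 1", call. = FALSE)
  }
  tracers <- c(paste0(aa_names, "_c"), paste0(aa_names, "_n"), "bulk_s")
  dimnames(loading) <- list(tracers, latent_axes)
  structure(list(loading = loading,
                 intercepts = stats::setNames(as.numeric(intercepts), tracers),
                 noise_sd = stats::setNames(as.numeric(noise_sd), tracers),
                 bulk_c_weights = as.numeric(bulk_c_weights),
                 bulk_n_weights = as.numeric(bulk_n_weights),
                 bulk_noise_sd = as.numeric(bulk_noise_sd)),
            class = "tracer_map")
}

#' Default tracer map
#'
#' All amino-acid delta13C tracers load near-equally on the carbon-source
#' axis, with a secondary carbon axis loading mainly on proline and the
#' other non-essential amino acids; all delta15N tracers load on the
#' nitrogen baseline, with the trophic axis loading on the trophic amino
#' acids (Ala, Asp, Glx, Ile, Leu, Pro, Val) and not on the source amino
#' acids (Gly, Lys, Phe); bulk delta34S loads on the sulphur axis alone.
#' Intercepts and noise are typical seabird-egg magnitudes (delta13C near
#' -22 permil, delta15N near +12 permil, delta34S near +17 permil, residual
#' SD 0.5 permil).
#'
#' @return A `tracer_map`.
#' @export
default_tracer_map <- function() {
  loading <- matrix(0, 21, 5)
  # carbon tracers: rows 1-10 in aa_names order
  loading[1:10, 1] <- c(1.0, 0.9, 1.1, 0.95, 1.05, 0.9, 1.0, 1.1, 0.95, 1.05)
  # secondary carbon: proline dominates, smaller weight on other
  # non-essential AAs (ala, gly, asp, glx)
  loading[1:10, 2] <- c(0.3, 0, 0.3, 0, 0, 1.2, 0.3, 0, 0.3, 0)
  # nitrogen tracers: rows 11-20
  loading[11:20, 3] <- c(1.0, 1.05, 0.95, 1.0, 1.0, 0.95, 1.05, 1.0, 1.0, 0.95)
  trophic_aa <- aa_names %in% c("ala", "val", "ile", "leu", "pro", "asp", "glx")
  loading[11:20, 4] <- ifelse(trophic_aa, 1.0, 0.05)
  loading[21, 5] <- 1.0
  intercepts <- c(seq(-24, -20, length.out = 10),  # AA d13C
                  seq(9, 15, length.out = 10),     # AA d15N
                  17)                              # bulk d34S
  tracer_map(loading = loading, intercepts = intercepts,
             noise_sd = rep(0.5, 21))
}

#' Generate a synthetic isotope community
#'
#' Draws each species' latent positions from its multivariate normal,
#' projects them onto the 21 tracers through the tracer map with additive
#' Gaussian noise, assigns collection years uniformly over the species'
#' year range, and derives bulk delta13C/delta15N as weighted amino-acid
#' means plus noise. Samples whose year falls at or after `period_cut`
#' receive the species' optional second-period effect (centroid shift,
#' covariance scale). Identical inputs and seed reproduce the dataset
#' exactly.
#'
#' @param specs List of [species_spec()] objects, at least one with
#'   `n_samples >= 1`.
#' @param map A [tracer_map()]; defaults to [default_tracer_map()].
#' @param seed Integer seed.
#' @param period_cut First year of the second period (default 1990).
#' @return An `isotope_dataset`.
#' @export
generate_community <- function(specs, map = default_tracer_map(),
                               seed = NULL, period_cut = 1990L) {
  if (!length(specs)) stop("at least one species_spec is required", call. = FALSE)
  if (inherits(specs, "species_spec")) specs <- list(specs)
  lapply(specs, function(s) {
    if (!inherits(s, "species_spec")) stop("specs must be species_spec objects",
                                           call. = FALSE)
  })
  if (!inherits(map, "tracer_map")) stop("map must be a tracer_map", call. = FALSE)
  if (sum(vapply(specs, function(s) s$n_samples, 1L)) < 1L) {
    stop("total n_samples must be >= 1", call. = FALSE)
  }
  set_seed_if(seed)
  rows <- list()
  counter <- 0L
  for (s in specs) {
    if (s$n_samples == 0L) next
    years <- sample(seq(s$year_range[1], s$year_range[2]), s$n_samples,
                    replace = TRUE)
    in_p2 <- years >= period_cut
    mean1 <- s$latent_mean
    cov1 <- s$latent_cov
    mean2 <- mean1 + (s$period_shift %||% rep(0, 5))
    cov2 <- cov1 * (s$period_cov_scale %||% 1)
    latent <- matrix(NA_real_, s$n_samples, 5)
    if (any(!in_p2)) latent[!in_p2, ] <- rmvn(sum(!in_p2), mean1, cov1)
    if (any(in_p2)) latent[in_p2, ] <- rmvn(sum(in_p2), mean2, cov2)
    tracers <- latent %*% t(map$loading) +
      matrix(map$intercepts, s$n_samples, 21, byrow = TRUE) +
      matrix(stats::rnorm(s$n_samples * 21, sd = rep(map$noise_sd,
                                                     each = s$n_samples)),
             s$n_samples, 21)
    aa_c <- tracers[, 1:10, drop = FALSE]
    aa_n <- tracers[, 11:20, drop = FALSE]
    bulk_c <- as.numeric(aa_c %*% map$bulk_c_weights) +
      stats::rnorm(s$n_samples, sd = map$bulk_noise_sd[1])
    bulk_n <- as.numeric(aa_n %*% map$bulk_n_weights) +
      stats::rnorm(s$n_samples, sd = map$bulk_noise_sd[2])
    df <- data.frame(sample_id = sprintf("%s_%03d", s$name,
                                         seq_len(s$n_samples) + counter),
                     species = s$name, year = years, site = s$site,
                     stringsAsFactors = FALSE)
    colnames(aa_c) <- paste0(aa_names, "_c")
    colnames(aa_n) <- paste0(aa_names, "_n")
    df <- cbind(df, aa_c, aa_n,
                data.frame(bulk_c = bulk_c, bulk_n = bulk_n,
                           bulk_s = tracers[, 21]))
    counter <- counter + s$n_samples
    rows[[length(rows) + 1L]] <- df
  }
  isotope_dataset(do.call(rbind, rows), allow_missing = FALSE)
}

#' Packaged five-species synthetic community
#'
#' A 63-sample, five-species configuration mimicking a coastal seabird
#' assemblage: a storm-petrel analogue far from all others (distinct
#' nitrogen baseline and sulphur), two alcid analogues separated only on the
#' carbon-source and sulphur axes, and two cormorant analogues close on all
#' axes but with the larger-sample generalist slightly higher-trophic. The
#' per-species sample allocation (18/16/11/9/9) is configurable via
#' `n_samples`.
#'
#' @param seed Integer seed.
#' @param n_samples Named or positional integer 5-vector of per-species
#'   sample counts (cormorant_generalist, cormorant_pelagic, auklet,
#'   murrelet, storm_petrel); must keep every species estimable in 5-D
#'   (n >= 7).
#' @return An `isotope_dataset` with 5 species.
#' @export
default_community <- function(seed = NULL,
                              n_samples = c(18L, 16L, 11L, 9L, 9L)) {
  stopifnot(length(n_samples) == 5L)
  cov0 <- diag(0.25, 5)
  specs <- list(
    species_spec("cormorant_generalist", n_samples[1],
                 latent_mean = c(0.3, 1.2, 0.5, 1.5, 0), latent_cov = cov0),
    species_spec("cormorant_pelagic", n_samples[2],
                 latent_mean = c(0.0, 0.6, 0.5, 1.0, 0), latent_cov = cov0),
    species_spec("rhinoceros_auklet", n_samples[3],
                 latent_mean = c(0.0, 0.0, 0.0, 0.3, -0.5), latent_cov = cov0),
    species_spec("ancient_murrelet", n_samples[4],
                 latent_mean = c(2.0, 0.0, 0.0, 0.0, 1.5), latent_cov = cov0),
    species_spec("storm_petrel", n_samples[5],
                 latent_mean = c(2.5, 0.0, 2.0, 0.0, 2.0), latent_cov = cov0))
  generate_community(specs, default_tracer_map(), seed = seed)
}
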