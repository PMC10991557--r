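# Dimension spaces: scaled PCA on the amino-acid delta13C and delta15N
# matrices, standardized bulk delta34S, and the fixed axis sets of the four
# dimensional approaches.

approach_axes <- list(
  "1D" = "PC1-Nss",
  "2D" = c("PC1-Css", "PC1-Nss"),
  "3D" = c("PC1-Css", "PC1-Nss", "stdDeltaS"),
  "5D" = c("PC1-Css", "PC1-Nss", "stdDeltaS", "PC2-Css", "PC2-Nss"))

#' Scaled principal component analysis with a fixed sign convention
#'
#' Centres and unit-scales each column, then eigen-decomposes the
#' correlation structure (via [stats::prcomp()]). The sign of each component
#' is fixed so that its largest-magnitude loading is positive, making
#' results invariant to row order and to positive column rescaling.
#' Per-variable contributions are squared loadings in percent, summing
#' to 100 per component.
#'
#' @param x Numeric matrix (samples x variables), no missing values, every
#'   column with positive variance. Column names label the variables.
#' @return A `pca_model` with elements `variable_names`, `center`, `scale`,
#'   `loadings` (orthonormal, columns = components), `explained_fraction`,
#'   `contributions_pct`, `scores`, `sdev`.
#' @export
fit_pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least two samples are required", call. = FALSE)
  if (anyNA(x)) stop("x contains missing values", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  vars <- apply(x, 2, stats::var)
  if (any(vars <= 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[vars <= 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  loadings <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(variable_names = colnames(x),
                 center = pc$center, scale = pc$scale,
                 loadings = loadings,
                 explained_fraction = ev / sum(ev),
                 contributions_pct = 100 * loadings^2,
                 scores = scores, sdev = pc$sdev),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("Scaled PCA on", length(x$variable_names), "variables,",
      nrow(x$scores), "samples\n")
  cat("Explained variance (%):",
      paste(sprintf("%.1f", 100 * x$explained_fraction[1:min(5, length(x$explained_fraction))]),
            collapse = ", "), "...\n")
  invisible(x)
}

# Project new data onto a fitted pca_model.
#' @noRd
pca_scores <- function(model, x) {
  scale(as.matrix(x), center = model$center, scale = model$scale) %*%
    model$loadings
}

#' Build an n-dimensional niche space
#'
#' Runs [fit_pca()] independently on the amino-acid delta13C and delta15N
#' matrices of a complete-case dataset, standardizes bulk delta34S to
#' `stdDeltaS` (mean 0, variance 1), and assembles the axis set of the
#' requested dimensional approach:
#' \describe{
#'   \item{1D}{PC1-Nss}
#'   \item{2D}{PC1-Css, PC1-Nss}
#'   \item{3D}{PC1-Css, PC1-Nss, stdDeltaS}
#'   \item{5D}{PC1-Css, PC1-Nss, stdDeltaS, PC2-Css, PC2-Nss}
#' }
#'
#' @param dataset A complete-case `isotope_dataset` (see
#'   [complete_case_filter()]).
#' @param approach One of `"1D"`, `"2D"`, `"3D"`, `"5D"`.
#' @return A `dimension_space`: list with `approach`, `axis_names`, `coords`
#'   (n x d matrix), `sample_id`, `species`, `year`, and the two fitted
#'   `pca_model`s (`pca_c`, `pca_n`) plus the sulphur standardization
#'   (`s_center`, `s_scale`).
#' @export
build_dimension_space <- function(dataset, approach = c("5D", "1D", "2D", "3D")) {
  approach <- match.arg(approach)
  dataset <- isotope_dataset(dataset)
  needed <- c(paste0(aa_names, "_c"), paste0(aa_names, "_n"), "bulk_s")
  if (anyNA(dataset[needed])) {
    stop("dataset has missing tracer values; apply complete_case_filter() first",
         call. = FALSE)
  }
  xc <- as.matrix(dataset[paste0(aa_names, "_c")])
  xn <- as.matrix(dataset[paste0(aa_names, "_n")])
  colnames(xc) <- colnames(xn) <- aa_names
  pca_c <- fit_pca(xc)
  pca_n <- fit_pca(xn)
  s_center <- mean(dataset$bulk_s)
  s_scale <- stats::sd(dataset$bulk_s)
  if (s_scale <= 0) stop("bulk_s has zero variance", call. = FALSE)
  std_s <- (dataset$bulk_s - s_center) / s_scale
  all_axes <- cbind("PC1-Css" = pca_c$scores[, 1],
                    "PC1-Nss" = pca_n$scores[, 1],
                    "stdDeltaS" = std_s,
                    "PC2-Css" = pca_c$scores[, 2],
                    "PC2-Nss" = pca_n$scores[, 2])
  axes <- approach_axes[[approach]]
  coords <- all_axes[, axes, drop = FALSE]
  rownames(coords) <- dataset$sample_id
  structure(list(approach = approach, axis_names = axes, coords = coords,
                 sample_id = dataset$sample_id, species = dataset$species,
                 year = dataset$year,
                 pca_c = pca_c, pca_n = pca_n,
                 s_center = s_center, s_scale = s_scale),
            class = "dimension_space")
}

#' @export
print.dimension_space <- function(x, ...) {
  cat(x$approach, "niche space:", nrow(x$coords), "samples,",
      length(unique(x$species)), "species\n")
  cat("Axes:", paste(x$axis_names, collapse = ", "), "\n")
  invisible(x)
}

#' Amino-acid trophic indices
#'
#' Computes, per sample, the delta15N spreads Glx-Lys and Glx-Phe, the
#' single-amino-acid trophic position
#' `TP = (d15N_Glx - d15N_Phe - beta) / tdf + 1`, and a multi-amino-acid
#' version using the mean of a trophic set minus the mean of a source set.
#' `beta` is the producer-level Glx-Phe offset and `tdf` the per-step
#' trophic discrimination factor, both in permil; the conventional 3.4 and
#' 7.6 permil defaults can be overridden.
#'
#' @param dataset An `isotope_dataset` with amino-acid delta15N present.
#' @param beta Baseline offset (permil), default 3.4.
#' @param tdf Trophic discrimination factor (permil), default 7.6; must be
#'   non-zero.
#' @param trophic_set,source_set Amino-acid codes used by `tp_mean`.
#' @return Data frame with `sample_id`, `species`, `glx_minus_lys`,
#'   `glx_minus_phe`, `tp_single`, `tp_mean`.
#' @export
trophic_indices <- function(dataset, beta = 3.4, tdf = 7.6,
                            trophic_set = c("glx", "ala", "asp", "ile",
                                            "leu", "pro", "val"),
                            source_set = c("phe", "lys", "gly")) {
  dataset <- isotope_dataset(dataset)
  if (tdf == 0) stop("tdf must be non-zero", call. = FALSE)
  stopifnot(all(trophic_set %in% aa_names), all(source_set %in% aa_names))
  glx <- dataset$glx_n
  lys <- dataset$lys_n
  phe <- dataset$phe_n
  tro <- rowMeans(dataset[paste0(trophic_set, "_n")])
  src <- rowMeans(dataset[paste0(source_set, "_n")])
  data.frame(sample_id = dataset$sample_id, species = dataset$species,
             glx_minus_lys = glx - lys,
             glx_minus_phe = glx - phe,
             tp_single = (glx - phe - beta) / tdf + 1,
             tp_mean = (tro - src - beta) / tdf + 1,
             stringsAsFactors = FALSE)
}

#' Correlate niche-space axes with bulk values and trophic indices
#'
#' Pearson correlations between every axis of a dimension space and bulk
#' delta13C, bulk delta15N and each trophic index, used to check that the
#' PCA axes behave as proxies (PC1 of carbon tracks bulk carbon, PC2 of
#' nitrogen tracks trophic level). Because the component orientation is a
#' package convention, each row records the axis orientation so signed
#' external values can be matched after flipping.
#'
#' @param space A `dimension_space`.
#' @param dataset The `isotope_dataset` the space was built from (aligned
#'   by `sample_id`).
#' @param indices Optional output of [trophic_indices()]; computed from
#'   `dataset` when omitted.
#' @return Data frame with columns `axis`, `variable`, `r`, `abs_r`,
#'   `n`, `axis_orientation`.
#' @export
validate_proxies <- function(space, dataset, indices = NULL) {
  stopifnot(inherits(space, "dimension_space"))
  dataset <- isotope_dataset(dataset)
  dataset <- dataset[match(space$sample_id, dataset$sample_id), , drop = FALSE]
  if (anyNA(dataset$sample_id)) {
    stop("dataset does not contain all samples of the dimension space",
         call. = FALSE)
  }
  if (nrow(dataset) < 3L) stop("at least 3 samples are required", call. = FALSE)
  if (is.null(indices)) indices <- trophic_indices(dataset)
  targets <- cbind(bulk_c = dataset$bulk_c, bulk_n = dataset$bulk_n,
                   glx_minus_lys = indices$glx_minus_lys,
                   glx_minus_phe = indices$glx_minus_phe,
                   tp_single = indices$tp_single,
                   tp_mean = indices$tp_mean)
  out <- expand.grid(axis = space$axis_names, variable = colnames(targets),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(a, v) {
    stats::cor(space$coords[, a], targets[, v], use = "complete.obs")
  }, out$axis, out$variable)
  out$abs_r <- abs(out$r)
  out$n <- nrow(dataset)
  out$axis_orientation <- "largest-|loading| positive"
  out
}
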