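# End-to-end orchestration: configuration, the full multi-approach analysis,
# and CSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects and validates every knob of [run_pipeline()].
#'
#' @param input Path to a canonical isotope CSV, or an `isotope_dataset`.
#' @param approaches Subset of `c("1D","2D","3D","5D")`, non-empty.
#' @param K Posterior draws per group (>= 100; published analyses of this
#'   kind typically use 100000 — scale down for quick runs).
#' @param alpha Niche-region probability mass in (0, 1).
#' @param n_mc Monte-Carlo points per posterior draw for overlap.
#' @param n_bins Bhattacharyya bins.
#' @param seed Integer seed for all stochastic stages.
#' @param temporal Optional list with elements `species` (label) and
#'   optionally `split` (a [period_split()]) requesting the two-period
#'   analysis.
#' @param out_dir Output directory (created if missing).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, approaches = c("1D", "2D", "3D", "5D"),
                            K = 100000, alpha = 0.95, n_mc = 1000,
                            n_bins = 100, seed = 1L, temporal = NULL,
                            out_dir = tempfile("isoniche_run_")) {
  approaches <- match.arg(approaches, c("1D", "2D", "3D", "5D"),
                          several.ok = TRUE)
  if (!length(approaches)) stop("approaches must be non-empty", call. = FALSE)
  if (K < 100) stop("K must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.null(temporal)) {
    stopifnot(is.list(temporal), !is.null(temporal$species))
    temporal$split <- temporal$split %||% period_split()
  }
  structure(list(input = input, approaches = approaches, K = as.integer(K),
                 alpha = alpha, n_mc = as.integer(n_mc),
                 n_bins = as.integer(n_bins), seed = as.integer(seed),
                 temporal = temporal, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full multi-approach niche analysis
#'
#' Executes, per dimensional approach: complete-case filtering, dimension
#' space construction, per-species niche posteriors, niche-size summaries,
#' all directional pairwise overlaps, Layman community metrics, and all
#' pairwise comparison statistics; plus the optional two-period temporal
#' analysis. Writes one CSV per table and a JSON manifest (configuration
#' echo, seed, row counts, package version) to the output directory. Groups
#' too small for an approach are reported as not estimable and the run
#' continues.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the computed tables (`niche_sizes`,
#'   `overlaps`, `layman`, `comparisons`, `proxy_correlations`,
#'   `pca_contributions`, optional `temporal_*`) plus `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- if (inherits(config$input, "isotope_dataset")) config$input
             else read_isotope_csv(config$input)
  n_raw <- nrow(dataset)
  dataset <- complete_case_filter(dataset)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set_seed_if(config$seed)
  stage_seeds <- draw_seeds(length(config$approaches) * 3 + 1)
  size_tab <- list()
  ov_tab <- list()
  lay_tab <- list()
  cmp_tab <- list()
  contrib_tab <- list()
  proxy_tab <- list()
  si <- 0L
  for (app in config$approaches) {
    space <- build_dimension_space(dataset, app)
    fit <- niche_fit(space, K = config$K, seed = stage_seeds[si + 1])
    summ <- summary(fit, alpha = config$alpha)
    size_tab[[app]] <- cbind(approach = app, as.data.frame(summ))
    ov <- pairwise_overlap(fit, alpha = config$alpha, n_mc = config$n_mc,
                           seed = stage_seeds[si + 2])
    ov_tab[[app]] <- cbind(approach = app, ov)
    if (length(fit$posteriors) >= 2L) {
      lay <- layman_metrics(fit)
      lay_tab[[app]] <- cbind(approach = app, lay$summary)
    }
    groups <- names(fit$posteriors)
    sizes <- lapply(fit$posteriors, niche_size_draws, alpha = config$alpha)
    if (length(groups) >= 2L) {
      prs <- utils::combn(groups, 2)
      cmp_seeds <- draw_seeds(ncol(prs))
      all_axes <- approach_axes[["5D"]]
      cmp_tab[[app]] <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
        a <- prs[1, i]; b <- prs[2, i]
        cm <- compare_groups(fit$posteriors[[a]], fit$posteriors[[b]],
                             sizes[[a]], sizes[[b]], alpha = config$alpha,
                             n_bins = config$n_bins, seed = cmp_seeds[i])
        bc <- stats::setNames(rep(NA_real_, length(all_axes)),
                              paste0("bc_", all_axes))
        bc[paste0("bc_", names(cm$bc_per_axis))] <- cm$bc_per_axis
        data.frame(approach = app, group_a = a, group_b = b,
                   t(bc), bc_size = cm$bc_size,
                   p_centroid_diff = cm$p_centroid_diff,
                   centroid_distance = cm$centroid_distance,
                   check.names = FALSE, stringsAsFactors = FALSE)
      }))
    }
    contrib_tab[[app]] <- data.frame(
      approach = app,
      element = rep(c("carbon", "nitrogen"), each = length(aa_names)),
      amino_acid = rep(aa_names, 2),
      pc1_contribution_pct = c(space$pca_c$contributions_pct[, 1],
                               space$pca_n$contributions_pct[, 1]),
      pc2_contribution_pct = c(space$pca_c$contributions_pct[, 2],
                               space$pca_n$contributions_pct[, 2]),
      stringsAsFactors = FALSE)
    proxy_tab[[app]] <- cbind(approach = app,
                              validate_proxies(space, dataset))
    si <- si + 3L
  }
  tables <- list(
    niche_sizes = do.call(rbind, c(size_tab, make.row.names = FALSE)),
    overlaps = do.call(rbind, c(ov_tab, make.row.names = FALSE)),
    layman = do.call(rbind, c(lay_tab, make.row.names = FALSE)),
    comparisons = if (length(cmp_tab))
      do.call(rbind, c(cmp_tab, make.row.names = FALSE)) else NULL,
    pca_contributions = do.call(rbind, c(contrib_tab, make.row.names = FALSE)),
    proxy_correlations = do.call(rbind, c(proxy_tab, make.row.names = FALSE)))
  if (!is.null(config$temporal)) {
    ta <- temporal_analysis(dataset, config$temporal$species,
                            split = config$temporal$split,
                            approaches = intersect(config$approaches,
                                                   c("2D", "3D", "5D")),
                            K = config$K, alpha = config$alpha,
                            n_mc = config$n_mc, n_bins = config$n_bins,
                            seed = stage_seeds[si + 1])
    tables$temporal_sizes <- ta$sizes
    tables$temporal_tests <- ta$tests
    tables$temporal_overlap <- ta$overlap
  }
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      utils::write.csv(tables[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    package = "isoniche",
    version = as.character(utils::packageVersion("isoniche")),
    seed = config$seed, K = config$K, alpha = config$alpha,
    n_mc = config$n_mc, n_bins = config$n_bins,
    approaches = config$approaches,
    n_samples_raw = n_raw, n_samples_complete = nrow(dataset),
    species = sort(unique(dataset$species)),
    temporal_species = config$temporal$species %||% NULL)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tables$out_dir <- config$out_dir
  invisible(tables)
}
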