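# Canonical per-sample isotope table: schema, validation, IO, filtering.

#' Amino acids measured per sample
#'
#' The fixed set of ten amino acids with compound-specific delta13C and
#' delta15N values: alanine, valine, glycine, isoleucine, leucine, proline,
#' aspartic acid, phenylalanine, glutamic acid (Glx) and lysine.
#'
#' @format Character vector of ten three-letter codes.
#' @export
aa_names <- c("ala", "val", "gly", "ile", "leu", "pro",
              "asp", "phe", "glx", "lys")

# Canonical column order for the isotope CSV dialect.
#' @noRd
canonical_columns <- function() {
  c("sample_id", "species", "year", "site",
    paste0(aa_names, "_c"), paste0(aa_names, "_n"),
    "bulk_c", "bulk_n", "bulk_s")
}

#' @noRd
tracer_columns <- function() {
  c(paste0(aa_names, "_c"), paste0(aa_names, "_n"),
    "bulk_c", "bulk_n", "bulk_s")
}

#' Construct and validate an isotope dataset
#'
#' Validates a data frame against the canonical per-sample schema
#' (`sample_id`, `species`, `year`, `site`, ten amino-acid delta13C columns
#' `ala_c` ... `lys_c`, ten delta15N columns `ala_n` ... `lys_n`, and bulk
#' `bulk_c`, `bulk_n`, `bulk_s`, all in permil) and returns it with columns
#' in canonical order.
#'
#' @param df A data frame containing all canonical columns (order free).
#' @param allow_missing Logical; if `TRUE`, `NA` tracer values are allowed
#'   (they can be removed later with [complete_case_filter()]).
#' @return A data frame of class `isotope_dataset`.
#' @seealso [read_isotope_csv()], [generate_community()]
#' @export
isotope_dataset <- function(df, allow_missing = TRUE) {
  cols <- canonical_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[cols]
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  df$site <- as.character(df$site)
  df$year <- as.integer(df$year)
  for (col in tracer_columns()) {
    df[[col]] <- as.numeric(df[[col]])
    bad <- is.nan(df[[col]]) | is.infinite(df[[col]])
    if (any(bad)) stop("non-finite value in column ", col, call. = FALSE)
    if (!allow_missing && anyNA(df[[col]])) {
      stop("missing value in column ", col, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("isotope_dataset", "data.frame")
  df
}

#' Read an isotope dataset from CSV
#'
#' Reads the canonical comma-delimited dialect (UTF-8, period decimal,
#' header row; column order free) and validates it.
#'
#' @param path Path to a CSV file.
#' @return An `isotope_dataset` data frame.
#' @export
read_isotope_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  isotope_dataset(df)
}

#' Write an isotope dataset to CSV
#'
#' Writes the canonical dialect. A write/read/write round trip is
#' byte-stable.
#'
#' @param x An `isotope_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(x, path) {
  x <- isotope_dataset(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only samples with a complete tracer set
#'
#' Retains rows with all twenty amino-acid values and bulk delta34S present
#' and finite, mirroring the usual requirement that every sample entering
#' the multivariate analysis carries the full tracer panel. Bulk delta13C
#' and delta15N may be missing (they are proxies, not model axes).
#'
#' @param dataset An `isotope_dataset`.
#' @param quiet Logical; if `FALSE`, the number of dropped rows is reported.
#' @return The filtered `isotope_dataset`, row order preserved.
#' @export
complete_case_filter <- function(dataset, quiet = TRUE) {
  dataset <- isotope_dataset(dataset)
  if (nrow(dataset) == 0L) stop("dataset is empty", call. = FALSE)
  needed <- c(paste0(aa_names, "_c"), paste0(aa_names, "_n"), "bulk_s")
  keep <- stats::complete.cases(dataset[needed])
  dropped <- sum(!keep)
  if (!quiet && dropped > 0L) {
    message(dropped, " of ", nrow(dataset),
            " sample(s) dropped by the complete-case filter")
  }
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    stop("no samples survive the complete-case filter", call. = FALSE)
  }
  class(out) <- c("isotope_dataset", "data.frame")
  out
}
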