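# Readers and writers for the metadata, taxonomy and chemistry tables, and
# relative-abundance aggregation. All on-disk formats are tab-delimited UTF-8
# with a header row.

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

CHEM_PARAMS <- c("CEC", "pH_H2O", "pH_KCl", "NO3_N", "NH4_N", "K2O",
                 "MgO", "CaO", "EC", "Tr_P2O5", "Humus", "WC")

FIELDS <- c("field_1", "field_2")
CROPS <- c("maize", "cabbage")
STAGES <- c("early", "middle", "late")

#' Read and validate sample metadata
#'
#' Metadata assigns every sample to one of the four field x crop sample
#' groups and to a growth stage and replicate. Values are validated against
#' the design enums (`field_1`/`field_2`, `maize`/`cabbage`,
#' `early`/`middle`/`late`).
#'
#' @param path TSV with columns `sample_id`, `field`, `crop`, `stage`,
#'   `replicate`.
#' @return data frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' @rdname read_sample_metadata
#' @param df data frame with the metadata columns.
#' @export
validate_sample_metadata <- function(df) {
  need <- c("sample_id", "field", "crop", "stage", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  for (col in c(field = "field", crop = "crop", stage = "stage")) {
    allowed <- switch(col, field = FIELDS, crop = CROPS, stage = STAGES)
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop("unknown ", col, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read and validate a taxonomy table
#'
#' One row per SV with the six ranks domain..genus. Missing or empty ranks
#' are filled with the literal sentinel `"NA"` (kept as a category, matching
#' the "not assigned" convention of amplicon taxonomy summaries).
#'
#' @param path TSV with columns `sv_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus` (missing trailing ranks tolerated).
#' @return data frame of class `taxonomy_table`.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  validate_taxonomy(df)
}

#' @rdname read_taxonomy
#' @param df data frame with at least an `sv_id` column.
#' @export
validate_taxonomy <- function(df) {
  if (!"sv_id" %in% names(df)) stop("taxonomy missing column: sv_id")
  df$sv_id <- as.character(df$sv_id)
  if (anyDuplicated(df$sv_id)) stop("duplicated sv_id in taxonomy")
  for (r in TAX_RANKS) {
    if (!r %in% names(df)) df[[r]] <- "NA"
    v <- as.character(df[[r]])
    v[is.na(v) | !nzchar(v)] <- "NA"
    df[[r]] <- v
  }
  df <- df[, c("sv_id", TAX_RANKS)]
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read metadata and taxonomy together
#'
#' @param meta_path metadata TSV path (see [read_sample_metadata()]).
#' @param tax_path taxonomy TSV path (see [read_taxonomy()]).
#' @return list with elements `metadata` and `taxonomy`.
#' @export
read_metadata_taxonomy <- function(meta_path, tax_path) {
  list(metadata = read_sample_metadata(meta_path),
       taxonomy = read_taxonomy(tax_path))
}

#' Check that a feature table, metadata and taxonomy agree
#'
#' Errors if any sample in the feature table lacks metadata or any SV lacks
#' a taxonomy row.
#'
#' @param ft a `feature_table`.
#' @param meta a `sample_metadata`.
#' @param tax a `taxonomy_table`, or `NULL` to skip the taxonomy check.
#' @return `TRUE`, invisibly.
#' @export
check_joined <- function(ft, meta, tax = NULL) {
  miss <- setdiff(sample_ids(ft), meta$sample_id)
  if (length(miss))
    stop("sample(s) lacking metadata: ", paste(utils::head(miss, 5), collapse = ", "))
  if (!is.null(tax)) {
    miss <- setdiff(sv_ids(ft), tax$sv_id)
    if (length(miss))
      stop("SV(s) lacking taxonomy: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a soil-chemistry table
#'
#' One row per (field, crop, stage) cell with the 12 measured parameters.
#'
#' @param path TSV with columns `field`, `crop`, `stage` and the 12
#'   parameters `CEC, pH_H2O, pH_KCl, NO3_N, NH4_N, K2O, MgO, CaO, EC,
#'   Tr_P2O5, Humus, WC`.
#' @return data frame of class `chem_table`.
#' @export
read_chem_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_chem_table(df)
}

#' @rdname read_chem_table
#' @param df data frame with the chemistry columns.
#' @export
validate_chem_table <- function(df) {
  miss <- setdiff(c("field", "crop", "stage", CHEM_PARAMS), names(df))
  if (length(miss)) stop("chemistry table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, c("field", "crop", "stage", CHEM_PARAMS)]
  vals <- as.matrix(df[, CHEM_PARAMS])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("chemistry values must be finite and non-negative")
  if (any(df$WC < 0 | df$WC > 1)) stop("WC must lie in [0, 1]")
  class(df) <- c("chem_table", "data.frame")
  df
}

#' Write a plain data frame as TSV
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate SV counts to taxon-level relative abundance
#'
#' Per-sample proportions are summed by the taxon at `rank`; taxa whose
#' share of the grand total is at or below `threshold` are pooled into a
#' `minor` bin (0.5% for major eukaryotic SVs, 1% for prokaryotic, in the
#' motivating study). The `"NA"` sentinel stays a category of its own.
#'
#' @param ft a `feature_table`.
#' @param tax a `taxonomy_table` covering the table's SVs.
#' @param rank `"phylum"`, `"family"` or `"genus"`.
#' @param threshold fraction in `[0, 1)`; taxa with grand-total share
#'   strictly above it are kept as major.
#' @return matrix of class `rel_abundance` (samples x taxa, rows sum to 1)
#'   with attributes `rank`, `threshold`, `minor_bin` (the pooled column
#'   name, `"minor"`).
#' @export
aggregate_relative_abundance <- function(ft, tax, rank = c("phylum", "family", "genus"),
                                         threshold = 0) {
  rank <- match.arg(rank)
  stopifnot(threshold >= 0, threshold < 1)
  check_joined(ft, data.frame(sample_id = sample_ids(ft)), tax)
  labels <- tax[[rank]][match(sv_ids(ft), tax$sv_id)]
  totals <- rowSums(ft)
  if (any(totals == 0)) stop("sample(s) with zero total reads")
  prop <- unclass(ft) / totals
  agg <- t(rowsum(t(prop), group = labels))  # samples x taxa
  grand <- colSums(unclass(ft))
  taxon_share <- rowsum(grand, labels)[, 1] / sum(grand)
  major <- names(taxon_share)[taxon_share > threshold]
  minor <- setdiff(colnames(agg), major)
  out <- agg[, major, drop = FALSE]
  out <- cbind(out, minor = if (length(minor))
    rowSums(agg[, minor, drop = FALSE]) else rep(0, nrow(agg)))
  # stable order: abundance-descending majors, then the minor bin
  ord <- c(major[order(taxon_share[major], decreasing = TRUE)], "minor")
  out <- out[, ord, drop = FALSE]
  structure(out, rank = rank, threshold = threshold, minor_bin = "minor",
            class = c("rel_abundance", "matrix", "array"))
}
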