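#' Construct and validate an SV feature table
#'
#' A feature table holds the read counts of amplicon sequence variants (SVs)
#' across samples. Counts are stored internally as a samples x SVs integer
#' matrix with unique sample and SV identifiers, optionally carrying per-SV
#' amplicon lengths (bp) and the marker gene the SVs derive from.
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   samples in rows and SVs in columns; `dimnames` may be supplied instead
#'   of `sample_ids` / `sv_ids`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param sv_ids character vector of unique SV identifiers.
#' @param sv_lengths optional named integer vector of amplicon lengths (bp),
#'   names matching `sv_ids`.
#' @param marker marker gene, `"16S"` (prokaryote) or `"18S"` (eukaryote).
#' @return An object of class `feature_table`: the counts matrix with
#'   attributes `sv_lengths` and `marker`.
#' @export
feature_table <- function(counts, sample_ids = rownames(counts),
                          sv_ids = colnames(counts), sv_lengths = NULL,
                          marker = c("16S", "18S")) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(sv_ids))
    stop("sample_ids and sv_ids are required (or supply dimnames)")
  sample_ids <- as.character(sample_ids)
  sv_ids <- as.character(sv_ids)
  if (nrow(counts) != length(sample_ids) || ncol(counts) != length(sv_ids))
    stop("counts dimensions (", nrow(counts), " x ", ncol(counts),
         ") do not match id lists (", length(sample_ids), " samples, ",
         length(sv_ids), " SVs)")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicated sample_id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sv_ids[duplicated(sv_ids)])
  if (length(dup))
    stop("duplicated sv_id(s): ", paste(dup, collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer count at sample '",
         sample_ids[bad[1, 1]], "', SV '", sv_ids[bad[1, 2]], "'")
  storage.mode(counts) <- "double"  # doubles hold counts exactly; avoids int overflow on sums
  dimnames(counts) <- list(sample_ids, sv_ids)
  if (!is.null(sv_lengths)) {
    if (is.null(names(sv_lengths)))
      stop("sv_lengths must be named by sv_id")
    missing_len <- setdiff(sv_ids, names(sv_lengths))
    if (length(missing_len))
      stop("sv_lengths missing for: ", paste(utils::head(missing_len, 5), collapse = ", "))
    sv_lengths <- as.integer(sv_lengths[sv_ids])
    names(sv_lengths) <- sv_ids
  }
  structure(counts, sv_lengths = sv_lengths, marker = marker,
            class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x), " samples x ", ncol(x), " SVs (",
      attr(x, "marker"), "), total reads ", format(sum(x), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Sample identifiers of a feature table
#' @param ft a `feature_table`.
#' @return character vector.
#' @export
sample_ids <- function(ft) rownames(ft)

#' SV identifiers of a feature table
#' @param ft a `feature_table`.
#' @return character vector.
#' @export
sv_ids <- function(ft) colnames(ft)

# rebuild the class/attributes after subsetting the bare matrix
ft_replace <- function(ft, counts, sample_keep = rownames(counts),
                       sv_keep = colnames(counts)) {
  len <- attr(ft, "sv_lengths")
  if (!is.null(len)) len <- len[sv_keep]
  feature_table(counts, sample_keep, sv_keep, sv_lengths = len,
                marker = attr(ft, "marker"))
}

#' Read an SV count table from TSV
#'
#' The on-disk layout is a tab-delimited UTF-8 file with a header row. With
#' `orientation = "svs-rows"` (the common export layout) the first column
#' holds SV ids and the remaining columns one sample each; with
#' `"samples-rows"` the transpose. The in-memory orientation is always
#' samples x SVs.
#'
#' @param path path to the TSV file.
#' @param marker `"16S"` or `"18S"`.
#' @param orientation `"svs-rows"` (default) or `"samples-rows"`.
#' @param sv_lengths optional named integer vector of SV lengths (bp).
#' @return a validated [feature_table()].
#' @export
read_feature_table <- function(path, marker = c("16S", "18S"),
                               orientation = c("svs-rows", "samples-rows"),
                               sv_lengths = NULL) {
  marker <- match.arg(marker)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric count at row '", ids[bad[1, 1]], "', column '",
         colnames(m)[bad[1, 2]], "' in ", path)
  }
  rownames(m) <- ids
  if (orientation == "svs-rows") m <- t(m)
  feature_table(m, rownames(m), colnames(m), sv_lengths = sv_lengths,
                marker = marker)
}

#' Write an SV count table to TSV
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @param orientation on-disk layout, see [read_feature_table()].
#' @param id_col header name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path,
                                orientation = c("svs-rows", "samples-rows"),
                                id_col = "sv_id") {
  orientation <- match.arg(orientation)
  m <- unclass(ft)
  if (orientation == "svs-rows") m <- t(m)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- if (orientation == "svs-rows") id_col else "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove SVs shorter than a minimum amplicon length
#'
#' Mirrors the SV length filter applied to denoised amplicons: SVs strictly
#' shorter than `min_len` bp are dropped (407 bp for 18S, 400 bp for 16S in
#' the motivating study). If the table carries no lengths the filter is a
#' no-op with a warning.
#'
#' @param ft a `feature_table`.
#' @param min_len minimum length in bp; SVs with length `< min_len` are removed.
#' @return filtered `feature_table`.
#' @export
filter_by_length <- function(ft, min_len) {
  len <- attr(ft, "sv_lengths")
  if (is.null(len)) {
    warning("feature table carries no sv_lengths; returning table unchanged")
    return(ft)
  }
  keep <- sv_ids(ft)[len >= min_len]
  ft_replace(ft, unclass(ft)[, keep, drop = FALSE], sample_ids(ft), keep)
}

#' Subset a feature table to one field x crop sample group
#'
#' The four field x crop combinations are the unit of the per-group clr and
#' network computation. SVs with zero total count inside the group are
#' flagged (attribute `zero_svs`) but retained; drop them with
#' [drop_zero_features()] before log-ratio work.
#'
#' @param ft a `feature_table`.
#' @param meta a `sample_metadata` data frame (see [read_sample_metadata()]).
#' @param field `"field_1"` or `"field_2"`.
#' @param crop `"maize"` or `"cabbage"`.
#' @return `feature_table` restricted to the group's samples, with attribute
#'   `zero_svs` listing SVs that have no reads in the group.
#' @export
subset_by_group <- function(ft, meta, field, crop) {
  field <- match.arg(field, c("field_1", "field_2"))
  crop <- match.arg(crop, c("maize", "cabbage"))
  keep <- meta$sample_id[meta$field == field & meta$crop == crop]
  keep <- intersect(sample_ids(ft), keep)
  if (!length(keep))
    stop("empty sample group: (", field, ", ", crop, ")")
  sub <- ft_replace(ft, unclass(ft)[keep, , drop = FALSE], keep, sv_ids(ft))
  attr(sub, "zero_svs") <- sv_ids(sub)[colSums(sub) == 0]
  sub
}

#' Drop SVs with zero total count
#' @param ft a `feature_table`.
#' @return `feature_table` without all-zero SV columns.
#' @export
drop_zero_features <- function(ft) {
  keep <- sv_ids(ft)[colSums(ft) > 0]
  ft_replace(ft, unclass(ft)[, keep, drop = FALSE], sample_ids(ft), keep)
}

#' Group label for every sample
#'
#' @param meta a `sample_metadata` data frame.
#' @return factor of `"field:crop"` group labels, one per row of `meta`,
#'   named by sample id.
#' @export
sample_groups <- function(meta) {
  g <- factor(paste(meta$field, meta$crop, sep = ":"))
  names(g) <- meta$sample_id
  g
}
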