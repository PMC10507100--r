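# Soil-chemistry normalization and clustering, redundancy analysis (RDA) of
# clr-transformed communities against chemistry, and feature-parameter
# association scores.

#' Percent-normalize a chemistry table for heatmap display
#'
#' Within each parameter column, every cell's value is divided by the column
#' total and expressed in percent, so each column sums to 100. The input
#' rows are the per-cell means (composite samples), which puts the
#' parameters — measured on wildly different scales — on a common footing.
#'
#' @param chem a `chem_table` (or a non-negative numeric matrix,
#'   cells x parameters).
#' @return numeric matrix (same shape) of percentages; attribute
#'   `row_labels` carries `"field:crop:stage"` labels when the input is a
#'   `chem_table`.
#' @export
percent_normalize_chem <- function(chem) {
  if (inherits(chem, "chem_table")) {
    m <- as.matrix(chem[, CHEM_PARAMS])
    rownames(m) <- paste(chem$field, chem$crop, chem$stage, sep = ":")
  } else {
    m <- as.matrix(chem)
  }
  if (any(m < 0)) stop("negative chemistry value")
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("all-zero parameter column(s): ", paste(zero, collapse = ", "))
  sweep(m, 2, tot, "/") * 100
}

#' Complete-linkage (farthest-neighbor) clustering of chemistry profiles
#'
#' Agglomerative clustering of the rows of a percentage matrix with
#' Euclidean distance and complete linkage (inter-cluster distance = maximum
#' pairwise distance), as used for the soil-chemistry heatmap.
#'
#' @param pct numeric matrix (rows = cells/samples), e.g. from
#'   [percent_normalize_chem()].
#' @return an [stats::hclust] object (`merge`, `height`, `order`, labels).
#' @export
cluster_samples_complete_linkage <- function(pct) {
  if (nrow(pct) < 2) stop("need >= 2 rows")
  stats::hclust(stats::dist(pct, method = "euclidean"), method = "complete")
}

#' Write a dendrogram as a merge-list TSV
#'
#' One row per merge step: negative entries are leaves (with labels),
#' positive entries earlier merge steps, plus the merge height.
#'
#' @param hc an [stats::hclust] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  lab <- function(i) vapply(i, function(k)
    if (k < 0) hc$labels[-k] else paste0("step_", k), "")
  df <- data.frame(step = seq_along(hc$height),
                   member_a = lab(hc$merge[, 1]),
                   member_b = lab(hc$merge[, 2]),
                   height = hc$height, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Redundancy analysis of a clr community matrix on chemistry
#'
#' The clr matrix (samples x features) is column-centred and regressed on
#' the (optionally standardized) chemistry matrix by least squares; the
#' singular-value decomposition of the fitted values gives the constrained
#' axes. Eigenvalue of axis a is `d_a^2 / (n - 1)`; the constrained
#' fraction is the summed constrained eigenvalues over the total variance.
#' Biplot vectors are the correlations of each parameter with the site
#' scores, scaled by each axis' share of the constrained variance — longer
#' arrows mean stronger association.
#'
#' @param clr_point point-estimate clr matrix, samples x features (see
#'   [clr_point()]).
#' @param chem per-sample chemistry matrix (samples x parameters), row
#'   order matching `clr_point` (use [chem_to_samples()] to broadcast
#'   cell-level chemistry).
#' @param standardize standardize chemistry columns to zero mean / unit
#'   variance (default `TRUE`); either way columns are centred.
#' @return object of class `rda_result`: `site_scores` (samples x axes),
#'   `feature_scores` (features x axes), `biplot_vectors`
#'   (parameters x axes), `eigenvalues`, `total_variance`,
#'   `constrained_fraction`, `rank`.
#' @export
rda_fit <- function(clr_point, chem, standardize = TRUE) {
  Y <- as.matrix(clr_point)
  X <- as.matrix(chem)
  n <- nrow(Y)
  if (nrow(X) != n) stop("samples do not align between clr and chemistry")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y)))
    X <- X[rownames(Y), , drop = FALSE]
  if (ncol(X) >= n) stop("more chemistry parameters than samples")
  Y <- scale(Y, center = TRUE, scale = FALSE)
  const <- apply(X, 2, stats::sd) == 0
  if (standardize) {
    if (any(const)) {
      warning("constant chemistry column(s) dropped: ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
    X <- scale(X)
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning("rank-deficient chemistry (rank ", qr_x$rank, " < ", ncol(X),
            "); fitting on its column space")
  fitted <- qr.fitted(qr_x, Y)
  sv <- svd(fitted)
  pos <- sv$d > max(sv$d[1], 1) * 1e-10
  r <- sum(pos)
  if (r == 0) stop("fitted values are identically zero")
  eig <- sv$d[pos]^2 / (n - 1)
  total <- sum(Y^2) / (n - 1)
  site <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos], r)
  feat <- sv$v[, pos, drop = FALSE]
  axes <- paste0("RDA", seq_len(r))
  dimnames(site) <- list(rownames(Y), axes)
  dimnames(feat) <- list(colnames(Y), axes)
  bip <- stats::cor(X, site)
  bip <- sweep(bip, 2, sqrt(eig / sum(eig)), "*")
  dimnames(bip) <- list(colnames(X), axes)
  structure(list(site_scores = site, feature_scores = feat,
                 biplot_vectors = bip,
                 eigenvalues = stats::setNames(eig, axes),
                 total_variance = total,
                 constrained_fraction = sum(eig) / total, rank = r),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("RDA: ", x$rank, " constrained axes, constrained fraction = ",
      format(x$constrained_fraction, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Rank feature-parameter associations
#'
#' Scores every (feature, parameter) pair by the Pearson correlation of the
#' feature's clr profile with the parameter across samples, optionally
#' restricting features to the `n_top_features` most abundant (top 350 SVs
#' by total reads in the motivating study). Per parameter, the `top_k`
#' features by `|score|` are reported. Constant features or parameters are
#' excluded.
#'
#' @param clr_point clr matrix, samples x features.
#' @param chem per-sample chemistry matrix.
#' @param top_k features reported per parameter.
#' @param abundance optional named vector of feature total abundances used
#'   for the top-`n_top_features` restriction (`NULL` = use all features).
#' @param n_top_features abundance cutoff (default 350).
#' @return data frame `parameter`, `feature`, `score`, `rank`, sorted by
#'   parameter then rank.
#' @export
feature_parameter_association <- function(clr_point, chem, top_k = 10,
                                          abundance = NULL,
                                          n_top_features = 350) {
  stopifnot(top_k >= 1)
  Y <- as.matrix(clr_point)
  X <- as.matrix(chem)
  if (!is.null(rownames(X)) && !is.null(rownames(Y)))
    X <- X[rownames(Y), , drop = FALSE]
  if (!is.null(abundance)) {
    keep <- names(sort(abundance, decreasing = TRUE))
    keep <- intersect(keep[seq_len(min(n_top_features, length(keep)))],
                      colnames(Y))
    Y <- Y[, keep, drop = FALSE]
  }
  ok_f <- apply(Y, 2, stats::sd) > 0
  ok_p <- apply(X, 2, stats::sd) > 0
  scores <- stats::cor(Y[, ok_f, drop = FALSE], X[, ok_p, drop = FALSE])
  rows <- lapply(colnames(scores), function(p) {
    s <- scores[, p]
    ord <- order(abs(s), decreasing = TRUE)[seq_len(min(top_k, length(s)))]
    data.frame(parameter = p, feature = names(s)[ord], score = s[ord],
               rank = seq_along(ord), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
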