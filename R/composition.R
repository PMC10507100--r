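# Centered log-ratio transformation with Dirichlet Monte-Carlo instances,
# and pairwise phi-proportionality. These operate within one sample group:
# the geometric-mean centring and the variances behind phi are taken over
# the group's samples.

#' Monte-Carlo centered log-ratio transformation
#'
#' In `montecarlo` mode, each sample's counts are converted to `M` Dirichlet
#' instances: a proportion vector is drawn from `Dirichlet(counts + prior)`
#' and clr-transformed, `clr_i = log p_i - mean_j log p_j`. The instances
#' propagate the count uncertainty of low-abundance SVs into downstream phi
#' values (the ALDEx2-style approach). In `point_estimate` mode a single
#' instance is built from `(counts + prior) / sum`.
#'
#' @param ft a `feature_table` restricted to one sample group; SVs that are
#'   all-zero in the group must be removed first ([drop_zero_features()]) —
#'   their log-ratios are meaningless.
#' @param M number of Monte-Carlo instances (default 128; ignored in
#'   point-estimate mode).
#' @param prior Dirichlet pseudo-count added to every cell (default 0.5).
#' @param seed integer seed (montecarlo mode).
#' @param mode `"montecarlo"` or `"point_estimate"`.
#' @return object of class `clr_ensemble`: list with `values`
#'   (`M x n_samples x n_features` array; `M = 1` for point estimates),
#'   `sample_ids`, `sv_ids`, `M`, `prior`, `mode`, `seed`.
#' @export
clr_ensemble <- function(ft, M = 128, prior = 0.5, seed = NULL,
                         mode = c("montecarlo", "point_estimate")) {
  mode <- match.arg(mode)
  m <- unclass(ft)
  if (any(colSums(m) == 0))
    stop("feature(s) with all-zero group counts; drop them first")
  n_s <- nrow(m); n_f <- ncol(m)
  if (mode == "montecarlo") {
    if (M < 1) stop("M must be >= 1 in montecarlo mode")
    if (is.null(seed)) stop("seed is required in montecarlo mode")
    set.seed(seed)
    vals <- array(NA_real_, c(M, n_s, n_f))
    alpha <- m + prior
    for (s in seq_len(n_s)) {
      # Dirichlet via gamma; clr needs only logs, normalization cancels in
      # the centring so log-gamma draws are centred directly
      g <- matrix(stats::rgamma(M * n_f, shape = rep(alpha[s, ], each = M)),
                  M, n_f)
      lg <- log(g)
      vals[, s, ] <- lg - rowMeans(lg)
    }
  } else {
    M <- 1L
    p <- (m + prior) / rowSums(m + prior)
    lp <- log(p)
    vals <- array(lp - rowMeans(lp), c(1, n_s, n_f))
  }
  structure(list(values = vals, sample_ids = rownames(m),
                 sv_ids = colnames(m), M = as.integer(M), prior = prior,
                 mode = mode, seed = seed),
            class = "clr_ensemble")
}

#' Point-estimate clr matrix
#'
#' Convenience wrapper returning the single-instance clr as a plain
#' samples x features matrix (the input to RDA and association scoring).
#'
#' @param ft a `feature_table` (zero-count features removed).
#' @param prior pseudo-count (default 0.5).
#' @return numeric matrix samples x features, rows centred to 0.
#' @export
clr_point <- function(ft, prior = 0.5) {
  ce <- clr_ensemble(ft, prior = prior, mode = "point_estimate")
  out <- ce$values[1, , , drop = TRUE]
  dim(out) <- c(length(ce$sample_ids), length(ce$sv_ids))
  dimnames(out) <- list(ce$sample_ids, ce$sv_ids)
  out
}

# directional phi on one clr instance (samples x features matrix):
# phi[i, j] = Var(clr_i - clr_j) / Var(clr_i), then symmetrized
phi_one_instance <- function(x, symmetrization) {
  C <- stats::cov(x)            # unbiased (n - 1) covariance
  v <- diag(C)
  vd <- outer(v, v, "+") - 2 * C  # Var(clr_i - clr_j)
  vd[vd < 0] <- 0                 # FP noise on perfectly proportional pairs
  p_dir <- vd / v                 # row i divided by Var(clr_i)
  out <- switch(symmetrization,
                max = pmax(p_dir, t(p_dir)),
                min = pmin(p_dir, t(p_dir)),
                mean = (p_dir + t(p_dir)) / 2)
  diag(out) <- 0
  list(phi = out, zero_var = v <= 0)
}

#' Pairwise phi-proportionality matrix
#'
#' For each clr instance, the directional statistic
#' `phi_(i->j) = Var_samples(clr_i - clr_j) / Var_samples(clr_i)` is
#' computed for every SV pair (unbiased sample variance over the group's
#' samples), symmetrized (default: max of the two directions, so an edge
#' later requires both directions under threshold), then aggregated across
#' instances (default: mean). phi is near 0 for proportionally co-varying
#' SVs and is invariant to the logarithm base. Features with zero variance
#' across samples have undefined phi: their rows/columns are `NA` and they
#' are listed in attribute `undefined_features`.
#'
#' @param clr a `clr_ensemble` over >= 3 samples.
#' @param symmetrization `"max"` (default), `"min"` or `"mean"`.
#' @param aggregation across instances, `"mean"` (default) or `"max"`.
#' @return symmetric matrix of class `phi_matrix` (features x features,
#'   zero diagonal) with attributes `symmetrization`, `aggregation`,
#'   `undefined_features`.
#' @export
phi_matrix <- function(clr, symmetrization = c("max", "min", "mean"),
                       aggregation = c("mean", "max")) {
  symmetrization <- match.arg(symmetrization)
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(clr, "clr_ensemble"))
  if (length(clr$sample_ids) < 3)
    stop("phi needs >= 3 samples in the group")
  n_f <- length(clr$sv_ids)
  acc <- matrix(0, n_f, n_f)
  zero_var <- rep(FALSE, n_f)
  for (inst in seq_len(clr$M)) {
    x <- clr$values[inst, , , drop = TRUE]
    dim(x) <- c(length(clr$sample_ids), n_f)
    pi_ <- phi_one_instance(x, symmetrization)
    zero_var <- zero_var | pi_$zero_var
    acc <- if (aggregation == "mean") acc + pi_$phi else pmax(acc, pi_$phi)
  }
  if (aggregation == "mean") acc <- acc / clr$M
  dimnames(acc) <- list(clr$sv_ids, clr$sv_ids)
  undef <- clr$sv_ids[zero_var]
  if (length(undef)) {
    acc[zero_var, ] <- NA_real_
    acc[, zero_var] <- NA_real_
    diag(acc) <- 0
    warning(length(undef), " feature(s) with zero sample variance: ",
            "phi undefined, excluded from network building")
  }
  structure(acc, symmetrization = symmetrization, aggregation = aggregation,
            undefined_features = undef,
            class = c("phi_matrix", "matrix", "array"))
}

#' Write a phi matrix as a long-form TSV
#'
#' One row per unordered SV pair: columns `sv_a`, `sv_b`, `phi`.
#'
#' @param phi a `phi_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phi_long <- function(phi, path) {
  ut <- upper.tri(phi)
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(sv_a = rownames(phi)[idx[, 1]],
                   sv_b = colnames(phi)[idx[, 2]],
                   phi = phi[ut], stringsAsFactors = FALSE)
  write_tsv(df, path)
}
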