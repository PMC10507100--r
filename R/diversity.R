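# Alpha/beta diversity: rarefaction, Shannon with Tukey-Kramer pairwise
# tests, Bray-Curtis distances, NMDS, PERMANOVA.

#' Rarefy all samples to an even sequencing depth
#'
#' Each sample is subsampled without replacement (one draw, no averaging) to
#' exactly `depth` reads. Samples with fewer total reads than `depth` are
#' dropped with a warning. The default depth is the minimum sample total, so
#' no sample is dropped.
#'
#' @param ft a `feature_table`.
#' @param depth target depth; default `min(rowSums(ft))`.
#' @param seed integer seed (recorded in attribute `rarefaction_seed`).
#' @return rarefied `feature_table`; every retained sample sums to `depth`.
#' @export
rarefy_even_depth <- function(ft, depth = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  totals <- rowSums(ft)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  stopifnot(depth >= 1)
  keep <- names(totals)[totals >= depth]
  if (!length(keep)) stop("all samples have fewer than ", depth, " reads")
  if (length(keep) < nrow(ft))
    warning(nrow(ft) - length(keep), " sample(s) below depth ", depth,
            " dropped: ", paste(setdiff(rownames(ft), keep), collapse = ", "))
  set.seed(seed)
  m <- unclass(ft)[keep, , drop = FALSE]
  # subsample reads without replacement: draw `depth` reads from the urn of
  # sum(x) reads labelled by SV
  out <- t(apply(m, 1, function(x) {
    reads <- rep.int(seq_along(x), x)
    picked <- sample(reads, depth, replace = FALSE)
    tabulate(picked, nbins = length(x))
  }))
  dimnames(out) <- dimnames(m)
  res <- ft_replace(ft, out, keep, sv_ids(ft))
  attr(res, "rarefaction_seed") <- seed
  attr(res, "rarefaction_depth") <- depth
  res
}

#' Shannon diversity index of one sample
#'
#' `H = -sum p_i log p_i` over SVs with nonzero counts, `p_i = count_i /
#' total`. Natural log by default (nats).
#'
#' @param counts non-negative count vector with positive total.
#' @param base logarithm base (default `exp(1)`).
#' @return Shannon index.
#' @export
shannon_index <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total <= 0) stop("all-zero sample")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Shannon index of every sample in a feature table
#' @param ft a `feature_table`.
#' @param base logarithm base.
#' @return named numeric vector, one index per sample.
#' @export
shannon_samples <- function(ft, base = exp(1)) {
  apply(unclass(ft), 1, shannon_index, base = base)
}

#' Tukey-Kramer pairwise comparisons of group means
#'
#' All-pairs studentized-range test with pooled within-group variance; the
#' Tukey-Kramer harmonic form handles unequal group sizes. p-values come
#' from the studentized range distribution with `N - k` error df.
#'
#' @param values named list, group -> numeric vector (each length >= 2).
#' @return data frame with columns `group_a`, `group_b`, `difference`
#'   (mean_b - mean_a), `se`, `q`, `p_value`, and attribute `df` (error df).
#'   With zero pooled variance and unequal means, `p_value` is the machine
#'   floor and the row is flagged in column `degenerate`.
#' @export
tukey_kramer <- function(values) {
  stopifnot(length(values) >= 2)
  if (any(vapply(values, length, 1L) < 2))
    stop("every group needs >= 2 values")
  k <- length(values)
  n <- vapply(values, length, 1L)
  m <- vapply(values, mean, 1)
  ss <- vapply(values, function(v) sum((v - mean(v))^2), 1)
  df <- sum(n) - k
  s2 <- sum(ss) / df
  pairs <- utils::combn(names(values), 2)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    stringsAsFactors = FALSE)
  out$difference <- m[out$group_b] - m[out$group_a]
  # Tukey-Kramer: SE^2 = s2/2 * (1/n_a + 1/n_b)
  out$se <- sqrt(s2 / 2 * (1 / n[out$group_a] + 1 / n[out$group_b]))
  out$degenerate <- FALSE
  if (s2 > 0) {
    out$q <- abs(out$difference) / out$se
    out$p_value <- stats::ptukey(out$q, nmeans = k, df = df,
                                 lower.tail = FALSE)
  } else {
    out$q <- ifelse(out$difference == 0, 0, Inf)
    out$p_value <- ifelse(out$difference == 0, 1, .Machine$double.xmin)
    out$degenerate <- out$difference != 0
  }
  rownames(out) <- NULL
  attr(out, "df") <- df
  out
}

#' Bray-Curtis distance matrix
#'
#' `BC(a, b) = 1 - 2 sum_i min(a_i, b_i) / (sum a + sum b)`.
#'
#' @param ft a `feature_table` (or bare count matrix, samples x features)
#'   with >= 2 samples, every sample total positive.
#' @return symmetric matrix of class `distance_matrix` with zero diagonal,
#'   entries in `[0, 1]`, sample ids as dimnames.
#' @export
bray_curtis_matrix <- function(ft) {
  m <- unclass(ft)
  if (nrow(m) < 2) stop("need >= 2 samples")
  if (any(rowSums(m) <= 0)) stop("sample(s) with zero total reads")
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

# -- NMDS --------------------------------------------------------------------

# Kruskal stress-1 with monotone (isotonic) fitted dissimilarities.
# d: configuration distances, ordered by increasing observed dissimilarity
# (primary tie approach: within observed ties, order by d so ties impose no
# constraint). Returns list(stress, dhat in the same order).
stress1_fit <- function(d_ord) {
  fit <- stats::isoreg(d_ord)$yf
  num <- sum((d_ord - fit)^2)
  den <- sum(d_ord^2)
  list(stress = sqrt(num / den), dhat = fit)
}

nmds_one_start <- function(dv, n, k, x0, max_iter, tol) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  X <- x0
  X_best <- x0
  trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    D <- as.matrix(stats::dist(X))
    dvec <- D[upper.tri(D)]
    # primary approach to ties: within tied dissimilarities, sort distances
    ord <- order(dv, dvec)
    sf <- stress1_fit(dvec[ord])
    stress <- sf$stress
    if (stress > prev) break  # majorization stalled; keep the best config
    trace <- c(trace, stress)
    X_best <- X
    improved <- prev - stress
    prev <- stress
    if (improved < tol) { converged <- TRUE; break }
    dhat <- numeric(length(dvec))
    dhat[ord] <- sf$dhat
    # Guttman transform
    B <- matrix(0, n, n)
    w <- ifelse(dvec > 0, dhat / dvec, 0)
    B[ij] <- -w
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  list(coordinates = X_best, stress = prev, trace = trace,
       converged = converged)
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Minimizes Kruskal stress-1 by iterative majorization (SMACOF / Guttman
#' transform) alternated with monotone regression of configuration distances
#' on dissimilarity ranks (pool-adjacent-violators; primary approach to
#' ties). The best configuration over `n_starts` random starts is kept and
#' centred; the first start is seeded from classical (metric) scaling.
#'
#' @param d a `distance_matrix` (or symmetric matrix with dimnames).
#' @param k embedding dimension (default 2).
#' @param n_starts number of random starts (default 20).
#' @param seed integer seed.
#' @param max_iter majorization iteration cap per start.
#' @param tol stop a start when the stress improvement falls below `tol`.
#' @return list of class `nmds_result`: `coordinates` (samples x k,
#'   centred), `stress`, `stress_trace` (per-iteration stress of the best
#'   start, non-increasing), `n_starts`, `converged`, `seed`.
#' @export
nmds_ordinate <- function(d, k = 2, n_starts = 20, seed, max_iter = 500,
                          tol = 1e-7) {
  if (missing(seed)) stop("seed is required")
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("need at least k + 1 points")
  set.seed(seed)
  dv <- d[upper.tri(d)]
  best <- NULL
  ref <- NULL  # first converged solution; fixes sign/rotation of the report
  for (s in seq_len(n_starts)) {
    x0 <- if (s == 1) {
      cm <- stats::cmdscale(d, k = k)
      if (ncol(cm) < k) cbind(cm, matrix(0, n, k - ncol(cm))) else cm
    } else {
      matrix(stats::rnorm(n * k), n, k) * mean(dv)
    }
    res <- nmds_one_start(dv, n, k, x0, max_iter, tol)
    if (is.null(ref) && res$converged) ref <- res$coordinates
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  X <- scale(best$coordinates, center = TRUE, scale = FALSE)
  if (!is.null(ref)) {
    # orthogonal Procrustes rotation onto the first converged configuration
    refc <- scale(ref, center = TRUE, scale = FALSE)
    sv <- svd(crossprod(X, refc))
    X <- X %*% (sv$u %*% t(sv$v))
  }
  rownames(X) <- rownames(d)
  colnames(X) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = X, stress = best$stress,
                 stress_trace = best$trace, n_starts = n_starts,
                 converged = best$converged, seed = seed),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS (", ncol(x$coordinates), "D): stress = ",
      format(x$stress, digits = 5), ", ", x$n_starts, " starts, converged = ",
      x$converged, "\n", sep = "")
  invisible(x)
}

# -- PERMANOVA ---------------------------------------------------------------

permanova_F <- function(d2, groups) {
  n <- nrow(d2)
  k <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  F <- (ss_between / (k - 1)) / (ss_within / (n - k))
  c(F = F, R2 = ss_between / ss_total, ss_total = ss_total,
    ss_within = ss_within)
}

# all distinct arrangements of a label multiset (columns of a matrix)
label_arrangements <- function(groups) {
  lv <- levels(groups)
  counts <- table(groups)
  n <- length(groups)
  rec <- function(free, remaining) {
    lab <- names(remaining)[remaining > 0]
    if (!length(lab)) return(matrix(integer(0), nrow = 0))
    if (length(lab) == 1) {
      m <- matrix(NA_integer_, 1, n)
      m[1, free] <- match(lab, lv)
      return(m)
    }
    l1 <- lab[1]
    picks <- utils::combn(free, remaining[[l1]])
    out <- NULL
    rem2 <- remaining
    rem2[[l1]] <- 0
    for (j in seq_len(ncol(picks))) {
      sub <- rec(setdiff(free, picks[, j]), rem2)
      sub[, picks[, j]] <- match(l1, lv)
      out <- rbind(out, sub)
    }
    out
  }
  rec(seq_len(n), as.list(counts))
}

n_arrangements <- function(groups) {
  counts <- as.integer(table(groups))
  exp(lgamma(length(groups) + 1) - sum(lgamma(counts + 1)))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the squared inter-sample distances by group:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, pseudo-F =
#' `(SS_between/(k-1)) / (SS_within/(n-k))`, `R2 = SS_between/SS_total`.
#' The p-value comes from permuting group labels; when the number of
#' distinct labelings is at most `exact_limit` every labeling is enumerated
#' and `p = #(F_perm >= F_obs) / #labelings` (the observed labeling is one
#' of them), otherwise `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)`
#' from random permutations.
#'
#' @param d a `distance_matrix`.
#' @param groups factor (or vector) of group labels, named by sample id or
#'   in `d`'s sample order; >= 2 groups, `n - k > 0`.
#' @param n_permutations number of random permutations (default 999).
#' @param seed integer seed for the permutations.
#' @param exact_limit enumerate exactly when the labeling count is at most
#'   this (default 5000).
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations` (0 when exact), `exact`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed,
                      exact_limit = 5000) {
  if (missing(seed)) stop("seed is required")
  d <- as.matrix(d)
  n <- nrow(d)
  if (!is.null(names(groups))) groups <- groups[rownames(d)]
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("need >= 2 groups")
  if (n - k <= 0) stop("residual df n - k must be positive")
  if (length(groups) != n) stop("groups length does not match d")
  d2 <- d^2
  obs <- permanova_F(d2, groups)
  eps <- 1e-12 * max(1, abs(obs[["F"]]))  # FP guard on >= comparisons
  exact <- n_arrangements(groups) <= exact_limit
  if (exact) {
    arr <- label_arrangements(groups)
    Fs <- apply(arr, 1, function(a)
      permanova_F(d2, factor(levels(groups)[a], levels = levels(groups)))[["F"]])
    p <- mean(Fs >= obs[["F"]] - eps)
    n_perm <- 0L
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_permutations)) {
      Fp <- permanova_F(d2, groups[sample.int(n)])[["F"]]
      if (Fp >= obs[["F"]] - eps) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_permutations)
    n_perm <- as.integer(n_permutations)
  }
  structure(list(pseudo_F = unname(obs[["F"]]), R2 = unname(obs[["R2"]]),
                 p_value = p, n_permutations = n_perm, exact = exact,
                 seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F = ", format(x$pseudo_F, digits = 5), ", R2 = ",
      format(x$R2, digits = 4), ", p = ", format(x$p_value, digits = 4),
      if (x$exact) " (exact enumeration)" else
        paste0(" (", x$n_permutations, " permutations)"), "\n", sep = "")
  invisible(x)
}
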