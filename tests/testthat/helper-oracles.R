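# Independent oracles and small fixture builders shared across tests.

# tiny feature table from a plain matrix
make_ft <- function(m, marker = "18S") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("SV_", seq_len(ncol(m)))
  feature_table(m, marker = marker)
}

# wrap a plain clr matrix (samples x features) as a single-instance ensemble
make_clr <- function(x) {
  structure(list(values = array(x, c(1, nrow(x), ncol(x))),
                 sample_ids = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                 sv_ids = colnames(x) %||% paste0("SV_", seq_len(ncol(x))),
                 M = 1L, prior = 0, mode = "point_estimate", seed = NULL),
            class = "clr_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force double-loop phi on one clr matrix
naive_phi <- function(x, symmetrization = "max") {
  n_f <- ncol(x)
  out <- matrix(0, n_f, n_f, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n_f)) for (j in seq_len(n_f)) {
    if (i == j) next
    out[i, j] <- stats::var(x[, i] - x[, j]) / stats::var(x[, i])
  }
  sym <- switch(symmetrization,
                max = pmax(out, t(out)), min = pmin(out, t(out)),
                mean = (out + t(out)) / 2)
  diag(sym) <- 0
  sym
}

# union-find connected components over an edge list (two-column matrix)
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in seq_len(nrow(edges))) {
    ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  unname(split(nodes, roots))
}

# studentized-range CDF by direct double quadrature (independent of ptukey)
ptukey_oracle <- function(q, k, df) {
  p_range <- function(r) {
    vapply(r, function(ri) stats::integrate(function(z)
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - ri))^(k - 1),
      -9, 9, rel.tol = 1e-10)$value, 1)
  }
  # S = sqrt(chi2_df / df); integrate P(range <= q s) against f_S
  fs <- function(s) exp((df / 2) * log(df) - (df / 2 - 1) * log(2) -
                          lgamma(df / 2) + (df - 1) * log(s) - df * s^2 / 2)
  stats::integrate(function(s) fs(s) * p_range(q * s), 0, Inf,
                   rel.tol = 1e-8)$value
}

# canonical unordered pair keys for edge-set comparisons
pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b))

edge_keys <- function(net) pair_keys(net$edges$sv_a, net$edges$sv_b)

planted_keys <- function(truth) {
  pp <- planted_pairs(truth)
  pair_keys(pp[, 1], pp[, 2])
}
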