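test_that("rarefaction subsamples to exact depth without replacement", {
  expect_equal(unname(unclass(rarefy_even_depth(
    make_ft(matrix(c(4, 0, 0), 1, 3)), depth = 2, seed = 1))[1, ]),
    c(2, 0, 0))
  sim <- generate_community(n_sv = 20, n_modules = 2, module_size = 3, seed = 2)
  r <- rarefy_even_depth(sim$feature_table, seed = 10)
  expect_true(all(rowSums(r) == min(rowSums(sim$feature_table))))
  # without replacement: never more reads of an SV than it had
  expect_true(all(unclass(r) <= unclass(sim$feature_table)))
  # seed-fixed reproducibility; samples under the depth get dropped
  r2 <- rarefy_even_depth(sim$feature_table, seed = 10)
  expect_identical(unclass(r), unclass(r2))
  expect_warning(r3 <- rarefy_even_depth(sim$feature_table,
                                         depth = sort(rowSums(sim$feature_table))[3],
                                         seed = 1), "dropped")
  expect_equal(nrow(r3), 34)
  expect_error(rarefy_even_depth(make_ft(matrix(c(2, 1), 1, 2)), depth = 10,
                                 seed = 1), "fewer")
})

test_that("Shannon index matches closed forms and the summation oracle", {
  expect_equal(shannon_index(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  oracle <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
  expect_equal(shannon_index(c(1, 2, 3)), oracle(c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  # H <= ln(S), equality iff uniform; agreement with vegan
  set.seed(1)
  for (rep in 1:10) {
    x <- rpois(8, 20) + 1
    expect_lte(shannon_index(x), log(length(x)))
    expect_equal(shannon_index(x), vegan::diversity(x, "shannon"),
                 tolerance = 1e-12)
  }
})

test_that("Tukey-Kramer q and p behave and match a quadrature oracle", {
  vals <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- tukey_kramer(vals)
  expect_equal(res$q, 0)
  expect_equal(res$p_value, 1)
  # widening the gap between two means strictly decreases p
  base <- list(a = c(0, 1, 2), b = c(3, 4, 5), c = c(1.5, 2.5, 3.5))
  p1 <- tukey_kramer(base)
  base$b <- base$b + 2
  p2 <- tukey_kramer(base)
  pick <- function(x) x$p_value[x$group_a == "a" & x$group_b == "b"]
  expect_lt(pick(p2), pick(p1))
  # balanced 3-group fixture against the studentized-range CDF oracle
  set.seed(42)
  vals <- list(g1 = rnorm(5, 0), g2 = rnorm(5, 1), g3 = rnorm(5, 2))
  res <- tukey_kramer(vals)
  for (r in seq_len(nrow(res))) {
    p_or <- 1 - ptukey_oracle(res$q[r], k = 3, df = attr(res, "df"))
    expect_equal(res$p_value[r], p_or, tolerance = 1e-3)
  }
  # zero pooled variance with unequal means: flagged machine-floor p
  degen <- tukey_kramer(list(a = c(1, 1), b = c(2, 2)))
  expect_true(degen$degenerate)
  expect_lte(degen$p_value, .Machine$double.xmin)
})

test_that("Bray-Curtis matches the hand formula and is a bounded semimetric", {
  ft <- make_ft(rbind(c(2, 0, 1), c(1, 1, 0)))
  expect_equal(bray_curtis_matrix(ft)[1, 2], 0.6)  # 1 - 2*1/5
  ft2 <- make_ft(rbind(c(3, 1, 0), c(3, 1, 0), c(0, 0, 9)))
  d <- bray_curtis_matrix(ft2)
  expect_equal(d[1, 2], 0)       # identical samples
  expect_equal(d[1, 3], 1)       # disjoint support
  set.seed(7)
  m <- matrix(rpois(5 * 12, 15), 5, 12) + 1
  d <- bray_curtis_matrix(make_ft(m))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_lt(max(abs(d - t(d))), 1e-12)
  # hand-formula oracle on every pair
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j],
                 1 - 2 * sum(pmin(m[i, ], m[j, ])) / (sum(m[i, ]) + sum(m[j, ])),
                 tolerance = 1e-12)
  expect_error(bray_curtis_matrix(make_ft(rbind(c(1, 1), c(0, 0)))), "zero total")
})

test_that("NMDS embeds exactly embeddable configurations at near-zero stress", {
  # 3 points always embed in 2D
  d3 <- as.matrix(dist(matrix(c(0, 0, 3, 1, 1, 4), 3, 2)))
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  r3 <- nmds_ordinate(d3, k = 2, n_starts = 5, seed = 1)
  expect_lt(r3$stress, 1e-6)
  # planar points recovered from their exact Euclidean distances
  set.seed(3)
  pts <- matrix(rnorm(20), 10, 2)
  d10 <- as.matrix(dist(pts))
  r10 <- nmds_ordinate(d10, k = 2, n_starts = 10, seed = 5)
  expect_lt(r10$stress, 0.01)
  expect_true(all(diff(r10$stress_trace) <= 1e-9))  # majorization never worsens
  # strictly monotone transform of dissimilarities: optimal stress unchanged
  r10t <- nmds_ordinate(d10^1.5, k = 2, n_starts = 10, seed = 5)
  expect_equal(r10t$stress, r10$stress, tolerance = 0.005)
})

test_that("NMDS stress is comparable to an independent optimizer on real-shaped data", {
  sim <- generate_community(n_sv = 30, n_modules = 2, module_size = 4, seed = 8)
  d <- bray_curtis_matrix(rarefy_even_depth(sim$feature_table, seed = 1))
  ours <- nmds_ordinate(d, n_starts = 10, seed = 2)
  ref <- vegan::monoMDS(as.dist(d), k = 2)
  expect_lt(ours$stress, ref$stress + 0.02)  # monoMDS stress is also Kruskal-1
})

test_that("PERMANOVA reproduces the enumerable fixture exactly", {
  x <- c(0, 1, 10, 11)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- c("A", "A", "B", "B")
  res <- permanova(d, g, seed = 1)
  expect_true(res$exact)
  expect_equal(res$pseudo_F, 200)
  expect_equal(res$R2, 100 / 101)
  expect_equal(res$p_value, 1 / 3)
  # full-enumeration oracle built independently with combn
  d2 <- d^2
  n <- 4
  Fs <- apply(combn(4, 2), 2, function(idx) {
    gg <- factor(ifelse(seq_len(4) %in% idx, "A", "B"))
    ssw <- sum(sapply(levels(gg), function(l) {
      s <- which(gg == l); sum(d2[s, s][upper.tri(d2[s, s])]) / length(s)
    }))
    sst <- sum(d2[upper.tri(d2)]) / n
    ((sst - ssw) / 1) / (ssw / 2)
  })
  expect_equal(res$p_value, mean(Fs >= 200 - 1e-9))
})

test_that("PERMANOVA is invariant to sample order and matches adonis2", {
  sim <- generate_community(n_sv = 25, n_modules = 2, module_size = 4, seed = 6)
  d <- bray_curtis_matrix(rarefy_even_depth(sim$feature_table, seed = 3))
  g <- sample_groups(sim$metadata)
  res <- permanova(d, g, n_permutations = 199, seed = 9)
  perm <- sample(rownames(d))
  res2 <- permanova(d[perm, perm], g, n_permutations = 199, seed = 9)
  expect_equal(res$pseudo_F, res2$pseudo_F, tolerance = 1e-12)
  expect_equal(res$R2, res2$R2, tolerance = 1e-12)
  # independent implementation: vegan::adonis2 one-way
  gdf <- data.frame(g = as.character(g[rownames(d)]))
  ref <- vegan::adonis2(as.dist(d) ~ g, data = gdf, permutations = 99)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$R2, ref$R2[1], tolerance = 1e-10)
  # sampled p converges to the exact p on the 4-point fixture
  x <- c(0, 1, 10, 11)
  d4 <- as.matrix(dist(x))
  dimnames(d4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  approx <- permanova(d4, c("A", "A", "B", "B"), n_permutations = 9999,
                      seed = 2, exact_limit = 1)
  expect_false(approx$exact)
  expect_equal(approx$p_value, 1 / 3, tolerance = 0.02)
  expect_gte(approx$p_value, 1 / 10000)  # +1 correction floor
})
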