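# helper: phi matrix with named entries, everything else far above threshold
phi_fixture <- function(ids, edges, value = 0.01, fill = 10) {
  p <- matrix(fill, length(ids), length(ids), dimnames = list(ids, ids))
  diag(p) <- 0
  for (e in edges) { p[e[1], e[2]] <- value; p[e[2], e[1]] <- value }
  structure(p, class = c("phi_matrix", "matrix", "array"))
}

# helper: conetwork with prescribed node degrees via a star-ish edge list
net_from_edges <- function(ids, edges, threshold = 0.12, group = NULL) {
  build_conetwork(phi_fixture(ids, edges), threshold, group = group)
}

test_that("thresholding is strict and isolated SVs are not nodes", {
  ids <- paste0("SV_", 1:5)
  empty <- build_conetwork(phi_fixture(ids, list(), fill = 0.12), 0.12)
  expect_length(empty$nodes, 0)       # phi == threshold makes no edge
  expect_length(empty$components, 0)
  tri <- net_from_edges(ids, list(c("SV_1", "SV_2"), c("SV_1", "SV_3"),
                                  c("SV_2", "SV_3")))
  expect_setequal(tri$nodes, c("SV_1", "SV_2", "SV_3"))
  expect_equal(unname(tri$degrees[tri$nodes]), c(2, 2, 2))
  expect_length(tri$components, 1)
  expect_false("SV_4" %in% tri$nodes)
})

test_that("edge sets are monotone in the threshold and degree sum = 2E", {
  set.seed(5)
  sim <- generate_community(n_sv = 30, n_modules = 3, module_size = 4, seed = 5)
  g <- drop_zero_features(subset_by_group(sim$feature_table, sim$metadata,
                                          "field_2", "cabbage"))
  phi <- phi_matrix(clr_ensemble(g, M = 16, seed = 1))
  prev <- NULL
  for (thr in c(0.3, 0.12, 0.05)) {
    net <- build_conetwork(phi, thr)
    keys <- edge_keys(net)
    expect_equal(sum(net$degrees), 2 * nrow(net$edges))
    if (!is.null(prev)) expect_true(all(keys %in% prev))  # lower thr: subset
    prev <- keys
  }
})

test_that("components match a union-find oracle and are size-ordered", {
  set.seed(6)
  for (rep in 1:5) {
    ids <- paste0("SV_", 1:15)
    pairs <- t(combn(ids, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.12, , drop = FALSE]
    net <- net_from_edges(ids, split(pick, row(pick)))
    oracle <- uf_components(net$nodes, as.matrix(net$edges[, 1:2]))
    expect_equal(length(net$components), length(oracle))
    key <- function(sets) sort(vapply(sets, function(s) paste(sort(s), collapse = "|"), ""))
    expect_identical(key(net$components), key(oracle))
    sizes <- lengths(net$components)
    expect_true(all(diff(sizes) <= 0))  # descending
    # tie-break: equal-sized clusters ordered by smallest member id
    if (any(duplicated(sizes))) {
      for (s in unique(sizes[duplicated(sizes)])) {
        tied <- net$components[sizes == s]
        firsts <- vapply(tied, min, "")
        expect_identical(firsts, sort(firsts))
      }
    }
  }
})

test_that("core nSV selection uses ceiling k and includes boundary ties", {
  ids <- paste0("SV_", sprintf("%02d", 1:10))
  # unique hub of degree 5 among 10 nodes: k = ceil(0.1 * 10) = 1
  star <- c(lapply(ids[2:6], function(j) c(ids[1], j)),
            list(c(ids[7], ids[8]), c(ids[9], ids[10])))
  net <- net_from_edges(ids, star)
  expect_length(net$nodes, 10)
  expect_identical(classify_core_nsvs(net, 0.10), ids[1])
  # two tied hubs at the k = 1 boundary are both included
  ids2 <- paste0("T", 1:10)
  edges2 <- c(lapply(ids2[3:6], function(j) c(ids2[1], j)),
              lapply(ids2[5:8], function(j) c(ids2[2], j)))
  net2 <- net_from_edges(ids2, edges2)
  expect_equal(unname(net2$degrees[c("T1", "T2")]), c(4, 4))
  expect_identical(classify_core_nsvs(net2, 0.10), c("T1", "T2"))
  expect_setequal(classify_core_nsvs(net2, 1.0), net2$nodes)
  # order-independence: permuting the phi matrix changes nothing
  perm <- sample(ids2)
  net3 <- build_conetwork(phi_fixture(ids2, edges2)[perm, perm], 0.12)
  expect_identical(classify_core_nsvs(net3, 0.10), c("T1", "T2"))
  expect_identical(classify_core_nsvs(net_from_edges(ids, list()), 0.5),
                   character(0))
})

test_that("cross-network classification matches hand-computed sets", {
  # hand-built four-network fixture:
  # X in all four; M in both maize only; C1, C2 in both cabbage only;
  # F1 in both field_1 only; P in field_1:maize only (specific to nothing)
  mk <- function(ids, group) {
    edges <- lapply(ids[-1], function(j) c(ids[1], j))
    net_from_edges(ids, edges, group = group)
  }
  nets <- list(
    "field_1:maize" = mk(c("X", "M", "F1", "P"), "field_1:maize"),
    "field_2:maize" = mk(c("X", "M", "Q"), "field_2:maize"),
    "field_1:cabbage" = mk(c("X", "C1", "C2", "F1"), "field_1:cabbage"),
    "field_2:cabbage" = mk(c("X", "C1", "C2"), "field_2:cabbage"))
  cmp <- compare_networks(nets, top_fraction = 0.10)
  expect_identical(cmp$common, "X")
  expect_identical(cmp$crop_specific$maize, "M")
  expect_identical(cmp$crop_specific$cabbage, c("C1", "C2"))
  expect_identical(cmp$field_specific$field_1, "F1")
  expect_identical(cmp$field_specific$field_2, character(0))
  # hubs: first id of each network has max degree -> core under 10%
  expect_identical(cmp$core[["field_1:maize"]], "X")
  expect_error(compare_networks(nets[1:3]), "missing")
  # identical node sets: common = N, all specific sets empty
  nets4 <- list("field_1:maize" = mk(c("A", "B"), "field_1:maize"),
                "field_2:maize" = mk(c("A", "B"), "field_2:maize"),
                "field_1:cabbage" = mk(c("A", "B"), "field_1:cabbage"),
                "field_2:cabbage" = mk(c("A", "B"), "field_2:cabbage"))
  cmp4 <- compare_networks(nets4)
  expect_setequal(cmp4$common, c("A", "B"))
  expect_length(unlist(cmp4$crop_specific), 0)
  expect_length(unlist(cmp4$field_specific), 0)
})

test_that("node taxon summary fractions cover NA and sum to one", {
  ids <- c("SV_1", "SV_2", "SV_3", "SV_4")
  net <- net_from_edges(ids, lapply(ids[-1], function(j) c(ids[1], j)))
  tax <- validate_taxonomy(data.frame(
    sv_id = ids, phylum = c("Ascomycota", "Ascomycota", "Ascomycota", "Cercozoa")))
  s <- node_taxon_summary(net, tax)
  expect_equal(unname(s["Ascomycota"]), 0.75)
  expect_equal(unname(s["Cercozoa"]), 0.25)
  tax2 <- validate_taxonomy(data.frame(sv_id = ids[1:2], phylum = "Ascomycota"))
  s2 <- node_taxon_summary(net, tax2)   # uncovered nodes -> "NA"
  expect_equal(unname(s2["NA"]), 0.5)
  expect_equal(sum(s2), 1)
})

test_that("the node ledger flags core/common/specific per group row", {
  mk <- function(ids, group) net_from_edges(
    ids, lapply(ids[-1], function(j) c(ids[1], j)), group = group)
  nets <- list("field_1:maize" = mk(c("X", "M"), "field_1:maize"),
               "field_2:maize" = mk(c("X", "M"), "field_2:maize"),
               "field_1:cabbage" = mk(c("X", "C"), "field_1:cabbage"),
               "field_2:cabbage" = mk(c("X", "C"), "field_2:cabbage"))
  cmp <- compare_networks(nets, top_fraction = 0.5)
  led <- node_ledger(nets, cmp)
  expect_equal(nrow(led), 8)
  expect_true(all(led$common[led$sv_id == "X"]))
  expect_true(all(led$crop_specific[led$sv_id %in% c("M", "C")]))
  expect_false(any(led$field_specific))
  expect_true(all(led$cluster == 1))
})
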