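# Thresholded phi co-occurrence networks per sample group and the
# cross-group node classification (core / common / crop- and field-specific
# node SVs).

#' Build a thresholded phi co-occurrence network
#'
#' An edge joins two SVs iff `phi < threshold` (strict, matching the
#' published cutoffs `< 0.12` for eukaryotic and `< 0.08` for prokaryotic
#' SVs). Nodes (nSVs) are the SVs with at least one edge; isolated SVs are
#' not part of the network. Connected components are ordered by size
#' descending, ties broken by the lexicographically smallest member id, so
#' "cluster 1" is always the largest cluster.
#'
#' @param phi a `phi_matrix` (undefined rows are skipped).
#' @param threshold positive phi cutoff.
#' @param group optional `"field:crop"` group label carried in the result.
#' @return object of class `conetwork`: list with `group`, `threshold`,
#'   `nodes` (character), `edges` (data frame `sv_a`, `sv_b`, `phi`),
#'   `degrees` (named integer), `components` (list of node-id vectors,
#'   size-descending), `graph` (the underlying igraph object).
#' @export
build_conetwork <- function(phi, threshold, group = NULL) {
  stopifnot(threshold > 0)
  p <- as.matrix(phi)
  p[is.na(p)] <- Inf  # undefined phi never makes an edge
  ut <- upper.tri(p)
  hit <- which(ut & p < threshold, arr.ind = TRUE)
  edges <- data.frame(sv_a = rownames(p)[hit[, 1]],
                      sv_b = colnames(p)[hit[, 2]],
                      phi = p[cbind(hit[, 1], hit[, 2])],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, c("sv_a", "sv_b")],
                                     directed = FALSE)
  igraph::E(g)$phi <- edges$phi
  nodes <- igraph::V(g)$name
  degrees <- igraph::degree(g)
  comp <- igraph::components(g)
  comps <- split(names(comp$membership), comp$membership)
  smallest <- vapply(comps, function(x) min(x), "")
  ord <- order(-lengths(comps), smallest)
  comps <- unname(comps[ord])
  structure(list(group = group, threshold = threshold, nodes = nodes,
                 edges = edges, degrees = degrees, components = comps,
                 graph = g),
            class = "conetwork")
}

#' @export
print.conetwork <- function(x, ...) {
  cat("conetwork", if (!is.null(x$group)) paste0(" [", x$group, "]"),
      ": ", length(x$nodes), " nSVs, ", nrow(x$edges), " links, ",
      length(x$components), " clusters (largest ",
      if (length(x$components)) length(x$components[[1]]) else 0,
      "), phi < ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Core node SVs of a network
#'
#' The core nSVs are the top `top_fraction` of a network's nodes ranked by
#' degree ("link number"): `k = ceiling(top_fraction * n_nodes)`, and every
#' node tied with the k-th degree is included, so the returned set can
#' exceed `k`.
#'
#' @param net a `conetwork`.
#' @param top_fraction fraction in `(0, 1]` (0.10 for eukaryotic networks,
#'   0.05 for prokaryotic in the motivating study).
#' @return character vector of core node ids (empty for an empty network).
#' @export
classify_core_nsvs <- function(net, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  deg <- net$degrees
  if (!length(deg)) return(character(0))
  k <- ceiling(top_fraction * length(deg))
  cutoff <- sort(deg, decreasing = TRUE)[k]
  sort(names(deg)[deg >= cutoff])
}

#' Classify node SVs across the four group networks
#'
#' `common` nSVs appear in all four networks. A crop-specific nSV is
#' present in both networks of one crop and absent from both networks of
#' the other crop; field-specific analogously over fields. Core sets are
#' attached per network via [classify_core_nsvs()].
#'
#' @param nets named list of exactly four `conetwork`s, names (or `$group`)
#'   being the `"field:crop"` labels.
#' @param top_fraction core fraction passed to [classify_core_nsvs()].
#' @return object of class `network_comparison`: list with `common`,
#'   `crop_specific` (named list maize/cabbage), `field_specific` (named
#'   list field_1/field_2), `core` (named list per group), `nodes` (named
#'   list per group).
#' @export
compare_networks <- function(nets, top_fraction = 0.10) {
  if (is.null(names(nets)) || any(!nzchar(names(nets))))
    names(nets) <- vapply(nets, function(n) n$group %||% "", "")
  expected <- as.vector(outer(FIELDS, CROPS, paste, sep = ":"))
  miss <- setdiff(expected, names(nets))
  if (length(nets) != 4 || length(miss))
    stop("need exactly the four group networks; missing: ",
         paste(miss, collapse = ", "))
  nodes <- lapply(nets[expected], function(n) n$nodes)
  common <- sort(Reduce(intersect, nodes))
  in_both <- function(a, b) intersect(nodes[[a]], nodes[[b]])
  in_either <- function(a, b) union(nodes[[a]], nodes[[b]])
  crop_specific <- list(
    maize = sort(setdiff(in_both("field_1:maize", "field_2:maize"),
                         in_either("field_1:cabbage", "field_2:cabbage"))),
    cabbage = sort(setdiff(in_both("field_1:cabbage", "field_2:cabbage"),
                           in_either("field_1:maize", "field_2:maize"))))
  field_specific <- list(
    field_1 = sort(setdiff(in_both("field_1:maize", "field_1:cabbage"),
                           in_either("field_2:maize", "field_2:cabbage"))),
    field_2 = sort(setdiff(in_both("field_2:maize", "field_2:cabbage"),
                           in_either("field_1:maize", "field_1:cabbage"))))
  core <- lapply(nets[expected], classify_core_nsvs,
                 top_fraction = top_fraction)
  structure(list(common = common, crop_specific = crop_specific,
                 field_specific = field_specific, core = core,
                 nodes = nodes, top_fraction = top_fraction),
            class = "network_comparison")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Phylum breakdown of a network's node SVs
#'
#' @param net a `conetwork`.
#' @param tax a `taxonomy_table`; nodes it does not cover count as `"NA"`.
#' @param rank taxonomic rank to summarize at (default `"phylum"`).
#' @return named numeric vector of fractions summing to 1 (empty for an
#'   empty network).
#' @export
node_taxon_summary <- function(net, tax, rank = "phylum") {
  stopifnot(rank %in% TAX_RANKS)
  if (!length(net$nodes)) return(stats::setNames(numeric(0), character(0)))
  lab <- tax[[rank]][match(net$nodes, tax$sv_id)]
  lab[is.na(lab)] <- "NA"
  tab <- table(lab) / length(net$nodes)
  out <- as.numeric(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Tidy node ledger across the four group networks
#'
#' One row per (group, nSV) with degree, cluster id (1 = largest cluster),
#' core / common / specificity flags and the node's phylum.
#'
#' @param nets named list of the four group `conetwork`s.
#' @param comparison matching [compare_networks()] result.
#' @param tax a `taxonomy_table` or `NULL`.
#' @return data frame.
#' @export
node_ledger <- function(nets, comparison, tax = NULL) {
  rows <- lapply(names(comparison$nodes), function(gname) {
    net <- nets[[gname]]
    if (!length(net$nodes)) return(NULL)
    cluster <- integer(0)
    for (i in seq_along(net$components))
      cluster[net$components[[i]]] <- i
    fld <- sub(":.*", "", gname); crp <- sub(".*:", "", gname)
    data.frame(group = gname, sv_id = net$nodes,
               degree = as.integer(net$degrees[net$nodes]),
               cluster = cluster[net$nodes],
               core = net$nodes %in% comparison$core[[gname]],
               common = net$nodes %in% comparison$common,
               crop_specific = net$nodes %in% comparison$crop_specific[[crp]],
               field_specific = net$nodes %in% comparison$field_specific[[fld]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), sv_id = character(0),
                      degree = integer(0), cluster = integer(0),
                      core = logical(0), common = logical(0),
                      crop_specific = logical(0), field_specific = logical(0))
  if (!is.null(tax)) {
    out$phylum <- tax$phylum[match(out$sv_id, tax$sv_id)]
    out$phylum[is.na(out$phylum)] <- "NA"
  }
  out <- out[order(out$group, -out$degree, out$sv_id), ]
  rownames(out) <- NULL
  out
}

#' Export a network as GraphML and an edge-list TSV
#'
#' @param net a `conetwork`.
#' @param graphml_path GraphML output path (skipped if `NULL`).
#' @param edgelist_path TSV output path (skipped if `NULL`).
#' @return invisibly, the paths written.
#' @export
write_conetwork <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edgelist_path))
    write_tsv(net$edges, edgelist_path)
  invisible(c(graphml_path, edgelist_path))
}
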