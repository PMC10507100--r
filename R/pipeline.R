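# Pipeline orchestration: one declarative config drives
# simulate -> diversity -> composition/network -> chemistry, with stage
# seeds derived deterministically from a master seed.

#' Build and validate a pipeline configuration
#'
#' Per-marker defaults follow the published analysis: phi threshold 0.12 and
#' core fraction 0.10 for 18S (eukaryote), 0.08 and 0.05 for 16S
#' (prokaryote); major-taxon abundance threshold 0.005 (18S) or 0.01 (16S).
#' Every stochastic stage derives its seed from `seed` by a fixed offset.
#'
#' @param marker `"18S"` or `"16S"`.
#' @param seed master seed (required).
#' @param simulate list of overrides for [generate_community()] /
#'   [generate_chemistry()], or `NULL` to read tables from `paths`.
#' @param paths named list (`feature_table`, `metadata`, `taxonomy`,
#'   `chemistry`, optional `orientation`) when not simulating.
#' @param phi_threshold,core_fraction,abundance_threshold analysis cutoffs;
#'   `NULL` picks the per-marker default.
#' @param M,prior Monte-Carlo clr settings.
#' @param n_permutations PERMANOVA permutations.
#' @param n_starts NMDS random starts.
#' @param min_prevalence minimum number of samples with nonzero count for an
#'   SV to enter the per-group clr/phi computation (default 1).
#' @param top_k_assoc features reported per chemistry parameter.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(marker = c("18S", "16S"), seed,
                            simulate = list(), paths = NULL,
                            phi_threshold = NULL, core_fraction = NULL,
                            abundance_threshold = NULL,
                            M = 128, prior = 0.5, n_permutations = 999,
                            n_starts = 20, min_prevalence = 1,
                            top_k_assoc = 10) {
  marker <- match.arg(marker)
  if (missing(seed) || is.null(seed)) stop("config missing key: seed")
  defaults <- if (marker == "18S")
    list(phi_threshold = 0.12, core_fraction = 0.10, abundance_threshold = 0.005)
  else
    list(phi_threshold = 0.08, core_fraction = 0.05, abundance_threshold = 0.01)
  cfg <- list(marker = marker, seed = as.integer(seed),
              simulate = simulate, paths = paths,
              phi_threshold = phi_threshold %||% defaults$phi_threshold,
              core_fraction = core_fraction %||% defaults$core_fraction,
              abundance_threshold = abundance_threshold %||% defaults$abundance_threshold,
              M = M, prior = prior, n_permutations = n_permutations,
              n_starts = n_starts, min_prevalence = min_prevalence,
              top_k_assoc = top_k_assoc)
  for (key in c("phi_threshold", "core_fraction", "abundance_threshold"))
    if (is.null(cfg[[key]]) || !is.finite(cfg[[key]]) || cfg[[key]] <= 0)
      stop("config missing key: ", key)
  class(cfg) <- "pipeline_config"
  cfg
}

# fixed per-stage seed offsets; all well below 2^31
stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 101L, chemistry = 211L, rarefy = 307L,
               nmds = 401L, permanova = 503L, clr = 601L)
  cfg$seed + offsets[[stage]]
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> relative-abundance aggregation ->
#' rarefied alpha/beta diversity (Shannon + Tukey-Kramer, NMDS, PERMANOVA)
#' -> chemistry normalization/clustering and RDA -> per-group clr, phi and
#' co-occurrence networks -> cross-network node classification, writing
#' every output table under `out_dir`. Running twice with the same config
#' produces byte-identical ledger TSVs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory results (`feature_table`,
#'   `metadata`, `taxonomy`, `chemistry`, `diversity`, `networks`,
#'   `comparison`, `rda`, `paths` of all files written).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  log_line("phiconet ", as.character(utils::packageVersion("phiconet")),
           " | R ", paste(R.version$major, R.version$minor, sep = "."))
  log_line("master seed: ", config$seed, " | marker: ", config$marker)
  paths <- list()
  emit <- function(name, writer) { paths[[name]] <<- writer; log_line("wrote ", paths[[name]]) }

  # -- inputs ----------------------------------------------------------------
  if (!is.null(config$paths)) {
    p <- config$paths
    ft <- read_feature_table(p$feature_table, marker = config$marker,
                             orientation = p$orientation %||% "svs-rows")
    mt <- read_metadata_taxonomy(p$metadata, p$taxonomy)
    meta <- mt$metadata; tax <- mt$taxonomy
    chem <- read_chem_table(p$chemistry)
    truth <- NULL
    log_line("loaded ", nrow(ft), " samples x ", ncol(ft), " SVs")
  } else {
    sim_args <- config$simulate
    sim_args$marker <- config$marker
    sim_args$seed <- sim_args$seed %||% stage_seed(config, "simulate")
    sim <- do.call(generate_community, sim_args)
    ft <- sim$feature_table; meta <- sim$metadata; tax <- sim$taxonomy
    truth <- sim$truth
    chem <- generate_chemistry(meta, seed = stage_seed(config, "chemistry"))
    emit("feature_table", write_feature_table(ft, file.path(out_dir, "feature_table.tsv")))
    emit("metadata", write_tsv(meta, file.path(out_dir, "metadata.tsv")))
    emit("taxonomy", write_tsv(tax, file.path(out_dir, "taxonomy.tsv")))
    emit("chemistry", write_tsv(chem, file.path(out_dir, "chemistry.tsv")))
    emit("truth", write_truth(truth, file.path(out_dir, "truth.json")))
    log_line("simulated ", nrow(ft), " samples x ", ncol(ft), " SVs")
  }
  check_joined(ft, meta, tax)
  groups <- sample_groups(meta)

  # -- relative abundance ----------------------------------------------------
  for (rank in c("phylum", "family", "genus")) {
    ra <- aggregate_relative_abundance(ft, tax, rank,
                                       threshold = config$abundance_threshold)
    df <- data.frame(sample_id = rownames(ra), as.data.frame(unclass(ra)),
                     check.names = FALSE)
    emit(paste0("rel_abundance_", rank),
         write_tsv(df, file.path(out_dir, paste0("rel_abundance_", rank, ".tsv"))))
  }

  # -- diversity -------------------------------------------------------------
  rft <- rarefy_even_depth(ft, seed = stage_seed(config, "rarefy"))
  log_line("rarefied to depth ", attr(rft, "rarefaction_depth"))
  shannon <- shannon_samples(rft)
  sh_df <- data.frame(sample_id = names(shannon),
                      group = as.character(groups[names(shannon)]),
                      shannon = shannon)
  emit("shannon", write_tsv(sh_df, file.path(out_dir, "shannon.tsv")))
  tk <- tukey_kramer(split(shannon, as.character(groups[names(shannon)])))
  emit("tukey_kramer", write_tsv(tk, file.path(out_dir, "shannon_tukey_kramer.tsv")))
  bc <- bray_curtis_matrix(rft)
  bc_df <- data.frame(sample_id = rownames(bc), as.data.frame(unclass(bc)),
                      check.names = FALSE)
  emit("bray_curtis", write_tsv(bc_df, file.path(out_dir, "bray_curtis.tsv")))
  nm <- nmds_ordinate(bc, n_starts = config$n_starts,
                      seed = stage_seed(config, "nmds"))
  nm_df <- data.frame(sample_id = rownames(nm$coordinates),
                      as.data.frame(nm$coordinates))
  emit("nmds", write_tsv(nm_df, file.path(out_dir, "nmds_coordinates.tsv")))
  log_line("NMDS stress ", format(nm$stress, digits = 5))
  pm <- permanova(bc, groups, n_permutations = config$n_permutations,
                  seed = stage_seed(config, "permanova"))
  jsonlite::write_json(unclass(pm), file.path(out_dir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA)
  paths$permanova <- file.path(out_dir, "permanova.json")
  log_line("PERMANOVA R2 ", format(pm$R2, digits = 4), ", p ", pm$p_value)

  # -- chemistry -------------------------------------------------------------
  pct <- percent_normalize_chem(chem)
  pct_df <- data.frame(cell = rownames(pct), as.data.frame(pct),
                       check.names = FALSE)
  emit("chem_percent", write_tsv(pct_df, file.path(out_dir, "chem_percent.tsv")))
  hc <- cluster_samples_complete_linkage(pct)
  emit("chem_dendrogram", write_dendrogram(hc, file.path(out_dir, "chem_dendrogram.tsv")))
  chem_s <- chem_to_samples(chem, meta)[sample_ids(ft), , drop = FALSE]
  clrp <- clr_point(drop_zero_features(ft), prior = config$prior)
  rda <- rda_fit(clrp, chem_s)
  emit("rda_site", write_tsv(
    data.frame(sample_id = rownames(rda$site_scores),
               as.data.frame(rda$site_scores)),
    file.path(out_dir, "rda_site_scores.tsv")))
  emit("rda_features", write_tsv(
    data.frame(feature = rownames(rda$feature_scores),
               as.data.frame(rda$feature_scores)),
    file.path(out_dir, "rda_feature_scores.tsv")))
  emit("rda_biplot", write_tsv(
    data.frame(parameter = rownames(rda$biplot_vectors),
               as.data.frame(rda$biplot_vectors)),
    file.path(out_dir, "rda_biplot_vectors.tsv")))
  log_line("RDA constrained fraction ", format(rda$constrained_fraction, digits = 4))
  assoc <- feature_parameter_association(clrp, chem_s,
                                         top_k = config$top_k_assoc,
                                         abundance = colSums(ft))
  emit("associations", write_tsv(assoc, file.path(out_dir, "feature_parameter_assoc.tsv")))

  # -- per-group networks ----------------------------------------------------
  nets <- list()
  for (field in FIELDS) for (crop in CROPS) {
    gname <- paste(field, crop, sep = ":")
    gft <- drop_zero_features(subset_by_group(ft, meta, field, crop))
    prev <- colSums(unclass(gft) > 0)
    gft <- ft_replace(gft, unclass(gft)[, prev >= config$min_prevalence,
                                        drop = FALSE])
    ce <- clr_ensemble(gft, M = config$M, prior = config$prior,
                       seed = stage_seed(config, "clr"))
    phi <- phi_matrix(ce)
    tag <- paste0(sub("field_", "f", field), "_", crop)
    emit(paste0("phi_", tag),
         write_phi_long(phi, file.path(out_dir, paste0("phi_", tag, ".tsv"))))
    net <- build_conetwork(phi, config$phi_threshold, group = gname)
    write_conetwork(net,
                    graphml_path = file.path(out_dir, paste0("network_", tag, ".graphml")),
                    edgelist_path = file.path(out_dir, paste0("edges_", tag, ".tsv")))
    paths[[paste0("network_", tag)]] <- file.path(out_dir, paste0("network_", tag, ".graphml"))
    paths[[paste0("edges_", tag)]] <- file.path(out_dir, paste0("edges_", tag, ".tsv"))
    log_line(gname, ": ", length(net$nodes), " nSVs, ", nrow(net$edges),
             " links, ", length(net$components), " clusters")
    nets[[gname]] <- net
  }
  comparison <- compare_networks(nets, top_fraction = config$core_fraction)
  ledger <- node_ledger(nets, comparison, tax)
  emit("node_ledger", write_tsv(ledger, file.path(out_dir, "node_ledger.tsv")))
  pies <- do.call(rbind, lapply(names(nets), function(g) {
    s <- node_taxon_summary(nets[[g]], tax)
    if (!length(s)) return(NULL)
    data.frame(group = g, phylum = names(s), fraction = as.numeric(s))
  }))
  if (!is.null(pies))
    emit("node_phylum_summary",
         write_tsv(pies, file.path(out_dir, "node_phylum_summary.tsv")))
  log_line("common nSVs: ", length(comparison$common),
           " | maize-specific: ", length(comparison$crop_specific$maize),
           " | cabbage-specific: ", length(comparison$crop_specific$cabbage))

  cfg_out <- config
  class(cfg_out) <- NULL
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths$config <- file.path(out_dir, "config.json")
  log_line("done")
  invisible(list(feature_table = ft, metadata = meta, taxonomy = tax,
                 chemistry = chem, truth = truth,
                 diversity = list(shannon = sh_df, tukey = tk,
                                  bray_curtis = bc, nmds = nm, permanova = pm),
                 rda = rda, associations = assoc, networks = nets,
                 comparison = comparison, node_ledger = ledger,
                 paths = paths))
}
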