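# Synthetic multi-domain soil community with planted proportional modules.
#
# The generator emulates the 36-sample rotation design (2 fields x 2 crops x
# 3 growth stages x 3 replicates). Per-sample basis abundances are
# log-normal; members of a planted module share a per-sample latent
# log-factor so their ratios are nearly constant (low phi), while
# non-module SVs fluctuate independently on the same scale. Observed counts
# are multinomial draws at a library depth sampled from depth_range.

EUK_PHYLA <- c("Ascomycota", "Basidiomycota", "Cercozoa", "Ciliophora",
               "Mucoromycota", "Oomycota", "NA")
PROK_PHYLA <- c("Pseudomonadota", "Acidobacteriota", "Actinomycetota",
                "Gemmatimonadota", "Bacteroidota", "Planctomycetota", "NA")

#' Build the 36-sample rotation design metadata
#'
#' @param n_replicates replicates per (field, crop, stage) cell (default 3).
#' @return a `sample_metadata` data frame with
#'   `2 x 2 x 3 x n_replicates` rows.
#' @export
rotation_design <- function(n_replicates = 3) {
  df <- expand.grid(replicate = seq_len(n_replicates), stage = STAGES,
                    crop = CROPS, field = FIELDS,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("field", "crop", "stage", "replicate")]
  df$sample_id <- sprintf("%s.%s.%s.r%d", sub("field_", "f", df$field),
                          substr(df$crop, 1, 3), substr(df$stage, 1, 3),
                          df$replicate)
  validate_sample_metadata(df[, c("sample_id", "field", "crop", "stage", "replicate")])
}

#' Generate a synthetic community with planted proportional modules
#'
#' Log basis abundance of SV i in sample s is
#' `b_i + L_{s,m(i)} + eps_{s,i} + g_{i,group(s)}`: a fixed per-SV baseline
#' `b_i ~ N(0, baseline_log_sd)`, a per-sample latent factor shared by all
#' members of module `m(i)` (`sd = module_latent_sd`), idiosyncratic noise
#' (`sd = within_module_noise_sd` for module members; non-module SVs instead
#' receive independent per-sample variation with `sd = module_latent_sd`,
#' the background sample-to-sample variability), and a group effect.
#' Counts are multinomial at a depth drawn uniformly from `depth_range`,
#' or the exact basis proportions when `counts_mode = "basis"`.
#'
#' @param n_sv number of SVs.
#' @param n_modules number of planted proportional modules.
#' @param module_size SVs per module (`n_modules * module_size <= n_sv`).
#' @param module_latent_sd log-scale sd of the shared module latent (and of
#'   the background variation of non-module SVs).
#' @param within_module_noise_sd log-scale sd of idiosyncratic noise inside
#'   modules; keep well below `module_latent_sd` for recoverable modules.
#' @param baseline_log_sd log-scale sd of per-SV baseline abundances.
#' @param group_effects either a numeric sd (each SV x group log-fold shift
#'   drawn `N(0, sd)`), or an explicit `n_sv x 4` matrix with columns named
#'   by the `"field:crop"` group labels, or `NULL` for no group structure.
#' @param depth_range integer interval for library depths.
#' @param marker `"18S"` (eukaryote taxonomy preset) or `"16S"` (prokaryote).
#' @param counts_mode `"multinomial"` (default) or `"basis"` (skip the
#'   sequencing step; counts are basis proportions scaled to
#'   `max(depth_range)`, useful for noise-free checks).
#' @param n_replicates replicates per design cell.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `feature_table`, `taxonomy`, `metadata`, `truth`.
#'   `truth` records module assignments, all latent parameters, the group
#'   effect matrix, per-sample depths and the seed.
#' @export
generate_community <- function(n_sv = 50, n_modules = 5, module_size = 5,
                               module_latent_sd = 1.0,
                               within_module_noise_sd = 0.05,
                               baseline_log_sd = 1.0,
                               group_effects = 1.25,
                               depth_range = c(20000L, 60000L),
                               marker = c("18S", "16S"),
                               counts_mode = c("multinomial", "basis"),
                               n_replicates = 3, seed) {
  marker <- match.arg(marker)
  counts_mode <- match.arg(counts_mode)
  if (missing(seed)) stop("seed is required")
  if (n_modules * module_size > n_sv)
    stop("infeasible module packing: ", n_modules, " x ", module_size,
         " > ", n_sv, " SVs")
  stopifnot(within_module_noise_sd >= 0, module_latent_sd > 0)
  set.seed(seed)

  meta <- rotation_design(n_replicates)
  n_samples <- nrow(meta)
  groups <- sample_groups(meta)
  group_levels <- levels(groups)
  svs <- sprintf("SV_%03d", seq_len(n_sv))
  module <- rep(NA_integer_, n_sv)
  module[seq_len(n_modules * module_size)] <- rep(seq_len(n_modules),
                                                  each = module_size)

  b <- stats::rnorm(n_sv, 0, baseline_log_sd)
  if (is.null(group_effects)) {
    g_eff <- matrix(0, n_sv, 4, dimnames = list(svs, group_levels))
  } else if (is.matrix(group_effects)) {
    if (nrow(group_effects) != n_sv ||
        !all(group_levels %in% colnames(group_effects)))
      stop("group_effects matrix must be n_sv x 4 with group-label columns")
    g_eff <- group_effects[, group_levels, drop = FALSE]
    rownames(g_eff) <- svs
  } else {
    g_eff <- matrix(stats::rnorm(n_sv * 4, 0, group_effects), n_sv, 4,
                    dimnames = list(svs, group_levels))
  }

  latent <- matrix(stats::rnorm(n_samples * n_modules, 0, module_latent_sd),
                   n_samples, n_modules)
  eps <- matrix(0, n_samples, n_sv)
  in_mod <- !is.na(module)
  eps[, in_mod] <- stats::rnorm(n_samples * sum(in_mod), 0,
                                within_module_noise_sd)
  eps[, !in_mod] <- stats::rnorm(n_samples * sum(!in_mod), 0,
                                 module_latent_sd)

  logbasis <- matrix(b, n_samples, n_sv, byrow = TRUE) + eps +
    t(g_eff[, as.character(groups[meta$sample_id])])
  logbasis[, in_mod] <- logbasis[, in_mod] + latent[, module[in_mod]]
  basis <- exp(logbasis)
  basis <- basis / rowSums(basis)
  dimnames(basis) <- list(meta$sample_id, svs)

  # uniform integer depths; sample.int avoids the length-1 sample() pitfall
  depths <- depth_range[1] +
    sample.int(depth_range[2] - depth_range[1] + 1L, n_samples,
               replace = TRUE) - 1L
  if (counts_mode == "multinomial") {
    counts <- t(vapply(seq_len(n_samples),
                       function(s) stats::rmultinom(1, depths[s], basis[s, ])[, 1],
                       numeric(n_sv)))
  } else {
    counts <- round(basis * max(depth_range) * 1e6)  # exact ratios preserved up to rounding
  }
  dimnames(counts) <- dimnames(basis)

  tax <- synthetic_taxonomy(svs, marker)
  truth <- list(module_assignments = stats::setNames(module, svs),
                module_latent_sd = module_latent_sd,
                within_module_noise_sd = within_module_noise_sd,
                baseline_log_sd = baseline_log_sd,
                group_effects = g_eff, depth_range = as.integer(depth_range),
                depths = stats::setNames(as.integer(depths), meta$sample_id),
                counts_mode = counts_mode, marker = marker,
                seed = as.integer(seed), basis = basis)
  class(truth) <- "synthetic_truth"
  list(feature_table = feature_table(counts, meta$sample_id, svs,
                                     marker = if (marker == "18S") "18S" else "16S"),
       taxonomy = tax, metadata = meta, truth = truth)
}

# deterministic taxonomy labels from the phylum pools; a slice of SVs stays
# unassigned ("NA") at phylum level like real SILVA assignments do
synthetic_taxonomy <- function(svs, marker) {
  pool <- if (marker == "18S") EUK_PHYLA else PROK_PHYLA
  domain <- if (marker == "18S") "Eukaryota" else "Bacteria"
  phyla <- pool[(seq_along(svs) - 1L) %% length(pool) + 1L]
  mk <- function(prefix) ifelse(phyla == "NA", "NA",
                                paste0(phyla, "_", prefix,
                                       (seq_along(svs) - 1L) %/% length(pool) %% 3 + 1L))
  validate_taxonomy(data.frame(sv_id = svs, domain = domain, phylum = phyla,
                               class = mk("c"), order = mk("o"),
                               family = mk("f"), genus = mk("g"),
                               stringsAsFactors = FALSE))
}

#' Planted same-module SV pairs
#'
#' @param truth a `synthetic_truth`.
#' @return two-column character matrix of unordered same-module SV pairs.
#' @export
planted_pairs <- function(truth) {
  mod <- truth$module_assignments
  out <- NULL
  for (m in unique(mod[!is.na(mod)])) {
    members <- names(mod)[!is.na(mod) & mod == m]
    if (length(members) >= 2) out <- rbind(out, t(utils::combn(members, 2)))
  }
  out
}

#' Serialize / reload a synthetic truth as JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path JSON path.
#' @return `path` (write) or the reloaded `synthetic_truth` (read).
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$basis <- NULL  # large; regenerate from seed when needed
  x$group_effects <- data.frame(sv_id = rownames(x$group_effects),
                                x$group_effects, check.names = FALSE)
  # named atomic vectors lose names in JSON arrays; ship them as tables
  x$module_assignments <- data.frame(sv_id = names(truth$module_assignments),
                                     module = unname(truth$module_assignments))
  x$depths <- data.frame(sample_id = names(truth$depths),
                         depth = unname(truth$depths))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ge <- x$group_effects
  m <- as.matrix(ge[, setdiff(names(ge), "sv_id"), drop = FALSE])
  rownames(m) <- ge$sv_id
  x$group_effects <- m
  x$module_assignments <- stats::setNames(as.integer(x$module_assignments$module),
                                          x$module_assignments$sv_id)
  x$depths <- stats::setNames(as.integer(x$depths$depth), x$depths$sample_id)
  class(x) <- "synthetic_truth"
  x
}

# -- chemistry ---------------------------------------------------------------

chem_baselines <- function() {
  c(CEC = 25, pH_H2O = 6.5, pH_KCl = 5.8, NO3_N = 10, NH4_N = 5, K2O = 40,
    MgO = 30, CaO = 300, EC = 0.3, Tr_P2O5 = 50, Humus = 5, WC = 0.25)
}

#' Default chemistry effect map for the rotation world
#'
#' Encodes the qualitative structure of the measured soils: nitrate and
#' ammonium nitrogen and conductivity high under maize at the early and
#' middle stages (fertilizer before sowing), humus high in field_1 (green
#' manure the previous year), water and exchangeable nutrients high in
#' field_2.
#'
#' @return named list: parameter -> named numeric vector of shifts keyed by
#'   field, crop, stage or `"field:crop"` group label.
#' @export
default_chem_effects <- function() {
  list(NO3_N = c(maize = 8, early = 6, middle = 3),
       NH4_N = c(maize = 4, early = 3, middle = 1.5),
       EC = c(maize = 0.25, early = 0.15),
       Humus = c(field_1 = 3),
       WC = c(field_2 = 0.15),
       K2O = c(field_2 = 20), MgO = c(field_2 = 15), CaO = c(field_2 = 100),
       Tr_P2O5 = c(field_2 = 30), CEC = c(field_2 = 6),
       pH_H2O = c(cabbage = 0.4), pH_KCl = c(cabbage = 0.4))
}

#' Generate a soil-chemistry table tied to the design
#'
#' One row per (field, crop, stage) cell — 12 rows for the full design.
#' `value = baseline + sum of matching shifts + Gaussian noise`, clipped at
#' 0; water content (`WC`) additionally clipped to `[0, 1]`. Noise sd is
#' `noise_sd` times each parameter's baseline (parameters live on very
#' different scales).
#'
#' @param meta a `sample_metadata` (defines the design cells).
#' @param effect_map list mapping parameter name to a named vector of
#'   shifts; keys may be a field, crop, stage, or `"field:crop"` label.
#' @param noise_sd relative noise level (fraction of baseline).
#' @param seed integer seed.
#' @return a `chem_table` (see [read_chem_table()]).
#' @export
generate_chemistry <- function(meta, effect_map = default_chem_effects(),
                               noise_sd = 0.05, seed) {
  if (missing(seed)) stop("seed is required")
  unknown <- setdiff(names(effect_map), CHEM_PARAMS)
  if (length(unknown))
    stop("unknown chemistry parameter(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  cells <- unique(meta[, c("field", "crop", "stage")])
  cells <- cells[order(cells$field, cells$crop, match(cells$stage, STAGES)), ]
  rownames(cells) <- NULL
  base <- chem_baselines()
  vals <- matrix(rep(base, each = nrow(cells)), nrow(cells), length(base),
                 dimnames = list(NULL, names(base)))
  for (p in names(effect_map)) {
    shifts <- effect_map[[p]]
    for (key in names(shifts)) {
      hit <- cells$field == key | cells$crop == key | cells$stage == key |
        paste(cells$field, cells$crop, sep = ":") == key
      vals[hit, p] <- vals[hit, p] + shifts[[key]]
    }
  }
  vals <- vals + matrix(stats::rnorm(length(vals)), nrow(vals)) *
    rep(base * noise_sd, each = nrow(vals))
  vals <- pmax(vals, 0)
  vals[, "WC"] <- pmin(vals[, "WC"], 1)
  validate_chem_table(cbind(cells, as.data.frame(vals)))
}

#' Broadcast cell-level chemistry to per-sample rows
#'
#' Chemistry is measured on composite (field, crop, stage) cells; ordination
#' needs one row per sample. Each cell's values are repeated for its
#' replicates.
#'
#' @param chem a `chem_table`.
#' @param meta a `sample_metadata`.
#' @return numeric matrix samples x 12 parameters, rownames = sample ids.
#' @export
chem_to_samples <- function(chem, meta) {
  key_c <- paste(chem$field, chem$crop, chem$stage)
  key_m <- paste(meta$field, meta$crop, meta$stage)
  idx <- match(key_m, key_c)
  if (anyNA(idx))
    stop("chemistry table lacks cell(s): ",
         paste(unique(key_m[is.na(idx)]), collapse = "; "))
  m <- as.matrix(chem[idx, CHEM_PARAMS])
  rownames(m) <- meta$sample_id
  m
}
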