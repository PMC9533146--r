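#' Assemble a pipeline configuration
#'
#' Central knob set for [run_pipeline()]. The defaults are the analysis'
#' canonical parameters — depth filter 3,000 reads, core prevalence 0.85,
#' correlation pruning at |rho| > 0.5, FDR 0.05, TVE over 5 axes, 9,999
#' PERMANOVA permutations — so a zero-argument configuration runs the
#' standard analysis. Either provide the four input paths or set
#' `synthetic = TRUE` to run on a freshly simulated cohort.
#'
#' @param counts,metadata,taxonomy,tree Input file paths (TSV / Newick).
#' @param synthetic If `TRUE`, simulate the cohort instead of reading files.
#' @param design A [synthetic_design()] used when `synthetic = TRUE`
#'   (default: the standard cohort design with `seed`).
#' @param rank Taxonomic rank for composition analyses (default genus).
#' @param min_depth Sample depth filter (reads).
#' @param prevalence Core prevalence threshold.
#' @param rho_threshold Network pruning threshold on |rho| (strict).
#' @param alpha FDR level for edge significance.
#' @param k TVE horizon (axes).
#' @param n_perm PERMANOVA permutations.
#' @param top_k Candidate-list size for the influence analysis.
#' @param candidate_mode `"centrality"` or `"abundance"`.
#' @param glm_families Family names used as biomass-model covariates
#'   (`NULL` = the 3 most abundant families).
#' @param normal_flora,disease_associated Paths to genus group lists
#'   (defaults: the bundled lists).
#' @param oxygen_annotation Optional path to a genus -> oxygen-class TSV.
#' @param seed Master seed for every stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts = NULL, metadata = NULL, taxonomy = NULL,
                            tree = NULL, synthetic = is.null(counts),
                            design = NULL, rank = "genus",
                            min_depth = 3000, prevalence = 0.85,
                            rho_threshold = 0.5, alpha = 0.05, k = 5,
                            n_perm = 9999, top_k = 50,
                            candidate_mode = c("centrality", "abundance"),
                            glm_families = NULL,
                            normal_flora = NULL, disease_associated = NULL,
                            oxygen_annotation = NULL, seed = 1L) {
  candidate_mode <- match.arg(candidate_mode)
  if (!synthetic && (is.null(counts) || is.null(metadata) ||
                     is.null(taxonomy) || is.null(tree)))
    stop("non-synthetic runs need counts, metadata, taxonomy and tree paths")
  stopifnot(min_depth >= 0, prevalence >= 0, prevalence <= 1,
            rho_threshold >= 0, rho_threshold <= 1,
            alpha >= 0, alpha <= 1, k >= 0, n_perm >= 1, top_k >= 1)
  structure(list(
    counts = counts, metadata = metadata, taxonomy = taxonomy, tree = tree,
    synthetic = synthetic, design = design, rank = rank,
    min_depth = min_depth, prevalence = prevalence,
    rho_threshold = rho_threshold, alpha = alpha, k = k, n_perm = n_perm,
    top_k = top_k, candidate_mode = candidate_mode,
    glm_families = glm_families, normal_flora = normal_flora,
    disease_associated = disease_associated,
    oxygen_annotation = oxygen_annotation, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  flat <- unclass(config)
  flat$design <- if (is.null(flat$design)) NULL else unclass(flat$design)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(flat[!vapply(flat, is.null, logical(1))], tmp)
  unname(tools::md5sum(tmp))
}

pipeline_provenance <- function(config) {
  c(config_hash = config_hash(config),
    seed = as.character(config$seed),
    tool = paste0("dmftmicro ",
                  as.character(utils::packageVersion("dmftmicro"))))
}

#' Run the full DMFT microbiota analysis
#'
#' Orchestrates the stages in order: depth filtering (profile), taxonomic
#' aggregation, diversity and ordination with PERMANOVA, pan/core/accessory
#' partitioning, per-category co-occurrence networks with the entropy
#' statistic, leave-one-genus-out TVE influence, and per-category
#' quasi-Poisson biomass models. Writes per-stage TSV/JSON artifacts (each
#' with a provenance header recording the configuration hash, seed and tool
#' version) plus a machine-readable `summary.json`. Identical configuration
#' and seed give a byte-identical summary.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts (created if absent).
#' @return The summary list, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- pipeline_provenance(config)
  summary <- list(provenance = as.list(prov))

  ## input
  if (config$synthetic) {
    design <- if (is.null(config$design))
      synthetic_design(seed = config$seed) else config$design
    ds <- generate_dataset(design)
    table <- ds$table; metadata <- ds$metadata
    taxonomy <- ds$taxonomy; tree <- ds$tree
  } else {
    table <- read_table(config$counts)
    metadata <- read_metadata(config$metadata)
    taxonomy <- read_taxonomy(config$taxonomy)
    tree <- read_tree(config$tree)
  }

  ## profile: depth filter
  n_input <- nrow(table$counts)
  table <- filter_by_depth(table, config$min_depth)
  if (nrow(table$counts) == 0) stop("stage profile: no samples pass the depth filter")
  metadata <- metadata[metadata$sample_id %in% sample_ids(table), ]
  summary$profile <- list(min_depth = config$min_depth, n_input = n_input,
                          n_retained = nrow(table$counts),
                          n_dropped = n_input - nrow(table$counts))

  ## aggregate
  genus_table <- aggregate_rank(table, taxonomy, config$rank)
  family_table <- aggregate_rank(table, taxonomy, "family")
  write_table(genus_table, file.path(output_dir, "genus_table.tsv"),
              provenance = prov)
  summary$aggregate <- list(rank = config$rank,
                            n_taxa_input = ncol(table$counts),
                            n_taxa_aggregated = ncol(genus_table$counts))

  ## diversity
  groups <- as.character(metadata$dmft_category)[
    match(sample_ids(table), metadata$sample_id)]
  alpha <- data.frame(
    sample_id = sample_ids(table), dmft_category = groups,
    observed = apply(table$counts, 1, observed_richness),
    shannon = apply(table$counts, 1, shannon))
  con <- file(file.path(output_dir, "alpha_diversity.tsv"), "wt")
  writeLines(provenance_lines(prov), con)
  utils::write.table(alpha, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  dists <- list(
    bray_curtis = bray_curtis(table),
    jensen_shannon = jensen_shannon(table),
    unweighted_unifrac = unifrac(table, tree, weighted = FALSE),
    weighted_unifrac = unifrac(table, tree, weighted = TRUE))
  perm <- lapply(seq_along(dists), function(i)
    permanova(dists[[i]], groups, n_perm = config$n_perm,
              seed = config$seed + i))
  names(perm) <- names(dists)
  for (nm in names(dists))
    write_distance(dists[[nm]], file.path(output_dir, paste0(nm, ".tsv")),
                   provenance = prov)
  ord <- pcoa(dists$weighted_unifrac)
  write_ordination(ord, file.path(output_dir, "pcoa_weighted_unifrac.tsv"),
                   file.path(output_dir, "pcoa_weighted_unifrac.json"),
                   k = config$k, provenance = prov)
  summary$diversity <- list(
    alpha_mean = lapply(split(alpha$shannon, alpha$dmft_category), mean),
    tve = tve(ord, config$k),
    permanova = lapply(perm, function(x)
      list(pseudo_F = x$pseudo_F, R2 = x$R2, p = x$p)))

  ## partition
  part <- partition_by_category(genus_table, metadata, config$prevalence)
  core_all <- dmft_core(part)
  lists <- if (is.null(config$normal_flora)) read_genus_lists() else
    read_genus_lists(config$normal_flora, config$disease_associated)
  props <- lapply(part, function(p)
    if (p$n_samples > 0 && length(p$pan))
      as.list(richness_proportions(p$pan, core_all, lists, p$accessory))
    else NULL)
  write_partition(part, file.path(output_dir, "partition.json"),
                  provenance = as.list(prov))
  summary$partition <- list(
    sizes = lapply(part, function(p) as.list(p$sizes)),
    dmft_core_size = length(core_all),
    genus_list_source = lists$source,
    richness_proportions = props)

  ## network
  net_block <- list()
  graphs <- list()
  for (cat in DMFT_LEVELS) {
    ids <- metadata$sample_id[metadata$dmft_category == cat]
    ids <- intersect(ids, sample_ids(genus_table))
    if (length(ids) < 4) {
      warning("stage network: category ", cat, " has < 4 samples; skipped")
      next
    }
    sub <- feature_table(genus_table$counts[ids, , drop = FALSE])
    sp <- spearman_matrix(sub)
    g <- build_graph(sp$rho, sp$p, config$rho_threshold, config$alpha,
                     category = cat)
    graphs[[cat]] <- g
    comm <- communities(g)
    write_graph(g, file.path(output_dir, paste0("network_", cat, ".tsv")),
                provenance = prov)
    net_block[[cat]] <- list(
      n_samples = length(ids), n_edges = nrow(g$edges),
      n_significant_edges = sum(g$edges$significant),
      entropy_edges = if (nrow(g$edges)) entropy_statistic(g) else NULL,
      entropy_pairs = entropy_statistic(g, "pairs"),
      n_communities = length(unique(comm)))
  }
  summary$network <- net_block

  ## influence
  infl_block <- list()
  for (cat in names(graphs)) {
    ids <- metadata$sample_id[metadata$dmft_category == cat]
    ids <- intersect(ids, sample_ids(table))
    if (length(ids) < 4) next
    sub <- feature_table(table$counts[ids, , drop = FALSE])
    cand <- if (config$candidate_mode == "centrality")
      select_candidates("centrality", graph = graphs[[cat]],
                        top_k = config$top_k)
    else
      select_candidates("abundance", table = sub, top_k = config$top_k)
    cand <- intersect(cand, taxon_ids(sub))
    if (length(cand) < 1) next
    oxy <- if (is.null(config$oxygen_annotation)) NULL else
      read_oxygen_annotation(config$oxygen_annotation)
    rep <- suppressWarnings(
      tve_impact(sub, tree, cand, k = config$k, oxygen = oxy))
    write_influence(rep, file.path(output_dir, paste0("influence_", cat, ".tsv")),
                    provenance = prov)
    top <- rep$genus[which.max(abs(rep$delta_tve))]
    infl_block[[cat]] <- list(
      baseline_tve = attr(rep, "baseline_tve"),
      n_candidates = nrow(rep),
      max_abs_delta_tve = max(abs(rep$delta_tve)),
      most_influential = top)
  }
  summary$influence <- infl_block

  ## glm
  fams <- config$glm_families
  if (is.null(fams)) {
    # at most 3 family covariates, fewer if the smallest category is tight
    # (intercept + 3 clinical terms + families must leave residual df)
    min_n <- min(table(factor(as.character(metadata$dmft_category),
                              levels = DMFT_LEVELS)))
    n_fam <- max(0, min(3, min_n - 5))
    mean_ra <- colMeans(relative_abundance(family_table))
    fams <- names(sort(mean_ra, decreasing = TRUE))[
      seq_len(min(n_fam, length(mean_ra)))]
  }
  if (length(fams) == 0) fams <- NULL
  cmp <- withCallingHandlers(
    per_category_models(genus_table, metadata,
                        if (is.null(fams)) NULL else family_table, fams),
    warning = function(w) invokeRestart("muffleWarning"))
  write_model_comparison(cmp,
                         tsv_path = file.path(output_dir, "glm_comparison.tsv"),
                         json_path = file.path(output_dir, "glm_comparison.json"),
                         provenance = prov)
  summary$glm <- list(
    families = if (is.null(fams)) character() else fams,
    dispersion = lapply(cmp$fits, `[[`, "dispersion"),
    n_models = length(cmp$fits))

  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
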