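#' Select candidate genera for the influence analysis
#'
#' Two candidate-ranking modes are used in practice: `"abundance"` ranks
#' genera by mean relative abundance across samples; `"centrality"` ranks
#' them by degree in a co-occurrence network (via [degree_rank()]). Both
#' truncate to the top `top_k` (default 50).
#'
#' @param mode `"abundance"` or `"centrality"`.
#' @param table A [feature_table()] (abundance mode).
#' @param graph A `cooccurrence_graph` (centrality mode).
#' @param top_k Maximum number of candidates.
#' @return Ordered character vector of genus names.
#' @export
select_candidates <- function(mode = c("abundance", "centrality"),
                              table = NULL, graph = NULL, top_k = 50) {
  mode <- match.arg(mode)
  if (mode == "abundance") {
    if (is.null(table)) stop("abundance mode needs `table`")
    stopifnot(inherits(table, "feature_table"))
    if (nrow(table$counts) == 0 || ncol(table$counts) == 0)
      stop("empty table")
    mean_ra <- colMeans(relative_abundance(table))
    ord <- order(-mean_ra, names(mean_ra))
    names(mean_ra)[ord][seq_len(min(top_k, length(mean_ra)))]
  } else {
    if (is.null(graph)) stop("centrality mode needs `graph`")
    degree_rank(graph, top_k = top_k)
  }
}

#' Leave-one-genus-out impact on ordination variance (delta-TVE)
#'
#' Measures how much each candidate genus shapes the community's ordination
#' structure: the baseline TVE is computed from a PCoA of the (normalized,
#' weighted) UniFrac distance matrix, then each candidate is dropped in
#' turn — its column removed from the table and its leaf pruned from the
#' tree — and the TVE recomputed from scratch.
#' `delta_tve(g) = tve_without_g - baseline_tve` (signed; the influential
#' genera are those with large `|delta_tve|`). Drops are independent, never
#' cumulative, so the result does not depend on candidate order.
#'
#' @param table A [feature_table()] with >= 4 samples.
#' @param tree Rooted `ape::phylo` covering every taxon of `table`.
#' @param candidates Ordered genus list, a subset of the table's taxa.
#' @param k TVE horizon (default 5 axes).
#' @param weighted,normalized UniFrac variant (defaults: weighted,
#'   normalized).
#' @param oxygen Optional named vector of oxygen-utilization classes
#'   (`aerobic`, `anaerobic`, `facultative`, `unknown`) used to annotate
#'   the report.
#' @return An object of class `influence_report`: data frame
#'   (`genus`, `delta_tve`, `oxygen_class`) plus attributes `baseline_tve`
#'   and `k`.
#' @export
tve_impact <- function(table, tree, candidates, k = 5, weighted = TRUE,
                       normalized = TRUE, oxygen = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$counts) < 4) stop("need at least 4 samples")
  bad <- setdiff(candidates, taxon_ids(table))
  if (length(bad))
    stop("candidates absent from table: ", paste(bad, collapse = ", "))
  bad_tree <- setdiff(candidates, tree$tip.label)
  if (length(bad_tree))
    stop("candidates absent from tree: ", paste(bad_tree, collapse = ", "))
  if (ncol(table$counts) < 2) stop("cannot drop from a single-genus table")
  baseline <- tve(pcoa(unifrac(table, tree, weighted = weighted,
                               normalized = normalized)), k)
  delta <- vapply(candidates, function(g) {
    keep <- setdiff(taxon_ids(table), g)
    if (length(keep) == 0) stop("dropping ", g, " leaves no community")
    sub <- table$counts[, keep, drop = FALSE]
    emptied <- rowSums(sub) == 0
    if (any(emptied)) {
      warning("dropping ", g, " empties sample(s) ",
              paste(rownames(sub)[emptied], collapse = ", "),
              "; excluded from the perturbed run")
      sub <- sub[!emptied, , drop = FALSE]
      if (nrow(sub) < 4) stop("too few samples left after dropping ", g)
    }
    sub_tree <- ape::drop.tip(tree, g)
    tve(pcoa(unifrac(feature_table(sub), sub_tree, weighted = weighted,
                     normalized = normalized)), k) - baseline
  }, numeric(1))
  ox <- rep("unknown", length(candidates))
  if (!is.null(oxygen)) {
    hit <- match(tolower(candidates), tolower(names(oxygen)))
    ox[!is.na(hit)] <- as.character(oxygen[hit[!is.na(hit)]])
  }
  report <- data.frame(genus = candidates, delta_tve = unname(delta),
                       oxygen_class = ox, stringsAsFactors = FALSE)
  structure(report, baseline_tve = baseline, k = k,
            class = c("influence_report", "data.frame"))
}

#' Read an oxygen-utilization annotation file
#'
#' Two-column TSV (genus, class); classes outside
#' aerobic/anaerobic/facultative map to `"unknown"`.
#'
#' @param path Path to the TSV (header required).
#' @return Named character vector genus -> class.
#' @export
read_oxygen_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  cls <- tolower(trimws(df[[2]]))
  cls[!cls %in% c("aerobic", "anaerobic", "facultative")] <- "unknown"
  stats::setNames(cls, trimws(df[[1]]))
}

#' Write an influence report as TSV
#' @param report An `influence_report`.
#' @param path Output path.
#' @param provenance Optional named character vector of comment lines.
#' @export
write_influence <- function(report, path, provenance = NULL) {
  stopifnot(inherits(report, "influence_report"))
  con <- file(path, open = "wt")
  writeLines(c(provenance_lines(provenance),
               sprintf("# baseline_tve: %.10f (k = %d)",
                       attr(report, "baseline_tve"), attr(report, "k"))), con)
  utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}
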