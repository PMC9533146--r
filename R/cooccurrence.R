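#' Genus-level Spearman correlation matrix
#'
#' Rank correlation (average ranks for ties) between all genus pairs on
#' within-sample relative abundances, with two-sided p-values from the
#' large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (p = 0 when |rho| = 1). Genera with zero variance across samples have no
#' defined correlation: their rows/columns are `NA` and they are listed in
#' the `constant` attribute.
#'
#' @param genus_table A [feature_table()] at genus rank with >= 4 samples
#'   and >= 2 genera.
#' @param method `"t"` (default) for the t approximation; `"exact"` uses the
#'   exact null distribution of the rank statistic via [stats::cor.test()]
#'   (small n, untied data only — falls back to the approximation on ties).
#' @return List with `rho` and `p` (genus x genus matrices; `p` diagonal is
#'   `NA`) and attribute `constant` naming zero-variance genera.
#' @export
spearman_matrix <- function(genus_table, method = c("t", "exact")) {
  stopifnot(inherits(genus_table, "feature_table"))
  method <- match.arg(method)
  n <- nrow(genus_table$counts)
  if (n < 4) stop("need at least 4 samples")
  if (ncol(genus_table$counts) < 2) stop("need at least 2 genera")
  p_rel <- relative_abundance(genus_table)
  const <- colnames(p_rel)[apply(p_rel, 2, function(x) length(unique(x)) == 1)]
  rho <- suppressWarnings(stats::cor(p_rel, method = "spearman"))
  rho[colnames(p_rel) %in% const, ] <- NA
  rho[, colnames(p_rel) %in% const] <- NA
  diag(rho) <- ifelse(colnames(p_rel) %in% const, NA, 1)
  if (method == "t") {
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    pm <- 2 * stats::pt(-abs(tt), df = n - 2)
    pm[abs(rho) >= 1 - 1e-12] <- 0
  } else {
    g <- ncol(p_rel)
    pm <- matrix(NA_real_, g, g, dimnames = dimnames(rho))
    for (i in seq_len(g - 1)) for (j in (i + 1):g) {
      if (is.na(rho[i, j])) next
      pm[i, j] <- pm[j, i] <- suppressWarnings(
        stats::cor.test(p_rel[, i], p_rel[, j], method = "spearman",
                        exact = TRUE)$p.value)
    }
  }
  diag(pm) <- NA
  structure(list(rho = rho, p = pm), constant = const)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate;
#' order-preserving. `NA` entries are passed through untouched.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- p_values
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Build a co-occurrence graph from correlation and significance matrices
#'
#' Keeps an (undirected) edge for every genus pair whose correlation is
#' strictly beyond the threshold (`rho > threshold` or `rho < -threshold`);
#' a pair at exactly the threshold is excluded. FDR significance
#' (`p_adj <= alpha`) is stored as an edge attribute — edges are annotated
#' by significance, not pruned by it. BH adjustment is applied across the
#' upper-triangle p-values here, so pass the raw p matrix from
#' [spearman_matrix()].
#'
#' @param rho Genus x genus correlation matrix.
#' @param p Genus x genus raw p-value matrix aligned with `rho`.
#' @param rho_threshold Absolute correlation cutoff (strict; default 0.5).
#' @param alpha FDR significance level for the edge flag (default 0.05).
#' @param category Optional label carried on the graph.
#' @return An object of class `cooccurrence_graph`: `nodes` (all genera),
#'   `edges` (data frame `u`, `v`, `rho`, `p_adj`, `significant`),
#'   `category`, and `n_pairs_tested`.
#' @export
build_graph <- function(rho, p, rho_threshold = 0.5, alpha = 0.05,
                        category = NULL) {
  if (!identical(dim(rho), dim(p)) ||
      !identical(dimnames(rho), dimnames(p)))
    stop("`rho` and `p` must be aligned matrices")
  nodes <- colnames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  # one BH family per graph: all testable (non-constant) pairs
  p_vec <- p[ut]
  p_adj <- bh_fdr(p_vec)
  keep <- !is.na(rho[ut]) & abs(rho[ut]) > rho_threshold
  edges <- data.frame(
    u = nodes[ut[keep, 1]], v = nodes[ut[keep, 2]],
    rho = rho[ut][keep], p_adj = p_adj[keep],
    significant = p_adj[keep] <= alpha,
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(nodes), edges = edges, category = category,
                 n_pairs_tested = sum(!is.na(p_vec)),
                 n_pairs_significant = sum(p_adj <= alpha, na.rm = TRUE),
                 rho_threshold = rho_threshold, alpha = alpha),
            class = "cooccurrence_graph")
}

#' @export
print.cooccurrence_graph <- function(x, ...) {
  cat(sprintf("<cooccurrence_graph>%s %d genera, %d edges (|rho| > %.2f), %d significant\n",
              if (is.null(x$category)) "" else paste0(" [", x$category, "]"),
              length(x$nodes), nrow(x$edges), x$rho_threshold,
              sum(x$edges$significant)))
  invisible(x)
}

#' Network entropy statistic: fraction of significant associations
#'
#' The proportion of pairwise genus associations that are statistically
#' significant after FDR correction. A high fraction means the community's
#' association structure is far from random (low entropy in the ecological
#' reading); the raw fraction is reported and interpretation is left to the
#' caller. By default the denominator is the retained edges of the pruned
#' network; `denominator = "pairs"` divides instead by every genus pair
#' that was tested.
#'
#' @param g A `cooccurrence_graph`.
#' @param denominator `"edges"` (default) or `"pairs"`.
#' @return Fraction in [0, 1].
#' @export
entropy_statistic <- function(g, denominator = c("edges", "pairs")) {
  stopifnot(inherits(g, "cooccurrence_graph"))
  denominator <- match.arg(denominator)
  if (denominator == "edges") {
    if (nrow(g$edges) == 0)
      stop("graph has no edges; entropy over edges is undefined")
    mean(g$edges$significant)
  } else {
    if (g$n_pairs_tested == 0) stop("no testable genus pairs")
    sum(g$edges$significant) / g$n_pairs_tested
  }
}

as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("u", "v")], directed = FALSE,
    vertices = data.frame(name = g$nodes))
  igraph::E(ig)$rho <- g$edges$rho
  igraph::E(ig)$p_adj <- g$edges$p_adj
  igraph::E(ig)$significant <- g$edges$significant
  ig
}

#' Extract communities from a co-occurrence graph
#'
#' Greedy modularity-maximizing agglomeration (Clauset-Newman-Moore style)
#' on absolute correlation weights, so negative associations contribute
#' their strength. Starting from singletons, the pair of connected
#' communities with the largest modularity gain is merged repeatedly until
#' the graph is exhausted; the partition with maximal modularity along the
#' merge path is returned. Ties in the gain break on the lexicographically
#' smallest community pair, making the result fully deterministic; isolated
#' genera stay singleton communities.
#'
#' @param g A non-empty `cooccurrence_graph`.
#' @param seed Unused by the deterministic greedy algorithm; accepted for
#'   interface stability.
#' @return Named integer vector: community id per genus (ids numbered by
#'   each community's lexicographically first member).
#' @export
communities <- function(g, seed = NULL) {
  stopifnot(inherits(g, "cooccurrence_graph"))
  nodes <- g$nodes
  if (length(nodes) == 0) stop("empty graph")
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      u <- g$edges$u[r]; v <- g$edges$v[r]
      w[u, v] <- w[v, u] <- abs(g$edges$rho[r])
    }
  }
  member <- seq_len(n)                      # community of each node
  two_m <- sum(w)                           # == 2 * total edge weight
  finalize <- function(member) {
    groups <- split(nodes, member)
    ord <- order(vapply(groups, min, character(1)))
    ids <- stats::setNames(integer(n), nodes)
    for (k in seq_along(ord)) ids[groups[[ord[k]]]] <- k
    ids
  }
  if (two_m == 0) return(finalize(member))
  modularity <- function(member) {
    q <- 0
    for (cc in unique(member)) {
      idx <- member == cc
      q <- q + sum(w[idx, idx]) / two_m - (sum(w[idx, ]) / two_m)^2
    }
    q
  }
  best <- list(q = modularity(member), member = member)
  repeat {
    comms <- sort(unique(member))
    if (length(comms) == 1) break
    best_gain <- -Inf; best_pair <- NULL
    for (ai in seq_len(length(comms) - 1)) {
      ia <- member == comms[ai]
      for (bi in (ai + 1):length(comms)) {
        ib <- member == comms[bi]
        e_ab <- sum(w[ia, ib])
        if (e_ab == 0) next                  # only connected communities merge
        gain <- 2 * (e_ab / two_m -
                       (sum(w[ia, ]) / two_m) * (sum(w[ib, ]) / two_m))
        # deterministic: strict improvement required, pairs scanned in
        # lexicographic community order so ties keep the first pair
        if (gain > best_gain + 1e-15) {
          best_gain <- gain
          best_pair <- c(comms[ai], comms[bi])
        }
      }
    }
    if (is.null(best_pair)) break            # disconnected remainder
    member[member == best_pair[2]] <- best_pair[1]
    q <- modularity(member)
    if (q > best$q + 1e-12) best <- list(q = q, member = member)
  }
  finalize(best$member)
}

#' Rank genera by degree centrality
#'
#' Nodes ordered by descending degree in the pruned network, ties broken
#' lexicographically, truncated to the top `top_k`.
#'
#' @param g A non-empty `cooccurrence_graph`.
#' @param top_k Maximum number of genera returned (default 50).
#' @return Character vector of genus names.
#' @export
degree_rank <- function(g, top_k = 50) {
  stopifnot(inherits(g, "cooccurrence_graph"))
  if (length(g$nodes) == 0) stop("empty graph")
  deg <- stats::setNames(integer(length(g$nodes)), g$nodes)
  if (nrow(g$edges)) {
    tab <- table(c(g$edges$u, g$edges$v))
    deg[names(tab)] <- as.integer(tab)
  }
  ord <- order(-deg, names(deg))
  names(deg)[ord][seq_len(min(top_k, length(deg)))]
}

#' Export a co-occurrence graph
#'
#' Edge list as TSV (`u`, `v`, `rho`, `p_adj`, `significant`) and,
#' optionally, GraphML for network viewers. `directed = TRUE` duplicates
#' each undirected edge as two arcs in the TSV for tools that expect arcs.
#'
#' @param g A `cooccurrence_graph`.
#' @param path Edge-list TSV path.
#' @param graphml_path Optional GraphML output path.
#' @param directed Emit both arc directions in the TSV.
#' @param provenance Optional named character vector of comment lines.
#' @export
write_graph <- function(g, path, graphml_path = NULL, directed = FALSE,
                        provenance = NULL) {
  stopifnot(inherits(g, "cooccurrence_graph"))
  edges <- g$edges
  if (directed && nrow(edges)) {
    rev <- edges
    rev[c("u", "v")] <- edges[c("v", "u")]
    edges <- rbind(edges, rev)
  }
  con <- file(path, open = "wt")
  writeLines(provenance_lines(provenance), con)
  utils::write.table(edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(g), graphml_path, format = "graphml")
  invisible(path)
}
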