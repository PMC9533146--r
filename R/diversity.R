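#' Shannon diversity of one sample
#'
#' `H = -sum(p_i * log(p_i))` in nats over taxa with positive counts, with
#' `p_i` the within-sample proportions.
#'
#' @param counts Non-negative numeric vector of counts for one sample.
#' @return Shannon entropy in nats.
#' @examples
#' shannon(c(5, 5, 5, 5))  # log(4)
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("all-zero sample has undefined diversity")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Observed richness of one sample
#'
#' @param counts Non-negative numeric vector of counts for one sample.
#' @return Number of taxa with count > 0.
#' @export
observed_richness <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  sum(counts > 0)
}

#' Rarefaction curves of alpha diversity
#'
#' Repeatedly subsamples each sample without replacement to each requested
#' depth and records the mean and standard deviation of an alpha-diversity
#' metric across repetitions. Samples shallower than a requested depth are
#' skipped for that depth with a warning.
#'
#' @param table A [feature_table()].
#' @param depths Integer vector of rarefaction depths.
#' @param n_reps Number of subsampling repetitions per depth.
#' @param seed Integer seed.
#' @param metric `"observed"` or `"shannon"`.
#' @return Data frame with columns `sample_id`, `depth`, `mean`, `sd`.
#' @export
rarefaction_curve <- function(table, depths, n_reps = 10, seed = 1L,
                              metric = c("observed", "shannon")) {
  stopifnot(inherits(table, "feature_table"))
  metric <- match.arg(metric)
  fn <- if (metric == "observed") observed_richness else shannon
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  full <- sample_depths(table)
  out <- list()
  skipped <- character()
  for (sid in sample_ids(table)) {
    x <- table$counts[sid, ]
    reads <- rep.int(seq_along(x), x)
    for (d in depths) {
      if (d > full[[sid]]) {
        skipped <- c(skipped, sprintf("%s@%d", sid, d))
        next
      }
      vals <- vapply(seq_len(n_reps), function(i) {
        sub <- tabulate(sample(reads, d), nbins = length(x))
        fn(sub)
      }, numeric(1))
      out[[length(out) + 1]] <- data.frame(
        sample_id = sid, depth = d,
        mean = mean(vals), sd = stats::sd(vals))
    }
  }
  if (length(skipped))
    warning("depth exceeds sample depth, skipped: ",
            paste(skipped, collapse = ", "))
  do.call(rbind, out)
}

check_distance_input <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$counts) < 2) stop("need at least 2 samples")
  if (any(sample_depths(table) == 0))
    stop("empty (all-zero) samples: ",
         paste(sample_ids(table)[sample_depths(table) == 0], collapse = ", "))
}

as_distance_matrix <- function(m) {
  m <- (m + t(m)) / 2          # enforce exact symmetry against roundoff
  diag(m) <- 0
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Validate a pairwise distance matrix
#'
#' Checks symmetry (within 1e-12), a zero diagonal and non-negativity.
#' @param d A square labeled numeric matrix.
#' @return `d`, invisibly.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("not a square matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("matrix is not symmetric")
  if (any(diag(d) != 0)) stop("diagonal is not exactly zero")
  if (any(d < 0)) stop("negative distances")
  invisible(d)
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)` computed on relative
#' abundances, so differences in library size do not masquerade as community
#' differences. Values lie in [0, 1].
#'
#' @param table A [feature_table()] with non-empty samples.
#' @return Symmetric samples x samples matrix of class `distance_matrix`.
#' @export
bray_curtis <- function(table) {
  check_distance_input(table)
  p <- relative_abundance(table)
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(abs(p[i, ] - p[j, ])) / sum(p[i, ] + p[j, ])
  }
  as_distance_matrix(d)
}

kl_div <- function(p, m) {
  i <- p > 0
  sum(p[i] * log(p[i] / m[i]))
}

#' Jensen-Shannon divergence between all sample pairs
#'
#' `JSD(P, Q) = KL(P || M)/2 + KL(Q || M)/2` with `M = (P + Q)/2`, natural
#' logarithms and `0 log 0 := 0`; bounded by `log(2)`. The metric form
#' (its square root) is available via `metric = TRUE`.
#'
#' @param table A [feature_table()] with non-empty samples.
#' @param metric If `TRUE`, return the square-root (metric) form.
#' @return Symmetric matrix of class `distance_matrix`.
#' @export
jensen_shannon <- function(table, metric = FALSE) {
  check_distance_input(table)
  p <- relative_abundance(table)
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- (p[i, ] + p[j, ]) / 2
    d[i, j] <- d[j, i] <- (kl_div(p[i, ], m) + kl_div(p[j, ], m)) / 2
  }
  if (metric) d <- sqrt(d)
  as_distance_matrix(d)
}

# per-branch structure of a rooted tree: for each edge, the set of leaf
# (taxon) columns descending from it, as an edges x taxa indicator matrix
branch_leaf_matrix <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  ind <- matrix(0, n_edge, n_tip)
  # postorder: children edges are visited before their parent edge
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  row_of <- match(paste(ord[, 1], ord[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))
  child_rows <- split(seq_len(n_edge), tree$edge[, 1])
  for (k in seq_len(n_edge)) {
    e <- row_of[k]
    child <- ord[k, 2]
    if (child <= n_tip) {
      ind[e, child] <- 1
    } else {
      for (ce in child_rows[[as.character(child)]]) ind[e, ] <- ind[e, ] + ind[ce, ]
    }
  }
  ind <- ind[, match(taxa, tree$tip.label), drop = FALSE]
  colnames(ind) <- taxa
  ind
}

#' UniFrac distances between all sample pairs
#'
#' Phylogenetic beta diversity over a rooted tree covering every taxon in
#' the table. Unweighted UniFrac is the fraction of branch length unique to
#' one of the two samples among branch length present in either. Weighted
#' UniFrac sums branch lengths times the absolute difference in the
#' proportion of each sample's reads descending through the branch;
#' `normalized = TRUE` (the default) divides by the same sum with the
#' proportions added, bounding the distance by 1.
#'
#' @param table A [feature_table()] whose taxa are all leaves of `tree`.
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param weighted Use abundance-weighted UniFrac.
#' @param normalized For the weighted variant, return the normalized form.
#' @return Symmetric matrix of class `distance_matrix`.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  check_distance_input(table)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  taxa <- taxon_ids(table)
  ind <- branch_leaf_matrix(tree, taxa)
  len <- tree$edge.length
  n <- nrow(table$counts)
  d <- matrix(0, n, n, dimnames = list(sample_ids(table), sample_ids(table)))
  if (weighted) {
    prop <- relative_abundance(table) %*% t(ind)   # samples x branches
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(len * abs(prop[i, ] - prop[j, ]))
      d[i, j] <- d[j, i] <- if (normalized)
        num / sum(len * (prop[i, ] + prop[j, ])) else num
    }
  } else {
    pres <- (table$counts > 0) %*% t(ind) > 0      # samples x branches
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- pres[i, ] | pres[j, ]
      uniq <- xor(pres[i, ], pres[j, ])
      d[i, j] <- d[j, i] <- sum(len[uniq]) / sum(len[either])
    }
  }
  as_distance_matrix(d)
}

#' Write / read a labeled square distance matrix as TSV
#' @param d A `distance_matrix` (or plain labeled square matrix).
#' @param path File path.
#' @param provenance Optional named character vector of comment lines.
#' @export
write_distance <- function(d, path, provenance = NULL) {
  validate_distance_matrix(unclass(d))
  header <- paste(c("#SampleID", colnames(d)), collapse = "\t")
  body <- vapply(seq_len(nrow(d)), function(i)
    paste(c(rownames(d)[i], format(d[i, ], digits = 15, scientific = FALSE,
                                   trim = TRUE)), collapse = "\t"), character(1))
  writeLines(c(provenance_lines(provenance), header, body), path)
  invisible(path)
}

#' @rdname write_distance
#' @export
read_distance <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^# ", lines)]
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  validate_distance_matrix(m)
  as_distance_matrix(m)
}
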