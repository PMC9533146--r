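#' Construct a feature table
#'
#' A feature table is the universal currency of the pipeline: a samples x taxa
#' matrix of non-negative integer counts with unique, aligned row (sample) and
#' column (taxon) labels. Row sums are the per-sample sequencing depths.
#'
#' @param counts Numeric matrix, samples in rows and taxa in columns, with
#'   dimnames. All entries must be non-negative integers (stored as double or
#'   integer; integrality is enforced).
#' @return An object of class `feature_table`.
#' @examples
#' m <- matrix(c(3, 0, 4, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("gA", "gB")))
#' ft <- feature_table(m)
#' sample_depths(ft)
#' @export
feature_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix (samples x taxa)")
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("`counts` must carry sample (row) names")
    rownames(counts) <- character(0)
  }
  if (is.null(colnames(counts))) {
    if (ncol(counts) > 0) stop("`counts` must carry taxon (column) names")
    colnames(counts) <- character(0)
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicated taxon identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts))) stop("`counts` contains missing values")
  if (any(counts < 0)) stop("`counts` contains negative entries")
  if (any(counts != round(counts))) stop("`counts` contains non-integer entries")
  storage.mode(counts) <- "double"
  structure(list(counts = counts), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d taxa; total count %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname feature_table
#' @param x A `feature_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' @rdname feature_table
#' @export
sample_depths <- function(x) rowSums(x$counts)

#' Relative abundances of a feature table
#'
#' Counts divided by per-sample depth. Samples with zero depth yield NaN and
#' are rejected because every downstream use assumes non-empty samples.
#'
#' @param x A `feature_table` or a counts matrix (samples x taxa).
#' @return A samples x taxa matrix of proportions; rows sum to 1.
#' @export
relative_abundance <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else x
  depth <- rowSums(m)
  if (any(depth == 0))
    stop("samples with zero depth: ",
         paste(rownames(m)[depth == 0], collapse = ", "))
  sweep(m, 1, depth, "/")
}

#' DMFT severity categories
#'
#' Category labels in order of increasing severity.
#' @export
DMFT_LEVELS <- c("healthy", "low", "medium", "high", "extremely_high")

#' Integer DMFT score ranges per category
#'
#' The clinical binning of the DMFT score: healthy is a score of 0, low 1-3,
#' medium 4-6, high 7-13 and extremely high 14 and above (capped at 32, the
#' maximum number of permanent teeth).
#' @export
DMFT_RANGES <- list(
  healthy        = 0L,
  low            = 1:3,
  medium         = 4:6,
  high           = 7:13,
  extremely_high = 14:32
)

#' Categorize a DMFT score
#'
#' Maps the decayed/missing/filled-teeth (DMFT) score onto the five severity
#' categories used throughout the pipeline: healthy (0), low (1-3),
#' medium (4-6), high (7-13) and extremely high (>= 14).
#'
#' @param score Vector of non-negative integer DMFT scores (at most 32).
#' @return A factor with levels [DMFT_LEVELS].
#' @examples
#' categorize_dmft(c(0, 2, 5, 13, 14))
#' @export
categorize_dmft <- function(score) {
  if (length(score) == 0) return(factor(character(), levels = DMFT_LEVELS))
  if (!is.numeric(score) || any(is.na(score)))
    stop("DMFT score must be numeric and non-missing")
  if (any(score < 0) || any(score != round(score)))
    stop("DMFT score must be a non-negative integer")
  if (any(score > 32)) stop("DMFT score cannot exceed 32")
  cut(score, breaks = c(-0.5, 0.5, 3.5, 6.5, 13.5, 32.5), labels = DMFT_LEVELS)
}

#' Filter samples by sequencing depth
#'
#' Retains exactly the samples whose total count (sequencing depth) is at
#' least `min_depth`; "at least" is inclusive. The taxon set and retained
#' counts are untouched. The operation is idempotent.
#'
#' @param table A `feature_table`.
#' @param min_depth Non-negative minimum per-sample depth (default 3000, the
#'   conventional amplicon cutoff used for this analysis).
#' @return A `feature_table` with a subset of samples (possibly zero rows).
#' @export
filter_by_depth <- function(table, min_depth = 3000) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(min_depth) || length(min_depth) != 1 || min_depth < 0)
    stop("`min_depth` must be a single non-negative number")
  keep <- sample_depths(table) >= min_depth
  feature_table(table$counts[keep, , drop = FALSE])
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Sums counts over all taxa sharing the same lineage label at the requested
#' rank. Per-sample totals are conserved exactly. Taxa whose label at the rank
#' is the empty string are pooled under `"unassigned"`.
#'
#' @param table A `feature_table`.
#' @param tax A taxonomy map as returned by [read_taxonomy()] or
#'   [taxonomy_map()]: a data frame with a `taxon_id` column and one column
#'   per rank.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return A `feature_table` whose taxa are the distinct labels at `rank`.
#' @export
aggregate_rank <- function(table, tax, rank = "genus") {
  stopifnot(inherits(table, "feature_table"))
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  missing <- setdiff(taxon_ids(table), tax$taxon_id)
  if (length(missing))
    stop("taxa without a lineage: ", paste(missing, collapse = ", "))
  lab <- tax[[rank]][match(taxon_ids(table), tax$taxon_id)]
  lab[is.na(lab) | lab == ""] <- "unassigned"
  groups <- factor(lab, levels = unique(lab))
  agg <- t(rowsum(t(table$counts), group = groups))
  colnames(agg) <- levels(groups)
  feature_table(agg)
}

#' Ordered taxonomic ranks understood by the pipeline
#' @export
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a sample metadata table
#'
#' Validates per-sample clinical attributes and (re)derives the DMFT category
#' from the score, so the category column can never drift out of sync with
#' the score.
#'
#' @param df Data frame with columns `sample_id`, `dmft_score`, `hiv_status`
#'   (`"positive"`/`"negative"`), `sex` (`"female"`/`"male"`),
#'   `periodontal_status` (`"gingivitis"`/`"periodontitis"`) and `flow_rate`
#'   (unstimulated salivary flow, ml/min, non-negative).
#' @return A data frame of class `sample_metadata` with a `dmft_category`
#'   factor column appended.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "dmft_score", "hiv_status", "sex",
           "periodontal_status", "flow_rate")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(df[[col]])), levels)
    if (length(bad)) stop(sprintf("invalid %s value(s): %s", col,
                                  paste(bad, collapse = ", ")))
    factor(as.character(df[[col]]), levels = levels)
  }
  df$hiv_status <- chk("hiv_status", c("negative", "positive"))
  df$sex <- chk("sex", c("female", "male"))
  df$periodontal_status <- chk("periodontal_status",
                               c("gingivitis", "periodontitis"))
  if (any(df$flow_rate < 0)) stop("flow_rate must be non-negative")
  df$dmft_category <- categorize_dmft(df$dmft_score)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Construct a taxonomy map
#'
#' @param taxon_id Character vector of taxon identifiers.
#' @param lineage Character vector of semicolon-delimited lineage strings
#'   (domain;phylum;class;order;family;genus). Trailing ranks may be omitted;
#'   missing ranks become the empty string.
#' @return Data frame of class `taxonomy_map` with columns `taxon_id` and the
#'   six ranks.
#' @export
taxonomy_map <- function(taxon_id, lineage) {
  if (anyDuplicated(taxon_id)) stop("duplicated taxon_id in taxonomy")
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  ranks <- t(vapply(parts, function(p) {
    p <- trimws(p)
    # strip SILVA-style rank prefixes such as "g__"
    p <- sub("^[dkpcofgs]__", "", p)
    length(p) <- length(TAXONOMIC_RANKS)
    p[is.na(p)] <- ""
    p
  }, character(length(TAXONOMIC_RANKS))))
  out <- data.frame(taxon_id = as.character(taxon_id), ranks,
                    stringsAsFactors = FALSE)
  names(out) <- c("taxon_id", TAXONOMIC_RANKS)
  class(out) <- c("taxonomy_map", "data.frame")
  out
}
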