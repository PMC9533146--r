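#' Read a feature table from TSV
#'
#' The on-disk dialect is the common amplicon one: taxa as rows, a leading
#' `#TaxonID` header naming the taxon column, one column per sample.
#' Provenance comment lines (`# key: value`) before the header are ignored.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return A [feature_table()].
#' @export
read_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^# ", lines)]
  if (!length(lines)) stop("empty feature table file: ", path)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, header = TRUE, check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  names(df)[1] <- sub("^#", "", names(df)[1])
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated row labels in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  if (any(m != round(m))) stop("non-integer counts in ", path)
  rownames(m) <- ids
  if (orientation == "taxa_rows") m <- t(m)
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @param provenance Optional named character vector written as leading
#'   `# key: value` comment lines.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path,
                        orientation = c("taxa_rows", "samples_rows"),
                        provenance = NULL) {
  stopifnot(inherits(table, "feature_table"))
  orientation <- match.arg(orientation)
  m <- table$counts
  if (orientation == "taxa_rows") {
    m <- t(m)
    lead <- "#TaxonID"
  } else {
    lead <- "#SampleID"
  }
  header <- paste(c(lead, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE)),
          collapse = "\t"), character(1))
  writeLines(c(provenance_lines(provenance), header, body), path, useBytes = TRUE)
  invisible(path)
}

provenance_lines <- function(provenance) {
  if (is.null(provenance)) return(character())
  paste0("# ", names(provenance), ": ", as.character(provenance))
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `dmft_score`, `hiv_status`, `sex`,
#' `periodontal_status`, `flow_rate`; validated by [sample_metadata()].
#'
#' @param path Path to a TSV file.
#' @return A `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "")
  df <- df[!grepl("^# ", df[[1]]), , drop = FALSE]
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param metadata A `sample_metadata` data frame.
#' @param path Output path.
#' @param provenance Optional named character vector of comment lines.
#' @export
write_metadata <- function(metadata, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_lines(provenance), con)
  utils::write.table(as.data.frame(metadata), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table from TSV
#'
#' Two tab-separated columns: taxon identifier and a SILVA-style
#' semicolon-delimited lineage string; split and validated by
#' [taxonomy_map()].
#'
#' @param path Path to a TSV file (header required).
#' @return A `taxonomy_map` data frame.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("taxonomy file must have taxon_id and lineage columns")
  taxonomy_map(df[[1]], df[[2]])
}

#' Write a taxonomy map to TSV as (taxon_id, lineage) pairs
#' @param tax A `taxonomy_map`.
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  lineage <- apply(as.matrix(tax[TAXONOMIC_RANKS]), 1, paste, collapse = ";")
  utils::write.table(data.frame(taxon_id = tax$taxon_id, lineage = lineage),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogenetic tree in Newick format
#'
#' Thin wrapper around [ape::read.tree()] that fails loudly on malformed
#' input instead of returning `NULL`.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("malformed Newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick in ", path)
  tree
}
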