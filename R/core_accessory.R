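#' Core taxa of a sample group
#'
#' The core microbiota is the set of taxa detected (count > 0) in at least a
#' threshold fraction of the samples; the comparison is inclusive, so a
#' taxon present in exactly 85% of samples belongs to the core at the
#' default threshold.
#'
#' @param table A [feature_table()] with at least one sample.
#' @param prevalence_threshold Fraction in [0, 1] (default 0.85).
#' @return Sorted character vector of taxon ids.
#' @export
core_taxa <- function(table, prevalence_threshold = 0.85) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$counts) == 0) stop("table has no samples")
  if (prevalence_threshold < 0 || prevalence_threshold > 1)
    stop("`prevalence_threshold` must lie in [0, 1]")
  prev <- colMeans(table$counts > 0)
  sort(names(prev)[prev >= prevalence_threshold])
}

#' Pan taxa of a sample group
#'
#' All taxa observed (count > 0) in at least one sample.
#'
#' @param table A [feature_table()].
#' @return Sorted character vector of taxon ids.
#' @export
pan_taxa <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  sort(taxon_ids(table)[colSums(table$counts > 0) > 0])
}

#' Pan/core/accessory partition per DMFT category
#'
#' For each severity category, subsets the samples and computes the pan
#' microbiota (taxa seen at least once), the core (taxa at or above the
#' prevalence threshold) and the accessory microbiota (pan minus core, the
#' transient "invaders"). The identity
#' `|accessory| = |pan| - |core|` holds exactly because `core` is a subset
#' of `pan` by construction.
#'
#' @param table A [feature_table()].
#' @param metadata A [sample_metadata()] covering every sample of `table`.
#' @param prevalence_threshold Core prevalence threshold (default 0.85).
#' @return An object of class `partition_result`: a named list per category
#'   with elements `pan`, `core`, `accessory` (sorted sets), `n_samples`
#'   and `sizes`.
#' @export
partition_by_category <- function(table, metadata, prevalence_threshold = 0.85) {
  stopifnot(inherits(table, "feature_table"))
  miss <- setdiff(sample_ids(table), metadata$sample_id)
  if (length(miss))
    stop("samples without metadata: ", paste(miss, collapse = ", "))
  cat_of <- as.character(metadata$dmft_category)[
    match(sample_ids(table), metadata$sample_id)]
  out <- list()
  for (cat in DMFT_LEVELS) {
    idx <- which(cat_of == cat)
    if (length(idx) == 0) {
      warning("category without samples: ", cat)
      out[[cat]] <- list(pan = character(), core = character(),
                         accessory = character(), n_samples = 0L,
                         sizes = c(pan = 0L, core = 0L, accessory = 0L))
      next
    }
    sub <- feature_table(table$counts[idx, , drop = FALSE])
    pan <- pan_taxa(sub)
    core <- core_taxa(sub, prevalence_threshold)
    accessory <- sort(setdiff(pan, core))
    stopifnot(length(accessory) == length(pan) - length(core))
    out[[cat]] <- list(pan = pan, core = core, accessory = accessory,
                       n_samples = length(idx),
                       sizes = c(pan = length(pan), core = length(core),
                                 accessory = length(accessory)))
  }
  structure(out, prevalence_threshold = prevalence_threshold,
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> prevalence threshold %.2f\n",
              attr(x, "prevalence_threshold")))
  for (cat in names(x))
    cat(sprintf("  %-15s n=%-3d pan=%-4d core=%-4d accessory=%d\n", cat,
                x[[cat]]$n_samples, x[[cat]]$sizes["pan"],
                x[[cat]]$sizes["core"], x[[cat]]$sizes["accessory"]))
  invisible(x)
}

#' The DMFT core: taxa shared by every category's core
#'
#' Intersection of the per-category core sets over all categories that
#' contain samples — the taxa present at high prevalence at every stage of
#' caries severity.
#'
#' @param partition A `partition_result` from [partition_by_category()].
#' @return Sorted character vector of taxon ids.
#' @export
dmft_core <- function(partition) {
  stopifnot(inherits(partition, "partition_result"))
  nonempty <- Filter(function(p) p$n_samples > 0, partition)
  if (length(nonempty) == 0) stop("all categories are empty")
  if (length(nonempty) < 2)
    stop("need cores from at least 2 non-empty categories")
  sort(Reduce(intersect, lapply(nonempty, `[[`, "core")))
}

#' Curated genus group lists (normal flora vs oral-disease-associated)
#'
#' Two disjoint, case-normalized genus sets used to break the pan
#' microbiota into ecological groups. The package ships editable default
#' lists under `inst/extdata/` compiled from the oral-microbiology
#' literature; report results alongside the list source used.
#'
#' @param normal_flora Character vector of genus names.
#' @param disease_associated Character vector of genus names.
#' @param source Free-text provenance of the lists.
#' @return A list of class `genus_group_lists`.
#' @export
genus_group_lists <- function(normal_flora, disease_associated,
                              source = "user-supplied") {
  nf <- sort(unique(trimws(tolower(normal_flora))))
  da <- sort(unique(trimws(tolower(disease_associated))))
  both <- intersect(nf, da)
  if (length(both))
    stop("genera in both lists: ", paste(both, collapse = ", "))
  structure(list(normal_flora = nf, disease_associated = da, source = source),
            class = "genus_group_lists")
}

#' Load genus group lists from newline-delimited files
#'
#' @param normal_flora_path,disease_associated_path Paths to plain-text
#'   files, one genus per line, `#` comments allowed. Defaults to the lists
#'   bundled with the package.
#' @return A [genus_group_lists()].
#' @export
read_genus_lists <- function(
    normal_flora_path = system.file("extdata", "normal_flora.txt",
                                    package = "dmftmicro"),
    disease_associated_path = system.file("extdata", "disease_associated.txt",
                                          package = "dmftmicro")) {
  rd <- function(p) {
    x <- trimws(readLines(p, encoding = "UTF-8"))
    x[nzchar(x) & !startsWith(x, "#")]
  }
  genus_group_lists(rd(normal_flora_path), rd(disease_associated_path),
                    source = paste(basename(normal_flora_path),
                                   basename(disease_associated_path),
                                   sep = " + "))
}

#' Richness proportions of a category's pan microbiota
#'
#' Assigns every genus of a category's pan microbiota to exactly one group
#' by the precedence DMFT-core > accessory > disease-associated > normal
#' flora > unclassified, then reports each group's share of the pan
#' richness. Shares sum to 1.
#'
#' @param category_taxa The category's pan genus set.
#' @param dmft_core The cross-category core from [dmft_core()].
#' @param lists A [genus_group_lists()].
#' @param accessory The category's accessory genus set.
#' @return Named numeric vector of proportions (`core`, `accessory`,
#'   `disease_associated`, `normal_flora`, `unclassified`).
#' @export
richness_proportions <- function(category_taxa, dmft_core, lists, accessory) {
  stopifnot(inherits(lists, "genus_group_lists"))
  if (length(category_taxa) == 0) stop("empty pan microbiota")
  lower <- tolower(category_taxa)
  group <- ifelse(category_taxa %in% dmft_core, "core",
           ifelse(category_taxa %in% accessory, "accessory",
           ifelse(lower %in% lists$disease_associated, "disease_associated",
           ifelse(lower %in% lists$normal_flora, "normal_flora",
                  "unclassified"))))
  levels <- c("core", "accessory", "disease_associated", "normal_flora",
              "unclassified")
  tab <- table(factor(group, levels = levels))
  out <- as.numeric(tab) / length(category_taxa)
  names(out) <- levels
  out
}

#' Write a partition result as JSON (sets sorted for determinism)
#' @param partition A `partition_result`.
#' @param path Output path.
#' @param provenance Optional named list merged into the JSON header.
#' @export
write_partition <- function(partition, path, provenance = NULL) {
  stopifnot(inherits(partition, "partition_result"))
  payload <- list(
    prevalence_threshold = attr(partition, "prevalence_threshold"),
    provenance = provenance,
    categories = lapply(partition, function(p)
      list(n_samples = p$n_samples, sizes = as.list(p$sizes),
           pan = p$pan, core = p$core, accessory = p$accessory)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
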