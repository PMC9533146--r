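test_that("DMFT categorization uses the clinical boundaries and partitions 0..32", {
  expect_equal(as.character(categorize_dmft(0)), "healthy")
  expect_equal(as.character(categorize_dmft(5)), "medium")
  expect_equal(as.character(categorize_dmft(14)), "extremely_high")
  expect_equal(as.character(categorize_dmft(c(1, 3, 4, 6, 7, 13, 32))),
               c("low", "low", "medium", "medium", "high", "high",
                 "extremely_high"))
  # total and deterministic: every score in 0..32 gets exactly one category,
  # and the preimages reproduce the declared score ranges
  cats <- categorize_dmft(0:32)
  expect_false(anyNA(cats))
  for (lvl in DMFT_LEVELS)
    expect_equal(which(cats == lvl) - 1L, as.integer(DMFT_RANGES[[lvl]]))
  expect_error(categorize_dmft(-1), "non-negative")
  expect_error(categorize_dmft(2.5), "integer")
  expect_error(categorize_dmft(33), "32")
})

test_that("depth filtering is inclusive at the boundary and idempotent", {
  m <- rbind(s1 = c(1500, 1499), s2 = c(1500, 1500), s3 = c(9000, 1000))
  colnames(m) <- c("gA", "gB")
  ft <- feature_table(m)
  kept <- filter_by_depth(ft, 3000)
  expect_equal(sample_ids(kept), c("s2", "s3"))
  expect_equal(taxon_ids(kept), c("gA", "gB"))
  expect_equal(kept$counts, m[c("s2", "s3"), ])
  # identity when everything passes; empty result allowed
  expect_equal(filter_by_depth(ft, 0)$counts, m)
  expect_equal(nrow(filter_by_depth(ft, 1e6)$counts), 0)
  expect_equal(filter_by_depth(kept, 3000)$counts, kept$counts)
})

test_that("feature table construction enforces the count invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(feature_table(m), "feature_table")
  bad <- m; bad[1] <- -1
  expect_error(feature_table(bad), "negative")
  bad <- m; bad[1] <- 1.5
  expect_error(feature_table(bad), "non-integer")
  dup <- m; rownames(dup) <- c("a", "a")
  expect_error(feature_table(dup), "duplicated sample")
  expect_error(feature_table(unname(m)), "names")
})

test_that("rank aggregation sums members and conserves per-sample depth", {
  m <- rbind(s1 = c(3, 4, 2), s2 = c(0, 1, 5))
  colnames(m) <- c("otu1", "otu2", "otu3")
  tax <- taxonomy_map(
    c("otu1", "otu2", "otu3"),
    c("Bacteria;P1;C1;O1;F1;Prevotella",
      "Bacteria;P1;C1;O1;F1;Prevotella",
      "Bacteria;P2;C2;O2;F2;Rothia"))
  agg <- aggregate_rank(feature_table(m), tax, "genus")
  expect_equal(agg$counts[, "Prevotella"], c(s1 = 7, s2 = 1))
  expect_equal(agg$counts[, "Rothia"], c(s1 = 2, s2 = 5))
  # all-distinct labels at genus: column permutation of the input
  tax2 <- taxonomy_map(colnames(m), paste0("B;P;C;O;F;G_", colnames(m)))
  agg2 <- aggregate_rank(feature_table(m), tax2, "genus")
  expect_equal(unname(agg2$counts), unname(m))
  # missing lineage is a hard error naming the taxa
  expect_error(aggregate_rank(feature_table(m), tax[-2, ], "genus"), "otu2")
})

test_that("aggregation conserves depth at every rank on random tables", {
  ft <- random_table(20, 50, seed = 42)
  set.seed(43)
  lineages <- sprintf("Bacteria;P%d;C%d;O%d;F%d;G%d",
                      sample(1:4, 50, TRUE), sample(1:6, 50, TRUE),
                      sample(1:8, 50, TRUE), sample(1:10, 50, TRUE),
                      sample(1:25, 50, TRUE))
  tax <- taxonomy_map(taxon_ids(ft), lineages)
  for (rank in TAXONOMIC_RANKS) {
    agg <- aggregate_rank(ft, tax, rank)
    expect_equal(sample_depths(agg), sample_depths(ft))
    # brute-force oracle: sum each sample's counts per label
    lab <- tax[[rank]][match(taxon_ids(ft), tax$taxon_id)]
    for (s in sample_ids(ft))
      expect_equal(agg$counts[s, ],
                   tapply(ft$counts[s, ], lab, sum)[colnames(agg$counts)],
                   ignore_attr = TRUE)
  }
})

test_that("feature table TSV round trip is the identity in both orientations", {
  ft <- make_table(matrix(c(0, 5, 2, 7, 1, 9, 3, 0, 4, 6, 8, 2), 3, 4))
  for (orient in c("taxa_rows", "samples_rows")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_table(ft, path, orientation = orient)
    back <- read_table(path, orientation = orient)
    expect_equal(back$counts, ft$counts)
  }
  # provenance comments survive the round trip unharmed
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(ft, path, provenance = c(seed = "7"))
  expect_equal(read_table(path)$counts, ft$counts)
})

test_that("malformed table and metadata files raise parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#TaxonID\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(read_table(path), "duplicated")
  writeLines(c("#TaxonID\ts1", "gA\t1.7"), path)
  expect_error(read_table(path), "non-integer")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1", nwk)
  expect_error(suppressWarnings(read_tree(nwk)), "malformed")
})

test_that("metadata and taxonomy readers validate and derive the category", {
  md_path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("s1", "s2"), dmft_score = c(0, 15),
                   hiv_status = c("positive", "negative"),
                   sex = c("female", "male"),
                   periodontal_status = c("gingivitis", "periodontitis"),
                   flow_rate = c(0.9, 1.2))
  write.table(df, md_path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- read_metadata(md_path)
  expect_equal(as.character(md$dmft_category), c("healthy", "extremely_high"))
  df$hiv_status <- c("yes", "no")
  write.table(df, md_path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_metadata(md_path), "invalid hiv_status")
})

test_that("Newick reading recovers topology and branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_tree(path)
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  expect_equal(sum(tree$edge.length), 5)
})
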