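# shared fixture builders: everything is generated in code, no stored data

make_table <- function(m, samples = NULL, taxa = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- taxa %||% sprintf("g%02d", seq_len(ncol(m)))
  feature_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n_samples, n_taxa, seed, lambda = 20,
                         zero_frac = 0.3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
  m[stats::runif(length(m)) < zero_frac] <- 0
  # guarantee no empty samples
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  make_table(m)
}

random_metadata <- function(table, seed, categories = DMFT_LEVELS) {
  set.seed(seed)
  ids <- sample_ids(table)
  cat <- rep_len(categories, length(ids))
  score <- vapply(cat, function(cc) {
    rng <- DMFT_RANGES[[cc]]
    if (length(rng) == 1) rng else sample(rng, 1)
  }, numeric(1))
  sample_metadata(data.frame(
    sample_id = ids, dmft_score = score,
    hiv_status = sample(c("positive", "negative"), length(ids), TRUE),
    sex = sample(c("female", "male"), length(ids), TRUE),
    periodontal_status = sample(c("gingivitis", "periodontitis"),
                                length(ids), TRUE),
    flow_rate = round(runif(length(ids), 0.2, 2), 2),
    stringsAsFactors = FALSE))
}

# independent recursive leaf-descendant finder used by UniFrac oracles:
# direct recursion over the edge table, unlike the package's postorder pass
tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

oracle_unifrac_pair <- function(x, y, tree, weighted, normalized = TRUE) {
  num <- den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- tips_below(tree, tree$edge[e, 2])
    l <- tree$edge.length[e]
    if (weighted) {
      a <- sum(x[leaves]) / sum(x)
      b <- sum(y[leaves]) / sum(y)
      num <- num + l * abs(a - b)
      den <- den + l * (a + b)
    } else {
      pa <- any(x[leaves] > 0); pb <- any(y[leaves] > 0)
      if (xor(pa, pb)) num <- num + l
      if (pa || pb) den <- den + l
    }
  }
  if (weighted && !normalized) num else num / den
}
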