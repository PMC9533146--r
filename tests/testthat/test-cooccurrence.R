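# helper: build aligned rho/p matrices from an edge description
toy_matrices <- function(nodes, edges) {
  n <- length(nodes)
  rho <- diag(1, n); p <- matrix(NA_real_, n, n)
  dimnames(rho) <- dimnames(p) <- list(nodes, nodes)
  p[upper.tri(p)] <- p[lower.tri(p)] <- 0.9   # default: weak, non-significant
  rho[upper.tri(rho)] <- rho[lower.tri(rho)] <- 0
  for (e in edges) {
    i <- e[[1]]; j <- e[[2]]
    rho[i, j] <- rho[j, i] <- as.numeric(e[[3]])
    p[i, j] <- p[j, i] <- as.numeric(e[[4]])
  }
  diag(p) <- NA
  list(rho = rho, p = p)
}

test_that("Spearman matrix matches a rank-then-Pearson oracle", {
  ft <- random_table(8, 6, seed = 41, lambda = 30, zero_frac = 0.2)
  sp <- spearman_matrix(ft)
  ra <- relative_abundance(ft)
  for (i in 1:5) for (j in (i + 1):6) {
    oracle <- cor(rank(ra[, i]), rank(ra[, j]))  # average ranks on ties
    expect_equal(sp$rho[i, j], oracle, tolerance = 1e-12)
  }
  expect_true(all(diag(sp$rho) == 1))
  # p-values follow the large-sample t approximation
  n <- 8
  r <- sp$rho[1, 2]
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(sp$p[1, 2], 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
})

test_that("monotone pairs reach rho of +/- 1 and constant genera are flagged", {
  m <- cbind(up = c(1, 2, 3, 5, 8, 13),
             up2 = c(2, 4, 9, 11, 20, 31),
             down = c(60, 50, 40, 30, 20, 10))
  depth_fix <- 200 - rowSums(m)
  ft <- make_table(cbind(m, filler = depth_fix))
  sp <- spearman_matrix(ft)
  expect_equal(sp$rho["up", "up2"], 1)
  expect_equal(sp$rho["up", "down"], -1)
  expect_equal(sp$p["up", "up2"], 0)
  # a genus with identical relative abundance everywhere has no correlation
  const <- make_table(cbind(a = c(10, 20, 30, 40), b = c(30, 60, 90, 120),
                            c = c(60, 120, 180, 240)))
  spc <- spearman_matrix(const)   # all columns constant in relative abundance
  expect_true(all(is.na(spc$rho)))
  expect_equal(sort(attr(spc, "constant")), c("a", "b", "c"))
  expect_error(spearman_matrix(make_table(matrix(1:6, 3, 2))), "4 samples")
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle on random vectors
  set.seed(44)
  for (i in 1:5) {
    p <- runif(20)
    m <- length(p)
    o <- order(p)
    stepped <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
    oracle <- numeric(m); oracle[o] <- stepped
    expect_equal(bh_fdr(p), oracle, tolerance = 1e-12)
  }
  # NA entries pass through without disturbing the rest
  expect_equal(bh_fdr(c(0.01, NA, 0.04))[2], NA_real_)
})

test_that("graph pruning is strict at the threshold and significance is an attribute", {
  tm <- toy_matrices(c("a", "b", "c"), list(
    list("a", "b", -0.6, 0.005),   # edge, significant after BH
    list("a", "c", 0.9, 0.5),      # edge, not significant
    list("b", "c", 0.5, 0.001)))   # exactly at threshold: excluded
  g <- build_graph(tm$rho, tm$p, rho_threshold = 0.5, alpha = 0.05)
  expect_equal(nrow(g$edges), 2)
  expect_false(any(g$edges$u == "b" & g$edges$v == "c"))
  ab <- g$edges[g$edges$u == "a" & g$edges$v == "b", ]
  expect_true(ab$significant)
  expect_equal(ab$rho, -0.6)
  ac <- g$edges[g$edges$u == "a" & g$edges$v == "c", ]
  expect_false(ac$significant)    # retained but flagged non-significant
  expect_true(all(abs(g$edges$rho) > 0.5))
})

test_that("graph construction is invariant to node order", {
  ft <- random_table(12, 8, seed = 47, lambda = 15)
  sp <- spearman_matrix(ft)
  g1 <- build_graph(sp$rho, sp$p)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  g2 <- build_graph(sp$rho[perm, perm], sp$p[perm, perm])
  key <- function(g) {
    e <- g$edges
    sort(paste(pmin(e$u, e$v), pmax(e$u, e$v), round(e$rho, 12)))
  }
  expect_equal(key(g1), key(g2))
  expect_equal(g1$nodes, g2$nodes)
})

test_that("the entropy statistic is the significant-edge fraction", {
  tm <- toy_matrices(c("a", "b", "c", "d"), list(
    list("a", "b", 0.9, 1e-6), list("c", "d", 0.9, 1e-6)))
  g <- build_graph(tm$rho, tm$p)
  expect_equal(entropy_statistic(g), 1.0)
  tm2 <- toy_matrices(c("a", "b", "c", "d"), list(
    list("a", "b", 0.9, 1e-6), list("c", "d", 0.9, 0.8)))
  g2 <- build_graph(tm2$rho, tm2$p)
  expect_equal(entropy_statistic(g2), 0.5)
  # over all tested pairs: 1 significant of 6
  expect_equal(entropy_statistic(g2, denominator = "pairs"), 1 / 6)
  expect_error(entropy_statistic(build_graph(
    structure(diag(1, 4), dimnames = rep(list(letters[1:4]), 2)),
    structure(matrix(0.9, 4, 4), dimnames = rep(list(letters[1:4]), 2)))),
    "no edges")
})

test_that("community extraction splits cliques and isolates singletons", {
  nodes <- letters[1:8]
  clique <- function(v) {
    out <- list()
    for (i in seq_along(v)[-length(v)]) for (j in (i + 1):length(v))
      out[[length(out) + 1]] <- list(v[i], v[j], 0.9, 1e-6)
    out
  }
  tm <- toy_matrices(nodes, c(clique(letters[1:4]), clique(letters[5:8]),
                              list(list("d", "e", 0.6, 1e-4))))
  g <- build_graph(tm$rho, tm$p)
  comm <- communities(g)
  expect_length(unique(comm), 2)
  expect_length(unique(comm[letters[1:4]]), 1)
  expect_length(unique(comm[letters[5:8]]), 1)
  # complete uniform graph: a single community
  tmc <- toy_matrices(letters[1:5], clique(letters[1:5]))
  gc <- build_graph(tmc$rho, tmc$p)
  expect_length(unique(communities(gc)), 1)
  # isolated nodes become singleton communities
  tmi <- toy_matrices(letters[1:5], list(list("a", "b", 0.9, 1e-6)))
  gi <- build_graph(tmi$rho, tmi$p)
  ci <- communities(gi)
  expect_equal(ci["a"], ci["b"], ignore_attr = TRUE)
  expect_length(unique(ci[c("c", "d", "e")]), 3)
})

test_that("degree ranking is descending with lexicographic ties", {
  # star: center first
  tm <- toy_matrices(c("hub", "x", "y", "z"), list(
    list("hub", "x", 0.9, 1e-6), list("hub", "y", 0.9, 1e-6),
    list("hub", "z", 0.9, 1e-6)))
  g <- build_graph(tm$rho, tm$p)
  expect_equal(degree_rank(g)[1], "hub")
  # 4-cycle (regular): pure lexicographic order
  tmr <- toy_matrices(c("d", "c", "b", "a"), list(
    list("a", "b", 0.9, 1e-6), list("b", "c", 0.9, 1e-6),
    list("c", "d", 0.9, 1e-6), list("d", "a", 0.9, 1e-6)))
  gr <- build_graph(tmr$rho, tmr$p)
  expect_equal(degree_rank(gr), c("a", "b", "c", "d"))
  expect_equal(degree_rank(gr, top_k = 2), c("a", "b"))
  # random graph: agrees with brute-force degree counting
  ft <- random_table(12, 10, seed = 48)
  sp <- spearman_matrix(ft)
  grand <- build_graph(sp$rho, sp$p, rho_threshold = 0.2)
  ranked <- degree_rank(grand, top_k = 100)
  deg <- sapply(grand$nodes, function(nd)
    sum(grand$edges$u == nd) + sum(grand$edges$v == nd))
  expect_equal(ranked, names(deg)[order(-deg, names(deg))])
})

test_that("graph export writes the edge list and optional arc duplication", {
  tm <- toy_matrices(c("a", "b", "c"), list(list("a", "b", 0.8, 1e-4)))
  g <- build_graph(tm$rho, tm$p)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, path)
  df <- read.delim(path, comment.char = "")
  expect_equal(nrow(df), 1)
  write_graph(g, path, directed = TRUE)
  expect_equal(nrow(read.delim(path, comment.char = "")), 2)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph(g, path, graphml_path = gml)
  expect_true(file.size(gml) > 0)
})
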