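test_that("core membership is inclusive at the prevalence boundary", {
  m <- matrix(0, 20, 3, dimnames = list(sprintf("s%d", 1:20),
                                        c("boundary", "everywhere", "rare")))
  m[1:17, "boundary"] <- 1      # prevalence exactly 0.85
  m[, "everywhere"] <- 2
  m[1, "rare"] <- 5
  ft <- feature_table(m)
  core <- core_taxa(ft, 0.85)
  expect_true("boundary" %in% core)
  expect_true("everywhere" %in% core)
  expect_false("rare" %in% core)
  expect_true("everywhere" %in% core_taxa(ft, 1.0))
  expect_error(core_taxa(ft, 1.5), "\\[0, 1\\]")
})

test_that("core and pan sets match brute-force presence counting", {
  ft <- random_table(30, 100, seed = 14, zero_frac = 0.6)
  presence <- ft$counts > 0
  oracle_core <- sort(colnames(presence)[colSums(presence) / 30 >= 0.85])
  expect_equal(core_taxa(ft, 0.85), oracle_core)
  oracle_pan <- sort(colnames(presence)[colSums(presence) > 0])
  expect_equal(pan_taxa(ft), oracle_pan)
  # pan equals the union of per-sample supports
  supports <- lapply(seq_len(30), function(i) colnames(presence)[presence[i, ]])
  expect_equal(pan_taxa(ft), sort(Reduce(union, supports)))
  # an all-zero column never enters the pan
  m <- ft$counts; m[, 1] <- 0
  expect_false(colnames(m)[1] %in% pan_taxa(feature_table(m)))
})

test_that("raising the prevalence threshold never adds core taxa", {
  ft <- random_table(25, 60, seed = 15, zero_frac = 0.5)
  thresholds <- seq(0, 1, by = 0.1)
  cores <- lapply(thresholds, function(t) core_taxa(ft, t))
  for (i in seq_along(cores)[-1])
    expect_true(all(cores[[i]] %in% cores[[i - 1]]))
})

test_that("per-category partition satisfies pan/core/accessory arithmetic", {
  ft <- random_table(20, 40, seed = 16, zero_frac = 0.5)
  md <- random_metadata(ft, seed = 17)
  part <- partition_by_category(ft, md, 0.85)
  for (cc in DMFT_LEVELS) {
    p <- part[[cc]]
    expect_true(all(p$core %in% p$pan))
    expect_equal(sort(p$accessory), sort(setdiff(p$pan, p$core)))
    expect_equal(p$sizes[["accessory"]], p$sizes[["pan"]] - p$sizes[["core"]])
  }
  # an absent category is reported empty with a warning
  md2 <- random_metadata(ft, seed = 18, categories = DMFT_LEVELS[1:4])
  expect_warning(part2 <- partition_by_category(ft, md2),
                 "extremely_high")
  expect_equal(part2$extremely_high$n_samples, 0L)
})

test_that("the DMFT core is the intersection of per-category cores", {
  ft <- random_table(20, 40, seed = 19, zero_frac = 0.5)
  md <- random_metadata(ft, seed = 20)
  part <- partition_by_category(ft, md, 0.85)
  oracle <- Reduce(intersect, lapply(part, `[[`, "core"))
  shared <- dmft_core(part)
  expect_equal(shared, sort(oracle))
  for (cc in DMFT_LEVELS) expect_true(all(shared %in% part[[cc]]$core))
})

test_that("richness proportions follow the precedence and sum to one", {
  lists <- genus_group_lists(normal_flora = c("NormA", "NormB"),
                             disease_associated = c("DisA", "DisB"))
  pan <- c("Core1", "Core2", "Core3", "Core4", "Core5",
           "Acc1", "DisA", "DisB", "NormA", "NormB")
  props <- richness_proportions(pan, dmft_core = paste0("Core", 1:5),
                                lists = lists, accessory = "Acc1")
  expect_equal(unname(props[c("core", "accessory", "disease_associated",
                              "normal_flora")]),
               c(0.5, 0.1, 0.2, 0.2))
  # precedence: a core genus that is also disease-associated counts as core
  props2 <- richness_proportions(c("DisA", "Other"), dmft_core = "DisA",
                                 lists = lists, accessory = character())
  expect_equal(unname(props2["core"]), 0.5)
  expect_equal(unname(props2["disease_associated"]), 0)
  # pan = core with empty lists: 100% core
  empty <- genus_group_lists(character(), character())
  props3 <- richness_proportions(c("a", "b"), dmft_core = c("a", "b"),
                                 lists = empty, accessory = character())
  expect_equal(unname(props3["core"]), 1)
  # sums to one on random inputs
  set.seed(22)
  for (i in 1:10) {
    pan <- sprintf("G%02d", sample(99, 30))
    props <- richness_proportions(
      pan, dmft_core = sample(pan, 10), lists = lists,
      accessory = sample(pan, 5))
    expect_equal(sum(props), 1, tolerance = 1e-12)
  }
  expect_error(richness_proportions(character(), "a", lists, character()),
               "empty")
})

test_that("genus group lists are case-normalized and must be disjoint", {
  expect_error(genus_group_lists(c("Rothia"), c("rothia")), "both lists")
  lists <- read_genus_lists()
  expect_gt(length(lists$normal_flora), 5)
  expect_gt(length(lists$disease_associated), 5)
  expect_length(intersect(lists$normal_flora, lists$disease_associated), 0)
})

test_that("partition JSON export is deterministic and complete", {
  ft <- random_table(15, 25, seed = 23, zero_frac = 0.4)
  md <- random_metadata(ft, seed = 24)
  part <- partition_by_category(ft, md)
  path <- withr::local_tempfile(fileext = ".json")
  write_partition(part, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$prevalence_threshold, 0.85)
  expect_equal(sort(names(back$categories)), sort(DMFT_LEVELS))
  expect_equal(back$categories$healthy$core, part$healthy$core)
})
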