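#' Describe a synthetic DMFT cohort design
#'
#' Collects every knob of the community simulator into a validated design
#' object. The defaults emulate the cohort the pipeline targets: 88 saliva
#' samples split 11/32/21/16/8 over the five DMFT severity categories, a
#' genus-level community of 165 taxa with a stable shared core of 65 genera
#' (so each category's pan microbiota is roughly 80 genera, about a quarter
#' of it accessory), category-private low-prevalence accessory taxa, and
#' wide lognormal library sizes centred on ~14,000 reads so that a
#' 3,000-read depth filter removes a handful of samples.
#'
#' Correlation between taxa is induced by shared lognormal latent factors
#' acting on Dirichlet concentrations: `factor_strength = 0` gives
#' independent taxa (the null used for calibration), larger values give more
#' and stronger positive pairwise associations. The default of 1 produces
#' the strongly structured co-occurrence typical of oral communities, where
#' most retained pairwise associations are significant.
#'
#' @param n_per_category Integer vector of length 5 (healthy, low, medium,
#'   high, extremely_high sample counts).
#' @param n_taxa Total number of genera simulated.
#' @param core_size Number of planted core genera (`<= n_taxa`).
#' @param core_prevalence_target Fraction of samples in which each core genus
#'   is present. At `1.0` presence is guaranteed by construction.
#' @param accessory_rate Fraction of each category's accessory pool that is
#'   actually used by that category.
#' @param accessory_occupancy Per-sample presence probability of an active
#'   accessory genus within its own category.
#' @param depth_log_mean,depth_log_sd Lognormal library-size parameters
#'   (natural-log scale).
#' @param base_concentration Dirichlet concentration of non-core genera.
#' @param core_concentration Dirichlet concentration of core genera.
#' @param n_latent_factors Number of shared latent factors.
#' @param factor_strength Non-negative scale of the latent-factor effect on
#'   log-concentrations; 0 means independent taxa.
#' @param glm_coefficients Planted log-scale effects of the clinical
#'   covariates on library size (microbial biomass): either a single named
#'   vector with any of `hiv`, `sex`, `periodontitis` (applied in every
#'   category) or a named list of such vectors keyed by category.
#' @param signal_genus Optional taxon index or id carrying a between-category
#'   abundance signal (its concentration is scaled by
#'   `exp(signal_strength * (category_index - 3))`).
#' @param signal_strength Strength of that signal on the log scale.
#' @param seed Integer seed; identical designs generate bit-identical data.
#' @return A list of class `synthetic_design`.
#' @export
synthetic_design <- function(n_per_category = c(healthy = 11, low = 32,
                                                medium = 21, high = 16,
                                                extremely_high = 8),
                             n_taxa = 165,
                             core_size = 65,
                             core_prevalence_target = 1.0,
                             accessory_rate = 0.85,
                             accessory_occupancy = 0.7,
                             depth_log_mean = log(14351),
                             depth_log_sd = 1.1,
                             base_concentration = 0.05,
                             core_concentration = 1.0,
                             n_latent_factors = 3,
                             factor_strength = 1,
                             glm_coefficients = NULL,
                             signal_genus = NULL,
                             signal_strength = 0,
                             seed = 1L) {
  if (length(n_per_category) != 5 || any(n_per_category < 0))
    stop("`n_per_category` must be five non-negative counts")
  names(n_per_category) <- DMFT_LEVELS
  if (core_size > n_taxa) stop("`core_size` cannot exceed `n_taxa`")
  rates <- c(core_prevalence_target, accessory_rate, accessory_occupancy)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (factor_strength < 0) stop("`factor_strength` must be >= 0")
  structure(list(
    n_per_category = as.integer(n_per_category), n_taxa = as.integer(n_taxa),
    core_size = as.integer(core_size),
    core_prevalence_target = core_prevalence_target,
    accessory_rate = accessory_rate, accessory_occupancy = accessory_occupancy,
    depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
    base_concentration = base_concentration,
    core_concentration = core_concentration,
    n_latent_factors = as.integer(n_latent_factors),
    factor_strength = factor_strength,
    glm_coefficients = glm_coefficients,
    signal_genus = signal_genus, signal_strength = signal_strength,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

# normalize planted covariate effects to a 5 x 3 matrix (category x effect)
planted_coefficients <- function(glm_coefficients) {
  effects <- c("hiv", "sex", "periodontitis")
  beta <- matrix(0, 5, 3, dimnames = list(DMFT_LEVELS, effects))
  if (is.null(glm_coefficients)) return(beta)
  if (is.list(glm_coefficients)) {
    bad <- setdiff(names(glm_coefficients), DMFT_LEVELS)
    if (length(bad)) stop("unknown category in glm_coefficients: ",
                          paste(bad, collapse = ", "))
    for (cat in names(glm_coefficients)) {
      v <- glm_coefficients[[cat]]
      beta[cat, names(v)] <- v
    }
  } else {
    v <- glm_coefficients
    bad <- setdiff(names(v), effects)
    if (length(bad)) stop("unknown effect in glm_coefficients: ",
                          paste(bad, collapse = ", "))
    beta[, names(v)] <- rep(v, each = 5)
  }
  beta
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1  # pathological underflow guard
  g / sum(g)
}

#' Generate a synthetic DMFT cohort
#'
#' Draws a full dataset under a [synthetic_design()]: per-sample library
#' sizes are lognormal (scaled by any planted covariate effects), latent
#' factors shift the log Dirichlet concentrations of loaded taxa, the
#' composition is Dirichlet and the counts multinomial at the drawn depth.
#' Core genera receive high concentration; accessory genera are zeroed
#' outside their own DMFT category. A ground-truth record of everything
#' planted accompanies the data so recovery can be tested.
#'
#' @param design A [synthetic_design()].
#' @return A list of class `synthetic_dataset` with elements `table`
#'   ([feature_table()]), `metadata` ([sample_metadata()]), `taxonomy`
#'   ([taxonomy_map()]), `tree` (`ape::phylo`) and `truth`
#'   (class `synthetic_truth`).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(design$seed)

  n_taxa <- design$n_taxa
  taxa <- sprintf("Genus_%03d", seq_len(n_taxa))
  core <- taxa[seq_len(design$core_size)]
  noncore <- setdiff(taxa, core)

  # accessory pools: non-core taxa dealt round-robin over the 5 categories,
  # each category using the leading accessory_rate fraction of its pool
  pool <- split(noncore, rep_len(DMFT_LEVELS, length(noncore)))
  accessory <- lapply(DMFT_LEVELS, function(cat) {
    p <- pool[[cat]]
    p[seq_len(ceiling(design$accessory_rate * length(p)))]
  })
  names(accessory) <- DMFT_LEVELS

  # latent-factor loadings: each taxon loads on at most one factor
  L <- max(design$n_latent_factors, 1L)
  loadings <- matrix(0, n_taxa, L, dimnames = list(taxa, paste0("F", seq_len(L))))
  if (design$n_latent_factors > 0) {
    loaded <- stats::runif(n_taxa) < 0.6
    which_f <- sample.int(design$n_latent_factors, n_taxa, replace = TRUE)
    loadings[cbind(seq_len(n_taxa), which_f)] <- as.numeric(loaded)
  }

  sig <- design$signal_genus
  if (!is.null(sig) && is.numeric(sig)) sig <- taxa[sig]
  if (!is.null(sig) && !sig %in% taxa) stop("signal_genus not among taxa")

  beta <- planted_coefficients(design$glm_coefficients)

  n <- sum(design$n_per_category)
  if (n == 0) stop("design has zero samples")
  cat_of <- rep(DMFT_LEVELS, times = design$n_per_category)
  ids <- sprintf("S%03d", seq_len(n))

  # clinical covariates drawn at cohort-typical frequencies
  hiv <- ifelse(stats::runif(n) < 0.67, "positive", "negative")
  sex <- ifelse(stats::runif(n) < 0.568, "female", "male")
  perio <- ifelse(stats::runif(n) < 0.421, "periodontitis", "gingivitis")
  score <- vapply(cat_of, function(cat) {
    rng <- if (cat == "extremely_high") 14:20 else DMFT_RANGES[[cat]]
    if (length(rng) == 1) rng else sample(rng, 1)
  }, numeric(1))
  flow <- round(pmax(stats::rnorm(n, 0.9, 0.5), 0.05), 2)

  base_alpha <- ifelse(taxa %in% core, design$core_concentration,
                       design$base_concentration)
  counts <- matrix(0, n, n_taxa, dimnames = list(ids, taxa))
  for (s in seq_len(n)) {
    cat <- cat_of[s]
    ci <- match(cat, DMFT_LEVELS)
    eta <- beta[cat, "hiv"] * (hiv[s] == "positive") +
      beta[cat, "sex"] * (sex[s] == "male") +
      beta[cat, "periodontitis"] * (perio[s] == "periodontitis")
    depth <- max(1, round(stats::rlnorm(1, design$depth_log_mean + eta,
                                        design$depth_log_sd)))
    alpha <- base_alpha
    # accessory genera exist only inside their own category, sporadically
    foreign <- unlist(accessory[setdiff(DMFT_LEVELS, cat)], use.names = FALSE)
    alpha[taxa %in% foreign | (taxa %in% noncore & !taxa %in% accessory[[cat]])] <- 0
    own <- taxa %in% accessory[[cat]]
    alpha[own] <- alpha[own] * (stats::runif(sum(own)) < design$accessory_occupancy)
    if (design$core_prevalence_target < 1) {
      keep <- stats::runif(design$core_size) < design$core_prevalence_target
      alpha[seq_len(design$core_size)][!keep] <- 0
    }
    if (design$factor_strength > 0) {
      f <- stats::rnorm(L)
      alpha <- alpha * exp(design$factor_strength * drop(loadings %*% f))
    }
    if (!is.null(sig))
      alpha[taxa == sig] <- alpha[taxa == sig] * exp(design$signal_strength * (ci - 3))
    pos <- which(alpha > 0)
    p <- rdirichlet1(alpha[pos])
    counts[s, pos] <- stats::rmultinom(1, depth, p)
    if (design$core_prevalence_target == 1) {
      # guarantee planted core presence: move single reads from the top taxon
      zero_core <- which(counts[s, seq_len(design$core_size)] == 0)
      for (z in zero_core) {
        top <- which.max(counts[s, ])
        counts[s, top] <- counts[s, top] - 1
        counts[s, z] <- 1
      }
    }
  }

  metadata <- sample_metadata(data.frame(
    sample_id = ids, dmft_score = score, hiv_status = hiv, sex = sex,
    periodontal_status = perio, flow_rate = flow, stringsAsFactors = FALSE))

  # fictional but nested lineage labels so rank aggregation is exercised
  fam <- ceiling(seq_len(n_taxa) / 5)
  phy <- ceiling(fam / 5)
  taxonomy <- taxonomy_map(taxa, sprintf(
    "Bacteria;SynPhylum_%02d;SynClass_%02d;SynOrder_%02d;SynFamily_%02d;%s",
    phy, phy, fam, fam, taxa))

  tree <- generate_tree(taxa, seed = design$seed + 1L)

  truth <- structure(list(
    core_taxa = core, accessory_taxa_by_category = accessory,
    factor_loadings = loadings, coefficients = beta,
    signal_genus = sig, signal_strength = design$signal_strength,
    seed = design$seed), class = "synthetic_truth")

  structure(list(table = feature_table(counts), metadata = metadata,
                 taxonomy = taxonomy, tree = tree, truth = truth,
                 design = design),
            class = "synthetic_dataset")
}

#' Generate a random rooted binary tree over given taxa
#'
#' Builds a topology by successive random joins of subtrees with
#' exponential(1) branch lengths — enough phylogenetic structure for
#' UniFrac without implying real biology.
#'
#' @param taxon_ids Character vector of at least two leaf labels.
#' @param seed Integer seed.
#' @return An `ape::phylo` rooted binary tree whose leaves are exactly
#'   `taxon_ids`.
#' @export
generate_tree <- function(taxon_ids, seed = 1L) {
  if (length(taxon_ids) < 2) stop("need at least 2 taxa to build a tree")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nodes <- paste0(taxon_ids, ":", format(stats::rexp(length(taxon_ids)), digits = 6))
  while (length(nodes) > 1) {
    pick <- sample.int(length(nodes), 2)
    joined <- sprintf("(%s,%s):%s", nodes[pick[1]], nodes[pick[2]],
                      format(stats::rexp(1), digits = 6))
    nodes <- c(nodes[-pick], joined)
  }
  newick <- paste0(sub(":[^():,]*$", "", nodes), ";")
  ape::read.tree(text = newick)
}

#' Write a synthetic dataset to disk in the pipeline's exchange formats
#'
#' Counts, metadata and taxonomy as TSV, the tree as Newick, the design as
#' YAML and the planted truth as JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(dataset$table, file.path(dir, "counts.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  yaml::write_yaml(unclass(dataset$design)[
    !vapply(unclass(dataset$design), is.null, logical(1))],
    file.path(dir, "design.yaml"))
  truth <- dataset$truth
  jsonlite::write_json(list(
    core_taxa = truth$core_taxa,
    accessory_taxa_by_category = truth$accessory_taxa_by_category,
    coefficients = as.data.frame(truth$coefficients),
    signal_genus = truth$signal_genus, seed = truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
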