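#' Principal coordinate analysis (PCoA)
#'
#' Classical metric scaling: the squared distance matrix is Gower
#' double-centered (`B = -J D^2 J / 2` with `J = I - 11'/n`) and
#' eigendecomposed. Coordinates are returned only for positive eigenvalues
#' (scaled by the square root of the eigenvalue); negative eigenvalues,
#' which arise for semi-metric dissimilarities, are reported but contribute
#' no axes.
#'
#' @param d A `distance_matrix` (or labeled symmetric matrix / `dist`).
#' @return An object of class `ordination_result` with `coordinates`
#'   (samples x positive axes), `eigenvalues` (all, descending) and
#'   `sample_ids`.
#' @export
pcoa <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  validate_distance_matrix(unclass(d))
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (unclass(d)^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-9 & e$values > 0
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = e$values,
                 sample_ids = rownames(d)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d positive axes; TVE(5) = %.3f\n",
              length(x$sample_ids), ncol(x$coordinates), tve(x, 5)))
  invisible(x)
}

#' Total variance explained by the first k principal coordinates
#'
#' `TVE = sum_{i<=k} max(lambda_i, 0) / sum_i max(lambda_i, 0)`: the
#' fraction of positive ordination variance captured by the leading `k`
#' axes. Negative eigenvalues are truncated at zero (no Lingoes/Cailliez
#' correction); `correction = "lingoes"` instead adds the smallest constant
#' to all squared distances that makes every eigenvalue non-negative.
#'
#' @param ord An `ordination_result` from [pcoa()].
#' @param k Number of leading axes (default 5).
#' @param correction `"none"` (truncate) or `"lingoes"`.
#' @return A fraction in [0, 1].
#' @export
tve <- function(ord, k = 5, correction = c("none", "lingoes")) {
  stopifnot(inherits(ord, "ordination_result"))
  correction <- match.arg(correction)
  if (k < 0) stop("`k` must be non-negative")
  lam <- ord$eigenvalues
  if (correction == "lingoes" && min(lam) < 0) lam <- lam - min(lam)
  lam <- pmax(lam, 0)
  if (sum(lam) == 0) stop("no positive eigenvalues; TVE undefined")
  sum(lam[seq_len(min(k, length(lam)))]) / sum(lam)
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared inter-sample distances into between-
#' and within-group components and assesses the pseudo-F statistic by
#' permuting group labels. With groups `g` and total `n`:
#' `pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g))`,
#' `R^2 = SS_between / SS_total`, and the p-value is
#' `(1 + #{permuted F >= observed F}) / (1 + n_perm)` so it can never be 0.
#'
#' @param d A `distance_matrix` (or labeled symmetric matrix / `dist`).
#' @param groups Vector of group labels aligned with the rows of `d`.
#' @param n_perm Number of label permutations (default 9999).
#' @param seed Optional integer seed for the permutations.
#' @return List of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `df`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  validate_distance_matrix(unclass(d))
  groups <- as.character(groups)
  n <- nrow(d)
  if (length(groups) != n) stop("`groups` length must match the matrix")
  tab <- table(groups)
  g <- length(tab)
  if (g < 2) stop("need at least 2 groups")
  if (n < 4) stop("need at least 4 samples")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  d2 <- unclass(d)^2
  ss <- permanova_ss(d2, groups)
  ss_between <- ss["total"] - ss["within"]
  f_obs <- (ss_between / (g - 1)) / (ss["within"] / (n - g))
  # permuting labels over samples == permuting samples over fixed label slots;
  # SS_total is permutation-invariant, so only SS_within is recomputed
  slots <- split(seq_len(n), groups)
  sizes <- lengths(slots)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    ssw <- 0
    for (k in seq_len(g)) {
      m <- idx[slots[[k]]]
      ssw <- ssw + sum(d2[m, m]) / (2 * sizes[[k]])
    }
    ((ss["total"] - ssw) / (g - 1)) / (ssw / (n - g))
  }, numeric(1))
  structure(list(
    pseudo_F = unname(f_obs),
    R2 = unname(ss_between / ss["total"]),
    p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
    n_perm = n_perm,
    df = c(between = g - 1, within = n - g)),
    class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Serialize an ordination: coordinates as TSV, eigenvalues and TVE as JSON
#'
#' @param ord An `ordination_result`.
#' @param coords_path Path for the coordinate TSV.
#' @param json_path Path for the eigenvalue/TVE JSON.
#' @param k TVE horizon recorded in the JSON.
#' @param provenance Optional named character vector of comment lines.
#' @export
write_ordination <- function(ord, coords_path, json_path, k = 5,
                             provenance = NULL) {
  stopifnot(inherits(ord, "ordination_result"))
  df <- data.frame(sample_id = ord$sample_ids, ord$coordinates,
                   check.names = FALSE)
  con <- file(coords_path, open = "wt")
  writeLines(provenance_lines(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  jsonlite::write_json(list(eigenvalues = ord$eigenvalues,
                            k = k, tve = tve(ord, k)),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(coords_path)
}
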