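#' Quasi-Poisson regression of a count outcome
#'
#' Log-link count regression fitted by iteratively reweighted least squares
#' (the standard GLM fit), with a free dispersion parameter
#' `phi = Pearson chi-squared / (n - p)` estimated afterwards; standard
#' errors are the Poisson ones inflated by `sqrt(phi)`. `phi` near 1 means
#' Poisson-like variation; `phi > 1` indicates overdispersion, which is the
#' rule for microbial biomass.
#'
#' @param y Non-negative count outcome vector.
#' @param design_matrix Numeric model matrix (including the intercept
#'   column), full rank, with `n > p`.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Convergence tolerance on the relative deviance change
#'   (default 1e-8).
#' @param offset Optional log-scale offset vector (e.g. log depth).
#' @return An object of class `glm_fit`: `coefficients`, `standard_errors`,
#'   `dispersion`, `deviance`, `n_obs`, `df_residual`, `converged`,
#'   `fitted`.
#' @export
fit_quasipoisson <- function(y, design_matrix, max_iter = 100, tol = 1e-8,
                             offset = NULL) {
  X <- as.matrix(design_matrix)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(y < 0)) stop("outcome must be non-negative")
  n <- length(y); p <- ncol(X)
  if (nrow(X) != n) stop("design matrix rows must match outcome length")
  if (n <= p) stop("need more observations than parameters")
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  fit <- stats::glm.fit(X, y, family = stats::poisson(),
                        offset = offset,
                        control = stats::glm.control(epsilon = tol,
                                                     maxit = max_iter))
  mu <- fit$fitted.values
  phi <- sum((y - mu)^2 / mu) / (n - p)
  # covariance of beta-hat: (X' W X)^-1 * phi, from the IRLS QR factor
  R <- qr.R(fit$qr)
  cov_unscaled <- chol2inv(R)
  se <- sqrt(diag(cov_unscaled) * phi)
  names(se) <- colnames(X)[fit$qr$pivot]
  se <- se[colnames(X)]
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    standard_errors = se,
    dispersion = phi,
    deviance = fit$deviance,
    n_obs = n,
    df_residual = n - p,
    converged = fit$converged,
    fitted = mu),
    class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> quasi-Poisson, n = %d, dispersion phi = %.3f, deviance = %.2f%s\n",
              x$n_obs, x$dispersion, x$deviance,
              if (x$converged) "" else " (NOT converged)"))
  print(round(rbind(estimate = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

#' Wald tests for a quasi-Poisson fit
#' @param fit A `glm_fit`.
#' @return Data frame with `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  z <- fit$coefficients / fit$standard_errors
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$standard_errors),
             z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Per-DMFT-category quasi-Poisson models of microbial biomass
#'
#' Splits the cohort into its five DMFT severity subsets and fits one
#' quasi-Poisson model per category with an identical covariate set, so the
#' coefficient differences across models describe what changes at each
#' caries stage. The outcome is the per-sample total genus-level count
#' (microbial biomass); covariates are sex, HIV status, periodontal status
#' and, optionally, family-level relative abundances for an explicit list
#' of families.
#'
#' @param table A genus-level [feature_table()].
#' @param metadata A [sample_metadata()] covering every sample.
#' @param family_table Optional family-level [feature_table()] supplying
#'   relative-abundance covariates.
#' @param families Character vector of family names to include as
#'   covariates (required when `family_table` is given).
#' @param adjust `"none"` (default, per-model Wald stars) or `"BH"` to FDR-
#'   adjust every p-value of the comparison table jointly.
#' @return An object of class `model_comparison`: list of `glm_fit` per
#'   category plus a long-format `table` (category, term, estimate, se, p,
#'   stars). Categories with too few samples are skipped with a warning.
#' @export
per_category_models <- function(table, metadata, family_table = NULL,
                                families = NULL, adjust = c("none", "BH")) {
  stopifnot(inherits(table, "feature_table"))
  adjust <- match.arg(adjust)
  ids <- sample_ids(table)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss)) stop("samples without metadata: ", paste(miss, collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), ]
  covars <- data.frame(
    intercept = 1,
    sex_male = as.numeric(md$sex == "male"),
    hiv_positive = as.numeric(md$hiv_status == "positive"),
    periodontitis = as.numeric(md$periodontal_status == "periodontitis"))
  if (!is.null(family_table)) {
    if (is.null(families)) stop("`families` must name the covariate families")
    bad <- setdiff(families, taxon_ids(family_table))
    if (length(bad)) stop("families absent from family_table: ",
                          paste(bad, collapse = ", "))
    fam_ra <- relative_abundance(family_table)[ids, families, drop = FALSE]
    colnames(fam_ra) <- make.names(colnames(fam_ra))
    covars <- cbind(covars, fam_ra)
  }
  y_all <- sample_depths(table)
  fits <- list()
  rows <- list()
  for (cat in DMFT_LEVELS) {
    idx <- which(as.character(md$dmft_category) == cat)
    X <- as.matrix(covars[idx, , drop = FALSE])
    # drop covariates constant within the category (they are unidentifiable)
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(x) length(unique(x)) > 1))
    X <- X[, keep, drop = FALSE]
    if (length(idx) <= ncol(X)) {
      warning("category ", cat, " has n <= p; skipped")
      next
    }
    fit <- fit_quasipoisson(y_all[idx], X)
    fits[[cat]] <- fit
    wt <- wald_table(fit)
    wt$category <- cat
    rows[[cat]] <- wt
  }
  if (length(fits) < 2) stop("need at least 2 categories with n > p")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (adjust == "BH") tab$p <- bh_fdr(tab$p)
  tab$stars <- significance_stars(tab$p)
  tab <- tab[, c("category", "term", "estimate", "se", "z", "p", "stars")]
  structure(list(fits = fits, table = tab, adjust = adjust),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d per-category quasi-Poisson fits (p adjust: %s)\n",
              length(x$fits), x$adjust))
  print(transform(x$table, estimate = round(estimate, 3), se = round(se, 3),
                  z = round(z, 2), p = signif(p, 3)))
  invisible(x)
}

#' Write a model comparison as TSV and JSON
#' @param comparison A `model_comparison`.
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @param provenance Optional named character vector of comment lines.
#' @export
write_model_comparison <- function(comparison, tsv_path = NULL,
                                   json_path = NULL, provenance = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, open = "wt")
    writeLines(provenance_lines(provenance), con)
    utils::write.table(comparison$table, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(json_path)) {
    payload <- list(
      adjust = comparison$adjust,
      dispersion = lapply(comparison$fits, `[[`, "dispersion"),
      table = comparison$table)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(comparison)
}
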