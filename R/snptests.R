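#' Back-transform breeding values to SNP effect estimates
#'
#' `g_hat = Z' G^-1 a_hat`. Because `G = Z Z'`, the reconstruction
#' `Z g_hat = a_hat` holds exactly and is a useful end-of-pipeline check.
#'
#' @param ahat Breeding-value vector (animal order of G).
#' @param G The full-genome `grm`.
#' @param Z The [standardize_markers()] result G was built from.
#' @return Named numeric vector of per-marker effects `g_hat`.
#' @export
backtransform <- function(ahat, G, Z) {
  stopifnot(inherits(G, "grm"), inherits(Z, "marker_z"))
  if (!identical(G$snp_ids, Z$snp_ids)) stop("G was not built from this Z (provenance mismatch)")
  ghat <- drop(crossprod(Z$Z, grm_solve(G, ahat)))
  stats::setNames(ghat, Z$snp_ids)
}

#' Diagonal of the SNP-effect covariance matrix
#'
#' Computes `diag(Z' G^-1 Var(a_hat) G^-1 Z)` column-by-column without ever
#' forming the m x m matrix. The factor `G^-1 Z` is computed once and can be
#' reused across traits via the cached Cholesky factor of G.
#'
#' @param Z A [standardize_markers()] result.
#' @param G The matching `grm`.
#' @param var_ahat The n x n covariance of `a_hat` from [var_ahat()].
#' @param full If `TRUE` return the full m x m matrix (guarded: refuses when
#'   m exceeds `max_m_full`).
#' @param max_m_full Size cap for the full-matrix request (default 2000).
#' @return Length-m vector of `Var(g_hat_j)` (or the full matrix).
#' @export
var_ghat_diag <- function(Z, G, var_ahat, full = FALSE, max_m_full = 2000) {
  stopifnot(inherits(Z, "marker_z"), inherits(G, "grm"))
  Ti <- grm_solve(G, Z$Z)           # G^-1 Z, n x m
  if (full) {
    if (ncol(Z$Z) > max_m_full) {
      stop("refusing to materialize a ", ncol(Z$Z), " x ", ncol(Z$Z),
           " matrix (cap ", max_m_full, "); use the diagonal")
    }
    out <- crossprod(Ti, var_ahat %*% Ti)
    dimnames(out) <- list(Z$snp_ids, Z$snp_ids)
    return((out + t(out)) / 2)
  }
  stats::setNames(colSums(Ti * (var_ahat %*% Ti)), Z$snp_ids)
}

#' Bundle SNP effect estimates with their variances
#'
#' @param ghat Effect estimates from [backtransform()].
#' @param var_ghat Diagonal variances from [var_ghat_diag()].
#' @param sigma2_g The common prior variance of a SNP effect, equal to the
#'   REML additive variance `sigma_a^2` of the animal model under the
#'   marker-model equivalence.
#' @return A list of class `snp_effects` with the derived prediction error
#'   variance `pev_ghat = sigma2_g - var_ghat`.
#' @export
snp_effects <- function(ghat, var_ghat, sigma2_g) {
  stopifnot(length(ghat) == length(var_ghat), sigma2_g >= 0)
  structure(list(ghat = ghat, var_ghat = var_ghat,
                 pev_ghat = sigma2_g - var_ghat, sigma2_g = sigma2_g),
            class = "snp_effects")
}

#' SNP_ej: effects standardized by their own estimation variance
#'
#' `SNP_ej = g_hat_j / sqrt(Var(g_hat_j))`. Markers whose estimation
#' variance is numerically degenerate (below `1e-12 * sigma2_g`) are flagged
#' untestable and returned as `NA` with a reason attribute.
#'
#' @param est A [snp_effects()] object.
#' @return Numeric vector of statistics; attribute `untestable` holds a
#'   character vector of reason codes (`""` where testable).
#' @export
snp_ej <- function(est) {
  stopifnot(inherits(est, "snp_effects"))
  floor_v <- 1e-12 * max(est$sigma2_g, .Machine$double.eps)
  bad <- est$var_ghat <= floor_v
  stat <- ifelse(bad, NA_real_, est$ghat / sqrt(est$var_ghat))
  attr(stat, "untestable") <- ifelse(bad, "degenerate_var_ghat", "")
  stat
}

#' SNP_epj: effects standardized by their prediction error variance
#'
#' `SNP_epj = g_hat_j / sqrt(sigma2_g - Var(g_hat_j))`. The denominator is
#' nearly constant across markers in practice, which makes this test over-
#' conservative; it is provided for comparison with [snp_ej()].
#'
#' @param est A [snp_effects()] object.
#' @return Numeric vector of statistics with an `untestable` attribute.
#' @export
snp_epj <- function(est) {
  stopifnot(inherits(est, "snp_effects"))
  bad <- est$pev_ghat <= 0
  stat <- ifelse(bad, NA_real_, est$ghat / sqrt(pmax(est$pev_ghat, 0)))
  attr(stat, "untestable") <- ifelse(bad, "nonpositive_pev_ghat", "")
  stat
}

#' Two-sided normal p-values for standardized statistics
#'
#' `p_j = 2 * (1 - Phi(|stat_j|))` with `Phi` the standard normal CDF.
#'
#' @param stats Numeric vector of standardized statistics.
#' @return Numeric vector of p-values in \[0, 1\] (`NA` stays `NA`).
#' @export
pvalues_normal <- function(stats) {
  2 * stats::pnorm(abs(stats), lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Nominal test size.
#' @param n_tests Number of tests corrected for.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Genome scan by back-transformation of a genomic evaluation
#'
#' Runs the full pipeline: founder allele frequencies, mean imputation,
#' VanRaden standardization, `G = Z Z'`, single-GRM REML animal model, BLUP,
#' PEV, back-transformation to per-marker effects with their exact
#' variances, and the SNP_ej / SNP_epj standardized tests with two-sided
#' normal p-values.
#'
#' @param geno A QC'd [geno_matrix()].
#' @param pheno Phenotype tibble (`sample_id`, trait, covariates).
#' @param trait Trait column name.
#' @param fixed Fixed-effects formula (default `~ 1`).
#' @param p Optional frequency vector; defaults to [founder_allele_freqs()].
#' @return A tibble of class `snp_scan` with one row per marker: `snp_id`,
#'   `chrom`, `pos_mb`, `ghat`, `var_ghat`, `pev_ghat`, `snp_ej`, `snp_epj`,
#'   `pvalue_ej`, `pvalue_epj`, `neglog10_p`, `untestable`. The fitted
#'   model, G and Z are attached as attributes (`fit`, `grm`, `Z`,
#'   `design`) for reuse by [segment_scan()].
#' @export
snp_scan <- function(geno, pheno, trait = "trait", fixed = ~1, p = NULL) {
  if (is.null(p)) p <- founder_allele_freqs(geno)
  geno <- mean_impute(geno, p)
  Z <- standardize_markers(geno, p)
  G <- ensure_invertible_grm(compute_grm(Z))
  data <- design_data(pheno, geno, trait = trait, fixed = fixed)
  fit <- reml_fit(data, G)
  a <- fit$ahat[, 1]
  pev <- pev_ahat(fit, data, G)
  va <- var_ahat(fit, G, pev = pev)
  ghat <- backtransform(a, G, Z)
  vg <- var_ghat_diag(Z, G, va)
  est <- snp_effects(ghat, vg, sigma2_g = fit$sigma2[[1]])
  ej <- snp_ej(est); epj <- snp_epj(est)
  p_ej <- pvalues_normal(ej)
  out <- tibble::tibble(
    snp_id = Z$snp_ids,
    chrom = geno$map$chrom,
    pos_mb = geno$map$pos_bp / 1e6,
    ghat = unname(ghat),
    var_ghat = unname(vg),
    pev_ghat = unname(est$pev_ghat),
    snp_ej = as.numeric(ej),
    snp_epj = as.numeric(epj),
    pvalue_ej = as.numeric(p_ej),
    pvalue_epj = as.numeric(pvalues_normal(epj)),
    neglog10_p = -log10(as.numeric(p_ej)),
    untestable = attr(ej, "untestable")
  )
  class(out) <- c("snp_scan", class(out))
  attr(out, "fit") <- fit
  attr(out, "grm") <- G
  attr(out, "Z") <- Z
  attr(out, "design") <- data
  attr(out, "geno") <- geno
  out
}

#' Write a scan result as TSV
#' @param scan A [snp_scan()] (or any tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  readr::write_tsv(tibble::as_tibble(scan), path)
  invisible(path)
}
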