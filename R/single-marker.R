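#' Single-marker mixed-model association scan (EMMA-style)
#'
#' Tests one SNP at a time as a fixed covariate in the animal model
#' `y = X beta + s_j b_j + N a + e`, `a ~ N(0, G sigma_a^2)`, with G built
#' from all markers (the tested SNP stays in G). In `p3d` mode the variance
#' components are estimated once under the null model and held fixed across
#' markers (the EMMAX / P3D shortcut); in `exact` mode the variance ratio is
#' re-optimized per marker. Both modes rotate `y`, `X` and the dosages by
#' the eigenvectors of `N G N'` once, then solve a small weighted
#' least-squares problem per marker. The Wald statistic for the SNP
#' coefficient is referred to the standard normal.
#'
#' @param data A [design_data()].
#' @param G The full-genome `grm`.
#' @param geno The complete [geno_matrix()] supplying the dosages.
#' @param mode `"p3d"` (default) or `"exact"`.
#' @return A tibble with one row per marker: `snp_id`, `chrom`, `pos_mb`,
#'   `effect`, `se`, `wald`, `pvalue`, `neglog10_p`, `untestable`.
#' @export
emma_scan <- function(data, G, geno, mode = c("p3d", "exact")) {
  mode <- match.arg(mode)
  if (anyNA(geno$dosage)) stop("dosages must be complete; run mean_impute() first")
  y <- data$y; X <- data$X
  n <- length(y); p <- ncol(X)
  K <- G$G[data$geno_idx, data$geno_idx, drop = FALSE]
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  S <- geno$dosage[data$geno_idx, , drop = FALSE]
  sd0 <- apply(S, 2, stats::sd)
  Ss <- crossprod(U, S)

  null_fit <- reml_fit(data, G)
  gamma0 <- if (null_fit$sigma2_e > 0) null_fit$sigma2[[1]] / null_fit$sigma2_e else Inf

  gls_one <- function(j, gamma, s2e = NULL) {
    w <- 1 / (gamma * d + 1)
    D <- cbind(Xs, Ss[, j])
    DtWD <- crossprod(D, D * w)
    R <- tryCatch(chol(DtWD), error = function(e) NULL)
    if (is.null(R)) return(c(NA, NA))
    Ci <- chol2inv(R)
    b <- Ci %*% crossprod(D, ys * w)
    if (is.null(s2e)) {
      # profile residual variance under the marker model (exact mode)
      resid <- ys - D %*% b
      s2e <- sum(resid^2 * w) / (n - p - 1)
    }
    se <- sqrt(s2e * Ci[p + 1, p + 1])
    c(b[p + 1], se)
  }

  est <- matrix(NA_real_, ncol(S), 2)
  for (j in seq_len(ncol(S))) {
    if (is.na(sd0[j]) || sd0[j] == 0) next
    if (mode == "p3d") {
      # V known up to sigma_e^2: V = sigma_e^2 (gamma K + I)
      est[j, ] <- gls_one(j, gamma0, s2e = null_fit$sigma2_e)
    } else {
      prof <- function(lg) {
        g <- exp(lg)
        w <- 1 / (g * d + 1)
        D <- cbind(Xs, Ss[, j])
        DtWD <- crossprod(D, D * w)
        R <- tryCatch(chol(DtWD), error = function(e) NULL)
        if (is.null(R)) return(-1e10)
        b <- chol2inv(R) %*% crossprod(D, ys * w)
        Q <- sum(ys^2 * w) - sum(crossprod(D, ys * w) * b)
        s2e <- Q / (n - p - 1)
        -0.5 * ((n - p - 1) * (log(s2e) + 1 + log(2 * pi)) +
                  sum(log(g * d + 1)) + 2 * sum(log(diag(R))))
      }
      opt <- stats::optimize(prof, c(log(1e-8), log(1e8)), maximum = TRUE)
      est[j, ] <- gls_one(j, exp(opt$maximum))
    }
  }
  wald <- est[, 1] / est[, 2]
  pv <- pvalues_normal(wald)
  tibble::tibble(
    snp_id = geno$map$snp_id,
    chrom = geno$map$chrom,
    pos_mb = geno$map$pos_bp / 1e6,
    effect = est[, 1], se = est[, 2], wald = wald,
    pvalue = pv, neglog10_p = -log10(pv),
    untestable = unname(ifelse(is.na(sd0) | sd0 == 0, "constant_dosage",
                               ifelse(is.na(wald), "singular_design", "")))
  )
}
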