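#' Row-shuffle a genotype block (LD-preserving)
#'
#' Applies one sample permutation jointly to every marker column of the
#' block, preserving allele frequencies and all within-block LD exactly
#' while breaking the genotype-phenotype link for those markers.
#'
#' @param geno A [geno_matrix()].
#' @param block Character vector of marker ids to shuffle.
#' @param perm Optional explicit permutation of `seq_len(n)`; drawn from the
#'   current RNG state when missing.
#' @return The permuted [geno_matrix()].
#' @export
permute_block_rows <- function(geno, block, perm = NULL) {
  if (!length(block)) stop("empty block")
  j <- match(block, colnames(geno$dosage))
  if (anyNA(j)) stop("block markers absent: ", paste(block[is.na(j)], collapse = ", "))
  n <- nrow(geno$dosage)
  if (is.null(perm)) perm <- sample.int(n)
  geno$dosage[, j] <- geno$dosage[perm, j, drop = FALSE]
  geno
}

#' Column-wise shuffle of a genotype block (LD-breaking)
#'
#' Permutes the samples independently for each marker column of the block,
#' preserving per-marker allele frequencies exactly but driving the
#' between-marker correlations toward zero (linkage equilibrium).
#'
#' @inheritParams permute_block_rows
#' @return The permuted [geno_matrix()].
#' @export
permute_block_columns <- function(geno, block) {
  if (!length(block)) stop("empty block")
  j <- match(block, colnames(geno$dosage))
  if (anyNA(j)) stop("block markers absent: ", paste(block[is.na(j)], collapse = ", "))
  n <- nrow(geno$dosage)
  for (col in j) geno$dosage[, col] <- geno$dosage[sample.int(n), col]
  geno
}

#' Plasmode configuration
#'
#' @param target_chromosome Chromosome whose markers are shuffled.
#' @param scenario `"LD_rows"` (joint row shuffle, LD kept) or
#'   `"LE_columns"` (independent per-marker shuffle, LE).
#' @param n_reps Number of permutation replicates (default 200).
#' @param alpha Type-I-error levels to tabulate.
#' @param seed RNG seed; per-replicate sub-seeds are drawn once from it so
#'   each replicate is individually reproducible.
#' @return A list of class `plasmode_config`.
#' @export
plasmode_config <- function(target_chromosome, scenario = c("LD_rows", "LE_columns"),
                            n_reps = 200, alpha = c(0.05, 0.01), seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_reps >= 1)
  structure(list(target_chromosome = as.character(target_chromosome),
                 scenario = scenario, n_reps = n_reps, alpha = alpha,
                 seed = seed),
            class = "plasmode_config")
}

#' Permutation (plasmode) study of the tests' type-I error
#'
#' Repeats `n_reps` times: shuffle the target chromosome's genotype block
#' (phenotypes are never touched), recompute founder frequencies and the
#' full G from the permuted matrix, refit the single-GRM animal model by
#' REML, back-transform, and collect the SNP_ej and SNP_epj p-values of the
#' block markers, which are now known nulls. Aggregates empirical type-I
#' error at each `alpha` and a QQ table whose envelope comes from the same
#' number of uniform U(0, 1) reference replicates.
#'
#' @param geno A complete, QC'd [geno_matrix()].
#' @param pheno Phenotype tibble.
#' @param config A [plasmode_config()].
#' @param trait,fixed Passed to [design_data()].
#' @return A list of class `plasmode_result`: `pvalues` (named list of
#'   n_reps x n_block matrices for `ej` and `epj`), `type1` tibble
#'   (statistic, alpha, size, binomial CI), `qq` tibble (rank, expected,
#'   observed per statistic, envelope), `h2` per replicate, `config`.
#' @export
run_plasmode <- function(geno, pheno, config, trait = "trait", fixed = ~1) {
  stopifnot(inherits(config, "plasmode_config"))
  block <- geno$map$snp_id[geno$map$chrom == config$target_chromosome]
  if (!length(block)) stop("target chromosome not in map: ", config$target_chromosome)
  set.seed(config$seed)
  rep_seeds <- sample.int(2^31 - 2, config$n_reps)
  env_seed <- sample.int(2^31 - 2, 1)
  nb <- length(block)

  one_rep <- function(r) {
    set.seed(rep_seeds[r])
    g <- if (config$scenario == "LD_rows") permute_block_rows(geno, block)
         else permute_block_columns(geno, block)
    p <- founder_allele_freqs(g)
    # a shuffle can leave a block marker monomorphic among the founder rows;
    # such markers would fall to QC in a fresh analysis, so drop them from
    # this replicate and report NA for their p-values
    poly <- p > 0 & p < 1
    if (!all(poly)) g <- g[, which(poly)]
    p <- p[poly]
    g <- mean_impute(g, p)
    Z <- standardize_markers(g, p)
    G <- suppressMessages(ensure_invertible_grm(compute_grm(Z)))
    data <- design_data(pheno, g, trait = trait, fixed = fixed)
    fit <- reml_fit(data, G)
    a <- fit$ahat[, 1]
    pev <- pev_ahat(fit, data, G)
    va <- var_ahat(fit, G, pev = pev)
    # only the block columns are needed
    jb <- match(block, Z$snp_ids)
    keep <- !is.na(jb)
    Zb <- Z$Z[, jb[keep], drop = FALSE]
    Gi_a <- grm_solve(G, a)
    ghat_b <- drop(crossprod(Zb, Gi_a))
    Ti <- grm_solve(G, Zb)
    vg_b <- colSums(Ti * (va %*% Ti))
    s2g <- fit$sigma2[[1]]
    est <- snp_effects(ghat_b, vg_b, s2g)
    p_ej <- p_epj <- rep(NA_real_, length(block))
    p_ej[keep] <- pvalues_normal(snp_ej(est))
    p_epj[keep] <- pvalues_normal(snp_epj(est))
    list(p_ej = p_ej, p_epj = p_epj, h2 = s2g / (s2g + fit$sigma2_e))
  }

  reps <- vector("list", config$n_reps)
  failed <- 0L
  for (r in seq_len(config$n_reps)) {
    reps[r] <- list(tryCatch(one_rep(r), error = function(e) {
      message("plasmode replicate ", r, " failed: ", conditionMessage(e))
      NULL
    }))
    if (is.null(reps[[r]])) failed <- failed + 1L
  }
  if (failed > 0.1 * config$n_reps) {
    stop(failed, " of ", config$n_reps, " plasmode replicates failed")
  }
  reps <- reps[!vapply(reps, is.null, TRUE)]
  P_ej <- do.call(rbind, lapply(reps, `[[`, "p_ej"))
  P_epj <- do.call(rbind, lapply(reps, `[[`, "p_epj"))
  h2 <- vapply(reps, `[[`, 0, "h2")

  type1 <- dplyr::bind_rows(lapply(c("ej", "epj"), function(st) {
    P <- if (st == "ej") P_ej else P_epj
    n_tot <- sum(!is.na(P))
    dplyr::bind_rows(lapply(config$alpha, function(a) {
      k <- sum(P < a, na.rm = TRUE)
      ci <- stats::qbinom(c(0.025, 0.975), n_tot, a) / n_tot
      tibble::tibble(statistic = st, alpha = a, n_tests = n_tot,
                     size = k / n_tot, ci_lower = ci[1], ci_upper = ci[2])
    }))
  }))

  # QQ table: order statistics of -log10 p averaged over replicates;
  # envelope from uniform reference replicates of the same shape
  set.seed(env_seed)
  n_rep_eff <- nrow(P_ej)
  Uref <- matrix(stats::runif(n_rep_eff * nb), n_rep_eff, nb)
  # fixed-length order statistics via quantiles, robust to per-replicate NAs
  sort_rows <- function(P) {
    probs <- (seq_len(nb) - 0.5) / nb
    t(apply(-log10(P), 1, stats::quantile, probs = rev(probs), na.rm = TRUE,
            names = FALSE))
  }
  Sej <- sort_rows(P_ej); Sepj <- sort_rows(P_epj); Su <- sort_rows(Uref)
  qq <- tibble::tibble(
    rank = seq_len(nb),
    expected = colMeans(Su),
    observed_ej = colMeans(Sej),
    observed_epj = colMeans(Sepj),
    envelope_lower = apply(Su, 2, stats::quantile, 0.025),
    envelope_upper = apply(Su, 2, stats::quantile, 0.975))

  structure(list(pvalues = list(ej = P_ej, epj = P_epj), type1 = type1,
                 qq = qq, h2 = h2, n_failed = failed, block = block,
                 config = config),
            class = "plasmode_result")
}

#' @export
print.plasmode_result <- function(x, ...) {
  cat(sprintf("<plasmode_result> %s on chromosome %s: %d replicates x %d null SNPs\n",
              x$config$scenario, x$config$target_chromosome,
              nrow(x$pvalues$ej), length(x$block)))
  print(x$type1)
  invisible(x)
}
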