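# shared fixtures and test-local oracles, all generated in code

# deterministic random genotype matrix: first `n_founders` samples founders
rand_geno <- function(n = 30, m = 40, seed = 1, n_founders = 8, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- stats::runif(m, 0.15, 0.85)
  d <- matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), n, m)
  map <- tibble::tibble(snp_id = sprintf("s%03d", seq_len(m)),
                        chrom = rep(c("1", "2"), length.out = m) |> sort(),
                        pos_bp = rep(seq_len(ceiling(m / 2)) * 5e5, 2)[seq_len(m)])
  samples <- tibble::tibble(sample_id = sprintf("a%03d", seq_len(n)),
                            founder = seq_len(n) <= n_founders,
                            sex = rep(c("M", "F"), length.out = n))
  geno_matrix(d, map, samples)
}

# drop markers monomorphic in founders so standardization is always legal
polymorphic_geno <- function(geno) {
  p <- founder_allele_freqs(geno)
  keep <- p > 0 & p < 1
  list(geno = geno[, which(keep)], p = p[keep])
}

# simulated phenotype with a handful of marker effects over a toy matrix
toy_study <- function(n = 40, m = 60, seed = 2, h2ish = 0.5) {
  g <- polymorphic_geno(rand_geno(n, m, seed = seed))
  Z <- standardize_markers(g$geno, g$p)
  set.seed(seed + 1000)
  eff <- stats::rnorm(ncol(Z$Z))
  tbv <- drop(Z$Z %*% eff)
  e <- stats::rnorm(n, 0, stats::sd(tbv) * sqrt((1 - h2ish) / h2ish))
  pheno <- tibble::tibble(sample_id = g$geno$samples$sample_id,
                          sex = g$geno$samples$sex,
                          trait = 7 + (g$geno$samples$sex == "M") + tbv + e)
  G <- ensure_invertible_grm(compute_grm(Z))
  data <- design_data(pheno, g$geno, fixed = ~sex)
  list(geno = g$geno, p = g$p, Z = Z, G = G, pheno = pheno, data = data)
}

# memoised medium-scale simulated study (n_f2 = 300, m = 800) shared by the
# equivalence / cross-method tests
.fixture_env <- new.env(parent = emptyenv())

medium_scan <- function() {
  if (!is.null(.fixture_env$medium)) return(.fixture_env$medium)
  cfg <- sim_config(n_f2 = 300)
  sim <- simulate_f2(cfg, seed = 7)
  qc <- qc_filter(sim$geno)
  scan <- suppressMessages(snp_scan(qc$geno, sim$pheno, fixed = ~sex))
  .fixture_env$medium <- list(sim = sim, geno = qc$geno, scan = scan)
  .fixture_env$medium
}

# independent oracle: the marker-effects (ridge) model fitted directly by its
# mixed-model equations at given variance components
#   [X'X  X'W ] [beta]   [X'y]
#   [W'X  W'W + I lambda] [g  ] = [W'y]
# with W = N Z and lambda = sigma_e^2 / sigma_g^2; returns solutions and the
# covariance diagonal Var(g_hat) = sigma_g^2 - C^gg sigma_e^2
ridge_2b_oracle <- function(data, Z, sigma2_g, sigma2_e) {
  X <- data$X
  W <- data$N %*% Z$Z
  lambda <- sigma2_e / sigma2_g
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + diag(lambda, ncol(W))))
  rhs <- c(crossprod(X, data$y), crossprod(W, data$y))
  Cinv <- chol2inv(chol(C))
  sol <- drop(Cinv %*% rhs)
  px <- ncol(X)
  list(beta = sol[seq_len(px)], ghat = sol[-seq_len(px)],
       var_ghat = sigma2_g - diag(Cinv)[-seq_len(px)] * sigma2_e,
       Cinv = Cinv)
}
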