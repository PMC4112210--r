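test_that("with G = I and no genetic signal, REML hits the boundary and beta is OLS", {
  set.seed(51)
  n <- 60
  d <- matrix(rbinom(n * 5, 2, 0.5), n, 5)
  g <- geno_matrix(d, tibble::tibble(snp_id = paste0("s", 1:5), chrom = "1",
                                     pos_bp = 1:5),
                   tibble::tibble(sample_id = paste0("a", 1:n),
                                  sex = rep(c("M", "F"), n / 2)))
  G <- structure(list(G = diag(1, n), snp_ids = paste0("s", 1:5),
                      p = rep(0.5, 5), m_divisor = 5, epsilon = 0,
                      cache = new.env()), class = "grm")
  rownames(G$G) <- colnames(G$G) <- g$samples$sample_id
  pheno <- tibble::tibble(sample_id = g$samples$sample_id, sex = g$samples$sex,
                          trait = 3 + (g$samples$sex == "M") * 0.5 + rnorm(n))
  data <- design_data(pheno, g, fixed = ~sex)
  fit <- reml_fit(data, G)
  # sigma_a^2 boundary: with G = I the two components are confounded, so the
  # genetic share should be small and beta must match weighted OLS closely
  ols <- lm(trait ~ sex, data = pheno)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-4)
})

test_that("BLUP matches a hand-built MME solve on a small toy", {
  st <- toy_study(n = 20, m = 15, seed = 52)
  fit <- reml_fit(st$data, st$G)
  # independent route: Henderson's equations at the fitted components
  X <- st$data$X; N <- st$data$N
  lambda <- fit$sigma2_e / fit$sigma2[[1]]
  Ginv <- solve(st$G$G)
  C <- rbind(cbind(crossprod(X), crossprod(X, N)),
             cbind(crossprod(N, X), crossprod(N) + Ginv * lambda))
  sol <- solve(C, c(crossprod(X, st$data$y), crossprod(N, st$data$y)))
  expect_equal(unname(fit$beta), unname(sol[1:ncol(X)]), tolerance = 1e-6)
  expect_equal(unname(fit$ahat[, 1]), unname(sol[-(1:ncol(X))]), tolerance = 1e-5)
})

test_that("BLUPs are orthogonal to the fixed effects (zero weighted mean)", {
  st <- toy_study(n = 30, m = 25, seed = 53)
  fit <- reml_fit(st$data, st$G)
  # residuals y - Xb - Na are V-orthogonal to X; for X containing an
  # intercept the record-weighted BLUPs carry no systematic offset
  r <- st$data$y - st$data$X %*% fit$beta - st$data$N %*% fit$ahat[, 1]
  expect_lt(abs(mean(r)) / sd(st$data$y), 0.02)
})

test_that("zero-residual direction gives zero BLUPs", {
  st <- toy_study(n = 15, m = 10, seed = 54)
  data <- st$data
  data$y <- drop(data$X %*% c(2, 0.5))  # y exactly in the X column space
  fit <- suppressWarnings(reml_fit(data, st$G))
  expect_lt(max(abs(fit$ahat)), 1e-6)
})

test_that("PEV from the MME equals the V-projection route", {
  st <- toy_study(n = 22, m = 18, seed = 55)
  fit <- reml_fit(st$data, st$G)
  pev_mme <- pev_ahat(fit, st$data, st$G, route = "mme")
  pev_v <- pev_ahat(fit, st$data, st$G, route = "vproj")
  expect_equal(pev_mme, pev_v, tolerance = 1e-6)
})

test_that("PEV shrinks when an animal gains a record and equals the prior without data", {
  st <- toy_study(n = 12, m = 10, seed = 56)
  fit <- reml_fit(st$data, st$G)
  # drop animal 1's record: its PEV must grow
  pheno_red <- st$pheno[-1, ]
  data_red <- design_data(pheno_red, st$geno, fixed = ~sex)
  pev_full <- pev_ahat(fit, st$data, st$G)
  pev_red <- pev_ahat(fit, data_red, st$G)
  expect_gt(pev_red[1, 1], pev_full[1, 1])
  # no data at all: PEV equals the prior variance G sigma_a^2
  data_none <- st$data
  data_none$N <- matrix(0, 0, ncol(st$data$N))
  data_none$X <- matrix(0, 0, ncol(st$data$X))
  data_none$y <- numeric(0)
  data_none$geno_idx <- integer(0)
  pev_none <- pev_ahat(fit, data_none, st$G)
  expect_equal(pev_none, st$G$G * fit$sigma2[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("Var(a_hat) equals the projection-matrix covariance and respects bounds", {
  st <- toy_study(n = 18, m = 14, seed = 57)
  fit <- reml_fit(st$data, st$G)
  pev <- pev_ahat(fit, st$data, st$G)
  va <- var_ahat(fit, st$G, pev = pev)
  # brute-force covariance: sigma_a^4 G N' P N G
  V <- fit$sigma2[[1]] * st$G$G[st$data$geno_idx, st$data$geno_idx] +
    diag(fit$sigma2_e, length(st$data$y))
  Vi <- solve(V)
  ViX <- Vi %*% st$data$X
  P <- Vi - ViX %*% solve(crossprod(st$data$X, ViX)) %*% t(ViX)
  GNt <- st$G$G[, st$data$geno_idx]
  va_brute <- fit$sigma2[[1]]^2 * GNt %*% P %*% t(GNt)
  expect_equal(va, (va_brute + t(va_brute)) / 2, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lte(sum(diag(va)), sum(diag(st$G$G)) * fit$sigma2[[1]] + 1e-8)
})

test_that("restricted likelihood is translation invariant and nested-monotone", {
  st <- toy_study(n = 25, m = 20, seed = 58)
  fit <- reml_fit(st$data, st$G)
  data2 <- st$data
  data2$y <- st$data$y + 100
  fit2 <- reml_fit(data2, st$G)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
  # scale equivariance: y * c multiplies both components by c^2
  data3 <- st$data
  data3$y <- st$data$y * 3
  fit3 <- reml_fit(data3, st$G)
  expect_equal(fit3$sigma2[[1]], 9 * fit$sigma2[[1]], tolerance = 1e-4)
  expect_equal(fit3$sigma2_e, 9 * fit$sigma2_e, tolerance = 1e-4)
})

test_that("single-GRM eigen path and generic optimizer agree", {
  st <- toy_study(n = 30, m = 40, seed = 59)
  fit_fast <- reml_fit(st$data, st$G)
  fit_gen <- blupscan:::reml_multi(st$data, list(st$G), tol = 1e-10)
  expect_equal(fit_fast$loglik, fit_gen$loglik, tolerance = 1e-6)
  expect_equal(fit_fast$sigma2[[1]], fit_gen$sigma2[[1]], tolerance = 1e-3)
})

test_that("animal model and marker model are equivalent (2a vs 2b)", {
  st <- toy_study(n = 26, m = 30, seed = 60)
  fit <- reml_fit(st$data, st$G)
  orc <- ridge_2b_oracle(st$data, st$Z, fit$sigma2[[1]], fit$sigma2_e)
  expect_equal(unname(fit$beta), orc$beta, tolerance = 1e-6)
  # a_hat = Z g_ridge and identical fitted values
  expect_equal(unname(fit$ahat[, 1]), unname(drop(st$Z$Z %*% orc$ghat)),
               tolerance = 1e-6)
  yhat_2a <- st$data$X %*% fit$beta + st$data$N %*% fit$ahat[, 1]
  yhat_2b <- st$data$X %*% orc$beta + st$data$N %*% st$Z$Z %*% orc$ghat
  expect_equal(drop(yhat_2a), drop(yhat_2b), tolerance = 1e-6)
})

test_that("REML recovers the simulated heritability on average", {
  h2 <- sapply(1:6, function(s) {
    sim <- simulate_f2(sim_config(
      n_f2 = 120,
      chromosomes = tibble::tibble(name = c("1", "2"), length_mb = c(60, 60),
                                   n_markers = c(150, 150))), seed = s)
    qc <- qc_filter(sim$geno)
    p <- founder_allele_freqs(qc$geno)
    geno <- mean_impute(qc$geno, p)
    Z <- standardize_markers(geno, p)
    G <- suppressMessages(ensure_invertible_grm(compute_grm(Z)))
    data <- design_data(sim$pheno, geno, fixed = ~sex)
    glance(reml_fit(data, G))$h2
  })
  expect_equal(mean(h2), 0.42, tolerance = 0.12)
})

test_that("tidy and glance expose components, fixed effects and fit summary", {
  st <- toy_study(n = 20, m = 15, seed = 61)
  fit <- reml_fit(st$data, st$G)
  td <- tidy(fit)
  expect_setequal(td$term[td$type == "variance"], c("sigma2_a", "sigma2_e"))
  expect_true(all(c("(Intercept)", "sexM") %in% td$term[td$type == "fixed"]))
  gl <- glance(fit)
  expect_true(gl$h2 >= 0 && gl$h2 <= 1)
  expect_identical(gl$logLik, restricted_loglik(fit))
})
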