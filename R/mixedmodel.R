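#' Assemble design data for the animal model
#'
#' Builds the phenotype vector `y`, fixed-effects incidence `X` (from a
#' formula evaluated on the phenotype table) and the record-to-animal
#' incidence `N` linking each record to its genotyped animal. Animals present
#' in the genotypes but absent from the phenotype table carry no record (no
#' row of N) and are predicted through relationships only.
#'
#' @param pheno Tibble with `sample_id`, the trait column and any covariates.
#' @param geno A [geno_matrix()] (defines the animal order of `N` and G).
#' @param trait Name of the trait column in `pheno`.
#' @param fixed One-sided formula for the fixed effects (default `~ 1`).
#' @return An object of class `design_data` with `y`, `X`, `N`, `geno_idx`,
#'   `sample_id` (record order) and `animal_id` (genotype order).
#' @export
design_data <- function(pheno, geno, trait = "trait", fixed = ~1) {
  pheno <- tibble::as_tibble(pheno)
  stopifnot(trait %in% names(pheno), "sample_id" %in% names(pheno))
  pheno <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  animal_id <- geno$samples$sample_id
  idx <- match(pheno$sample_id, animal_id)
  if (anyNA(idx)) {
    stop("phenotyped samples without genotypes: ",
         paste(pheno$sample_id[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
  }
  X <- stats::model.matrix(fixed, data = pheno)
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design X is rank deficient")
  n_obs <- nrow(pheno)
  N <- matrix(0, n_obs, length(animal_id))
  N[cbind(seq_len(n_obs), idx)] <- 1
  structure(list(y = as.numeric(pheno[[trait]]), X = X, N = N, geno_idx = idx,
                 sample_id = pheno$sample_id, animal_id = animal_id),
            class = "design_data")
}

#' @export
print.design_data <- function(x, ...) {
  cat(sprintf("<design_data> %d records, %d fixed effects, %d animals in G\n",
              length(x$y), ncol(x$X), length(x$animal_id)))
  invisible(x)
}

# exact restricted log-likelihood for given V (obs scale), includes the
# -(n-p)/2 log(2*pi) constant so nested fits are comparable
reml_loglik_V <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  R <- chol(V)
  logdetV <- 2 * sum(log(diag(R)))
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  Rx <- chol(XtViX)
  logdetX <- 2 * sum(log(diag(Rx)))
  beta <- backsolve(Rx, backsolve(Rx, crossprod(Vi_X, y), transpose = TRUE))
  yPy <- sum(y * Vi_y) - sum(crossprod(X, Vi_y) * beta)
  list(loglik = -0.5 * (logdetV + logdetX + yPy + (n - p) * log(2 * pi)),
       beta = drop(beta))
}

# single-GRM REML profiled over the ratio gamma = sigma_a^2 / sigma_e^2,
# using the eigendecomposition of K = N G N'
reml_single <- function(data, G, tol = 1e-8) {
  y <- data$y; X <- data$X
  n <- length(y); p <- ncol(X)
  K <- G$G[data$geno_idx, data$geno_idx, drop = FALSE]
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)

  profile <- function(gamma) {
    w <- 1 / (gamma * d + 1)
    XtWX <- crossprod(Xs, Xs * w)
    Rx <- chol(XtWX)
    bhat <- backsolve(Rx, backsolve(Rx, crossprod(Xs, ys * w), transpose = TRUE))
    Q <- sum(ys^2 * w) - sum(crossprod(Xs, ys * w) * bhat)
    s2e <- Q / (n - p)
    ll <- -0.5 * ((n - p) * (log(s2e) + 1 + log(2 * pi)) +
                    sum(log(gamma * d + 1)) + 2 * sum(log(diag(Rx))))
    list(loglik = ll, s2e = s2e, beta = drop(bhat))
  }

  lo <- log(1e-8); hi <- log(1e8)
  opt <- stats::optimize(function(lg) profile(exp(lg))$loglik, c(lo, hi),
                         maximum = TRUE, tol = tol)
  cand <- list(c(gamma = exp(opt$maximum), ll = opt$objective),
               c(gamma = 0, ll = profile(0)$loglik))
  best <- cand[[which.max(vapply(cand, `[[`, 0, "ll"))]]
  gamma <- unname(best["gamma"])
  at_bound <- abs(opt$maximum - hi) < 1e-3
  prof <- profile(gamma)
  s2e <- prof$s2e
  s2a <- gamma * s2e
  list(sigma2 = c(sigma2_a = s2a), sigma2_e = s2e, beta = prof$beta,
       loglik = prof$loglik, converged = !at_bound, n_iter = NA_integer_,
       method = "eigen", eigen = list(U = eg$vectors, d = d))
}

# multi-GRM REML by L-BFGS-B on log variance components with analytic
# gradient -0.5 * (tr(P K_k) - y' P K_k P y)
reml_multi <- function(data, grms, init = NULL, tol = 1e-8, max_iter = 200) {
  y <- data$y; X <- data$X
  n <- length(y); p <- ncol(X)
  Ks <- lapply(grms, function(G) {
    K <- G$G[data$geno_idx, data$geno_idx, drop = FALSE]
    (K + t(K)) / 2
  })
  Ks <- c(Ks, list(diag(1, n)))
  k <- length(Ks)
  vy <- stats::var(y)
  floor_vc <- 1e-10 * vy

  eval_at <- function(theta) {
    V <- matrix(0, n, n)
    for (j in seq_len(k)) V <- V + theta[j] * Ks[[j]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    Rx <- chol(XtViX)
    W <- chol2inv(Rx)
    P <- Vi - ViX %*% W %*% t(ViX)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
    gr <- vapply(seq_len(k), function(j) {
      -0.5 * (sum(P * Ks[[j]]) - sum(Py * (Ks[[j]] %*% Py)))
    }, 0)
    beta <- W %*% crossprod(ViX, y)
    list(loglik = ll, grad = gr, beta = drop(beta))
  }

  if (is.null(init)) {
    one <- reml_single(data, structure(list(
      G = Reduce(`+`, lapply(grms, function(g) g$G)),
      cache = new.env(parent = emptyenv())), class = "grm"), tol = tol)
    s2a <- max(one$sigma2[["sigma2_a"]], 10 * floor_vc)
    w <- rep(1 / (k - 1), k - 1)
    if (k == 3) w <- c(0.1, 0.9)
    init <- c(s2a * w, max(one$sigma2_e, 10 * floor_vc))
  }
  init <- pmax(init, 10 * floor_vc)

  fn <- function(lth) {
    ev <- eval_at(exp(lth))
    if (is.null(ev)) return(1e10)
    -ev$loglik
  }
  gr <- function(lth) {
    ev <- eval_at(exp(lth))
    if (is.null(ev)) return(rep(0, k))
    -ev$grad * exp(lth)
  }
  opt <- stats::optim(log(init), fn, gr, method = "L-BFGS-B",
                      lower = log(floor_vc), upper = log(1e6 * vy),
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  theta <- exp(opt$par)
  ev <- eval_at(theta)
  converged <- opt$convergence == 0
  nm <- if (k == 3) c("sigma2_a1", "sigma2_a2") else paste0("sigma2_a", seq_len(k - 1))
  if (k == 2) nm <- "sigma2_a"
  # components at the floor are boundary estimates; report them as 0
  theta[theta <= 2 * floor_vc] <- 0
  list(sigma2 = stats::setNames(theta[seq_len(k - 1)], nm), sigma2_e = theta[k],
       beta = ev$beta, loglik = ev$loglik, converged = converged,
       n_iter = opt$counts[["function"]], method = "lbfgs", eigen = NULL)
}

#' REML fit of the centred animal model
#'
#' Fits `y = X beta + sum_k N a_k + e` with `a_k ~ N(0, G_k sigma_k^2)` and
#' `e ~ N(0, I sigma_e^2)` by restricted maximum likelihood. With a single
#' GRM the problem is reduced to a one-dimensional profile likelihood in the
#' variance ratio via the eigendecomposition of `N G N'`; with two or more
#' GRMs a bounded quasi-Newton search on log variance components (analytic
#' gradient) is used, initialized from the single-GRM fit unless `init` is
#' given. The reported restricted log-likelihood includes the
#' `-(n-p)/2 log(2 pi)` constant, so values are comparable across nested
#' fits within a run.
#'
#' @param data A [design_data()].
#' @param grms A single `grm` or a list of `grm` objects.
#' @param init Optional numeric vector of starting variance components
#'   (`c(sigma2_a..., sigma2_e)`), multi-GRM fits only.
#' @param tol Convergence tolerance.
#' @param max_iter Iteration cap for the multi-GRM optimizer.
#' @return An object of class `reml_fit` with variance components, fixed
#'   effects `beta`, BLUPs `ahat` (one column per random term plus their
#'   sum when there are several), the restricted log-likelihood, and
#'   convergence information.
#' @export
reml_fit <- function(data, grms, init = NULL, tol = 1e-8, max_iter = 200) {
  stopifnot(inherits(data, "design_data"))
  if (inherits(grms, "grm")) grms <- list(grms)
  if (length(data$y) < ncol(data$X) + 2) stop("too few observations for REML")
  res <- if (length(grms) == 1) reml_single(data, grms[[1]], tol = tol)
         else reml_multi(data, grms, init = init, tol = tol, max_iter = max_iter)
  if (!res$converged) warning("REML did not converge; treat estimates with caution")
  fit <- structure(c(res, list(n_obs = length(data$y), p = ncol(data$X),
                               n_grm = length(grms))),
                   class = "reml_fit")
  fit$ahat <- blup(fit, data, grms)
  names(fit$beta) <- colnames(data$X)
  fit
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("<reml_fit>", x$method, "| logLik =", format(x$loglik, digits = 8),
      if (!x$converged) "(NOT converged)", "\n")
  print(round(c(x$sigma2, sigma2_e = x$sigma2_e), 6))
  invisible(x)
}

# V on the observation scale for a fit
obs_V <- function(fit, data, grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  n <- length(data$y)
  V <- diag(fit$sigma2_e, n)
  for (j in seq_along(grms)) {
    K <- grms[[j]]$G[data$geno_idx, data$geno_idx, drop = FALSE]
    V <- V + fit$sigma2[j] * (K + t(K)) / 2
  }
  V
}

#' BLUP of the random effects
#'
#' `a_hat_k = sigma_k^2 G_k N' V^-1 (y - X beta_hat)`, evaluated at the REML
#' estimates. Genotyped animals without records are predicted through their
#' relationships.
#'
#' @param fit A [reml_fit()].
#' @param data The [design_data()] used for the fit.
#' @param grms The GRM (or list of GRMs) used for the fit.
#' @return A matrix with one column per random term (named as in
#'   `fit$sigma2`) plus a `total` column when there are several; row names
#'   are animal ids.
#' @export
blup <- function(fit, data, grms) {
  if (inherits(grms, "grm")) grms <- list(grms)
  V <- obs_V(fit, data, grms)
  R <- chol(V)
  Vi_r <- backsolve(R, backsolve(R, data$y - data$X %*% fit$beta, transpose = TRUE))
  acc <- rep(0, length(data$animal_id))
  tNv <- acc
  for (i in seq_along(Vi_r)) tNv[data$geno_idx[i]] <- tNv[data$geno_idx[i]] + Vi_r[i]
  out <- vapply(seq_along(grms), function(j) {
    drop(fit$sigma2[j] * (grms[[j]]$G %*% tNv))
  }, numeric(length(tNv)))
  colnames(out) <- names(fit$sigma2)
  rownames(out) <- data$animal_id
  if (ncol(out) > 1) out <- cbind(out, total = rowSums(out))
  out
}

#' Prediction error variance of the breeding values
#'
#' For the single-GRM animal model, `PEV(a_hat) = C_aa * sigma_e^2` where
#' `C_aa` is the random-effect block of the inverse mixed-model-equations
#' coefficient matrix `[[X'X, X'N], [N'X, N'N + G^-1 lambda]]`,
#' `lambda = sigma_e^2 / sigma_a^2`. An equivalent V-space route
#' (`G sigma_a^2 - sigma_a^4 G N' P N G`) is available for cross-checking.
#'
#' @param fit A single-GRM [reml_fit()].
#' @param data The [design_data()] used.
#' @param grm The `grm` used.
#' @param route `"mme"` (default) or `"vproj"`.
#' @return The n_animal x n_animal PEV matrix.
#' @export
pev_ahat <- function(fit, data, grm, route = c("mme", "vproj")) {
  route <- match.arg(route)
  stopifnot(fit$n_grm == 1)
  s2a <- fit$sigma2[[1]]; s2e <- fit$sigma2_e
  if (s2a <= 0) return(0 * grm$G)
  if (length(data$y) == 0) return(grm$G * s2a)  # no records: prior variance
  if (route == "mme") {
    lambda <- s2e / s2a
    X <- data$X; N <- data$N
    Ginv <- grm_solve(grm, diag(1, nrow(grm$G)))
    C <- rbind(cbind(crossprod(X), crossprod(X, N)),
               cbind(crossprod(N, X), crossprod(N) + Ginv * lambda))
    Cinv <- tryCatch(chol2inv(chol(C)), error = function(e)
      stop("MME coefficient matrix is singular; regularize the GRM"))
    ii <- ncol(X) + seq_len(nrow(grm$G))
    pev <- Cinv[ii, ii, drop = FALSE] * s2e
  } else {
    V <- obs_V(fit, data, list(grm))
    R <- chol(V)
    Vi <- chol2inv(R)
    ViX <- Vi %*% data$X
    P <- Vi - ViX %*% chol2inv(chol(crossprod(data$X, ViX))) %*% t(ViX)
    GNt <- grm$G[, data$geno_idx, drop = FALSE]
    pev <- grm$G * s2a - s2a^2 * GNt %*% P %*% t(GNt)
  }
  dimnames(pev) <- dimnames(grm$G)
  (pev + t(pev)) / 2
}

#' Variance of the estimated breeding values
#'
#' `Var(a_hat) = G sigma_a^2 - PEV`.
#'
#' @param fit A single-GRM [reml_fit()].
#' @param grm The `grm` used for the fit.
#' @param pev Optional precomputed [pev_ahat()] matrix.
#' @param data Required if `pev` is missing.
#' @return The n x n covariance matrix of `a_hat`.
#' @export
var_ahat <- function(fit, grm, pev = NULL, data = NULL) {
  if (is.null(pev)) {
    if (is.null(data)) stop("supply either pev or data")
    pev <- pev_ahat(fit, data, grm)
  }
  va <- grm$G * fit$sigma2[[1]] - pev
  if (min(diag(va)) < -1e-6 * max(abs(diag(va)), 1)) {
    stop("Var(a_hat) has a negative diagonal beyond tolerance; numerical failure")
  }
  (va + t(va)) / 2
}

#' Restricted log-likelihood at the optimum
#' @param fit A [reml_fit()].
#' @return Scalar log-likelihood (constant convention: includes
#'   `-(n-p)/2 log(2 pi)`).
#' @export
restricted_loglik <- function(fit) fit$loglik

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit into one row per parameter
#' @param x A [reml_fit()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `type` (variance / fixed).
#' @export
tidy.reml_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = names(c(x$sigma2, sigma2_e = x$sigma2_e)),
                   estimate = unname(c(x$sigma2, x$sigma2_e)),
                   type = "variance"),
    tibble::tibble(term = names(x$beta), estimate = unname(x$beta), type = "fixed")
  )
}

#' One-row summary of a REML fit
#' @param x A [reml_fit()].
#' @param ... Unused.
#' @return A tibble with log-likelihood, heritability, convergence info.
#' @export
glance.reml_fit <- function(x, ...) {
  tot <- sum(x$sigma2) + x$sigma2_e
  tibble::tibble(logLik = x$loglik, h2 = sum(x$sigma2) / tot,
                 sigma2_e = x$sigma2_e, n_obs = x$n_obs,
                 converged = x$converged, method = x$method)
}
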