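#' Configuration for the F2-cross simulator
#'
#' Defaults emulate a two-line resource cross at a scale small enough for
#' routine testing: 4 + 15 founders, 40 F1, 300 F2, two 100-Mb chromosomes
#' with 400 evenly spaced markers each, adjacent-haplotype correlation 0.8,
#' ten additive QTL and a target heritability of 0.42 with a sex fixed
#' effect.
#'
#' @param n_founders_a,n_founders_b Founder counts in the two lines.
#' @param n_f1 Number of F1 animals (the first `n_f1_males` are male).
#' @param n_f1_males Number of F1 males used as sires.
#' @param n_f2 Number of F2 animals (the phenotyped generation).
#' @param chromosomes Tibble with `name`, `length_mb`, `n_markers`.
#' @param ld_rho Adjacent-marker haplotype correlation in \[0, 1).
#' @param freq_beta Two shape parameters of the Beta distribution of
#'   ancestral allele frequencies.
#' @param line_divergence Concentration divisor for line-specific
#'   frequencies around the ancestral one (smaller = more divergent lines);
#'   line frequencies are drawn from `Beta(p0 * k, (1 - p0) * k)` with
#'   `k = 1 / line_divergence`.
#' @param n_qtl Number of additive QTL (ignored when `qtl` is given).
#' @param qtl Optional tibble `snp_id` (or `marker_index`), `effect`
#'   pinning the QTL explicitly.
#' @param h2_target Narrow-sense heritability of the simulated trait.
#' @param sex_effect Additive fixed effect of sex "M" in trait units.
#' @param mu Trait mean.
#' @param recomb_rate_per_100mb Expected crossovers per 100 Mb per meiosis.
#' @param missing_rate Fraction of dosage cells masked missing (MCAR).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders_a = 4, n_founders_b = 15,
                       n_f1 = 40, n_f1_males = 8, n_f2 = 300,
                       chromosomes = tibble::tibble(
                         name = c("1", "2"), length_mb = c(100, 100),
                         n_markers = c(400, 400)),
                       ld_rho = 0.8, freq_beta = c(2, 2),
                       line_divergence = 0.1,
                       n_qtl = 10, qtl = NULL,
                       h2_target = 0.42, sex_effect = 1.0, mu = 10,
                       recomb_rate_per_100mb = 1.0, missing_rate = 0) {
  stopifnot(h2_target > 0, h2_target < 1, ld_rho >= 0, ld_rho < 1,
            n_f1_males >= 1, n_f1_males < n_f1)
  structure(list(n_founders_a = n_founders_a, n_founders_b = n_founders_b,
                 n_f1 = n_f1, n_f1_males = n_f1_males, n_f2 = n_f2,
                 chromosomes = tibble::as_tibble(chromosomes),
                 ld_rho = ld_rho, freq_beta = freq_beta,
                 line_divergence = line_divergence,
                 n_qtl = n_qtl, qtl = qtl, h2_target = h2_target,
                 sex_effect = sex_effect, mu = mu,
                 recomb_rate_per_100mb = recomb_rate_per_100mb,
                 missing_rate = missing_rate),
            class = "sim_config")
}

sim_marker_map <- function(config) {
  purrr::pmap_dfr(config$chromosomes, function(name, length_mb, n_markers) {
    pos <- round(seq(0.5, length_mb - 0.5, length.out = n_markers) * 1e6)
    tibble::tibble(snp_id = sprintf("snp_%s_%04d", name, seq_len(n_markers)),
                   chrom = as.character(name), pos_bp = pos)
  })
}

# binary first-order Markov chain with per-marker stationary frequencies p
# and exact adjacent correlation rho (clipped where the transition
# probabilities would leave [0, 1])
markov_haplotypes <- function(n_hap, p, rho) {
  m <- length(p)
  H <- matrix(0L, n_hap, m)
  H[, 1] <- stats::rbinom(n_hap, 1, p[1])
  if (m > 1) for (j in 2:m) {
    pp <- p[j - 1]; pc <- p[j]
    p1 <- pc + rho * sqrt(pc * (1 - pc) * (1 - pp) / pp)
    p0 <- pc - rho * sqrt(pc * (1 - pc) * pp / (1 - pp))
    prob <- ifelse(H[, j - 1] == 1, min(max(p1, 0), 1), min(max(p0, 0), 1))
    H[, j] <- stats::rbinom(n_hap, 1, prob)
  }
  H
}

#' Simulate founder haplotype pools for the two lines
#'
#' Per chromosome, binary haplotypes are drawn from a first-order Markov
#' chain whose stationary allele frequencies follow the configured Beta
#' distribution and whose adjacent-marker correlation is `ld_rho`; the two
#' lines get divergent frequencies around a shared ancestral value.
#'
#' @param config A [sim_config()].
#' @param n_hap_a,n_hap_b Haplotypes per line (default two per founder).
#' @return A list with `line_a`, `line_b` (lists of per-chromosome 0/1
#'   matrices), `map`, and `freqs` (tibble of line frequencies).
#' @export
sim_founder_haplotypes <- function(config, n_hap_a = 2 * config$n_founders_a,
                                   n_hap_b = 2 * config$n_founders_b) {
  map <- sim_marker_map(config)
  k <- 1 / config$line_divergence
  p0 <- stats::rbeta(nrow(map), config$freq_beta[1], config$freq_beta[2])
  p0 <- pmin(pmax(p0, 0.05), 0.95)
  p_a <- stats::rbeta(nrow(map), p0 * k, (1 - p0) * k)
  p_b <- stats::rbeta(nrow(map), p0 * k, (1 - p0) * k)
  p_a <- pmin(pmax(p_a, 0.02), 0.98)
  p_b <- pmin(pmax(p_b, 0.02), 0.98)
  split_idx <- split(seq_len(nrow(map)), map$chrom)[unique(map$chrom)]
  line_a <- lapply(split_idx, function(ix) markov_haplotypes(n_hap_a, p_a[ix], config$ld_rho))
  line_b <- lapply(split_idx, function(ix) markov_haplotypes(n_hap_b, p_b[ix], config$ld_rho))
  list(line_a = line_a, line_b = line_b, map = map,
       freqs = tibble::tibble(snp_id = map$snp_id, p_ancestral = p0,
                              p_line_a = p_a, p_line_b = p_b))
}

# one gamete from a diploid parent: Haldane crossovers (Poisson count,
# uniform positions), per chromosome
make_gamete <- function(hap1, hap2, pos_mb_list, rate_per_100mb) {
  lapply(seq_along(hap1), function(ci) {
    pos <- pos_mb_list[[ci]]
    len <- max(pos)
    n_xo <- stats::rpois(1, rate_per_100mb * len / 100)
    cur <- sample(1:2, 1)
    if (n_xo == 0) return(if (cur == 1) hap1[[ci]] else hap2[[ci]])
    xo <- sort(stats::runif(n_xo, 0, len))
    src <- cur + cumsum(c(0, rep(1, n_xo)))  # phase index per interval
    interval <- findInterval(pos, xo) + 1
    use1 <- (src[interval] %% 2) == 1
    ifelse(use1, hap1[[ci]], hap2[[ci]])
  })
}

#' Simulate the F0 -> F1 -> F2 cross
#'
#' Founders take haplotypes from their line's pool; F1 animals are produced
#' by line-A sire x line-B dam matings; F2 animals come from F1 male x F1
#' female matings avoiding full-sib pairs where the design permits. Meiosis
#' uses Haldane crossovers (Poisson count proportional to chromosome
#' length).
#'
#' @param haps Output of [sim_founder_haplotypes()].
#' @param config The [sim_config()].
#' @return A list with `geno` (a [geno_matrix()] over all generations,
#'   founders flagged, sex assigned) and `pedigree`.
#' @export
sim_cross <- function(haps, config) {
  map <- haps$map
  chroms <- unique(map$chrom)
  pos_mb_list <- lapply(chroms, function(ch) map$pos_bp[map$chrom == ch] / 1e6)
  n_a <- config$n_founders_a; n_b <- config$n_founders_b

  founder <- function(pool, i) lapply(pool, function(H) list(H[2 * i - 1, ], H[2 * i, ]))
  animals <- list()
  ids <- character(0); gen <- character(0); sex <- character(0)
  add <- function(id, g, sx, hap) {
    animals[[id]] <<- hap
    ids <<- c(ids, id); gen <<- c(gen, g); sex <<- c(sex, sx)
  }
  for (i in seq_len(n_a)) add(sprintf("A%02d", i), "F0", "M", founder(haps$line_a, i))
  for (i in seq_len(n_b)) add(sprintf("B%02d", i), "F0", "F", founder(haps$line_b, i))

  mate <- function(sire, dam) {
    g1 <- make_gamete(lapply(animals[[sire]], `[[`, 1), lapply(animals[[sire]], `[[`, 2),
                      pos_mb_list, config$recomb_rate_per_100mb)
    g2 <- make_gamete(lapply(animals[[dam]], `[[`, 1), lapply(animals[[dam]], `[[`, 2),
                      pos_mb_list, config$recomb_rate_per_100mb)
    purrr::map2(g1, g2, function(a, b) list(a, b))
  }

  ped <- list()
  f1_sire <- sample(sprintf("A%02d", seq_len(n_a)), config$n_f1, replace = TRUE)
  f1_dam <- sample(sprintf("B%02d", seq_len(n_b)), config$n_f1, replace = TRUE)
  for (i in seq_len(config$n_f1)) {
    id <- sprintf("F1_%03d", i)
    add(id, "F1", if (i <= config$n_f1_males) "M" else "F", mate(f1_sire[i], f1_dam[i]))
    ped[[id]] <- c(f1_sire[i], f1_dam[i])
  }
  males <- ids[gen == "F1" & sex == "M"]
  females <- ids[gen == "F1" & sex == "F"]
  for (i in seq_len(config$n_f2)) {
    s <- sample(males, 1)
    ok <- females[vapply(females, function(f) !identical(ped[[f]], ped[[s]]), TRUE)]
    if (!length(ok)) {
      warning("no non-full-sib mate available; falling back to random mating")
      ok <- females
    }
    dm <- sample(ok, 1)
    id <- sprintf("F2_%04d", i)
    add(id, "F2", sample(c("M", "F"), 1), mate(s, dm))
    ped[[id]] <- c(s, dm)
  }

  dosage <- matrix(0, length(ids), nrow(map),
                   dimnames = list(ids, map$snp_id))
  col_of <- split(seq_len(nrow(map)), map$chrom)[chroms]
  for (i in seq_along(ids)) {
    hap <- animals[[ids[i]]]
    for (ci in seq_along(chroms)) {
      dosage[i, col_of[[ci]]] <- hap[[ci]][[1]] + hap[[ci]][[2]]
    }
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dosage)) < config$missing_rate
    dosage[mask] <- NA
  }
  samples <- tibble::tibble(sample_id = ids, generation = gen,
                            founder = gen == "F0", sex = sex)
  list(geno = geno_matrix(dosage, map, samples),
       pedigree = tibble::tibble(
         sample_id = names(ped),
         sire = vapply(ped, `[[`, "", 1), dam = vapply(ped, `[[`, "", 2)))
}

#' Simulate phenotypes with additive QTL at a target heritability
#'
#' True breeding values are the sum of QTL effects times centred dosages;
#' the residual standard deviation is set from the realized genetic variance
#' among the phenotyped (F2) animals so the expected heritability equals
#' `h2_target`. Only F2 animals receive records, mirroring a resource-cross
#' design where founders and F1 are genotyped but the trait is measured in
#' the final generation.
#'
#' @param geno The [geno_matrix()] from [sim_cross()].
#' @param config The [sim_config()].
#' @return A list with `pheno` (tibble `sample_id`, `sex`, `trait`) and
#'   `truth` (QTL table, true breeding values, realized h2, sigma2_e).
#' @export
sim_phenotype <- function(geno, config) {
  d <- geno$dosage
  if (anyNA(d)) {
    cm <- colMeans(d, na.rm = TRUE)
    mis <- which(is.na(d), arr.ind = TRUE)
    d[mis] <- cm[mis[, 2]]
  }
  qtl <- config$qtl
  if (is.null(qtl)) {
    # spread QTL evenly over the genome, effects from a standard normal
    idx <- unique(round(seq(1, ncol(d), length.out = config$n_qtl)))
    qtl <- tibble::tibble(snp_id = colnames(d)[idx],
                          effect = stats::rnorm(length(idx)))
  } else {
    qtl <- tibble::as_tibble(qtl)
    if (!"snp_id" %in% names(qtl)) qtl$snp_id <- colnames(d)[qtl$marker_index]
  }
  jx <- match(qtl$snp_id, colnames(d))
  if (anyNA(jx)) stop("QTL marker(s) not in map: ",
                      paste(qtl$snp_id[is.na(jx)], collapse = ", "))
  Dq <- sweep(d[, jx, drop = FALSE], 2, colMeans(d[, jx, drop = FALSE]), "-")
  tbv <- drop(Dq %*% qtl$effect)
  f2 <- geno$samples$generation == "F2"
  var_g <- stats::var(tbv[f2])
  if (var_g <= 0) stop("zero genetic variance among F2; h2 target unreachable")
  sigma2_e <- var_g * (1 - config$h2_target) / config$h2_target
  e <- stats::rnorm(sum(f2), 0, sqrt(sigma2_e))
  sexM <- geno$samples$sex[f2] == "M"
  y <- config$mu + config$sex_effect * sexM + unname(tbv[f2]) + e
  pheno <- tibble::tibble(sample_id = geno$samples$sample_id[f2],
                          sex = geno$samples$sex[f2], trait = y)
  realized_h2 <- var_g / (var_g + sigma2_e)
  list(pheno = pheno,
       truth = list(qtl = qtl,
                    tbv = stats::setNames(tbv, geno$samples$sample_id),
                    var_g_f2 = var_g, sigma2_e = sigma2_e,
                    realized_h2 = realized_h2))
}

#' Simulate a complete F2 study
#'
#' Seeds the RNG, then runs [sim_founder_haplotypes()], [sim_cross()] and
#' [sim_phenotype()].
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return A list of class `f2_sim` with `geno`, `pheno`, `truth`,
#'   `pedigree`, `config`, `seed`.
#' @export
simulate_f2 <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  haps <- sim_founder_haplotypes(config)
  cross <- sim_cross(haps, config)
  ph <- sim_phenotype(cross$geno, config)
  structure(list(geno = cross$geno, pheno = ph$pheno, truth = ph$truth,
                 pedigree = cross$pedigree, founder_freqs = haps$freqs,
                 config = config, seed = seed),
            class = "f2_sim")
}

#' @export
print.f2_sim <- function(x, ...) {
  cat(sprintf("<f2_sim> seed %d: %d animals x %d markers, %d phenotyped, target h2 = %.2f\n",
              x$seed, nrow(x$geno$dosage), ncol(x$geno$dosage),
              nrow(x$pheno), x$config$h2_target))
  invisible(x)
}

#' Write a simulated study to disk as plain-text files
#'
#' @param sim An [simulate_f2()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `genotypes.tsv`, `map.tsv`,
#'   `samples.tsv`, `phenotypes.tsv`, `qtl_truth.tsv`, `config.yaml`-style
#'   `config.tsv`.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$geno, file.path(dir, "genotypes.tsv"), "dosage-tsv")
  readr::write_tsv(sim$geno$map, file.path(dir, "map.tsv"))
  readr::write_tsv(sim$geno$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$pheno, file.path(dir, "phenotypes.tsv"))
  readr::write_tsv(sim$truth$qtl, file.path(dir, "qtl_truth.tsv"))
  cfg <- sim$config
  flat <- tibble::tibble(
    key = c("n_founders_a", "n_founders_b", "n_f1", "n_f1_males", "n_f2",
            "ld_rho", "h2_target", "sex_effect", "mu",
            "recomb_rate_per_100mb", "missing_rate", "seed"),
    value = c(cfg$n_founders_a, cfg$n_founders_b, cfg$n_f1, cfg$n_f1_males,
              cfg$n_f2, cfg$ld_rho, cfg$h2_target, cfg$sex_effect, cfg$mu,
              cfg$recomb_rate_per_100mb, cfg$missing_rate, sim$seed))
  readr::write_tsv(flat, file.path(dir, "config.tsv"))
  invisible(dir)
}
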