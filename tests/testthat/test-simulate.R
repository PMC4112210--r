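test_that("founder haplotypes realize the requested adjacent correlation", {
  cfg0 <- sim_config(ld_rho = 0,
                     chromosomes = tibble::tibble(name = "1", length_mb = 50,
                                                  n_markers = 120),
                     freq_beta = c(8, 8))  # frequencies near 0.5
  set.seed(111)
  h0 <- sim_founder_haplotypes(cfg0, n_hap_a = 2000, n_hap_b = 4)
  H <- h0$line_a[[1]]
  adj0 <- sapply(seq_len(ncol(H) - 1), function(j) cor(H[, j], H[, j + 1]))
  expect_lt(mean(abs(adj0)), 3 / sqrt(2000))

  # the chain attains ld_rho when adjacent frequencies are similar, so pin
  # the frequency distribution tightly around 0.5 for the calibration check
  cfg9 <- sim_config(ld_rho = 0.9,
                     chromosomes = tibble::tibble(name = "1", length_mb = 50,
                                                  n_markers = 120),
                     freq_beta = c(60, 60), line_divergence = 0.01)
  set.seed(112)
  h9 <- sim_founder_haplotypes(cfg9, n_hap_a = 2000, n_hap_b = 4)
  H9 <- h9$line_a[[1]]
  adj9 <- sapply(seq_len(ncol(H9) - 1), function(j) cor(H9[, j], H9[, j + 1]))
  expect_equal(mean(adj9), 0.9, tolerance = 0.05)
})

test_that("diploid dosage variance matches 2pq at p = 0.5 without LD", {
  set.seed(113)
  H <- blupscan:::markov_haplotypes(4000, rep(0.5, 50), 0)
  dos <- H[seq(1, 4000, 2), ] + H[seq(2, 4000, 2), ]
  expect_equal(mean(apply(dos, 2, var)), 0.5, tolerance = 0.03)
})

test_that("a cross of fixed lines gives all-heterozygous F1", {
  cfg <- sim_config(n_f2 = 10, n_f1 = 6, n_f1_males = 2,
                    chromosomes = tibble::tibble(name = "1", length_mb = 20,
                                                 n_markers = 15))
  set.seed(114)
  haps <- sim_founder_haplotypes(cfg)
  haps$line_a[[1]][] <- 1L  # line A fixed for the reference allele
  haps$line_b[[1]][] <- 0L
  cross <- sim_cross(haps, cfg)
  f1 <- cross$geno$samples$generation == "F1"
  expect_true(all(cross$geno$dosage[f1, ] == 1))
  f2 <- cross$geno$samples$generation == "F2"
  expect_true(all(cross$geno$dosage[f2, ] %in% 0:2))
})

test_that("without recombination each gamete is an intact founder haplotype", {
  cfg <- sim_config(n_f2 = 20, n_f1 = 6, n_f1_males = 2,
                    recomb_rate_per_100mb = 0,
                    chromosomes = tibble::tibble(name = "1", length_mb = 50,
                                                 n_markers = 40))
  set.seed(115)
  haps <- sim_founder_haplotypes(cfg)
  cross <- sim_cross(haps, cfg)
  pool <- rbind(haps$line_a[[1]], haps$line_b[[1]])
  pool_keys <- apply(pool, 1, paste, collapse = "")
  f1 <- which(cross$geno$samples$generation == "F1")
  for (i in f1) {
    dos <- cross$geno$dosage[i, ]
    # F1 dosage must decompose as one line-A plus one line-B haplotype
    a_keys <- apply(haps$line_a[[1]], 1, paste, collapse = "")
    found <- any(vapply(seq_len(nrow(haps$line_a[[1]])), function(r) {
      rem <- dos - haps$line_a[[1]][r, ]
      all(rem %in% 0:1) && paste(rem, collapse = "") %in%
        apply(haps$line_b[[1]], 1, paste, collapse = "")
    }, TRUE))
    expect_true(found)
  }
})

test_that("LD decays with distance in the simulated F2", {
  cfg <- sim_config(n_f2 = 200,
                    chromosomes = tibble::tibble(name = "1", length_mb = 50,
                                                 n_markers = 200))
  sim <- simulate_f2(cfg, seed = 116)
  f2 <- sim$geno$samples$generation == "F2"
  d <- sim$geno$dosage[f2, ]
  pos <- sim$geno$map$pos_bp / 1e6
  r2_at <- function(gap_lo, gap_hi) {
    pairs <- which(outer(pos, pos, function(a, b) {
      g <- b - a; g > gap_lo & g <= gap_hi
    }), arr.ind = TRUE)
    pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
    pairs <- pairs[sample(nrow(pairs), min(300, nrow(pairs))), , drop = FALSE]
    mean(sapply(seq_len(nrow(pairs)), function(k) {
      suppressWarnings(cor(d[, pairs[k, 1]], d[, pairs[k, 2]])^2)
    }), na.rm = TRUE)
  }
  set.seed(117)
  expect_gt(r2_at(0, 0.3), r2_at(0.9, 1.5))
})

test_that("phenotypes hit the target heritability structure", {
  cfg <- sim_config(n_f2 = 150,
                    chromosomes = tibble::tibble(name = c("1", "2"),
                                                 length_mb = c(50, 50),
                                                 n_markers = c(100, 100)))
  sim <- simulate_f2(cfg, seed = 118)
  expect_equal(sim$truth$realized_h2, 0.42, tolerance = 1e-12)
  f2 <- sim$geno$samples$generation == "F2"
  expect_equal(nrow(sim$pheno), sum(f2))
  # truth record scores the BLUP: accuracy is positive and grows with h2
  qc <- qc_filter(sim$geno)
  p <- founder_allele_freqs(qc$geno)
  Z <- standardize_markers(mean_impute(qc$geno, p), p)
  G <- suppressMessages(ensure_invertible_grm(compute_grm(Z)))
  data <- design_data(sim$pheno, qc$geno, fixed = ~sex)
  fit <- reml_fit(data, G)
  acc <- cor(fit$ahat[, 1], sim$truth$tbv[qc$geno$samples$sample_id])
  expect_gt(acc, 0.5)
  # no QTL: pure noise around the fixed effects
  cfg0 <- sim_config(n_f2 = 30, qtl = tibble::tibble(snp_id = character(0),
                                                     effect = numeric(0)))
  expect_error(simulate_f2(cfg0, seed = 119), "zero genetic variance")
})

test_that("simulated studies round-trip through the readers", {
  cfg <- sim_config(n_f2 = 25, n_f1 = 8, n_f1_males = 3,
                    chromosomes = tibble::tibble(name = "1", length_mb = 20,
                                                 n_markers = 30),
                    missing_rate = 0.04)
  sim <- simulate_f2(cfg, seed = 120)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  g <- read_genotypes(file.path(dir, "genotypes.tsv"), "dosage-tsv",
                      map = read_marker_map(file.path(dir, "map.tsv")))
  expect_equal(unname(g$dosage), unname(sim$geno$dosage))
  expect_equal(g$map$pos_bp, sim$geno$map$pos_bp)
  ph <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph$trait, sim$pheno$trait, tolerance = 1e-12)
})
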