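scan_stub <- function(df) {
  class(df) <- c("snp_scan", class(df))
  df
}

test_that("peak selection takes the per-chromosome argmax with stable ties", {
  tab <- tibble::tibble(
    snp_id = c("a", "b", "c", "d"),
    chrom = c("1", "1", "1", "2"),
    pos_mb = c(1, 2, 3, 5),
    neglog10_p = -log10(c(0.2, 0.001, 0.05, 0.9)))
  peaks <- select_peaks(scan_stub(tab))
  expect_equal(peaks$snp_id[peaks$chrom == "1"], "b")
  expect_equal(peaks$snp_id[peaks$chrom == "2"], "d")  # single-SNP chromosome
  # tie at two positions: the lower position wins and the tie is messaged
  tie <- tibble::tibble(snp_id = c("x", "y"), chrom = "3", pos_mb = c(9, 4),
                        neglog10_p = c(2, 2))
  expect_message(pk <- select_peaks(scan_stub(tie)), "tie")
  expect_equal(pk$snp_id, "y")
})

test_that("windows are closed +/- 1 Mb intervals clipped at chromosome ends", {
  map <- tibble::tibble(snp_id = paste0("m", 1:7), chrom = "6",
                        pos_bp = c(0.3, 134.5, 135.08, 136.08, 137.08, 137.2, 139) * 1e6)
  peak <- tibble::tibble(snp_id = "m4", chrom = "6", pos_mb = 136.08)
  seg <- make_window(peak, map)
  expect_setequal(seg$member_snp_ids, c("m3", "m4", "m5"))  # closed interval ends
  expect_equal(seg$window, c(135.08, 137.08))
  # clipping at the chromosome start
  peak2 <- tibble::tibble(snp_id = "m1", chrom = "6", pos_mb = 0.3)
  seg2 <- make_window(peak2, map)
  expect_equal(seg2$window[1], 0.3)       # no marker below the peak
  expect_equal(seg2$member_snp_ids, "m1") # lone marker in its window
})

test_that("LRT arithmetic reproduces the published table values", {
  lk_m1 <- -1227.938
  lk_m2 <- c(-1210.800, -1223.178, -1224.540)
  stat <- lrt(lk_m2, lk_m1)
  expect_equal(round(stat, 2), c(34.28, 9.52, 6.80))
  expect_equal(stat[2], 9.520, tolerance = 1e-12)
  expect_equal(lrt(-5, -5), 0)
  expect_error(lrt(-6, -5), "negative LRT")
})

test_that("chi-square(0.5 df) p-values match the published values and gamma form", {
  stat <- c(34.28, 9.52, 6.80)
  pv <- lrt_pvalue(stat)
  expect_equal(pv[1], 1.1e-9, tolerance = 0.03)
  expect_equal(pv[2], 6.5e-4, tolerance = 0.01)
  expect_equal(pv[3], 3.1e-3, tolerance = 0.01)
  # the unrounded table-2 statistic reproduces the printed 1.133459e-09
  expect_equal(lrt_pvalue(2 * (1227.938 - 1210.800)), 1.133459e-09,
               tolerance = 1e-4)
  # 0.5-df chi-square is gamma(shape 0.25, scale 2)
  expect_equal(pv, pgamma(stat, shape = 0.25, scale = 2, lower.tail = FALSE))
  expect_equal(lrt_pvalue(0), 1)
  # boundary mixture alternative
  expect_equal(lrt_pvalue(4, mixture = TRUE),
               0.5 * pchisq(4, 1, lower.tail = FALSE))
  expect_equal(lrt_pvalue(0, mixture = TRUE), 1)
})

test_that("variance proportions reproduce the published table arithmetic", {
  mk_fit <- function(e, a2, a1) {
    structure(list(sigma2 = c(sigma2_a1 = a1, sigma2_a2 = a2), sigma2_e = e,
                   n_grm = 2), class = "reml_fit")
  }
  expect_equal(round(variance_proportion(mk_fit(3.73, 1.95, 0.70)), 2), 0.11)
  expect_equal(round(variance_proportion(mk_fit(3.67, 2.42, 0.63)), 2), 0.09)
  expect_equal(round(variance_proportion(mk_fit(3.69, 2.55, 0.15)), 2), 0.02)
  expect_equal(variance_proportion(mk_fit(1, 1, 0)), 0)
})

test_that("segment model degenerates to the single-GRM model when G1 = G", {
  st <- toy_study(n = 24, m = 20, seed = 81)
  fit1 <- reml_fit(st$data, st$G)
  zeroG <- structure(list(G = matrix(0, 24, 24), snp_ids = character(0),
                          p = numeric(0), m_divisor = 1L, epsilon = 0,
                          cache = new.env()), class = "grm")
  dimnames(zeroG$G) <- dimnames(st$G$G)
  fit2 <- suppressWarnings(fit_segment_model(st$data, st$G, zeroG, init_fit = fit1))
  expect_equal(fit2$loglik, fit1$loglik, tolerance = 1e-4)
})

test_that("a segment carrying the QTL partitions the additive variance", {
  qtl <- tibble::tibble(snp_id = c("snp_1_0040", "snp_1_0041", "snp_2_0040"),
                        effect = c(1.2, 0.8, 0.5))
  cfg <- sim_config(n_f2 = 150,
                    chromosomes = tibble::tibble(name = c("1", "2"),
                                                 length_mb = c(40, 40),
                                                 n_markers = c(80, 80)),
                    qtl = qtl)
  sim <- simulate_f2(cfg, seed = 82)
  qc <- qc_filter(sim$geno)
  scan <- suppressMessages(snp_scan(qc$geno, sim$pheno, fixed = ~sex))
  segs <- segment_scan(scan)
  s1 <- segs[segs$chrom == "1", ]
  expect_gt(s1$segm_va, 0)
  expect_gt(s1$lrt, 5)
  # additivity: reduced-model sigma_a^2 close to sigma_a1^2 + sigma_a2^2
  expect_equal(s1$var_a_m1, s1$segm_va + s1$var_a_m2,
               tolerance = 0.35)
  expect_equal(s1$prop_total,
               s1$segm_va / (s1$segm_va + s1$var_a_m2 + s1$var_e_m2),
               tolerance = 1e-10)
  # LRT non-negative on every converged segment
  expect_true(all(segs$lrt[segs$converged] >= 0))
})

test_that("null segments give small LRT at the boundary", {
  qtl <- tibble::tibble(snp_id = c("snp_1_0020", "snp_1_0060"), effect = c(1, -1))
  cfg <- sim_config(n_f2 = 120,
                    chromosomes = tibble::tibble(name = c("1", "2"),
                                                 length_mb = c(40, 40),
                                                 n_markers = c(80, 80)),
                    qtl = qtl)
  sim <- simulate_f2(cfg, seed = 83)
  qc <- qc_filter(sim$geno)
  scan <- suppressMessages(snp_scan(qc$geno, sim$pheno, fixed = ~sex))
  geno <- attr(scan, "geno"); Z <- attr(scan, "Z"); G <- attr(scan, "grm")
  fit1 <- attr(scan, "fit"); data <- attr(scan, "design")
  # fixed mid-chromosome-2 window, far from any QTL
  mid <- tibble::tibble(snp_id = "snp_2_0040", chrom = "2",
                        pos_mb = geno$map$pos_bp[match("snp_2_0040", geno$map$snp_id)] / 1e6)
  seg <- make_window(mid, geno$map)
  pn <- stats::setNames(Z$p, Z$snp_ids)
  G1 <- segment_grm(geno, pn, seg$member_snp_ids)
  G2 <- complement_grm(G, Z, seg$member_snp_ids)
  fit2 <- fit_segment_model(data, G1, G2, init_fit = fit1)
  stat <- lrt(fit2$loglik, fit1$loglik)
  expect_lt(stat, 6)
  expect_gt(lrt_pvalue(stat), 0.01)
})

test_that("the segment report carries the Bonferroni segment count", {
  st <- toy_study(n = 30, m = 30, seed = 84)
  scan <- suppressMessages(snp_scan(st$geno, st$pheno, fixed = ~sex, p = st$p))
  segs <- segment_scan(scan, alpha = 0.05, half_width_mb = 1,
                       genome_length_mb = 2800)
  expect_equal(attr(segs, "n_segments"), 1400)
  expect_equal(attr(segs, "threshold"), 3.571429e-05, tolerance = 1e-6)
})
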