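#' Apply genotype quality-control edits
#'
#' Filters are applied sequentially, mirroring the usual editing pipeline for
#' dense SNP panels: (1) drop markers with unknown map position, (2) drop
#' samples with more than `max_sample_missing` of their markers missing,
#' (3) drop markers with more than `max_marker_missing` missing calls
#' (computed on the remaining samples), (4) drop markers whose minor allele
#' frequency is below `maf_min` (again on the remaining samples, so
#' monomorphic markers leave under this rule). Comparisons are strict:
#' "more than 10% missing" removes only fractions greater than 0.10, and the
#' MAF rule removes only frequencies strictly below `maf_min`.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param max_marker_missing Maximum tolerated missing fraction per marker
#'   (default 0.10).
#' @param max_sample_missing Maximum tolerated missing fraction per sample
#'   (default 0.10).
#' @param drop_unmapped Drop markers with `NA` chromosome or position.
#' @return A list with elements `geno` (the filtered [geno_matrix()]) and
#'   `report`, a tibble tallying removals per rule plus the final dimensions.
#' @export
qc_filter <- function(geno, maf_min = 0.01, max_marker_missing = 0.10,
                      max_sample_missing = 0.10, drop_unmapped = TRUE) {
  if (ncol(geno$dosage) == 0 || nrow(geno$dosage) == 0) stop("empty genotype matrix")
  n0 <- nrow(geno$dosage); m0 <- ncol(geno$dosage)

  n_unmapped <- 0L
  if (drop_unmapped) {
    keep <- !(is.na(geno$map$chrom) | is.na(geno$map$pos_bp))
    n_unmapped <- sum(!keep)
    if (n_unmapped) geno <- geno[, which(keep)]
  }

  d <- geno$dosage
  samp_miss <- rowMeans(is.na(d))
  keep_s <- samp_miss <= max_sample_missing
  n_samp <- sum(!keep_s)
  if (n_samp) geno <- geno[which(keep_s), ]

  d <- geno$dosage
  mark_miss <- colMeans(is.na(d))
  keep_m <- mark_miss <= max_marker_missing
  n_miss <- sum(!keep_m)
  if (n_miss) geno <- geno[, which(keep_m)]

  d <- geno$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_f <- !is.na(maf) & maf >= maf_min
  n_maf <- sum(!keep_f)
  if (n_maf) geno <- geno[, which(keep_f)]

  if (ncol(geno$dosage) == 0) stop("no markers left after QC")

  report <- tibble::tibble(
    rule = c("unmapped", "sample_missingness", "marker_missingness", "maf"),
    markers_removed = c(n_unmapped, 0L, n_miss, n_maf),
    samples_removed = c(0L, n_samp, 0L, 0L)
  )
  attr(report, "input_dim") <- c(samples = n0, markers = m0)
  attr(report, "final_dim") <- c(samples = nrow(geno$dosage), markers = ncol(geno$dosage))
  list(geno = geno, report = report)
}

#' Reference-allele frequencies from founder animals
#'
#' Frequencies are computed per marker from the animals flagged as founders
#' in the sample table: `p_j` = (sum of founder dosages at marker j) /
#' (2 x number of founders with a call at j). If no sample is flagged as a
#' founder the whole sample is used, with a warning.
#'
#' @param geno A [geno_matrix()].
#' @param founders Optional character vector of founder sample ids,
#'   overriding the `founder` flag in `geno$samples`.
#' @return Named numeric vector `p` of length `ncol(geno$dosage)`.
#' @export
founder_allele_freqs <- function(geno, founders = NULL) {
  if (is.null(founders)) {
    founders <- geno$samples$sample_id[isTRUE_vec(geno$samples$founder)]
    if (!length(founders)) {
      warning("no samples flagged as founders; using all samples for allele frequencies")
      founders <- geno$samples$sample_id
    }
  }
  idx <- match(founders, geno$samples$sample_id)
  if (anyNA(idx)) stop("unknown founder sample id(s): ",
                       paste(founders[is.na(idx)], collapse = ", "))
  d <- geno$dosage[idx, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  if (any(n_called == 0)) {
    stop("markers with no non-missing founder call: ",
         paste(colnames(d)[n_called == 0], collapse = ", "))
  }
  p <- colSums(d, na.rm = TRUE) / (2 * n_called)
  stats::setNames(p, colnames(d))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Impute missing dosages by twice the allele frequency
#'
#' Each missing cell at marker j is replaced by `2 * p[j]`, the expected
#' dosage under Hardy-Weinberg at the frequency used downstream for
#' centring, so imputed cells contribute nothing to the centred marker
#' matrix.
#'
#' @param geno A [geno_matrix()].
#' @param p Frequency vector aligned to the markers (named or positional).
#' @return A [geno_matrix()] with no missing cells.
#' @export
mean_impute <- function(geno, p) {
  p <- align_freqs(p, colnames(geno$dosage))
  d <- geno$dosage
  mis <- which(is.na(d), arr.ind = TRUE)
  if (nrow(mis)) d[mis] <- 2 * p[mis[, 2]]
  geno$dosage <- d
  geno
}

align_freqs <- function(p, snp_ids) {
  if (!is.null(names(p))) {
    idx <- match(snp_ids, names(p))
    if (anyNA(idx)) stop("frequency vector lacks entries for: ",
                         paste(snp_ids[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
    p <- p[idx]
  } else if (length(p) != length(snp_ids)) {
    stop("frequency vector length ", length(p), " does not match ",
         length(snp_ids), " markers")
  }
  unname(p)
}
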