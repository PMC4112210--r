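#' Standardize a dosage matrix to the scaled marker matrix Z
#'
#' Column j of Z is `(M[, j] - 2 p_j) / sqrt(m_divisor * 2 p_j (1 - p_j))`:
#' dosages centred at twice the reference-allele frequency and scaled by the
#' expected binomial standard deviation times the square root of the number
#' of markers, so that `G = Z Z'` has diagonal near 1 under random mating at
#' the same frequencies (the VanRaden scaling).
#'
#' @param geno A [geno_matrix()] with no missing cells.
#' @param p Reference-allele frequency vector (named or aligned), all
#'   strictly inside (0, 1).
#' @param m_divisor Marker count in the scaling denominator; defaults to the
#'   number of markers in `geno`.
#' @return An object of class `marker_z` with fields `Z` (n x m matrix),
#'   `p`, `m_divisor`, `snp_ids`.
#' @export
standardize_markers <- function(geno, p, m_divisor = ncol(geno$dosage)) {
  d <- geno$dosage
  if (anyNA(d)) stop("missing dosages; run mean_impute() first")
  p <- align_freqs(p, colnames(d))
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    stop("monomorphic marker(s) reached standardization (QC should remove them): ",
         paste(colnames(d)[mono][1:min(5, sum(mono))], collapse = ", "))
  }
  denom <- sqrt(m_divisor * 2 * p * (1 - p))
  Z <- sweep(d, 2, 2 * p, "-")
  Z <- sweep(Z, 2, denom, "/")
  structure(list(Z = Z, p = p, m_divisor = m_divisor, snp_ids = colnames(d)),
            class = "marker_z")
}

new_grm <- function(G, snp_ids, p, m_divisor, epsilon = 0) {
  G <- (G + t(G)) / 2
  structure(list(G = G, snp_ids = snp_ids, p = p, m_divisor = m_divisor,
                 epsilon = epsilon, cache = new.env(parent = emptyenv())),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d x %d from %d markers (m_divisor = %d, epsilon = %g)\n",
              nrow(x$G), ncol(x$G), length(x$snp_ids), x$m_divisor, x$epsilon))
  invisible(x)
}

#' Genomic relationship matrix G = Z Z'
#'
#' @param Z A [standardize_markers()] result.
#' @return A `grm` object carrying its provenance (marker set, frequencies,
#'   divisor, regularization epsilon).
#' @export
compute_grm <- function(Z) {
  stopifnot(inherits(Z, "marker_z"))
  new_grm(tcrossprod(Z$Z), Z$snp_ids, Z$p, Z$m_divisor)
}

#' Segment relationship matrix
#'
#' Builds a GRM from the segment's markers only, with the scaling divisor
#' equal to the segment size (each segment gets its own full-strength
#' standardization, not the genome-wide one).
#'
#' @param geno A complete [geno_matrix()].
#' @param p Frequency vector for all markers of `geno` (named).
#' @param segment_markers Character vector of marker ids in the segment.
#' @return A `grm`.
#' @export
segment_grm <- function(geno, p, segment_markers) {
  if (!length(segment_markers)) stop("empty segment")
  missing_ids <- setdiff(segment_markers, colnames(geno$dosage))
  if (length(missing_ids)) stop("segment markers absent from genotypes: ",
                                paste(missing_ids, collapse = ", "))
  sub <- geno[, segment_markers]
  p <- align_freqs(p, colnames(geno$dosage))
  names(p) <- colnames(geno$dosage)
  Zs <- standardize_markers(sub, p[segment_markers],
                            m_divisor = length(segment_markers))
  compute_grm(Zs)
}

#' Complement relationship matrix G2 = G - Zs Zs'
#'
#' `Zs` keeps the genome-wide scaling of `Z` (divisor m, not m - m_s), so
#' that subtracting its cross-product from G removes exactly the segment's
#' contribution: `G2 + Zs Zs' = G`.
#'
#' @param G The full-genome `grm` built from `Z`.
#' @param Z The [standardize_markers()] result G was built from.
#' @param segment_markers Character vector of marker ids to remove.
#' @return A `grm`.
#' @export
complement_grm <- function(G, Z, segment_markers) {
  stopifnot(inherits(G, "grm"), inherits(Z, "marker_z"))
  if (!identical(G$snp_ids, Z$snp_ids) || !isTRUE(all.equal(G$p, Z$p)) ||
      G$m_divisor != Z$m_divisor) {
    stop("G was not built from this Z (provenance mismatch)")
  }
  if (!length(segment_markers)) return(G)
  idx <- match(segment_markers, Z$snp_ids)
  if (anyNA(idx)) stop("segment markers absent from Z: ",
                       paste(segment_markers[is.na(idx)], collapse = ", "))
  Zs <- Z$Z[, idx, drop = FALSE]
  keep <- setdiff(Z$snp_ids, segment_markers)
  new_grm(G$G - tcrossprod(Zs), keep, Z$p[-idx], Z$m_divisor)
}

#' Bridge identity between segment scalings
#'
#' The segment columns of the genome-scaled Z satisfy
#' `Zs Zs' = (m_seg / m) * G1`, linking the complement subtraction (genome
#' scaling) to the segment GRM (segment scaling).
#'
#' @param G1 Segment `grm` from [segment_grm()].
#' @param m_total Genome-wide marker count m.
#' @return The matrix `Zs Zs'` implied by G1.
#' @export
segment_crossprod_from_g1 <- function(G1, m_total) {
  (G1$m_divisor / m_total) * G1$G
}

#' Ridge-regularize a GRM
#'
#' @param G A `grm`.
#' @param epsilon Non-negative ridge added to the diagonal.
#' @return `G + epsilon * I` with epsilon recorded in the provenance.
#' @export
regularize_grm <- function(G, epsilon) {
  stopifnot(inherits(G, "grm"), epsilon >= 0)
  if (epsilon == 0) return(G)
  new_grm(G$G + diag(epsilon, nrow(G$G)), G$snp_ids, G$p, G$m_divisor,
          epsilon = G$epsilon + epsilon)
}

#' Guarantee an invertible GRM
#'
#' Returns the GRM unchanged when its Cholesky factorization is well
#' conditioned; otherwise adds the default ridge
#' `epsilon = 1e-8 * mean(diag(G))` (messaged). Run this once before any
#' step that needs `G^-1` (MME prediction error variances, the
#' back-transformation) so the same matrix is used throughout.
#'
#' @param G A `grm`.
#' @return A `grm`, possibly regularized.
#' @export
ensure_invertible_grm <- function(G) {
  R <- tryCatch(chol(G$G), error = function(e) NULL)
  ok <- !is.null(R) && (min(diag(R)) / max(diag(R)))^2 > 1e-10
  if (ok) {
    G$cache$chol <- R
    return(G)
  }
  eps <- 1e-8 * mean(diag(G$G))
  message("GRM is singular or near-singular; adding ridge epsilon = ", signif(eps, 3))
  regularize_grm(G, eps)
}

# Cached Cholesky factor of a grm; regularizes once (1e-8 * mean diag) if the
# plain factorization fails, with a message.
grm_chol <- function(G) {
  if (!is.null(G$cache$chol)) return(G$cache$chol)
  R <- tryCatch(chol(G$G), error = function(e) NULL)
  if (is.null(R)) {
    eps <- 1e-8 * mean(diag(G$G))
    message("GRM not positive definite; adding ridge epsilon = ", signif(eps, 3))
    R <- chol(G$G + diag(eps, nrow(G$G)))
  }
  G$cache$chol <- R
  R
}

grm_solve <- function(G, b) {
  R <- grm_chol(G)
  backsolve(R, backsolve(R, b, transpose = TRUE))
}

#' Write / read a GRM as TSV with a metadata sidecar
#'
#' The TSV has a sample-id header and one row per sample at full double
#' precision (17 significant digits); `<path>.meta.tsv` records the marker
#' divisor and epsilon, and `<path>.p.tsv` the frequency vector.
#'
#' @param G A `grm`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_grm <- function(G, path) {
  ids <- rownames(G$G)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(G$G)))
  header <- paste(c("sample_id", ids), collapse = "\t")
  body <- vapply(seq_len(nrow(G$G)), function(i) {
    paste(c(ids[i], formatC(G$G[i, ], digits = 17, format = "g")), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  writeLines(c("key\tvalue",
               paste0("m_divisor\t", G$m_divisor),
               paste0("epsilon\t", formatC(G$epsilon, digits = 17, format = "g"))),
             paste0(path, ".meta.tsv"))
  writeLines(c("snp_id\tp",
               paste0(G$snp_ids, "\t", formatC(G$p, digits = 17, format = "g"))),
             paste0(path, ".p.tsv"))
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  G <- matrix(as.numeric(unlist(lapply(rows, `[`, -1L))), nrow = length(rows),
              byrow = TRUE, dimnames = list(ids, ids))
  meta <- utils::read.table(paste0(path, ".meta.tsv"), header = TRUE, sep = "\t")
  pt <- utils::read.table(paste0(path, ".p.tsv"), header = TRUE, sep = "\t")
  new_grm(G, as.character(pt$snp_id), stats::setNames(pt$p, pt$snp_id),
          m_divisor = as.integer(meta$value[meta$key == "m_divisor"]),
          epsilon = as.numeric(meta$value[meta$key == "epsilon"]))
}
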