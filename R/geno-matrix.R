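#' Genotype matrix container
#'
#' Bundles an n x m allele-dosage matrix (counted-allele dosages in \[0, 2\],
#' `NA` for missing) with its marker map and sample table. Row names of
#' `dosage` are sample ids, column names are marker ids, and both are kept in
#' step with `map$snp_id` and `samples$sample_id`.
#'
#' @param dosage Numeric matrix, samples in rows, markers in columns.
#' @param map Tibble/data frame with columns `snp_id`, `chrom`, `pos_bp`
#'   (1-based base pairs; `NA` position marks an unmapped marker).
#' @param samples Tibble/data frame with column `sample_id` plus optional
#'   `founder` (logical) and covariate columns (e.g. `sex`).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, map, samples = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  map <- tibble::as_tibble(map)
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
  if (anyDuplicated(map$snp_id)) stop("duplicated snp_id in marker map")
  if (ncol(dosage) != nrow(map)) {
    stop("dosage has ", ncol(dosage), " columns but map has ", nrow(map), " markers")
  }
  if (is.null(samples)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(dosage)))
    samples <- tibble::tibble(sample_id = ids)
  }
  samples <- tibble::as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  if (nrow(samples) != nrow(dosage)) {
    stop("dosage has ", nrow(dosage), " rows but sample table has ", nrow(samples))
  }
  if (!"founder" %in% names(samples)) samples$founder <- FALSE
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- map$snp_id
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  structure(list(dosage = dosage, map = map, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  n_mis <- sum(is.na(x$dosage))
  cat(sprintf("<geno_matrix> %d samples x %d markers (%d chromosome(s), %d missing cells)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chrom)), n_mis))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

# Subset by sample / marker index or id, keeping map and samples aligned.
#' Subset a genotype matrix
#' @param x A [geno_matrix()].
#' @param i,j Sample / marker selectors (indices, logicals, or ids).
#' @param ... Unused.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$map$snp_id)
  geno_matrix(x$dosage[i, j, drop = FALSE], x$map[j, , drop = FALSE],
              x$samples[i, , drop = FALSE])
}

#' Marker positions in megabases
#' @param map A marker map tibble with `pos_bp`.
#' @return The map with a derived `pos_mb = pos_bp / 1e6` column.
#' @export
with_pos_mb <- function(map) {
  dplyr::mutate(map, pos_mb = .data$pos_bp / 1e6)
}
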