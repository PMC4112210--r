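#' Read a genotype dosage file
#'
#' Supported formats:
#' \describe{
#'   \item{`dosage-tsv`}{Header row of marker ids, then one row per sample
#'     whose first column is the sample id and remaining columns are dosages.}
#'   \item{`plink-raw`}{The PLINK 1.9 `--recode A` dialect: columns FID, IID,
#'     PAT, MAT, SEX, PHENOTYPE followed by one allele-count column per
#'     marker; the counted allele is the one named in the column header.}
#'   \item{`plink-bed`}{A PLINK binary triplet; `path` names the `.bed` file
#'     and the matching `.bim`/`.fam` must sit next to it.}
#' }
#' Missing genotypes coded `NA`, `-9` or an empty field are mapped to `NA`.
#'
#' @param path File to read.
#' @param format One of `"dosage-tsv"`, `"plink-raw"`, `"plink-bed"`.
#' @param map Optional marker map tibble (`snp_id`, `chrom`, `pos_bp`). The
#'   `.bim` supplies the map for `plink-bed`; for the other formats markers
#'   without a supplied map entry get `NA` chromosome/position (and are then
#'   dropped by [qc_filter()] when `drop_unmapped = TRUE`).
#' @return A [geno_matrix()] preserving the file's sample and marker order.
#' @export
read_genotypes <- function(path, format = c("dosage-tsv", "plink-raw", "plink-bed"),
                           map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
    "dosage-tsv" = read_dosage_tsv(path),
    "plink-raw"  = read_plink_raw(path),
    "plink-bed"  = read_plink_bed(path)
  )
  if (!is.null(map)) {
    map <- tibble::as_tibble(map)
    idx <- match(colnames(out$dosage), map$snp_id)
    out$map <- tibble::tibble(
      snp_id = colnames(out$dosage),
      chrom = ifelse(is.na(idx), NA, as.character(map$chrom[idx])),
      pos_bp = ifelse(is.na(idx), NA_real_, as.numeric(map$pos_bp[idx]))
    )
  }
  geno_matrix(out$dosage, out$map, out$samples)
}

parse_dosage_cell <- function(x) {
  x[x %in% c("", "NA", "-9", "-9.0")] <- NA
  suppressWarnings(as.numeric(x))
}

read_dosage_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("parse error in ", path, ": need a header and at least one sample row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  snp_ids <- header[-1]
  m <- length(snp_ids)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != m + 1L)
  if (length(bad)) {
    stop("parse error in ", path, ": line ", bad[1] + 1L, " has ",
         lengths(rows)[bad[1]], " fields, expected ", m + 1L)
  }
  ids <- vapply(rows, `[[`, "", 1L)
  dosage <- matrix(parse_dosage_cell(unlist(lapply(rows, `[`, -1L))),
                   nrow = length(rows), ncol = m, byrow = TRUE,
                   dimnames = list(ids, snp_ids))
  list(dosage = dosage,
       map = tibble::tibble(snp_id = snp_ids, chrom = NA_character_, pos_bp = NA_real_),
       samples = tibble::tibble(sample_id = ids))
}

read_plink_raw <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"), check.names = FALSE)
  meta_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta_cols %in% names(dat)[1:6])) {
    stop("parse error in ", path, ": not a PLINK --recode A file (missing FID/IID header)")
  }
  snp_cols <- setdiff(names(dat), meta_cols)
  # header is SNPID_<counted allele>; strip the allele suffix for the marker id
  snp_ids <- sub("_[A-Za-z0-9*]+$", "", snp_cols)
  dosage <- as.matrix(dat[, snp_cols, drop = FALSE])
  storage.mode(dosage) <- "double"
  dimnames(dosage) <- list(dat$IID, snp_ids)
  sex <- dat$SEX
  list(dosage = dosage,
       map = tibble::tibble(snp_id = snp_ids, chrom = NA_character_, pos_bp = NA_real_),
       samples = tibble::tibble(sample_id = as.character(dat$IID),
                                sex = ifelse(is.na(sex), NA_character_,
                                             ifelse(sex == 1, "M", "F"))))
}

# Minimal SNP-major PLINK .bed decoder (2 bits/genotype):
# 00 = 2 copies of A1, 10 = 1 copy, 11 = 0 copies, 01 = missing.
read_plink_bed <- function(path) {
  stub <- sub("\\.bed$", "", path)
  bim_path <- paste0(stub, ".bim"); fam_path <- paste0(stub, ".fam")
  if (!file.exists(bim_path) || !file.exists(fam_path)) {
    stop("plink-bed requires ", bim_path, " and ", fam_path)
  }
  fam <- utils::read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  bim <- utils::read.table(bim_path, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("parse error: ", path, " lacks the PLINK .bed magic number")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bpm <- ceiling(n / 4)
  if (length(raw) - 3L != bpm * m) {
    stop("parse error: ", path, " has wrong length for ", n, " samples x ", m, " markers")
  }
  body <- raw[-(1:3)]
  # unpack all 2-bit codes at once
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8)
  codes <- bits[seq(1, 7, 2), , drop = FALSE] + 2L * bits[seq(2, 8, 2), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4 * bpm)[seq_len(n), , drop = FALSE]
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  dosage <- matrix(lookup[as.character(codes)], nrow = n, ncol = m,
                   dimnames = list(fam$V2, bim$V2))
  list(dosage = dosage,
       map = tibble::tibble(snp_id = bim$V2, chrom = as.character(bim$V1),
                            pos_bp = as.numeric(bim$V4)),
       samples = tibble::tibble(sample_id = as.character(fam$V2),
                                sex = ifelse(fam$V5 == 1, "M",
                                             ifelse(fam$V5 == 2, "F", NA_character_))))
}

#' Write genotypes to disk
#'
#' @param geno A [geno_matrix()].
#' @param path Output path (for `plink-bed`, the `.bed` path; `.bim`/`.fam`
#'   are written alongside).
#' @param format Same choices as [read_genotypes()].
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("dosage-tsv", "plink-raw", "plink-bed")) {
  format <- match.arg(format)
  d <- geno$dosage
  if (format == "dosage-tsv") {
    header <- paste(c("sample_id", colnames(d)), collapse = "\t")
    body <- vapply(seq_len(nrow(d)), function(i) {
      paste(c(rownames(d)[i], ifelse(is.na(d[i, ]), "NA", format(d[i, ], digits = 17))),
            collapse = "\t")
    }, "")
    writeLines(c(header, body), path)
  } else if (format == "plink-raw") {
    sex <- if ("sex" %in% names(geno$samples)) {
      ifelse(geno$samples$sex == "M", 1L, 2L)
    } else rep(0L, nrow(d))
    header <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                      paste0(colnames(d), "_A")), collapse = " ")
    body <- vapply(seq_len(nrow(d)), function(i) {
      paste(c(rownames(d)[i], rownames(d)[i], "0", "0", sex[i], "-9",
              ifelse(is.na(d[i, ]), "NA", format(d[i, ], digits = 17))),
            collapse = " ")
    }, "")
    writeLines(c(header, body), path)
  } else {
    if (any(!is.na(d) & d != round(d))) {
      stop("plink-bed cannot represent fractional dosages; write dosage-tsv instead")
    }
    write_plink_bed(geno, path)
  }
  invisible(path)
}

write_plink_bed <- function(geno, path) {
  d <- geno$dosage
  stub <- sub("\\.bed$", "", path)
  n <- nrow(d); m <- ncol(d)
  sex <- if ("sex" %in% names(geno$samples)) {
    ifelse(is.na(geno$samples$sex), 0L, ifelse(geno$samples$sex == "M", 1L, 2L))
  } else rep(0L, n)
  utils::write.table(
    data.frame(geno$samples$sample_id, geno$samples$sample_id, 0L, 0L, sex, -9),
    paste0(stub, ".fam"), quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(ifelse(is.na(geno$map$chrom), 0, geno$map$chrom), geno$map$snp_id, 0,
               ifelse(is.na(geno$map$pos_bp), 0, geno$map$pos_bp), "A", "B"),
    paste0(stub, ".bim"), quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  bpm <- ceiling(n / 4)
  padded <- matrix(0L, 4 * bpm, m)
  padded[seq_len(n), ] <- code
  bytes <- padded[seq(1, 4 * bpm, 4), , drop = FALSE] +
    4L * padded[seq(2, 4 * bpm, 4), , drop = FALSE] +
    16L * padded[seq(3, 4 * bpm, 4), , drop = FALSE] +
    64L * padded[seq(4, 4 * bpm, 4), , drop = FALSE]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(path)
}

#' Read a marker map TSV (snp_id, chrom, pos_bp)
#' @param path TSV with header columns `snp_id`, `chrom`, `pos_bp`.
#' @return A tibble.
#' @export
read_marker_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(snp_id = "c", chrom = "c", pos_bp = "d"))
}

#' Read a phenotype/covariate TSV keyed by sample_id
#' @param path TSV with header; must contain a `sample_id` column.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(out)) stop("phenotype file lacks a sample_id column")
  out$sample_id <- as.character(out$sample_id)
  out
}
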