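#' Select the peak marker of each chromosome
#'
#' The marker with the largest `-log10(p)` per chromosome; ties are broken
#' by smaller position, then lexicographic marker id (tie-breaks messaged).
#'
#' @param scan A [snp_scan()] tibble.
#' @return A tibble with one row per chromosome.
#' @export
select_peaks <- function(scan) {
  scan <- tibble::as_tibble(scan)
  scan <- scan[!is.na(scan$neglog10_p), , drop = FALSE]
  if (!nrow(scan)) stop("no testable markers in scan")
  peaks <- scan |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(df, key) {
      top <- df[df$neglog10_p == max(df$neglog10_p), , drop = FALSE]
      if (nrow(top) > 1) {
        message("peak tie on chromosome ", key$chrom[[1]],
                "; keeping the smallest position")
        top <- top[order(top$pos_mb, top$snp_id), , drop = FALSE]
      }
      top[1, , drop = FALSE]
    }) |>
    dplyr::ungroup()
  peaks
}

#' Define the candidate segment around a peak marker
#'
#' All markers on the peak's chromosome within `half_width_mb` megabases of
#' the peak (closed interval, clipped at the chromosome ends).
#'
#' @param peak A one-row tibble with `snp_id`, `chrom`, `pos_mb`.
#' @param map Marker map (with `snp_id`, `chrom`, `pos_bp`).
#' @param half_width_mb Half window width in Mb (default 1).
#' @return A list of class `segment_def`: `chrom`, `peak_snp_id`,
#'   `peak_pos_mb`, `window` (lo, hi in Mb), `member_snp_ids`.
#' @export
make_window <- function(peak, map, half_width_mb = 1.0) {
  stopifnot(nrow(peak) == 1, !is.na(peak$pos_mb))
  map <- with_pos_mb(tibble::as_tibble(map))
  on_chr <- map[map$chrom == peak$chrom & !is.na(map$pos_mb), , drop = FALSE]
  lo <- max(peak$pos_mb - half_width_mb, min(on_chr$pos_mb))
  hi <- min(peak$pos_mb + half_width_mb, max(on_chr$pos_mb))
  members <- on_chr$snp_id[on_chr$pos_mb >= peak$pos_mb - half_width_mb &
                             on_chr$pos_mb <= peak$pos_mb + half_width_mb]
  structure(list(chrom = peak$chrom, peak_snp_id = peak$snp_id,
                 peak_pos_mb = peak$pos_mb, window = c(lo, hi),
                 member_snp_ids = members),
            class = "segment_def")
}

#' Fit the two-GRM segment model
#'
#' `y = X beta + a1 + a2 + e` with `a1 ~ N(0, G1 sigma_a1^2)` over the
#' segment relationship matrix and `a2 ~ N(0, G2 sigma_a2^2)` over the
#' complement.
#'
#' @param data A [design_data()].
#' @param G1 Segment `grm` from [segment_grm()].
#' @param G2 Complement `grm` from [complement_grm()].
#' @param init_fit Optional single-GRM [reml_fit()] of the reduced model;
#'   its estimates seed the optimizer as
#'   `(0.1 sigma_a^2, 0.9 sigma_a^2, sigma_e^2)`.
#' @return A two-component [reml_fit()].
#' @export
fit_segment_model <- function(data, G1, G2, init_fit = NULL) {
  init <- NULL
  if (!is.null(init_fit)) {
    s2a <- init_fit$sigma2[[1]]
    init <- c(0.1 * s2a, 0.9 * s2a, init_fit$sigma2_e)
  }
  reml_fit(data, list(G1, G2), init = init)
}

#' Likelihood-ratio statistic for nested REML fits
#'
#' @param loglik_full Log-likelihood of the full (segment) model.
#' @param loglik_reduced Log-likelihood of the reduced model.
#' @return `2 * (loglik_full - loglik_reduced)`, floored at 0; values below
#'   -1e-6 raise an error (a failed optimization, not a valid LRT).
#' @export
lrt <- function(loglik_full, loglik_reduced) {
  stat <- 2 * (loglik_full - loglik_reduced)
  if (any(stat < -1e-6)) {
    stop("negative LRT (", format(min(stat)), "): the full-model fit did not reach its optimum")
  }
  pmax(stat, 0)
}

#' P-value of the segment LRT
#'
#' By default the upper-tail probability of a chi-square distribution with
#' 0.5 degrees of freedom (a gamma with shape 0.25 and scale 2), the
#' reference that reproduces published segment tests of this form. A
#' conventional boundary mixture `0.5 chi2_0 + 0.5 chi2_1` is available via
#' `mixture = TRUE` for sensitivity analysis.
#'
#' @param lrt Non-negative LRT statistic (vectorized).
#' @param df Degrees of freedom of the chi-square reference (default 0.5).
#' @param mixture Use the 50:50 point-mass/chi-square(1) mixture instead.
#' @return Upper-tail p-value(s).
#' @export
lrt_pvalue <- function(lrt, df = 0.5, mixture = FALSE) {
  stopifnot(all(lrt >= 0))
  if (mixture) {
    return(ifelse(lrt == 0, 1, 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)))
  }
  stats::pchisq(lrt, df = df, lower.tail = FALSE)
}

#' Proportion of total variance explained by the segment
#'
#' `sigma_a1^2 / (sigma_e^2 + sigma_a1^2 + sigma_a2^2)` from a two-GRM fit.
#'
#' @param fit A two-component [reml_fit()].
#' @return Scalar proportion in \[0, 1\].
#' @export
variance_proportion <- function(fit) {
  stopifnot(fit$n_grm == 2)
  tot <- fit$sigma2_e + sum(fit$sigma2)
  unname(fit$sigma2[["sigma2_a1"]] / tot)
}

#' Candidate-segment screen
#'
#' Takes a completed [snp_scan()], picks the peak marker per chromosome,
#' builds the +/- `half_width_mb` Mb segment, fits the two-GRM variance
#' partition model against the single-GRM reduced model (re-fitted once and
#' reused for all segments), and reports the LRT with its chi-square(0.5 df)
#' p-value and Bonferroni call.
#'
#' @param scan A [snp_scan()] result (must carry its `fit`/`grm`/`Z`/`design`
#'   attributes).
#' @param alpha Nominal size before Bonferroni (default 0.05).
#' @param half_width_mb Segment half width in Mb (default 1).
#' @param genome_length_mb Genome length used for the Bonferroni segment
#'   count `genome_length_mb / (2 * half_width_mb)`; defaults to the summed
#'   chromosome spans of the scan's map.
#' @param mixture Passed to [lrt_pvalue()].
#' @return A tibble of class `segment_scan`, one row per chromosome:
#'   segment definition, both log-likelihoods, LRT, `pvalue_lrt`, variance
#'   components of both models, `segm_va`, `prop_total`, `significant`.
#' @export
segment_scan <- function(scan, alpha = 0.05, half_width_mb = 1.0,
                         genome_length_mb = NULL, mixture = FALSE) {
  fit1 <- attr(scan, "fit"); G <- attr(scan, "grm"); Z <- attr(scan, "Z")
  data <- attr(scan, "design"); geno <- attr(scan, "geno")
  if (is.null(fit1) || is.null(G) || is.null(Z) || is.null(data) || is.null(geno)) {
    stop("scan lacks its model attributes; pass the object returned by snp_scan()")
  }
  map <- with_pos_mb(geno$map)
  if (is.null(genome_length_mb)) {
    genome_length_mb <- sum(tapply(map$pos_mb, map$chrom, function(x) diff(range(x))))
  }
  n_segments <- max(1, round(genome_length_mb / (2 * half_width_mb)))
  threshold <- bonferroni_threshold(alpha, n_segments)
  peaks <- select_peaks(scan)
  p_named <- stats::setNames(Z$p, Z$snp_ids)

  rows <- purrr::map(seq_len(nrow(peaks)), function(i) {
    peak <- peaks[i, , drop = FALSE]
    seg <- make_window(peak, geno$map, half_width_mb)
    G1 <- segment_grm(geno, p_named, seg$member_snp_ids)
    G2 <- complement_grm(G, Z, seg$member_snp_ids)
    fit2 <- tryCatch(fit_segment_model(data, G1, G2, init_fit = fit1),
                     error = function(e) NULL)
    if (is.null(fit2)) {
      return(tibble::tibble(
        chrom = seg$chrom, peak_snp_id = seg$peak_snp_id,
        peak_pos_mb = seg$peak_pos_mb, neglog10_p = peak$neglog10_p,
        n_markers = length(seg$member_snp_ids),
        loglik_m1 = fit1$loglik, loglik_m2 = NA_real_, lrt = NA_real_,
        pvalue_lrt = NA_real_, var_e_m1 = fit1$sigma2_e,
        var_a_m1 = fit1$sigma2[[1]], var_e_m2 = NA_real_, var_a_m2 = NA_real_,
        segm_va = NA_real_, prop_total = NA_real_,
        converged = FALSE, significant = NA))
    }
    stat <- lrt(fit2$loglik, fit1$loglik)
    pv <- lrt_pvalue(stat, mixture = mixture)
    tibble::tibble(
      chrom = seg$chrom, peak_snp_id = seg$peak_snp_id,
      peak_pos_mb = seg$peak_pos_mb, neglog10_p = peak$neglog10_p,
      n_markers = length(seg$member_snp_ids),
      loglik_m1 = fit1$loglik, loglik_m2 = fit2$loglik, lrt = stat,
      pvalue_lrt = pv, var_e_m1 = fit1$sigma2_e, var_a_m1 = fit1$sigma2[[1]],
      var_e_m2 = fit2$sigma2_e, var_a_m2 = fit2$sigma2[["sigma2_a2"]],
      segm_va = fit2$sigma2[["sigma2_a1"]],
      prop_total = variance_proportion(fit2),
      converged = fit2$converged,
      significant = fit2$converged & pv < threshold)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("segment_scan", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "n_segments") <- n_segments
  out
}
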