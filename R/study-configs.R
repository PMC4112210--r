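#' Preset simulation designs for the package's evaluation studies
#'
#' Two ready-made [sim_config()] presets used throughout the documentation,
#' the test suite and `scripts/acceptance.R`, so the same study conditions
#' are reproducible everywhere.
#'
#' `config_reduced_gwas()` is a desk-scale genome scan design: 300 F2
#' animals and 800 markers on three chromosomes (400 + 250 + 150). The
#' third, 150-marker chromosome is the designated shuffle target for the
#' plasmode type-I-error study. Ten additive QTL, target heritability 0.42,
#' a sex fixed effect.
#'
#' `config_segment_power()` is the segment-test design: 500 F2 animals and
#' 1000 markers on two 100-Mb chromosomes. One major QTL sits mid
#' chromosome 1 with an effect sized to explain about 12% of the phenotypic
#' variance (the scale of segment effect the method is meant to flag), plus
#' four background QTL on the same chromosome; chromosome 2 carries no QTL
#' and provides null segments.
#'
#' @return A [sim_config()].
#' @export
config_reduced_gwas <- function() {
  sim_config(
    n_f2 = 300,
    chromosomes = tibble::tibble(name = c("1", "2", "3"),
                                 length_mb = c(100, 62.5, 37.5),
                                 n_markers = c(400, 250, 150)))
}

#' @rdname config_reduced_gwas
#' @export
config_segment_power <- function() {
  qtl <- tibble::tibble(
    snp_id = c("snp_1_0250", sprintf("snp_1_%04d", c(50, 150, 350, 450))),
    effect = c(0.506, 0.4, -0.4, 0.4, -0.4))
  sim_config(
    n_f2 = 500,
    chromosomes = tibble::tibble(name = c("1", "2"),
                                 length_mb = c(100, 100),
                                 n_markers = c(500, 500)),
    qtl = qtl)
}
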