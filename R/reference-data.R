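#' Published per-class fractions for the canine at-risk cohort
#'
#' Previously reported per-length-class genome fractions and at-risk
#' genotype fractions for a panel of roughly 2,500 dogs genotyped on a
#' dense SNP array carrying probes for recessive disease variants, with ROH
#' called by both a zero-heterozygote scan workflow and a sliding-window
#' workflow. At-risk genotype distributions are reported separately for the
#' ancient, multi-breed *SOD1* degenerative-myelopathy allele and for the
#' other (mostly breed-specific) recessive conditions, alongside the
#' published relative risks of each ROH class versus the non-ROH
#' background.
#'
#' These values serve as inputs for validating the relative-risk
#' arithmetic: recomputing RR from the rounded printed fractions reproduces
#' every published RR to within the rounding of those inputs.
#'
#' @return Tibble: `caller` (`"SCAN"` = zero-het scan workflow,
#'   `"WINDOWED"` = sliding-window workflow), `class`, `genome_pct`,
#'   `sod1_pct`, `other_pct`, `rr_published` (RR for the non-*SOD1*
#'   cohort).
#' @export
published_atrisk_fractions <- function() {
  cls <- factor(c("SUB", "SHORT", "MEDIUM", "LONG"),
                levels = c("SUB", "SHORT", "MEDIUM", "LONG"))
  dplyr::bind_rows(
    tibble::tibble(
      caller = "WINDOWED", class = cls,
      genome_pct = c(75.9, 4.5, 3.3, 16.4),
      sod1_pct = c(36.4, 19.4, 15.2, 29.0),
      other_pct = c(9.9, 14.9, 11.6, 63.5),
      rr_published = c(1.0, 25.7, 27.4, 29.8)
    ),
    tibble::tibble(
      caller = "SCAN", class = cls,
      genome_pct = c(75.1, 4.7, 3.1, 17.1),
      sod1_pct = c(34.3, 18.7, 14.5, 32.5),
      other_pct = c(7.8, 14.7, 11.4, 66.1),
      rr_published = c(1.0, 29.8, 35.7, 37.0)
    )
  )
}
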