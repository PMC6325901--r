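#' Configuration for the pedigree genotype simulator
#'
#' Describes a synthetic SNP-array cohort: the genome (chromosome lengths and
#' marker density), a founder haplotype pool, a consanguineous pedigree
#' template, optional recessive disease loci, and a genotyping error model.
#' Defaults mirror a dense canine array: one autosomal marker per ~12.8 kb,
#' one X marker per ~28.2 kb, a per-call error rate of 1e-4 (99.99%
#' concordance) and no missingness (imputed panels).
#'
#' @param chrom_lengths Named numeric vector of autosome lengths in bp
#'   (names must be `"1"`..`"38"`). Default: five 60-Mb chromosomes.
#' @param x_length Length of chromosome X in bp, or `NULL` to simulate
#'   autosomes only.
#' @param markers_per_mb Autosomal marker density (markers / Mb).
#' @param x_markers_per_mb Chromosome X marker density.
#' @param n_founder_haps Size of the founder haplotype pool.
#' @param beta_af Length-2 numeric, shape parameters of the Beta
#'   distribution that per-marker allele frequencies are drawn from.
#'   `c(2, 2)` gives the common-variant spectrum typical of an
#'   ascertained genotyping array.
#' @param ld_rho Adjacent-marker allele copying probability in founder
#'   haplotypes (first-order Markov stand-in for LD; 0 = independent
#'   markers).
#' @param cm_per_mb Constant recombination rate used to convert physical to
#'   genetic distance.
#' @param pedigree Mating template producing each sampled offspring:
#'   `"unrelated"` (outbred), `"fullsib"` (parents are full siblings,
#'   expected inbreeding F = 1/4), `"first_cousin"` (F = 1/16), or
#'   `"cousin<g>"` for g-th cousin parents (F = 1/4^(g+1)).
#' @param n_offspring Number of offspring sampled, each from an independent
#'   pedigree instance.
#' @param disease_loci Optional tibble of recessive disease loci to plant:
#'   columns `locus_id`, `chrom`, `pos` (snapped to the nearest marker) and
#'   `carrier_freq` (frequency of the single origin haplotype among
#'   pedigree-founder haplotypes).
#' @param error_rate Per-call genotyping error probability (flips
#'   homozygous to heterozygous and vice versa), applied after truth
#'   segments are recorded.
#' @param missing_rate Per-call missingness probability, applied after the
#'   error model.
#' @param breed_label Breed assigned to all simulated samples (or `NA`).
#' @param seed Integer seed; mandatory, so a config reruns bit-identically.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = stats::setNames(rep(6e7, 5), as.character(1:5)),
                       x_length = NULL,
                       markers_per_mb = 78,
                       x_markers_per_mb = 35.5,
                       n_founder_haps = 100,
                       beta_af = c(2, 2),
                       ld_rho = 0,
                       cm_per_mb = 1.0,
                       pedigree = "unrelated",
                       n_offspring = 50,
                       disease_loci = NULL,
                       error_rate = 1e-4,
                       missing_rate = 0,
                       breed_label = NA_character_,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  stopifnot(
    all(names(chrom_lengths) %in% autosome_labels()),
    all(chrom_lengths > 0),
    length(beta_af) == 2, all(beta_af > 0),
    ld_rho >= 0, ld_rho <= 1,
    error_rate >= 0, error_rate <= 1,
    missing_rate >= 0, missing_rate <= 1,
    n_founder_haps >= 2,
    n_offspring >= 1
  )
  depth <- pedigree_loop_depth(pedigree)
  if (!is.null(disease_loci)) {
    disease_loci <- tibble::as_tibble(disease_loci)
    stopifnot(all(c("locus_id", "chrom", "pos", "carrier_freq") %in% names(disease_loci)))
    disease_loci$chrom <- as.character(disease_loci$chrom)
    if (any(disease_loci$chrom == "X")) stop("disease loci are supported on autosomes only")
    if (any(!disease_loci$chrom %in% names(chrom_lengths))) stop("disease locus on unknown chromosome")
    if (any(disease_loci$carrier_freq < 0 | disease_loci$carrier_freq > 1)) {
      stop("carrier_freq must be in [0, 1]")
    }
    if (sum(disease_loci$carrier_freq) >= 1) {
      stop("summed carrier frequencies must be < 1")
    }
  }
  structure(
    list(chrom_lengths = chrom_lengths, x_length = x_length,
         markers_per_mb = markers_per_mb, x_markers_per_mb = x_markers_per_mb,
         n_founder_haps = as.integer(n_founder_haps), beta_af = beta_af,
         ld_rho = ld_rho, cm_per_mb = cm_per_mb,
         pedigree = pedigree, loop_depth = depth,
         n_offspring = as.integer(n_offspring), disease_loci = disease_loci,
         error_rate = error_rate, missing_rate = missing_rate,
         breed_label = breed_label, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# NA = unrelated parents; 0 = full sibs; g >= 1 = g-th cousins
pedigree_loop_depth <- function(pedigree) {
  if (pedigree == "unrelated") return(NA_integer_)
  if (pedigree == "fullsib") return(0L)
  if (pedigree == "first_cousin") return(1L)
  m <- regmatches(pedigree, regexec("^cousin([0-9]+)$", pedigree))[[1]]
  if (length(m) == 2) return(as.integer(m[2]))
  stop("unknown pedigree template: ", pedigree)
}

#' Expected pedigree inbreeding coefficient for a template
#'
#' `1/4` for offspring of full siblings, `1/16` for first cousins, and
#' `1/4^(g+1)` for g-th cousins; 0 for unrelated parents.
#'
#' @param pedigree Template string as in [sim_config()].
#' @return Expected F.
#' @export
pedigree_expected_f <- function(pedigree) {
  d <- pedigree_loop_depth(pedigree)
  if (is.na(d)) 0 else 0.25^(d + 1)
}
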