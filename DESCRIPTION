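Package: autozyg
Title: Runs of Homozygosity, Inbreeding Coefficients, and Recessive
    Disease Enrichment from SNP Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and analysis of runs of homozygosity (ROH) in dense
    diploid SNP genotype panels, with an emphasis on domestic dog cohorts.
    Provides a zero-heterozygote scan caller (minimum span, gap merging, and
    marker-count filtering) and a sliding-window caller, genomic inbreeding
    coefficients (F_ROH) for autosomes and chromosome X, classification of
    homozygous recessive disease genotypes by overlapping ROH length class
    with relative-risk estimates against the non-ROH background, a
    tract-resampling null model, per-breed ROH density maps, PLINK text
    .ped/.map input and output, LD pruning and method-of-moments relatedness
    (PI_HAT) filtering, and a pedigree genotype simulator that records true
    autozygous segments so caller accuracy can be measured against known
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
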