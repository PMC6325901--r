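---
title: "Detecting runs of homozygosity and recessive-disease enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and recessive-disease enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozyg)
```

## The model

A diploid genome is autozygous wherever its two haplotypes coalesce in a
recent common ancestor; such segments are homozygous at every assayed
marker (barring genotyping error) and appear as runs of homozygosity
(ROH). Since coalescence eventually happens everywhere, "autozygous" is
only meaningful above a minimum tract length: segments inherited through
g meioses have expected length 100/g cM, so a 0.5 Mb floor (at ~1 cM/Mb)
corresponds to coancestry up to roughly a hundred meioses deep, while
tracts over 5 Mb indicate very recent inbreeding.

The per-individual genomic inbreeding coefficient is
`F_ROH = sum(tract lengths in scope) / L`. The denominator L is not
uniquely defined by convention; `compute_froh()` defaults to the summed
per-chromosome marker span (self-contained for any panel) and accepts
fixed assembly lengths for cross-panel comparability. Autosomes and
chromosome X are always computed separately, X in females only — a
hemizygous male X is homozygous by construction and both callers skip it.

Recessive disease variants provide an external validation of ROH calling:
each descends from a single mutational origin, so a homozygote's two
copies share that origin and must be flanked by a (possibly eroded)
shared haplotype. Classifying every at-risk genotype by the length class
of its containing tract — sub-threshold (< 0.5 Mb, i.e. not in a called
ROH), short (0.5–2.5 Mb), medium (2.5–5 Mb), long (> 5 Mb) — and dividing
each class's share of at-risk genotypes by its share of genome gives the
relative risk of harbouring a deleterious recessive homozygote, baselined
at the sub-threshold class. Class bounds are left-closed (a tract of
exactly 2,500,000 bp is medium). Genome shares are averaged per dog and
then across dogs, not pooled, so heavily inbred genomes do not dominate
the denominator.

## The two callers

`scan_roh()` implements a three-stage scan:

1. maximal stretches of markers containing no heterozygote (and, under
   the default `BREAK` missing policy, no missing call), kept when their
   span (last − first marker + 1) is at least `min_span` = 500,000 bp;
2. neighbouring runs separated by strictly less than `merge_gap` =
   50,000 bp are unioned transitively — isolated clusters of
   heterozygotes shorter than 50 kb typically reflect genotyping error or
   polymorphic structural variants, and bridging them restores long
   tracts that would otherwise fragment;
3. merged tracts containing fewer than `min_markers` = 41 array markers
   (counting every marker in the span, heterozygous gap markers
   included) are removed, guarding against spurious calls in
   marker-poor regions.

Run endpoints are marker positions, never midpoints to the flanking
heterozygote, and every length is `end − start + 1` bp. The ">= 500 kb"
boundary is inclusive. Doubling `merge_gap` to 100 kb is the standard
sensitivity check; called coverage is monotone non-decreasing in the gap
and non-increasing in the marker threshold.

`windowed_roh()` implements the documented sliding-window algorithm:
41-SNP windows, a window "hits" when it has zero heterozygous and zero
missing calls; a SNP qualifies when at least 5% of the windows containing
it hit; maximal qualifying stretches are trimmed to their outermost
homozygous SNPs and reported at ≥ 41 SNPs and ≥ 500 kb. Marker-density
and physical-gap checks are deliberately disabled rather than silently
defaulted: on a ~12.8 kb-spaced array they are redundant with the
marker-count rule. Because segment-end trimming is under-documented in
the original software, the caller is verified against a second,
independently coded naive implementation of the same published algorithm
(in the test suite) rather than against binaries.

With zero-heterozygote windows a single heterozygous call always splits a
tract; this makes the scan caller's explicit gap-merge the more sensitive
of the two for long ROH, which matches how the two workflows compare on
real cohorts.

## What the simulator emulates — and what it does not

`simulate_pedigree()` generates each sampled offspring from an
independent instance of a consanguineous pedigree template ("fullsib",
"first_cousin", "cousin\<g\>", or "unrelated"). Founders draw whole-genome
haplotypes from a finite pool without replacement within a pedigree, so
realized inbreeding converges to the pedigree expectation
(F = 1/4^(d+1) for loop depth d). Meiosis places Poisson(length_cM/100)
crossovers uniformly, without interference, converting physical to
genetic distance at a constant 1 cM/Mb. Wherever an offspring's two
gametes descend from the same pool haplotype the genome is autozygous;
these truth segments are recorded *before* the error model runs
(homozygote↔heterozygote flips at `error_rate`, masking at
`missing_rate`), so sensitivity and precision are measured against
error-free truth. Allele frequencies follow Beta(2, 2) — the
common-variant spectrum of an ascertained genotyping array; a first-order
Markov copying knob (`ld_rho`) crudely mimics LD but no claim of realism
is made for it. Chromosome X, when enabled, is transmitted with male
hemizygosity (sire X to daughters, unrecombined) at the lower marker
density typical of X arrays.

Two realism gaps matter for interpretation. First, every autozygous
segment descends from a pedigree loop a few meioses deep, so simulated
tracts are megabase-scale; the abundant sub-megabase tracts of real
breeds (ancient bottlenecks) are not reproduced, and tests passing here
say nothing about caller behaviour at the 0.5 Mb detection floor on real
LD structure. Second, founder haplotypes are atomic: background
identity-by-state mosaics shorter than a founder block do not occur, so
false-positive ROH rates on real data will exceed the (near-zero)
simulated ones. Disease alleles are planted on exactly one founder
haplotype (single mutational origin) at a marker position, with
`carrier_freq` controlling how often pedigree founders draw that
haplotype.

## Null models for tract-length curves

`cumulative_curve()` orders tracts longest to shortest and reports the
fraction (or, optionally, the length-weighted fraction) of tracts at
least x long. To judge whether the tracts overlapping disease genotypes
are an unusual sample, `resample_null()` draws 1000 same-size subsets
uniformly without replacement from the cohort's full tract set and
returns the pointwise min–max envelope (and 2.5/97.5% quantiles): a curve
escaping the min–max band anywhere is a stronger departure than any of
1000 random draws.

That uniform null is the right comparison for the classic
"disease-overlapping tracts vs all tracts" figure, but it is *not* the
right null for asking whether one particular locus is special. Tracts
covering any fixed genomic position are a length-biased sample (a tract
covers a point with probability proportional to its length) and are
spatially correlated (truncated near chromosome ends, locally similar in
the middle), so under the uniform null even a neutral locus is rejected
essentially always — we measured rejection in a third to all of seeds
across simulator configurations. `locus_null()` therefore builds the
matched null: each replicate stabs a marker position drawn uniformly from
the map, collects the tracts covering it, and size-matches to the
observed count. A neutral locus is exchangeable with these replicates by
construction; a planted disease allele, whose homozygotes ride long
recent identity-by-descent tracts, is not. The package's control
experiment uses both: the planted allele's tract curve must escape the
uniform resampling envelope (the published-style comparison), and
neutral random loci must stay inside the locus-matched envelope.

With a single simulated disease locus the locus-null envelope is wide
(covering tracts of one position overlap each other), so distinguishing
one disease locus from one random locus has limited power; the real
leverage in cohort data comes from pooling across many disease loci, as
a 29-locus panel does.

## Numerical and design choices

- Coordinates are 1-based inclusive bp; `length = end − start + 1`
  everywhere, including the ≥ 500,000 bp run filter.
- A gap of exactly `merge_gap` bp does **not** merge; a tract of exactly
  41 markers survives the filter; a tract of exactly 2.5 Mb is medium.
- LD pruning (`ld_prune()`, 200-SNP windows, step 100, r² > 0.90 on
  genotype dosage correlation) removes the lower-MAF member of an
  offending pair (tie: the later map position), repeats passes to a fixed
  point so the operation is idempotent, and never removes monomorphic
  markers (their r² is undefined and treated as 0).
- `pi_hat()` follows the method-of-moments identity-by-state
  decomposition (Purcell et al. 2007) without finite-sample
  allele-frequency corrections; IBD-state estimates are clamped to [0, 1]
  and renormalized, pairs with under 100 informative markers are flagged.
  `drop_close_relatives()` greedily removes the sample in the most
  over-threshold pairs (ties lexicographic) until the relatedness graph
  is clear — one documented deterministic rule among the many the
  underlying tools leave unspecified.
- Relative risk at the baseline class is 1 by construction, even when a
  perfect caller leaves the baseline with zero at-risk genotypes; a class
  with zero genome share has undefined (NA) risk.
- `simulate_founders()` and `simulate_pedigree()` consume separate RNG
  streams derived from the config seed, so the same config is
  bit-reproducible end to end.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: caller-vs-oracle
equivalence on 1000 random chromosomes of up to 200 markers; a
200-offspring full-sib cohort on 30 chromosomes × ~5,000 markers
(~150,000 markers, ~1.9 Gb — array density matching one marker per
12.8 kb) for F_ROH truth recovery and base-level precision of tracts
≥ 2.5 Mb; and a 150-offspring first-cousin cohort with a planted
recessive allele (carrier haplotype frequency 0.4, chosen so most
homozygotes arise from two recent carrier parents and ride long tracts)
for the 1000-replicate envelope controls with 20 neutral loci. These
sizes give Monte-Carlo error comfortably inside the stated tolerances
(±0.02 on F_ROH recovery; precision ≥ 0.95).

## Known limitations

- The windowed caller is faithful to the *documented* algorithm; corner
  cases of the original implementation's end-trimming may differ.
- `pi_hat()` omits the small-sample bias corrections of the original
  method-of-moments scheme; on panels of a few dozen samples or fewer,
  estimates for unrelated pairs are noisier and clamping inflates their
  mean slightly above zero.
- The simulator cannot produce ancient sub-megabase autozygosity or
  realistic LD, as discussed above; conclusions about the 0.5–2.5 Mb
  class on real data rest on the callers' marker-level correctness, not
  on simulated recovery.
- Disease loci are simulated on autosomes only and at marker positions
  (the array assays the variants directly).
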