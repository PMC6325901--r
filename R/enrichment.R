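#' ROH length-class specification
#'
#' The four canonical tract-length classes: `SUB` (< 0.5 Mb, below the
#' detection threshold — equivalently, "not in a called ROH"), `SHORT`
#' (0.5–2.5 Mb), `MEDIUM` (2.5–5 Mb) and `LONG` (> 5 Mb). Interior bounds
#' are left-closed / right-open, so a tract of exactly 2,500,000 bp is
#' `MEDIUM`. `SUB` is the baseline class for relative risks.
#'
#' @param bounds Increasing numeric vector of interior class bounds in bp.
#' @param labels Class labels, `length(bounds) + 1` of them; the first is
#'   the baseline.
#' @return A `length_class_spec`.
#' @export
length_class_spec <- function(bounds = c(5e5, 2.5e6, 5e6),
                              labels = c("SUB", "SHORT", "MEDIUM", "LONG")) {
  stopifnot(all(diff(bounds) > 0), length(labels) == length(bounds) + 1)
  structure(list(bounds = bounds, labels = labels), class = "length_class_spec")
}

#' Classify tract lengths
#' @param length_bp Numeric vector of tract lengths.
#' @param spec A [length_class_spec()].
#' @return Factor of class labels (all spec labels as levels).
#' @export
classify_length <- function(length_bp, spec = length_class_spec()) {
  idx <- findInterval(length_bp, spec$bounds, left.open = FALSE) + 1L
  factor(spec$labels[idx], levels = spec$labels)
}

#' Assign each at-risk genotype the class of its overlapping ROH
#'
#' For every (sample, locus) at-risk record, finds the tract of that sample
#' containing the locus position (`start <= pos <= end`; tracts of one
#' sample are disjoint so there is at most one) and assigns the tract's
#' length class; records with no containing tract get the baseline class.
#' Loci flagged off the marker grid are excluded with a warning.
#'
#' @param disease A `disease_table` (see [read_disease_table()]).
#' @param tracts Tract tibble from one caller.
#' @param spec A [length_class_spec()].
#' @return Tibble: `sample_id`, `locus_id`, `chrom`, `pos`, `tract_start`,
#'   `tract_end`, `tract_length` (NA when uncovered), `class`.
#' @export
classify_at_risk <- function(disease, tracts, spec = length_class_spec()) {
  recs <- dplyr::left_join(disease$records,
                           disease$loci[, c("locus_id", "chrom", "pos", "off_grid")],
                           by = "locus_id")
  if (any(recs$off_grid)) {
    warning(sum(recs$off_grid), " at-risk record(s) at off-grid loci excluded",
            call. = FALSE)
    recs <- recs[!recs$off_grid, ]
  }
  hit <- dplyr::inner_join(recs, tracts,
                           by = c("sample_id", "chrom"),
                           relationship = "many-to-many") |>
    dplyr::filter(.data$start <= .data$pos, .data$pos <= .data$end) |>
    dplyr::select("sample_id", "locus_id", tract_start = "start",
                  tract_end = "end", tract_length = "length")
  out <- dplyr::left_join(recs[, c("sample_id", "locus_id", "chrom", "pos")],
                          hit, by = c("sample_id", "locus_id"))
  out$class <- classify_length(dplyr::coalesce(out$tract_length, 0), spec)
  out
}

#' Mean per-class genome fractions across individuals
#'
#' For each individual, the summed length of its tracts in each class is
#' divided by L (see [compute_froh()] for the denominator modes); the
#' baseline class gets the remainder, so fractions sum to 1 per
#' individual. Fractions are then averaged across individuals, unweighted
#' ("average fraction of genome in each class across all dogs" — not the
#' pooled ratio, which weights inbred genomes more).
#'
#' @param tracts Tract tibble (autosomes are used).
#' @param panel The panel the tracts were called on.
#' @param spec A [length_class_spec()].
#' @param L_mode,L_fixed Denominator, as in [compute_froh()].
#' @return Tibble `class`, `genome_fraction` (proportions summing to 1).
#' @export
genome_fractions <- function(tracts, panel, spec = length_class_spec(),
                             L_mode = c("marker_span", "fixed"), L_fixed = NULL) {
  L_mode <- match.arg(L_mode)
  chroms <- intersect(unique(panel$map$chrom), autosome_labels())
  if (L_mode == "marker_span") {
    span <- panel$map |>
      dplyr::filter(.data$chrom %in% chroms) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$pos) - min(.data$pos) + 1)
    L <- sum(span$len)
  } else {
    if (is.null(L_fixed)) stop("L_mode = 'fixed' requires L_fixed")
    L <- sum(L_fixed[chroms])
  }
  tr <- tracts[tracts$chrom %in% chroms, ]
  tr$class <- classify_length(tr$length, spec)
  per_dog <- tr |>
    dplyr::group_by(.data$sample_id, .data$class) |>
    dplyr::summarise(bp = sum(.data$length), .groups = "drop") |>
    tidyr::complete(sample_id = panel$samples$sample_id,
                    class = factor(spec$labels, levels = spec$labels),
                    fill = list(bp = 0)) |>
    dplyr::mutate(frac = .data$bp / L)
  covered <- per_dog |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(tot = sum(.data$frac))
  stopifnot(all(covered$tot <= 1 + 1e-9))
  per_dog$frac[per_dog$class == spec$labels[1]] <-
    1 - covered$tot[match(per_dog$sample_id[per_dog$class == spec$labels[1]],
                          covered$sample_id)]
  per_dog |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(genome_fraction = mean(.data$frac)) |>
    dplyr::arrange(.data$class)
}

#' Relative risk of harbouring an at-risk genotype, per length class
#'
#' The density of at-risk genotypes per unit of genome in each class,
#' relative to the baseline (non-ROH) class:
#' `RR(c) = [atrisk(c) / genome(c)] / [atrisk(SUB) / genome(SUB)]`, so
#' `RR(SUB) = 1` by construction. A zero genome fraction makes RR
#' undefined (`NA`). RR is invariant to rescaling either set of fractions
#' by a common factor, so percentages and proportions give the same
#' answer.
#'
#' @param fractions Tibble with columns `class`, `genome_fraction`,
#'   `atrisk_fraction` (the first row / first factor level is the
#'   baseline).
#' @return The input with an `rr` column appended.
#' @export
relative_risk <- function(fractions) {
  stopifnot(all(c("class", "genome_fraction", "atrisk_fraction") %in% names(fractions)))
  base_rate <- fractions$atrisk_fraction[1] / fractions$genome_fraction[1]
  rr <- (fractions$atrisk_fraction / fractions$genome_fraction) / base_rate
  rr[1] <- 1  # baseline, by construction (even if its at-risk fraction is 0)
  rr[fractions$genome_fraction == 0] <- NA_real_
  dplyr::mutate(fractions, rr = rr)
}

#' Build the per-class enrichment table for one cohort
#'
#' Combines [genome_fractions()], the at-risk class distribution from
#' [classify_at_risk()], and [relative_risk()] into one table (percentages
#' sum to 100 per column).
#'
#' @param disease A `disease_table`.
#' @param tracts Tract tibble from one caller.
#' @param panel The panel.
#' @param spec A [length_class_spec()].
#' @param cohort Label for the cohort (e.g. `"ALL"`, `"SOD1"`, `"OTHER"`).
#' @param L_mode,L_fixed See [genome_fractions()].
#' @return An `enrichment_table` tibble: `class`, `genome_pct`,
#'   `atrisk_pct`, `rr`, `cohort`, `caller`, with attribute `n_atrisk`.
#' @export
enrichment_table <- function(disease, tracts, panel, spec = length_class_spec(),
                             cohort = "ALL", L_mode = "marker_span", L_fixed = NULL) {
  gf <- genome_fractions(tracts, panel, spec, L_mode, L_fixed)
  cls <- classify_at_risk(disease, tracts, spec)
  ar <- as.data.frame(table(cls$class) / nrow(cls))
  out <- gf |>
    dplyr::mutate(atrisk_fraction = ar$Freq[match(.data$class, ar$Var1)]) |>
    relative_risk() |>
    dplyr::transmute(
      class = .data$class,
      genome_pct = 100 * .data$genome_fraction,
      atrisk_pct = 100 * .data$atrisk_fraction,
      rr = .data$rr,
      cohort = cohort,
      caller = if (nrow(tracts) > 0) tracts$caller[1] else NA_character_
    )
  attr(out, "n_atrisk") <- nrow(cls)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Cumulative tract-length distribution
#'
#' Tracts ordered longest to shortest: the curve gives, for each length x,
#' the fraction of tracts (or of total tract length, with
#' `weight = "length"`) at least x long. Evaluated at the sorted unique
#' tract lengths; non-increasing in x by construction.
#'
#' @param tracts Tract tibble (or any tibble with a `length` column).
#' @param weight `"count"` (default) or `"length"`.
#' @return A `roh_cumulative` tibble: `length`, `frac_ge`.
#' @export
cumulative_curve <- function(tracts, weight = c("count", "length")) {
  weight <- match.arg(weight)
  if (nrow(tracts) == 0) {
    return(structure(tibble::tibble(length = numeric(), frac_ge = numeric()),
                     class = c("roh_cumulative", class(tibble::tibble()))))
  }
  out <- eval_cumulative(tracts$length, sort(unique(tracts$length)), weight)
  structure(out, class = c("roh_cumulative", class(out)))
}

eval_cumulative <- function(lengths, grid, weight = "count") {
  s <- sort(lengths)
  if (weight == "count") {
    n_lt <- findInterval(grid - 0.5, s)
    frac <- (length(s) - n_lt) / length(s)
  } else {
    cw <- cumsum(s)
    n_lt <- findInterval(grid - 0.5, s)
    tot <- sum(s)
    frac <- (tot - c(0, cw)[n_lt + 1]) / tot
  }
  tibble::tibble(length = grid, frac_ge = frac)
}

#' Resampling null for disease-overlapping tract lengths
#'
#' Draws `n_reps` sets of `k` tracts uniformly *without replacement* from
#' the cohort's full tract set — mimicking the sampling of the k
#' disease-overlapping tracts — and computes each replicate's cumulative
#' length curve on the full set's length grid. Returns the pointwise
#' envelope (min/max and quantiles). An observed curve lying outside the
#' min–max envelope anywhere is a stronger departure than any of the
#' `n_reps` random draws.
#'
#' @param tracts Full tract set for the cohort.
#' @param k Number of tracts per replicate (the observed count of
#'   disease-overlapping tracts).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param weight Curve weighting, as in [cumulative_curve()].
#' @return A `roh_null` list: `envelope` (tibble `length`, `lo`, `hi`,
#'   `q025`, `q975`), `k`, `n_reps`, `full_curve`.
#' @export
resample_null <- function(tracts, k, n_reps = 1000, seed, weight = "count") {
  if (missing(seed)) stop("resample_null: a seed is required")
  n <- nrow(tracts)
  if (k > n) stop("k (", k, ") exceeds the number of tracts (", n, ")")
  if (k < 1) stop("k must be >= 1")
  set.seed(seed)
  grid <- sort(unique(tracts$length))
  mat <- matrix(NA_real_, nrow = n_reps, ncol = length(grid))
  for (r in seq_len(n_reps)) {
    smp <- tracts$length[sample.int(n, k)]
    mat[r, ] <- eval_cumulative(smp, grid, weight)$frac_ge
  }
  new_roh_null(mat, grid, tracts$length, k, n_reps, weight)
}

new_roh_null <- function(mat, grid, all_lengths, k, n_reps, weight) {
  envelope <- tibble::tibble(
    length = grid,
    lo = apply(mat, 2, min),
    hi = apply(mat, 2, max),
    q025 = apply(mat, 2, stats::quantile, 0.025),
    q975 = apply(mat, 2, stats::quantile, 0.975)
  )
  structure(list(envelope = envelope, k = k, n_reps = n_reps,
                 full_curve = eval_cumulative(all_lengths, grid, weight),
                 weight = weight),
            class = "roh_null")
}

#' Random-locus null for locus-anchored tract sets
#'
#' The set of tracts overlapping a fixed genomic position is a
#' *length-biased*, spatially correlated sample of the cohort's tracts (a
#' tract covers a point with probability proportional to its length, and
#' covering tracts near a chromosome end are truncated), so comparing it
#' against the uniform resampling null of [resample_null()] rejects even a
#' neutral locus. The matched null asks instead: "does this locus look
#' like a *random* locus?" Each replicate stabs a marker position drawn
#' uniformly from the map, collects the tracts covering it across samples,
#' and (when more than `k` cover it) subsamples `k` of them, mirroring how
#' an observed locus-anchored set of size `k` arises.
#'
#' @param tracts Full tract set for the cohort.
#' @param panel The panel (its marker map supplies the stab positions).
#' @param k Size cap per replicate: the observed locus-anchored count.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param weight Curve weighting, as in [cumulative_curve()].
#' @return A `roh_null`, as for [resample_null()].
#' @export
locus_null <- function(tracts, panel, k, n_reps = 1000, seed, weight = "count") {
  if (missing(seed)) stop("locus_null: a seed is required")
  if (nrow(tracts) == 0) stop("no tracts")
  set.seed(seed)
  grid <- sort(unique(tracts$length))
  mat <- matrix(NA_real_, nrow = n_reps, ncol = length(grid))
  by_chrom <- split(tracts, tracts$chrom)
  r <- 1L
  while (r <= n_reps) {
    j <- sample.int(nrow(panel$map), 1)
    ch <- panel$map$chrom[j]; p <- panel$map$pos[j]
    trc <- by_chrom[[ch]]
    if (is.null(trc)) next
    cov <- trc$length[trc$start <= p & trc$end >= p]
    if (length(cov) < 1) next
    if (length(cov) > k) cov <- cov[sample.int(length(cov), k)]
    mat[r, ] <- eval_cumulative(cov, grid, weight)$frac_ge
    r <- r + 1L
  }
  new_roh_null(mat, grid, tracts$length, k, n_reps, weight)
}

#' Does an observed tract set leave the resampling envelope?
#'
#' Evaluates the observed cumulative curve on the null's length grid and
#' reports whether it escapes the min–max envelope at any grid point.
#'
#' @param null A `roh_null` from [resample_null()].
#' @param observed Tract tibble (the disease-overlapping tracts).
#' @return List: `outside` (logical), `n_outside` (grid points escaped),
#'   `curve` (observed curve on the grid).
#' @export
envelope_test <- function(null, observed) {
  obs <- eval_cumulative(observed$length, null$envelope$length, null$weight)
  out <- obs$frac_ge > null$envelope$hi + 1e-12 |
    obs$frac_ge < null$envelope$lo - 1e-12
  list(outside = any(out), n_outside = sum(out), curve = obs)
}

#' @export
print.roh_null <- function(x, ...) {
  cat("<roh_null> ", x$n_reps, " replicates of ", x$k, " tracts; grid of ",
      nrow(x$envelope), " lengths\n", sep = "")
  invisible(x)
}

#' @method glance roh_null
#' @export
glance.roh_null <- function(x, ...) {
  tibble::tibble(k = x$k, n_reps = x$n_reps, n_grid = nrow(x$envelope),
                 weight = x$weight)
}
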