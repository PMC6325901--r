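#' Parameters for the zero-heterozygote scan caller
#'
#' The scan caller declares a run of homozygosity wherever a stretch of
#' markers contains no heterozygous call and spans at least `min_span` bp,
#' then merges neighbouring runs separated by less than `merge_gap` bp
#' (small gaps of clustered heterozygotes typically reflect genotyping error
#' or copy-number variants, most of which are < 50 kb), and finally drops
#' merged tracts containing fewer than `min_markers` array markers (guarding
#' against spurious calls in marker-poor regions).
#'
#' @param min_span Minimum run length in bp (length = end - start + 1).
#' @param merge_gap Runs closer than this many bp are unioned; the gap must
#'   be *strictly* smaller. Doubling it (50 kb to 100 kb) is the standard
#'   sensitivity check.
#' @param min_markers Minimum number of markers inside a merged tract.
#' @param missing_policy `"BREAK"`: a missing call terminates a run
#'   (appropriate for unimputed data); `"IGNORE"`: missing calls are
#'   treated as homozygous.
#' @return A `scan_params` list.
#' @export
scan_params <- function(min_span = 500000, merge_gap = 50000, min_markers = 41,
                        missing_policy = c("BREAK", "IGNORE")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(min_span > 0, merge_gap > 0, min_markers >= 1, merge_gap < min_span)
  structure(list(min_span = min_span, merge_gap = merge_gap,
                 min_markers = as.integer(min_markers),
                 missing_policy = missing_policy),
            class = "scan_params")
}

param_fingerprint <- function(p) {
  paste(vapply(p, function(v) paste0(format(v, scientific = FALSE), collapse = ","), ""),
        collapse = ";")
}

#' Find maximal homozygous runs on one chromosome
#'
#' Lowest-level step of the scan caller: maximal stretches of consecutive
#' markers with no heterozygous call (and, under the `BREAK` missing
#' policy, no missing call), reported from first to last marker of the
#' stretch, keeping only runs of length `>= min_span` bp.
#'
#' @param calls Integer vector of genotype codes (0/1/2/NA) for one sample
#'   on one chromosome, in map order.
#' @param pos Numeric vector of marker positions (bp), sorted increasing.
#' @param params A [scan_params()].
#' @return Tibble `start`, `end`, `n_markers` (one row per raw run).
#' @export
find_homozygous_runs <- function(calls, pos, params = scan_params()) {
  stopifnot(length(calls) == length(pos))
  if (length(calls) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(), n_markers = integer()))
  }
  bad <- calls == 1L
  bad[is.na(bad)] <- params$missing_policy == "BREAK"
  r <- rle(!bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values
  s <- starts[ok]; e <- ends[ok]
  span <- pos[e] - pos[s] + 1
  keep <- span >= params$min_span
  tibble::tibble(start = pos[s][keep], end = pos[e][keep],
                 n_markers = (e - s + 1L)[keep])
}

#' Merge neighbouring runs separated by a small gap
#'
#' Runs on the same sample and chromosome whose gap (next start minus
#' previous end) is strictly less than `merge_gap` are unioned,
#' transitively; the merged tract spans from the first start to the last
#' end. A gap of exactly `merge_gap` is *not* merged.
#'
#' @param runs Tibble with `start`, `end`, sorted by `start` (one sample,
#'   one chromosome).
#' @param params A [scan_params()].
#' @return Tibble `start`, `end` of merged runs.
#' @export
merge_runs <- function(runs, params = scan_params()) {
  if (nrow(runs) <= 1) return(runs[, c("start", "end")])
  gap <- runs$start[-1] - runs$end[-nrow(runs)]
  grp <- cumsum(c(1, gap >= params$merge_gap))
  tibble::tibble(start = runs$start, end = runs$end, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end)) |>
    dplyr::select("start", "end")
}

#' Apply the marker-count filter to merged runs
#'
#' Counts every array marker with position inside `[start, end]` (including
#' heterozygous markers inside merged gaps) and drops tracts with fewer
#' than `min_markers`.
#'
#' @param merged Tibble `start`, `end` (one sample, one chromosome).
#' @param pos Sorted marker positions for that chromosome.
#' @param params A [scan_params()].
#' @return Tibble `start`, `end`, `length`, `n_markers`.
#' @export
filter_tracts <- function(merged, pos, params = scan_params()) {
  n_mark <- findInterval(merged$end, pos) - findInterval(merged$start - 1, pos)
  out <- tibble::tibble(start = merged$start, end = merged$end,
                        length = merged$end - merged$start + 1,
                        n_markers = as.integer(n_mark))
  out[out$n_markers >= params$min_markers, ]
}

#' Call runs of homozygosity with the scan caller
#'
#' Composition of [find_homozygous_runs()], [merge_runs()] and
#' [filter_tracts()] over every sample and chromosome of a panel. Male
#' chromosome X is skipped (hemizygous X is homozygous by construction, so
#' calling ROH there would be artifactual).
#'
#' @param panel A [genotype_panel()].
#' @param params A [scan_params()].
#' @return A tibble of ROH tracts: `sample_id`, `chrom`, `start`, `end`,
#'   `length`, `n_markers`, `caller` (`"SCAN"`), `params` (fingerprint).
#'   Tracts of one sample on one chromosome are disjoint and sorted.
#' @export
scan_roh <- function(panel, params = scan_params()) {
  stopifnot(inherits(panel, "genotype_panel"))
  chroms <- unique(panel$map$chrom)
  males <- panel$samples$sex == "M"
  res <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    mi <- which(panel$map$chrom == chroms[ci])
    pos <- panel$map$pos[mi]
    skip_males <- chroms[ci] == "X"
    per_sample <- vector("list", n_samples(panel))
    for (si in seq_len(n_samples(panel))) {
      if (skip_males && males[si]) next
      raw <- find_homozygous_runs(panel$geno[si, mi], pos, params)
      if (nrow(raw) == 0) next
      tr <- filter_tracts(merge_runs(raw, params), pos, params)
      if (nrow(tr) == 0) next
      tr$sample_id <- panel$samples$sample_id[si]
      per_sample[[si]] <- tr
    }
    out <- dplyr::bind_rows(per_sample)
    if (nrow(out) > 0) out$chrom <- chroms[ci]
    res[[ci]] <- out
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(), length = numeric(),
                          n_markers = integer(), caller = character(),
                          params = character()))
  }
  out$caller <- "SCAN"
  out$params <- param_fingerprint(params)
  dplyr::arrange(out[, c("sample_id", "chrom", "start", "end", "length",
                         "n_markers", "caller", "params")],
                 .data$sample_id, match(.data$chrom, valid_chromosomes()), .data$start)
}
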