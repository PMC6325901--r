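#' Parameters for the sliding-window ROH caller
#'
#' The window caller follows the classic SNP-count sliding-window scheme:
#' windows of `window_snps` markers slide one marker at a time; a window is
#' a "hit" when it contains at most `window_het` heterozygous and at most
#' `window_missing` missing calls; each SNP's hit proportion is the
#' fraction of windows containing it that are hits; SNPs with proportion at
#' least `hit_threshold` qualify; maximal stretches of qualifying SNPs,
#' trimmed to their outermost homozygous calls, are reported when they
#' contain at least `min_snps` markers and span at least `min_kb` kb.
#' Marker-density and physical-gap checks are deliberately disabled (not
#' merely defaulted high): the density of a modern array makes them
#' redundant and the marker-count filter plays that role.
#'
#' @param window_snps Window size in SNPs.
#' @param window_het Maximum heterozygous calls per hit window.
#' @param window_missing Maximum missing calls per hit window.
#' @param hit_threshold Minimum per-SNP hit proportion.
#' @param min_snps Minimum SNPs in a reported segment.
#' @param min_kb Minimum segment span in kb.
#' @return A `window_params` list (fields `density_check` and `gap_check`
#'   are fixed to `"disabled"`).
#' @export
window_params <- function(window_snps = 41, window_het = 0, window_missing = 0,
                          hit_threshold = 0.05, min_snps = 41, min_kb = 500) {
  stopifnot(window_snps >= 1, window_het >= 0, window_missing >= 0,
            hit_threshold >= 0, hit_threshold <= 1, min_snps >= 1, min_kb > 0)
  structure(list(window_snps = as.integer(window_snps),
                 window_het = as.integer(window_het),
                 window_missing = as.integer(window_missing),
                 hit_threshold = hit_threshold,
                 min_snps = as.integer(min_snps), min_kb = min_kb,
                 density_check = "disabled", gap_check = "disabled"),
            class = "window_params")
}

# One sample, one chromosome. Returns start/end/n_markers rows.
windowed_roh_chrom <- function(calls, pos, p) {
  n <- length(calls)
  w <- p$window_snps
  empty <- tibble::tibble(start = numeric(), end = numeric(), n_markers = integer())
  if (n < w) return(empty)
  het <- as.integer(calls == 1L & !is.na(calls))
  mis <- as.integer(is.na(calls))
  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  starts <- seq_len(n - w + 1L)
  hit <- (chet[starts + w] - chet[starts]) <= p$window_het &
    (cmis[starts + w] - cmis[starts]) <= p$window_missing
  chit <- c(0, cumsum(hit))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)           # first window index containing SNP j
  hi <- pmin(j, n - w + 1L)            # last window index containing SNP j
  n_win <- hi - lo + 1L
  n_hit <- chit[hi + 1L] - chit[lo]
  qual <- n_hit / n_win >= p$hit_threshold
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  segs <- which(r$values)
  if (length(segs) == 0) return(empty)
  out_s <- integer(0); out_e <- integer(0)
  hom <- !is.na(calls) & calls != 1L
  for (k in segs) {
    e <- ends[k]; s <- e - r$lengths[k] + 1L
    idx <- s:e
    hom_idx <- idx[hom[idx]]
    if (length(hom_idx) == 0) next
    s2 <- hom_idx[1]; e2 <- hom_idx[length(hom_idx)]
    if (e2 - s2 + 1L < p$min_snps) next
    if (pos[e2] - pos[s2] + 1 < p$min_kb * 1000) next
    out_s <- c(out_s, s2); out_e <- c(out_e, e2)
  }
  tibble::tibble(start = pos[out_s], end = pos[out_e],
                 n_markers = out_e - out_s + 1L)
}

#' Call runs of homozygosity with the sliding-window caller
#'
#' See [window_params()] for the algorithm. Chromosomes with fewer markers
#' than one window produce no calls (a message notes this). Male chromosome
#' X is skipped as in [scan_roh()].
#'
#' @param panel A [genotype_panel()].
#' @param params A [window_params()].
#' @return Tibble of tracts in the same layout as [scan_roh()], with
#'   `caller = "WINDOWED"`.
#' @export
windowed_roh <- function(panel, params = window_params()) {
  stopifnot(inherits(panel, "genotype_panel"))
  chroms <- unique(panel$map$chrom)
  males <- panel$samples$sex == "M"
  res <- list()
  short_chroms <- character(0)
  for (ci in seq_along(chroms)) {
    mi <- which(panel$map$chrom == chroms[ci])
    if (length(mi) < params$window_snps) {
      short_chroms <- c(short_chroms, chroms[ci])
      next
    }
    pos <- panel$map$pos[mi]
    skip_males <- chroms[ci] == "X"
    for (si in seq_len(n_samples(panel))) {
      if (skip_males && males[si]) next
      tr <- windowed_roh_chrom(panel$geno[si, mi], pos, params)
      if (nrow(tr) == 0) next
      tr$sample_id <- panel$samples$sample_id[si]
      tr$chrom <- chroms[ci]
      res[[length(res) + 1L]] <- tr
    }
  }
  if (length(short_chroms) > 0) {
    message("windowed_roh: chromosome(s) shorter than one window, no calls: ",
            paste(short_chroms, collapse = ", "))
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(), length = numeric(),
                          n_markers = integer(), caller = character(),
                          params = character()))
  }
  out$length <- out$end - out$start + 1
  out$caller <- "WINDOWED"
  out$params <- param_fingerprint(params)
  dplyr::arrange(out[, c("sample_id", "chrom", "start", "end", "length",
                         "n_markers", "caller", "params")],
                 .data$sample_id, match(.data$chrom, valid_chromosomes()), .data$start)
}
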