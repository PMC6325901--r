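# Independent brute-force oracles. Deliberately naive (explicit loops,
# O(n^2) where that is the simplest correct thing) so they share no code
# with the package implementations they check.

# Enumerate-merge-filter oracle for the scan caller on one chromosome.
brute_scan <- function(calls, pos, min_span = 500000, merge_gap = 50000,
                       min_markers = 41, break_on_missing = TRUE) {
  n <- length(calls)
  bad <- rep(FALSE, n)
  for (i in seq_len(n)) {
    bad[i] <- (!is.na(calls[i]) && calls[i] == 1L) ||
      (is.na(calls[i]) && break_on_missing)
  }
  # all maximal runs of !bad
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!bad[i]) {
      j <- i
      while (j < n && !bad[j + 1L]) j <- j + 1L
      if (pos[j] - pos[i] + 1 >= min_span) runs[[length(runs) + 1L]] <- c(pos[i], pos[j])
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(runs) == 0) {
    return(data.frame(start = numeric(), end = numeric(), n_markers = integer()))
  }
  # transitive merge of runs with gap strictly below merge_gap
  merged <- list(runs[[1]])
  for (k in seq_along(runs)[-1]) {
    last <- merged[[length(merged)]]
    if (runs[[k]][1] - last[2] < merge_gap) {
      merged[[length(merged)]] <- c(last[1], runs[[k]][2])
    } else {
      merged[[length(merged) + 1L]] <- runs[[k]]
    }
  }
  out <- do.call(rbind, lapply(merged, function(m) {
    cnt <- 0L
    for (p in pos) if (p >= m[1] && p <= m[2]) cnt <- cnt + 1L
    data.frame(start = m[1], end = m[2], n_markers = cnt)
  }))
  out[out$n_markers >= min_markers, , drop = FALSE]
}

# Naive sliding-window caller for one chromosome (reference implementation
# of the same published algorithm, coded with explicit loops).
brute_windowed <- function(calls, pos, w = 41, max_het = 0, max_miss = 0,
                           thr = 0.05, min_snps = 41, min_kb = 500) {
  n <- length(calls)
  if (n < w) return(data.frame(start = numeric(), end = numeric(), n_markers = integer()))
  is_het <- !is.na(calls) & calls == 1L
  is_miss <- is.na(calls)
  n_win <- n - w + 1L
  hit <- logical(n_win)
  for (s in seq_len(n_win)) {
    idx <- s:(s + w - 1L)
    hit[s] <- sum(is_het[idx]) <= max_het && sum(is_miss[idx]) <= max_miss
  }
  qual <- logical(n)
  for (j in seq_len(n)) {
    wins <- intersect(seq_len(n_win), (j - w + 1L):j)
    qual[j] <- mean(hit[wins]) >= thr
  }
  segs <- list()
  j <- 1L
  while (j <= n) {
    if (qual[j]) {
      k <- j
      while (k < n && qual[k + 1L]) k <- k + 1L
      hom <- which(!is_het[j:k] & !is_miss[j:k]) + j - 1L
      if (length(hom) > 0) {
        s2 <- hom[1]; e2 <- hom[length(hom)]
        if (e2 - s2 + 1L >= min_snps && pos[e2] - pos[s2] + 1 >= min_kb * 1000) {
          segs[[length(segs) + 1L]] <-
            data.frame(start = pos[s2], end = pos[e2], n_markers = e2 - s2 + 1L)
        }
      }
      j <- k + 1L
    } else j <- j + 1L
  }
  if (length(segs) == 0) {
    return(data.frame(start = numeric(), end = numeric(), n_markers = integer()))
  }
  do.call(rbind, segs)
}

# Random single-chromosome call vector with het/missing at given rates.
random_calls <- function(n, p_het = 0.25, p_miss = 0) {
  u <- runif(n)
  calls <- ifelse(u < p_het, 1L, ifelse(runif(n) < 0.5, 0L, 2L))
  calls[runif(n) < p_miss] <- NA_integer_
  calls
}

# Small panel on one or more chromosomes from explicit call vectors.
toy_panel <- function(calls_by_sample, pos, chrom = "1", sex = NULL, breed = NULL) {
  n <- length(calls_by_sample)
  map <- tibble::tibble(chrom = chrom, marker_id = paste0("m", seq_along(pos)),
                        cm = pos / 1e6, pos = pos)
  samples <- tibble::tibble(
    sample_id = sprintf("T%02d", seq_len(n)),
    breed = if (is.null(breed)) NA_character_ else breed,
    sex = if (is.null(sex)) "F" else sex
  )
  geno <- do.call(rbind, calls_by_sample)
  genotype_panel(map, samples, geno)
}
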