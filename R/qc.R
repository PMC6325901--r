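#' LD pruning of a genotype panel
#'
#' Sliding-window linkage-disequilibrium pruning in the style of PLINK's
#' `--indep-pairwise`: within each window of `window_snps` markers
#' (advancing by `step_snps`), while any retained pair has squared
#' genotype-dosage correlation above `r2_max`, one member is removed. The
#' removal rule is deterministic: the marker with the lower minor-allele
#' frequency goes; on a tie, the one later in map order. Monomorphic
#' markers have undefined r² and are never removed for LD (r² treated as
#' 0). Passes repeat until no marker is removed, so the result is a fixed
#' point and pruning is idempotent.
#'
#' @param panel A [genotype_panel()].
#' @param window_snps,step_snps Window size and step, in SNPs.
#' @param r2_max Maximum tolerated pairwise r².
#' @return Character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(panel, window_snps = 200, step_snps = 100, r2_max = 0.90) {
  stopifnot(inherits(panel, "genotype_panel"), window_snps >= 2, step_snps >= 1)
  keep <- rep(TRUE, n_markers(panel))
  maf <- marker_maf(panel)
  for (ch in unique(panel$map$chrom)) {
    mi <- which(panel$map$chrom == ch)
    if (length(mi) < 2) next
    repeat {
      removed <- ld_prune_pass(panel$geno, mi[keep[mi]], maf,
                               window_snps, step_snps, r2_max)
      if (length(removed) == 0) break
      keep[removed] <- FALSE
    }
  }
  panel$map$marker_id[keep]
}

# One pass over one chromosome's retained marker indices; returns global
# indices removed.
ld_prune_pass <- function(geno, idx, maf, window_snps, step_snps, r2_max) {
  active <- rep(TRUE, length(idx))
  removed <- integer(0)
  s <- 1L
  repeat {
    win <- which(active)
    win <- win[win >= s & win < s + window_snps]
    if (length(win) >= 2) {
      for (a in seq_len(length(win) - 1L)) {
        if (!active[win[a]]) next
        for (b in seq((a + 1L), length(win))) {
          if (!active[win[a]]) break
          if (!active[win[b]]) next
          i <- idx[win[a]]; j <- idx[win[b]]
          r2 <- dosage_r2(geno[, i], geno[, j])
          if (!is.na(r2) && r2 > r2_max) {
            drop_local <- if (maf[i] < maf[j]) win[a]
            else if (maf[j] < maf[i]) win[b]
            else max(win[a], win[b])   # tie: later map position
            active[drop_local] <- FALSE
            removed <- c(removed, idx[drop_local])
          }
        }
      }
    }
    if (s + window_snps > length(idx)) break
    s <- s + step_snps
  }
  removed
}

dosage_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) return(NA_real_)
  v1 <- stats::var(g1[ok]); v2 <- stats::var(g2[ok])
  if (v1 == 0 || v2 == 0) return(0)   # monomorphic: never pruned for LD
  stats::cor(g1[ok], g2[ok])^2
}

marker_maf <- function(panel) {
  p <- colMeans(panel$geno, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Method-of-moments pairwise relatedness (PI_HAT)
#'
#' Estimates P(IBD = 0/1/2) for every sample pair from identity-by-state
#' counts, following the classic method-of-moments scheme (Purcell et al.
#' 2007, as in PLINK `--genome`, without the finite-sample allele-frequency
#' corrections): the expected number of IBS-0/1/2 markers under each IBD
#' state is computed from panel allele frequencies, and observed counts are
#' solved for the IBD-state proportions, which are clamped to `[0, 1]` and
#' renormalized. `PI_HAT = P(IBD=2) + P(IBD=1)/2`.
#'
#' Only autosomal markers that are polymorphic and non-missing in both
#' members of a pair are used; pairs with fewer than 100 such markers are
#' flagged `low_confidence`.
#'
#' @param panel A [genotype_panel()].
#' @param pairs Optional two-column matrix/tibble of sample id pairs;
#'   default all unordered pairs.
#' @return Tibble: `id1`, `id2`, `ibs0`, `ibs1`, `ibs2`, `p_ibd0`,
#'   `p_ibd1`, `p_ibd2`, `pi_hat`, `low_confidence`.
#' @export
pi_hat <- function(panel, pairs = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  auto <- which(panel$map$chrom %in% autosome_labels())
  g <- panel$geno[, auto, drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  q <- 1 - p
  # per-marker P(IBS = i | IBD = z)
  e00 <- 2 * p^2 * q^2
  e10 <- 4 * p^3 * q + 4 * p * q^3
  e20 <- 1 - e00 - e10
  e11 <- 2 * p^2 * q + 2 * p * q^2
  e21 <- 1 - e11

  ids <- panel$samples$sample_id
  if (is.null(pairs)) {
    cmb <- utils::combn(ids, 2)
    pairs <- tibble::tibble(id1 = cmb[1, ], id2 = cmb[2, ])
  } else {
    pairs <- tibble::as_tibble(as.data.frame(pairs, stringsAsFactors = FALSE))
    names(pairs)[1:2] <- c("id1", "id2")
  }
  res <- purrr::pmap_dfr(pairs, function(id1, id2, ...) {
    g1 <- g[match(id1, ids), ]
    g2 <- g[match(id2, ids), ]
    ok <- !is.na(g1) & !is.na(g2)
    d <- abs(g1[ok] - g2[ok])
    ibs <- integer(length(d))
    ibs[d == 2] <- 0L
    ibs[d == 1] <- 1L
    ibs[d == 0] <- 2L
    n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- sum(ibs == 2L)
    E00 <- sum(e00[ok]); E10 <- sum(e10[ok]); E20 <- sum(e20[ok])
    E11 <- sum(e11[ok]); E21 <- sum(e21[ok]); E22 <- sum(ok)
    p0 <- if (E00 > 0) n0 / E00 else 0
    p1 <- if (E11 > 0) (n1 - p0 * E10) / E11 else 0
    p2 <- (n2 - p0 * E20 - p1 * E21) / E22
    pr <- pmin(pmax(c(p0, p1, p2), 0), 1)
    pr <- pr / sum(pr)
    tibble::tibble(id1 = id1, id2 = id2, ibs0 = n0, ibs1 = n1, ibs2 = n2,
                   p_ibd0 = pr[1], p_ibd1 = pr[2], p_ibd2 = pr[3],
                   pi_hat = pr[3] + pr[2] / 2,
                   low_confidence = sum(ok) < 100)
  })
  res
}

#' Remove close relatives from a panel
#'
#' Given pairwise PI_HAT estimates, iteratively removes the sample involved
#' in the most over-threshold pairs (ties broken by lexicographic sample
#' id) until no pair exceeds the threshold — a greedy vertex cover of the
#' relatedness graph.
#'
#' @param panel A [genotype_panel()].
#' @param relatedness Output of [pi_hat()] (or any tibble with `id1`,
#'   `id2`, `pi_hat`). Computed from the panel if omitted.
#' @param threshold Maximum tolerated PI_HAT.
#' @return List: `panel` (reduced), `removed` (tibble `sample_id`,
#'   `n_pairs` logging each removal in order).
#' @export
drop_close_relatives <- function(panel, relatedness = NULL, threshold = 0.45) {
  if (is.null(relatedness)) relatedness <- pi_hat(panel)
  over <- relatedness[relatedness$pi_hat > threshold, c("id1", "id2")]
  removed <- tibble::tibble(sample_id = character(), n_pairs = integer())
  while (nrow(over) > 0) {
    deg <- sort(table(c(over$id1, over$id2)), decreasing = TRUE)
    top <- max(deg)
    victim <- sort(names(deg)[deg == top])[1]
    removed <- dplyr::bind_rows(removed,
                                tibble::tibble(sample_id = victim, n_pairs = as.integer(top)))
    over <- over[over$id1 != victim & over$id2 != victim, ]
  }
  keep <- setdiff(panel$samples$sample_id, removed$sample_id)
  list(panel = subset_panel(panel, samples = keep), removed = removed)
}
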