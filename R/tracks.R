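#' Local ROH density across the genome for one breed
#'
#' For each evaluation position, the fraction of the breed's sampled dogs
#' carrying a tract covering that position. The default grid is the marker
#' positions themselves (no interpolation between markers); a fixed-step
#' grid is available.
#'
#' @param tracts Tract tibble.
#' @param panel The panel (source of marker grid and breed metadata).
#' @param breed Breed label; its samples define the denominator `n`.
#' @param grid `"markers"` or a numeric step in bp for a regular grid.
#' @return A `density_track` tibble: `breed`, `chrom`, `pos`, `density`,
#'   `n`.
#' @export
roh_density <- function(tracts, panel, breed, grid = "markers") {
  ids <- panel$samples$sample_id[!is.na(panel$samples$breed) &
                                   panel$samples$breed == breed]
  if (length(ids) == 0) stop("no samples with breed '", breed, "'")
  n <- length(ids)
  tr <- tracts[tracts$sample_id %in% ids, ]
  out <- purrr::map_dfr(unique(panel$map$chrom), function(ch) {
    pos <- if (identical(grid, "markers")) {
      panel$map$pos[panel$map$chrom == ch]
    } else {
      rng <- range(panel$map$pos[panel$map$chrom == ch])
      seq(rng[1], rng[2], by = grid)
    }
    trc <- tr[tr$chrom == ch, ]
    # interval stabbing: #(starts <= p) - #(ends < p)
    cnt <- findInterval(pos, sort(trc$start)) - findInterval(pos - 0.5, sort(trc$end))
    tibble::tibble(breed = breed, chrom = ch, pos = pos, density = cnt / n, n = n)
  })
  stopifnot(all(out$density >= 0 & out$density <= 1))
  class(out) <- c("density_track", class(out))
  out
}

#' Detect ROH islands in a density track
#'
#' Maximal intervals where the density meets or exceeds `threshold` over a
#' span of at least `min_span` bp — regions where (nearly) the whole breed
#' sample is homozygous, reflecting drift or selective sweeps.
#'
#' @param track A `density_track` from [roh_density()].
#' @param threshold Minimum density.
#' @param min_span Minimum island span in bp.
#' @return Tibble: `breed`, `chrom`, `start`, `end`, `span`,
#'   `mean_density`.
#' @export
detect_islands <- function(track, threshold = 0.95, min_span = 1e6) {
  track |>
    dplyr::group_by(.data$breed, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      hi <- d$density >= threshold
      if (!any(hi)) {
        return(tibble::tibble(start = numeric(), end = numeric(),
                              span = numeric(), mean_density = numeric()))
      }
      r <- rle(hi)
      e <- cumsum(r$lengths); s <- e - r$lengths + 1L
      keep <- which(r$values)
      res <- purrr::map_dfr(keep, function(k) {
        tibble::tibble(start = d$pos[s[k]], end = d$pos[e[k]],
                       span = d$pos[e[k]] - d$pos[s[k]] + 1,
                       mean_density = mean(d$density[s[k]:e[k]]))
      })
      res[res$span >= min_span, ]
    }) |>
    dplyr::ungroup()
}

#' Per-breed cumulative ROH length distributions
#'
#' One cumulative tract-length curve (see [cumulative_curve()]) per breed,
#' for autosomal tracts or for chromosome X tracts in females only. Breeds
#' with no eligible samples or tracts are skipped with a warning.
#'
#' @param tracts Tract tibble.
#' @param samples Sample metadata (`sample_id`, `breed`, `sex`).
#' @param scope `"autosomes"` or `"chrx"`.
#' @param weight As in [cumulative_curve()].
#' @return Tibble: `breed`, `length`, `frac_ge`.
#' @export
breed_cumulative <- function(tracts, samples, scope = c("autosomes", "chrx"),
                             weight = "count") {
  scope <- match.arg(scope)
  keep <- if (scope == "autosomes") tracts$chrom != "X" else tracts$chrom == "X"
  tr <- tracts[keep, ]
  if (scope == "chrx") {
    females <- samples$sample_id[samples$sex == "F"]
    tr <- tr[tr$sample_id %in% females, ]
  }
  tr <- dplyr::left_join(tr, samples[, c("sample_id", "breed")], by = "sample_id")
  tr$breed <- dplyr::coalesce(tr$breed, "unknown")
  skipped <- setdiff(unique(stats::na.omit(samples$breed)), unique(tr$breed))
  if (length(skipped) > 0) {
    warning("breed(s) with no eligible tracts skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  tr |>
    dplyr::group_by(.data$breed) |>
    dplyr::group_modify(~ cumulative_curve(.x, weight)) |>
    dplyr::ungroup()
}
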