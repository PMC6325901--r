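#' Genomic inbreeding coefficient from ROH tracts
#'
#' For each individual j, `F_ROH = sum_k length(ROH_k) / L`: the summed
#' length of the individual's ROH tracts in scope divided by the genome (or
#' X chromosome) length L. Autosomal and X coefficients use disjoint tract
#' sets; chromosome X is computed in females only. Samples with no tracts
#' get `F_ROH = 0`.
#'
#' Two denominators are available. `"marker_span"` (default) is
#' self-contained: L is the summed per-chromosome distance from first to
#' last marker (+1). `"fixed"` takes user-supplied assembly lengths for
#' comparability across panels.
#'
#' @param tracts Tract tibble from [scan_roh()] or [windowed_roh()]. Mixing
#'   callers in one computation is an error.
#' @param panel The [genotype_panel()] the tracts were called on.
#' @param scope `"autosomes"` or `"chrx"` (females only).
#' @param L_mode `"marker_span"` or `"fixed"`.
#' @param L_fixed Named numeric vector of per-chromosome lengths (bp),
#'   required for `L_mode = "fixed"`.
#' @param par_interval Optional pseudoautosomal interval excluded from the
#'   X scope (tract overlap with it is subtracted and L reduced
#'   accordingly); without one, the whole X is used and a message notes the
#'   caveat.
#' @return Tibble: `sample_id`, `scope`, `froh`, `roh_bp`, `L_bp`, `L_mode`.
#' @export
compute_froh <- function(tracts, panel, scope = c("autosomes", "chrx"),
                         L_mode = c("marker_span", "fixed"), L_fixed = NULL,
                         par_interval = panel$par_interval) {
  scope <- match.arg(scope)
  L_mode <- match.arg(L_mode)
  if (nrow(tracts) > 0 && length(unique(tracts$caller)) > 1) {
    stop("tracts from more than one caller; compute F_ROH per caller")
  }
  if (nrow(tracts) > 0 && length(unique(tracts$params)) > 1) {
    stop("tracts from more than one parameter set; compute F_ROH per parameter set")
  }
  chroms <- if (scope == "autosomes") {
    intersect(unique(panel$map$chrom), autosome_labels())
  } else "X"
  if (scope == "chrx" && !"X" %in% panel$map$chrom) {
    stop("panel has no chromosome X markers")
  }
  if (scope == "chrx" && is.null(par_interval)) {
    message("compute_froh: no pseudoautosomal interval supplied; whole X used")
  }
  samples <- panel$samples
  if (scope == "chrx") samples <- samples[samples$sex == "F", ]

  if (L_mode == "marker_span") {
    span <- panel$map |>
      dplyr::filter(.data$chrom %in% chroms) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(len = max(.data$pos) - min(.data$pos) + 1)
    L_per_chrom <- stats::setNames(span$len, span$chrom)
  } else {
    if (is.null(L_fixed)) stop("L_mode = 'fixed' requires L_fixed")
    if (!all(chroms %in% names(L_fixed))) stop("L_fixed missing chromosome(s)")
    L_per_chrom <- L_fixed[chroms]
  }
  L <- sum(L_per_chrom)

  tr <- tracts[tracts$chrom %in% chroms & tracts$sample_id %in% samples$sample_id, ]
  if (scope == "chrx" && !is.null(par_interval) && nrow(tr) > 0) {
    ov <- pmax(0, pmin(tr$end, par_interval[2]) - pmax(tr$start, par_interval[1]) + 1)
    tr$length <- tr$length - ov
    L <- L - max(0, par_interval[2] - par_interval[1] + 1)
  }
  sums <- tr |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(roh_bp = sum(.data$length))
  out <- tibble::tibble(sample_id = samples$sample_id) |>
    dplyr::left_join(sums, by = "sample_id") |>
    dplyr::mutate(
      scope = if (scope == "autosomes") "AUTOSOMES" else "CHR_X",
      roh_bp = dplyr::coalesce(.data$roh_bp, 0),
      L_bp = L,
      froh = .data$roh_bp / L,
      L_mode = L_mode
    ) |>
    dplyr::select("sample_id", "scope", "froh", "roh_bp", "L_bp", "L_mode")
  stopifnot(all(out$froh >= 0 & out$froh <= 1))
  out
}

#' Summarise F_ROH by breed
#'
#' Groups per-sample F_ROH values by breed (samples without a breed label
#' fall into `"unknown"`) and reports the distribution per group. Empty
#' groups are skipped with a warning.
#'
#' @param froh Output of [compute_froh()].
#' @param samples Sample metadata tibble (`sample_id`, `breed`), e.g.
#'   `panel$samples`.
#' @return List of class `froh_summary`: `groups` (one row per breed: n,
#'   mean, median, quartiles) and `values` (per-sample F_ROH with breed).
#' @export
froh_by_group <- function(froh, samples) {
  values <- froh |>
    dplyr::left_join(samples[, c("sample_id", "breed")], by = "sample_id") |>
    dplyr::mutate(breed = dplyr::coalesce(.data$breed, "unknown"))
  groups <- values |>
    dplyr::group_by(.data$breed, .data$scope) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$froh),
      median = stats::median(.data$froh),
      q25 = stats::quantile(.data$froh, 0.25),
      q75 = stats::quantile(.data$froh, 0.75),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean))
  structure(list(groups = groups, values = values), class = "froh_summary")
}

#' @export
print.froh_summary <- function(x, ...) {
  cat("<froh_summary> ", nrow(x$groups), " group(s)\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' @method tidy froh_summary
#' @export
tidy.froh_summary <- function(x, ...) x$groups

#' @method glance froh_summary
#' @export
glance.froh_summary <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$groups), n_samples = nrow(x$values),
                 mean_froh = mean(x$values$froh))
}
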