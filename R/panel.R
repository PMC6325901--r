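#' Genotype panel container
#'
#' A `genotype_panel` bundles the three pieces every analysis stage shares: a
#' marker map, per-sample metadata, and a samples-by-markers matrix of diploid
#' calls. Calls are coded as the dosage of the "B" allele: `0` (homozygous A),
#' `1` (heterozygous), `2` (homozygous B), `NA` (missing). Which physical
#' allele is labelled "A" is arbitrary (the first allele observed at the
#' marker) but stable within a panel; downstream ROH analyses only ever ask
#' whether a call is heterozygous or missing.
#'
#' Coordinates are 1-based inclusive physical base pairs throughout, and a
#' tract length is always `end - start + 1`.
#'
#' @param map Tibble with columns `chrom` (character, `"1"`..`"38"` or
#'   `"X"`), `marker_id`, `cm` (genetic position, may be 0), `pos`
#'   (physical bp). Markers must be unique and, within a chromosome, sorted
#'   by strictly increasing `pos`.
#' @param samples Tibble with columns `sample_id`, `breed` (character or
#'   `NA`), `sex` (`"F"`, `"M"` or `"U"` for unknown).
#' @param geno Integer matrix, `nrow(samples)` x `nrow(map)`, values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names marker ids.
#' @param par_interval Optional length-2 numeric: the pseudoautosomal
#'   interval on chromosome X (bp, inclusive). Male heterozygous X calls
#'   outside this interval are flagged (attribute `x_het_flags`), never
#'   silently altered.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(map, samples, geno, par_interval = NULL) {
  map <- tibble::as_tibble(map)
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("chrom", "marker_id", "cm", "pos") %in% names(map)))
  if (!"breed" %in% names(samples)) samples$breed <- NA_character_
  if (!"sex" %in% names(samples)) samples$sex <- "U"
  samples$sex <- ifelse(samples$sex %in% c("F", "M"), samples$sex, "U")

  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker ids in map: ",
         paste(utils::head(map$marker_id[duplicated(map$marker_id)], 3), collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids: ",
         paste(utils::head(samples$sample_id[duplicated(samples$sample_id)], 3), collapse = ", "))
  }
  bad_chrom <- setdiff(unique(map$chrom), valid_chromosomes())
  if (length(bad_chrom) > 0) {
    stop("unknown chromosome label(s): ", paste(bad_chrom, collapse = ", "))
  }
  incr <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L) |>
    dplyr::pull("ok")
  if (!all(incr)) stop("marker positions must be strictly increasing within each chromosome")

  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(map)) {
    stop("geno must be ", nrow(samples), " x ", nrow(map),
         ", got ", nrow(geno), " x ", ncol(geno))
  }
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  rownames(geno) <- samples$sample_id
  colnames(geno) <- map$marker_id

  panel <- structure(
    list(map = map, samples = samples, geno = geno, par_interval = par_interval),
    class = "genotype_panel"
  )
  flags <- male_x_het_flags(panel)
  if (nrow(flags) > 0) {
    attr(panel, "x_het_flags") <- flags
    warning(nrow(flags), " heterozygous chrX call(s) in male sample(s) outside ",
            "the pseudoautosomal interval; flagged in attr(panel, 'x_het_flags')",
            call. = FALSE)
  }
  panel
}

valid_chromosomes <- function() c(as.character(1:38), "X")

autosome_labels <- function() as.character(1:38)

male_x_het_flags <- function(panel) {
  males <- panel$samples$sample_id[panel$samples$sex == "M"]
  x_idx <- which(panel$map$chrom == "X")
  if (length(males) == 0 || length(x_idx) == 0) {
    return(tibble::tibble(sample_id = character(), marker_id = character(), pos = numeric()))
  }
  if (!is.null(panel$par_interval)) {
    pos <- panel$map$pos[x_idx]
    x_idx <- x_idx[pos < panel$par_interval[1] | pos > panel$par_interval[2]]
  }
  if (length(x_idx) == 0) {
    return(tibble::tibble(sample_id = character(), marker_id = character(), pos = numeric()))
  }
  sub <- panel$geno[males, x_idx, drop = FALSE]
  hit <- which(sub == 1L, arr.ind = TRUE)
  tibble::tibble(
    sample_id = males[hit[, 1]],
    marker_id = panel$map$marker_id[x_idx[hit[, 2]]],
    pos = panel$map$pos[x_idx[hit[, 2]]]
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", nrow(x$samples), " samples x ", nrow(x$map),
      " markers (", length(unique(x$map$chrom)), " chromosomes)\n", sep = "")
  br <- unique(stats::na.omit(x$samples$breed))
  if (length(br) > 0) cat("  breeds: ", paste(utils::head(br, 8), collapse = ", "),
                          if (length(br) > 8) ", ..." else "", "\n", sep = "")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missingness: %.3f%%; heterozygosity: %.3f\n",
              100 * miss, mean(x$geno == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Number of samples / markers in a panel
#' @param panel A `genotype_panel`.
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' @rdname n_samples
#' @export
n_markers <- function(panel) nrow(panel$map)

#' Subset a panel by samples and/or markers
#'
#' @param panel A `genotype_panel`.
#' @param samples Character vector of sample ids to keep (default all).
#' @param markers Character vector of marker ids to keep (default all).
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(panel)) else match(samples, panel$samples$sample_id)
  mi <- if (is.null(markers)) seq_len(n_markers(panel)) else match(markers, panel$map$marker_id)
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(mi)) stop("unknown marker id(s)")
  mi <- sort(mi)  # preserve map order
  genotype_panel(panel$map[mi, ], panel$samples[si, ],
                 panel$geno[si, mi, drop = FALSE], panel$par_interval)
}

#' Tidy a genotype panel into long format
#'
#' One row per sample x marker with the call spelled out. Intended for small
#' panels (plots, toy examples); the matrix form is the working
#' representation.
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `marker_id`, `chrom`, `pos`,
#'   `call` (`"HOM_A"`, `"HET"`, `"HOM_B"`, `"MISSING"`).
#' @method tidy genotype_panel
#' @export
tidy.genotype_panel <- function(x, ...) {
  calls <- c("HOM_A", "HET", "HOM_B")
  tibble::tibble(
    sample_id = rep(x$samples$sample_id, times = n_markers(x)),
    marker_id = rep(x$map$marker_id, each = n_samples(x)),
    chrom = rep(x$map$chrom, each = n_samples(x)),
    pos = rep(x$map$pos, each = n_samples(x)),
    call = ifelse(is.na(as.vector(x$geno)), "MISSING", calls[as.vector(x$geno) + 1L])
  )
}

#' One-row summary of a genotype panel
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return A one-row tibble: sample, marker and chromosome counts,
#'   missingness and mean heterozygosity.
#' @method glance genotype_panel
#' @export
glance.genotype_panel <- function(x, ...) {
  tibble::tibble(
    n_samples = n_samples(x),
    n_markers = n_markers(x),
    n_chrom = length(unique(x$map$chrom)),
    missingness = mean(is.na(x$geno)),
    het_rate = mean(x$geno == 1L, na.rm = TRUE)
  )
}
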