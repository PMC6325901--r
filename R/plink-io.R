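#' Read a PLINK text .ped/.map pair
#'
#' Parses the PLINK 1.x text dialect: a 4-column whitespace-delimited .map
#' (chromosome, marker id, genetic position in cM, physical position in bp)
#' and a .ped with six leading fields (family, individual, father, mother,
#' sex, phenotype) followed by two allele fields per marker. `0 0` is the
#' missing genotype. Alleles are normalized per marker so that the first
#' non-missing allele observed becomes allele "A"; ROH analyses only use
#' het / non-het status, so the labelling is arbitrary but stable.
#'
#' Markers are sorted by position within each chromosome; if the input .map
#' was unsorted a message notes the re-sort. Sex codes 1/M and 2/F are
#' recognised; anything else is "U".
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @param par_interval Optional pseudoautosomal interval on X, passed through
#'   to [genotype_panel()].
#' @return A [genotype_panel()].
#' @export
read_plink <- function(ped_path, map_path, par_interval = NULL) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf != 4L)) {
    stop(".map line ", which(nf != 4L)[1], " has ", nf[nf != 4L][1],
         " fields, expected 4")
  }
  map <- tibble::tibble(
    chrom = vapply(map_fields, `[[`, "", 1L),
    marker_id = vapply(map_fields, `[[`, "", 2L),
    cm = as.numeric(vapply(map_fields, `[[`, "", 3L)),
    pos = as.numeric(vapply(map_fields, `[[`, "", 4L))
  )
  map$chrom <- normalize_chrom(map$chrom)
  bad <- setdiff(unique(map$chrom), valid_chromosomes())
  if (length(bad) > 0) stop("unknown chromosome label(s) in .map: ", paste(bad, collapse = ", "))
  if (anyDuplicated(map$marker_id)) stop("duplicate marker id(s) in .map")
  ord <- order(match(map$chrom, valid_chromosomes()), map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    message("read_plink: .map was not position-sorted within chromosomes; re-sorted")
  }
  map <- map[ord, ]
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  sample_id <- character(n)
  sex <- character(n)
  breed <- rep(NA_character_, n)
  # allele seen first at each marker becomes "A"
  allele_a <- rep(NA_character_, m)
  allele_b <- rep(NA_character_, m)

  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      stop(".ped line ", i, " has ", length(f), " fields, expected ", 6L + 2L * m)
    }
    sample_id[i] <- f[2]
    sex[i] <- c("1" = "M", "2" = "F")[f[5]]
    if (is.na(sex[i])) sex[i] <- c("M" = "M", "F" = "F")[toupper(f[5])]
    if (is.na(sex[i])) sex[i] <- "U"
    if (f[1] != f[2] && f[1] != "0" && f[1] != "FAM") breed[i] <- f[1]

    a1 <- f[seq(7L, by = 2L, length.out = m)][ord]
    a2 <- f[seq(8L, by = 2L, length.out = m)][ord]
    miss <- a1 == "0" | a2 == "0"
    if (any(a1 == "0" & a2 != "0") || any(a2 == "0" & a1 != "0")) {
      warning(".ped line ", i, ": half-missing genotype(s) treated as missing",
              call. = FALSE)
    }
    obs <- !miss
    new_a <- obs & is.na(allele_a)
    allele_a[new_a] <- a1[new_a]
    other <- obs & !is.na(allele_a) & a1 != allele_a & is.na(allele_b)
    allele_b[other] <- a1[other]
    other2 <- obs & !is.na(allele_a) & a2 != allele_a & is.na(allele_b)
    allele_b[other2] <- a2[other2]
    tri <- obs & !is.na(allele_b) &
      ((a1 != allele_a & a1 != allele_b) | (a2 != allele_a & a2 != allele_b))
    if (any(tri)) {
      stop(".ped line ", i, ": more than two alleles at marker ",
           map$marker_id[which(tri)[1]])
    }
    b1 <- !is.na(allele_b) & a1 == allele_b
    b2 <- !is.na(allele_b) & a2 == allele_b
    g <- b1 + b2
    g[miss] <- NA_integer_
    geno[i, ] <- as.integer(g)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id in .ped: ", sample_id[duplicated(sample_id)][1])
  }
  samples <- tibble::tibble(sample_id = sample_id, breed = breed, sex = sex)
  genotype_panel(map, samples, geno, par_interval = par_interval)
}

normalize_chrom <- function(x) {
  x <- sub("^chr", "", x, ignore.case = TRUE)
  x[x %in% c("39", "x")] <- "X"
  x
}

#' Write a panel as PLINK text .ped/.map
#'
#' The inverse of [read_plink()]: alleles are written as `A`/`B` (the
#' normalized labels), missing calls as `0 0`, sex as 1 (male) / 2 (female) /
#' 0 (unknown). Reading the files back reproduces the panel's calls exactly,
#' and re-writing a just-read panel reproduces the .map byte for byte.
#'
#' @param panel A [genotype_panel()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink <- function(panel, ped_path, map_path) {
  map_lines <- sprintf("%s\t%s\t%s\t%s",
                       panel$map$chrom, panel$map$marker_id,
                       format(panel$map$cm, trim = TRUE, scientific = FALSE),
                       format(panel$map$pos, trim = TRUE, scientific = FALSE))
  writeLines(map_lines, map_path)

  sexcode <- c(M = "1", F = "2", U = "0")[panel$samples$sex]
  fam <- ifelse(is.na(panel$samples$breed), panel$samples$sample_id, panel$samples$breed)
  gt <- c("A A", "A B", "B B")
  ped_lines <- vapply(seq_len(n_samples(panel)), function(i) {
    g <- panel$geno[i, ]
    cells <- ifelse(is.na(g), "0 0", gt[g + 1L])
    paste(fam[i], panel$samples$sample_id[i], "0", "0", sexcode[i], "-9",
          paste(cells, collapse = " "))
  }, "")
  writeLines(ped_lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a recessive disease locus / at-risk genotype table
#'
#' A single delimited text file (tab or comma, with header) with one row per
#' at-risk record and columns `sample_id`, `locus_id`, `chrom`, `pos`, and
#' optionally `risk_allele`. Rows with an empty `sample_id` declare a locus
#' with no at-risk carriers. Duplicate (sample, locus) rows are collapsed
#' with a warning. If a panel is supplied, sample ids and locus positions
#' are validated against it: unknown sample ids are an error, loci outside
#' the marker span of their chromosome are flagged `off_grid`.
#'
#' @param path Path to the table.
#' @param panel Optional [genotype_panel()] for validation.
#' @return A `disease_table`: list of tibbles `loci` (locus_id, chrom, pos,
#'   risk_allele, off_grid) and `records` (sample_id, locus_id).
#' @export
read_disease_table <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  need <- c("sample_id", "locus_id", "chrom", "pos")
  if (!all(need %in% names(df))) {
    stop("disease table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"risk_allele" %in% names(df)) df$risk_allele <- NA_character_
  df$pos <- as.numeric(df$pos)
  df$chrom <- normalize_chrom(df$chrom)
  disease_table(
    loci = dplyr::distinct(tibble::as_tibble(df),
                           .data$locus_id, .data$chrom, .data$pos, .data$risk_allele),
    records = tibble::as_tibble(df)[df$sample_id != "" & !is.na(df$sample_id),
                                    c("sample_id", "locus_id")],
    panel = panel
  )
}

#' Construct a disease table from tibbles
#'
#' @param loci Tibble: `locus_id`, `chrom`, `pos`, optional `risk_allele`.
#' @param records Tibble: `sample_id`, `locus_id` — one row per at-risk
#'   (homozygous risk) genotype observation.
#' @param panel Optional panel for validation (see [read_disease_table()]).
#' @return A `disease_table`.
#' @export
disease_table <- function(loci, records, panel = NULL) {
  loci <- tibble::as_tibble(loci)
  if (!"risk_allele" %in% names(loci)) loci$risk_allele <- NA_character_
  records <- tibble::as_tibble(records)
  if (anyDuplicated(loci$locus_id)) stop("duplicate locus id(s)")
  ndup <- nrow(records) - nrow(dplyr::distinct(records))
  if (ndup > 0) {
    warning(ndup, " duplicate (sample, locus) record(s) collapsed", call. = FALSE)
    records <- dplyr::distinct(records)
  }
  unknown <- setdiff(records$locus_id, loci$locus_id)
  if (length(unknown) > 0) {
    stop("at-risk record(s) reference unknown locus: ", paste(unknown, collapse = ", "))
  }
  loci$off_grid <- FALSE
  if (!is.null(panel)) {
    bad_s <- setdiff(records$sample_id, panel$samples$sample_id)
    if (length(bad_s) > 0) {
      stop("at-risk record(s) reference unknown sample: ", paste(bad_s, collapse = ", "))
    }
    span <- panel$map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(lo = min(.data$pos), hi = max(.data$pos))
    loci <- dplyr::left_join(loci, span, by = "chrom")
    loci$off_grid <- is.na(loci$lo) | loci$pos < loci$lo | loci$pos > loci$hi
    if (any(loci$off_grid)) {
      warning(sum(loci$off_grid), " locus/loci fall outside the marker span and are flagged off_grid",
              call. = FALSE)
    }
    loci$lo <- loci$hi <- NULL
  }
  structure(list(loci = loci, records = records), class = "disease_table")
}

#' @export
print.disease_table <- function(x, ...) {
  cat("<disease_table> ", nrow(x$loci), " loci, ", nrow(x$records),
      " at-risk genotype record(s)\n", sep = "")
  invisible(x)
}

#' @method tidy disease_table
#' @export
tidy.disease_table <- function(x, ...) {
  dplyr::left_join(x$records, x$loci, by = "locus_id")
}
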