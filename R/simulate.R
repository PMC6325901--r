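#' Simulate a founder haplotype pool
#'
#' Builds the marker map (uniformly placed markers at the configured density,
#' sorted within each chromosome) and a pool of phased founder haplotypes.
#' Per-marker allele frequencies are drawn from `Beta(a, b)`; haplotype
#' alleles are Bernoulli draws, optionally with first-order Markov copying
#' of the previous marker's allele (probability `ld_rho`) as a crude stand-in
#' for linkage disequilibrium.
#'
#' Uses the config seed, so the same config always yields the same pool.
#'
#' @param config A [sim_config()].
#' @return A `founder_pool`: list with `map` (marker map tibble), `haps`
#'   (haplotypes x markers 0/1 matrix), `freq` (per-marker allele-1
#'   frequency), `disease` (planted loci, initially empty), and the config.
#' @export
simulate_founders <- function(config) {
  set.seed(config$seed)
  lens <- config$chrom_lengths
  chroms <- names(lens)
  dens <- rep(config$markers_per_mb, length(lens))
  if (!is.null(config$x_length)) {
    lens <- c(lens, X = config$x_length)
    chroms <- c(chroms, "X")
    dens <- c(dens, config$x_markers_per_mb)
  }
  maps <- purrr::map(seq_along(chroms), function(i) {
    n <- max(2L, round(lens[i] / 1e6 * dens[i]))
    pos <- sort(sample.int(lens[i], n))
    tibble::tibble(
      chrom = chroms[i],
      marker_id = sprintf("c%s_m%06d", chroms[i], seq_len(n)),
      cm = pos / 1e6 * config$cm_per_mb,
      pos = as.numeric(pos)
    )
  })
  map <- dplyr::bind_rows(maps)
  m <- nrow(map)
  freq <- stats::rbeta(m, config$beta_af[1], config$beta_af[2])
  H <- config$n_founder_haps
  haps <- matrix(stats::rbinom(H * m, 1L, rep(freq, each = H)), nrow = H)
  if (config$ld_rho > 0) {
    new_chrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
    for (j in seq_len(m)[-1]) {
      if (new_chrom[j]) next
      copy <- stats::runif(H) < config$ld_rho
      haps[copy, j] <- haps[copy, j - 1L]
    }
  }
  structure(
    list(map = map, haps = haps, freq = freq,
         disease = tibble::tibble(locus_id = character(), chrom = character(),
                                  pos = numeric(), marker_idx = integer(),
                                  origin_hap = integer(), carrier_freq = numeric()),
         config = config),
    class = "founder_pool"
  )
}

#' @export
print.founder_pool <- function(x, ...) {
  cat("<founder_pool> ", nrow(x$haps), " haplotypes x ", ncol(x$haps),
      " markers; ", nrow(x$disease), " disease locus/loci planted\n", sep = "")
  invisible(x)
}

#' Plant a recessive disease allele on a single founder haplotype
#'
#' Recessive disease mutations arise once, so each risk allele lives on
#' exactly one founder haplotype background. The marker nearest the requested
#' position is overwritten: allele 1 (the risk allele) on the origin
#' haplotype, allele 0 on every other haplotype. `carrier_freq` sets the
#' frequency with which pedigree founders draw the origin haplotype, i.e.
#' the carrier haplotype frequency in the founding population. Requesting a
#' second origin for a locus already planted is an error.
#'
#' @param pool A `founder_pool`.
#' @param locus List or one-row data frame with `locus_id`, `chrom`, `pos`.
#' @param carrier_freq Origin-haplotype frequency among pedigree founder
#'   haplotype draws, in `[0, 1)`.
#' @param origin_hap Index of the origin haplotype (default: drawn from the
#'   pool's RNG-independent choice, haplotype 1 + number already planted).
#' @return The modified pool.
#' @export
plant_disease_allele <- function(pool, locus, carrier_freq, origin_hap = NULL) {
  stopifnot(inherits(pool, "founder_pool"))
  locus <- as.list(locus)
  if (locus$locus_id %in% pool$disease$locus_id) {
    stop("locus ", locus$locus_id,
         " already planted; a recessive risk allele has a single founder origin")
  }
  if (carrier_freq < 0 || carrier_freq >= 1) stop("carrier_freq must be in [0, 1)")
  if (carrier_freq > 0 && nrow(pool$haps) < 2) {
    stop("carrier_freq > 0 requires a pool of at least 2 haplotypes")
  }
  if (sum(pool$disease$carrier_freq) + carrier_freq >= 1) {
    stop("summed carrier frequencies must be < 1")
  }
  chrom <- as.character(locus$chrom)
  idx_chrom <- which(pool$map$chrom == chrom)
  if (length(idx_chrom) == 0) stop("no markers on chromosome ", chrom)
  j <- idx_chrom[which.min(abs(pool$map$pos[idx_chrom] - locus$pos))]
  if (is.null(origin_hap)) {
    used <- pool$disease$origin_hap
    origin_hap <- setdiff(seq_len(nrow(pool$haps)), used)[1]
  }
  pool$haps[, j] <- 0L
  pool$haps[origin_hap, j] <- 1L
  pool$freq[j] <- carrier_freq
  pool$disease <- dplyr::bind_rows(pool$disease, tibble::tibble(
    locus_id = locus$locus_id, chrom = chrom, pos = pool$map$pos[j],
    marker_idx = j, origin_hap = as.integer(origin_hap),
    carrier_freq = carrier_freq
  ))
  pool
}

# ---- gamete machinery ----------------------------------------------------
# A gamete on one chromosome is a mosaic of founder-pool haplotypes,
# stored as parallel vectors: segment start positions (bk, first always 1)
# and founder haplotype ids. Segments tile [1, chrom_length].

founder_gamete <- function(hap_id) list(bk = 1, id = as.integer(hap_id))

# One meiosis: Poisson(length_cM / 100) crossovers, uniform placement,
# no interference; random starting phase.
meiosis <- function(g1, g2, chrom_len, cm_per_mb) {
  n_x <- stats::rpois(1L, chrom_len / 1e6 * cm_per_mb / 100)
  phase <- stats::runif(1) < 0.5
  if (n_x == 0L) return(if (phase) g1 else g2)
  cuts <- sort(unique(round(stats::runif(n_x, 2, chrom_len - 1))))
  if (length(cuts) == 0L) return(if (phase) g1 else g2)
  bounds <- c(1, cuts, chrom_len + 1)
  out_bk <- numeric(0); out_id <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    src <- if (xor(phase, k %% 2L == 0L)) g1 else g2
    lo <- bounds[k]; hi <- bounds[k + 1L]
    i0 <- findInterval(lo, src$bk)
    i1 <- findInterval(hi - 1e-9, src$bk)
    bk <- src$bk[i0:i1]; bk[1] <- lo
    keep <- bk < hi
    out_bk <- c(out_bk, bk[keep]); out_id <- c(out_id, src$id[i0:i1][keep])
  }
  dedup <- c(TRUE, out_id[-1] != out_id[-length(out_id)])
  list(bk = out_bk[dedup], id = out_id[dedup])
}

# Per-pedigree founder haplotype dispenser. Each slot is a disease-origin
# haplotype with its carrier frequency (origins may recur — that is how
# homozygotes arise); all other slots take distinct pool haplotypes, so
# pedigree founders are unrelated and realized F matches the template.
make_hap_dispenser <- function(pool) {
  H <- nrow(pool$haps)
  origin <- pool$disease$origin_hap
  cum_cf <- cumsum(pool$disease$carrier_freq)
  avail <- setdiff(sample.int(H, H), origin)
  ptr <- 0L
  function(k) {
    out <- integer(k)
    for (t in seq_len(k)) {
      hit <- if (length(cum_cf) > 0) which(stats::runif(1) < cum_cf)[1] else NA_integer_
      if (!is.na(hit)) {
        out[t] <- origin[hit]
      } else {
        ptr <<- ptr + 1L
        if (ptr > length(avail)) {
          # pool smaller than the pedigree needs: recycle (founders then share
          # haplotypes, adding background relatedness — unavoidable at tiny H)
          avail <<- sample(avail)
          ptr <<- 1L
        }
        out[t] <- avail[ptr]
      }
    }
    out
  }
}

new_founder_ind <- function(sex, dispense, chrom_lens, has_x) {
  ids <- dispense(2L)
  haps <- purrr::map(seq_along(chrom_lens), function(i) {
    list(founder_gamete(ids[1]), founder_gamete(ids[2]))
  })
  names(haps) <- names(chrom_lens)
  x <- NULL
  if (has_x) {
    xids <- dispense(if (sex == "M") 1L else 2L)
    x <- if (sex == "M") list(founder_gamete(xids[1])) else
      list(founder_gamete(xids[1]), founder_gamete(xids[2]))
  }
  list(sex = sex, haps = haps, x = x)
}

make_child <- function(mother, father, sex, chrom_lens, x_len, cm_per_mb) {
  haps <- purrr::map(seq_along(chrom_lens), function(i) {
    list(meiosis(mother$haps[[i]][[1]], mother$haps[[i]][[2]], chrom_lens[i], cm_per_mb),
         meiosis(father$haps[[i]][[1]], father$haps[[i]][[2]], chrom_lens[i], cm_per_mb))
  })
  names(haps) <- names(chrom_lens)
  x <- NULL
  if (!is.null(x_len)) {
    from_mother <- if (length(mother$x) == 2L) {
      meiosis(mother$x[[1]], mother$x[[2]], x_len, cm_per_mb)
    } else mother$x[[1]]
    x <- if (sex == "F") list(from_mother, father$x[[1]]) else list(from_mother)
  }
  list(sex = sex, haps = haps, x = x)
}

# Build one offspring from an independent pedigree instance.
pedigree_offspring <- function(config, pool, sex) {
  lens <- config$chrom_lengths
  xl <- config$x_length
  has_x <- !is.null(xl)
  cm <- config$cm_per_mb
  d <- config$loop_depth
  dispense <- make_hap_dispenser(pool)
  if (is.na(d)) {
    mom <- new_founder_ind("F", dispense, lens, has_x)
    dad <- new_founder_ind("M", dispense, lens, has_x)
    return(make_child(mom, dad, sex, lens, xl, cm))
  }
  anc_f <- new_founder_ind("F", dispense, lens, has_x)
  anc_m <- new_founder_ind("M", dispense, lens, has_x)
  s1 <- make_child(anc_f, anc_m, "F", lens, xl, cm)
  s2 <- make_child(anc_f, anc_m, "M", lens, xl, cm)
  for (g in seq_len(d)) {
    s1 <- make_child(s1, new_founder_ind("M", dispense, lens, has_x), "F", lens, xl, cm)
    s2 <- make_child(new_founder_ind("F", dispense, lens, has_x), s2, "M", lens, xl, cm)
  }
  make_child(s1, s2, sex, lens, xl, cm)
}

# Overlay an individual's two gametes on one chromosome into truth segments.
overlay_truth <- function(g1, g2, chrom_len) {
  bk <- sort(unique(c(g1$bk, g2$bk)))
  id1 <- g1$id[findInterval(bk, g1$bk)]
  id2 <- g2$id[findInterval(bk, g2$bk)]
  auto <- id1 == id2
  keep <- c(TRUE, auto[-1] != auto[-length(auto)] |
              (auto[-1] & id1[-1] != id1[-length(id1)]))
  bk <- bk[keep]; auto <- auto[keep]; id1 <- id1[keep]
  tibble::tibble(
    start = bk,
    end = c(bk[-1] - 1, chrom_len),
    autozygous = auto,
    founder_hap = ifelse(auto, id1, NA_integer_)
  )
}

gamete_alleles <- function(g, pool, marker_idx, marker_pos) {
  seg <- findInterval(marker_pos, g$bk)
  pool$haps[cbind(g$id[seg], marker_idx)]
}

#' Simulate a genotype panel from a pedigree template, with truth
#'
#' Each offspring is drawn from an independent instance of the configured
#' pedigree (so inbreeding realizations are independent across samples).
#' Meiosis places Poisson(length_cM / 100) crossovers uniformly along the
#' chromosome, without interference. Wherever an offspring's two gametes
#' descend from the same founder-pool haplotype, the genome is autozygous;
#' these true identity-by-descent segments are recorded *before* the error
#' model runs, so truth is error-free. Genotyping errors then flip calls at
#' rate `error_rate` (homozygous to heterozygous and heterozygous to a
#' random homozygote) and missingness masks calls at rate `missing_rate`.
#'
#' Chromosome X, when simulated, is transmitted with male hemizygosity
#' (fathers pass their single X to daughters, unrecombined); male X
#' genotypes are reported as homozygous calls and X truth segments are
#' recorded for females only.
#'
#' @param config A [sim_config()].
#' @param pool A `founder_pool` from [simulate_founders()], possibly with
#'   disease alleles planted via [plant_disease_allele()]. Defaults to
#'   `simulate_founders(config)` with the config's loci planted.
#' @return A list of class `sim_panel`: `panel` (a [genotype_panel()]),
#'   `truth` (tibble `sample_id`, `chrom`, `start`, `end`, `autozygous`,
#'   `founder_hap` — segments tile each chromosome), and `disease` (a
#'   `disease_table` of planted loci and the samples observed homozygous
#'   for the risk allele, or `NULL`).
#' @export
simulate_pedigree <- function(config, pool = NULL) {
  if (is.null(pool)) {
    pool <- simulate_founders(config)
    if (!is.null(config$disease_loci)) {
      for (i in seq_len(nrow(config$disease_loci))) {
        pool <- plant_disease_allele(pool,
                                     config$disease_loci[i, c("locus_id", "chrom", "pos")],
                                     config$disease_loci$carrier_freq[i])
      }
    }
  }
  set.seed(config$seed + 1L)
  lens <- config$chrom_lengths
  has_x <- !is.null(config$x_length)
  all_chroms <- c(names(lens), if (has_x) "X")
  all_lens <- c(lens, if (has_x) stats::setNames(config$x_length, "X"))
  map <- pool$map
  n <- config$n_offspring
  ids <- sprintf("S%04d", seq_len(n))
  sexes <- sample(c("F", "M"), n, replace = TRUE)

  chrom_idx <- purrr::map(all_chroms, function(ch) which(map$chrom == ch))
  names(chrom_idx) <- all_chroms

  geno <- matrix(NA_integer_, nrow = n, ncol = nrow(map))
  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    ind <- pedigree_offspring(config, pool, sexes[i])
    truths <- vector("list", length(all_chroms))
    for (ci in seq_along(all_chroms)) {
      ch <- all_chroms[ci]
      mi <- chrom_idx[[ch]]
      mpos <- map$pos[mi]
      if (ch == "X") {
        if (ind$sex == "M") {
          a <- gamete_alleles(ind$x[[1]], pool, mi, mpos)
          geno[i, mi] <- 2L * a
          truths[[ci]] <- NULL
        } else {
          a1 <- gamete_alleles(ind$x[[1]], pool, mi, mpos)
          a2 <- gamete_alleles(ind$x[[2]], pool, mi, mpos)
          geno[i, mi] <- a1 + a2
          tr <- overlay_truth(ind$x[[1]], ind$x[[2]], all_lens[[ci]])
          truths[[ci]] <- dplyr::mutate(tr, chrom = ch, .before = 1)
        }
      } else {
        g <- ind$haps[[ch]]
        a1 <- gamete_alleles(g[[1]], pool, mi, mpos)
        a2 <- gamete_alleles(g[[2]], pool, mi, mpos)
        geno[i, mi] <- a1 + a2
        tr <- overlay_truth(g[[1]], g[[2]], all_lens[[ci]])
        truths[[ci]] <- dplyr::mutate(tr, chrom = ch, .before = 1)
      }
    }
    truth_list[[i]] <- dplyr::mutate(dplyr::bind_rows(truths), sample_id = ids[i], .before = 1)
  }
  truth <- dplyr::bind_rows(truth_list)

  # error model, after truth recording
  if (config$error_rate > 0) {
    flip <- which(stats::runif(length(geno)) < config$error_rate & !is.na(geno))
    if (length(flip) > 0) {
      old <- geno[flip]
      newv <- ifelse(old == 1L,
                     ifelse(stats::runif(length(flip)) < 0.5, 0L, 2L),
                     1L)
      geno[flip] <- newv
    }
  }
  if (config$missing_rate > 0) {
    geno[stats::runif(length(geno)) < config$missing_rate] <- NA_integer_
  }

  samples <- tibble::tibble(sample_id = ids, breed = config$breed_label, sex = sexes)
  panel <- genotype_panel(map, samples, geno)

  disease <- NULL
  if (nrow(pool$disease) > 0) {
    recs <- purrr::map_dfr(seq_len(nrow(pool$disease)), function(k) {
      j <- pool$disease$marker_idx[k]
      hom <- which(geno[, j] == 2L)
      tibble::tibble(sample_id = ids[hom], locus_id = pool$disease$locus_id[k])
    })
    disease <- disease_table(
      loci = pool$disease[, c("locus_id", "chrom", "pos")],
      records = recs, panel = panel
    )
  }
  structure(list(panel = panel, truth = truth, disease = disease, config = config),
            class = "sim_panel")
}

#' @export
print.sim_panel <- function(x, ...) {
  cat("<sim_panel> pedigree '", x$config$pedigree, "', expected F = ",
      format(pedigree_expected_f(x$config$pedigree)), "\n", sep = "")
  print(x$panel)
  cat("  truth: ", sum(x$truth$autozygous), " autozygous segment(s) across samples\n", sep = "")
  invisible(x)
}

#' True autozygous genome fraction per sample
#'
#' Sums truth autozygous segment lengths over autosomes and divides by the
#' summed chromosome lengths, optionally counting only segments of at least
#' `min_length` bp (the detectable fraction for a caller with that floor).
#'
#' @param sim A `sim_panel` from [simulate_pedigree()].
#' @param min_length Count only autozygous segments of at least this many bp.
#' @return Tibble `sample_id`, `autozygous_bp`, `genome_bp`, `fraction`.
#' @export
truth_autozygous_fraction <- function(sim, min_length = 0) {
  lens <- sim$config$chrom_lengths
  L <- sum(lens)
  sim$truth |>
    dplyr::filter(.data$chrom != "X") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(autozygous_bp = sum((.data$end - .data$start + 1) *
                                           (.data$autozygous &
                                              (.data$end - .data$start + 1) >= min_length))) |>
    dplyr::mutate(genome_bp = L, fraction = .data$autozygous_bp / L) |>
    dplyr::right_join(tibble::tibble(sample_id = sim$panel$samples$sample_id),
                      by = "sample_id") |>
    dplyr::mutate(dplyr::across(c("autozygous_bp", "fraction"),
                                ~ dplyr::coalesce(.x, 0)),
                  genome_bp = L) |>
    dplyr::arrange(.data$sample_id)
}
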