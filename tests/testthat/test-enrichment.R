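test_that("length classes are left-closed at their lower bounds", {
  spec <- length_class_spec()
  expect_equal(as.character(classify_length(c(0, 4.9e5, 5e5, 2.5e6 - 1, 2.5e6,
                                              5e6 - 1, 5e6, 6e6), spec)),
               c("SUB", "SUB", "SHORT", "SHORT", "MEDIUM", "MEDIUM", "LONG", "LONG"))
})

test_that("at-risk genotypes take the class of their containing tract", {
  tracts <- tibble::tibble(
    sample_id = c("d1", "d1", "d2"), chrom = "1",
    start = c(1e6, 2e7, 1e6), end = c(7e6 - 1, 2.1e7 - 1, 3.5e6 - 1),
    length = c(6e6, 1e6, 2.5e6), n_markers = 100L, caller = "SCAN", params = "x"
  )
  dz <- disease_table(
    loci = tibble::tibble(locus_id = c("L1", "L2"), chrom = "1",
                          pos = c(2e6, 1.5e7)),
    records = tibble::tibble(sample_id = c("d1", "d1", "d2"),
                             locus_id = c("L1", "L2", "L1"))
  )
  cl <- classify_at_risk(dz, tracts)
  expect_equal(as.character(cl$class[cl$sample_id == "d1" & cl$locus_id == "L1"]),
               "LONG")    # inside the 6-Mb tract
  expect_equal(as.character(cl$class[cl$sample_id == "d1" & cl$locus_id == "L2"]),
               "SUB")     # no containing tract
  expect_equal(as.character(cl$class[cl$sample_id == "d2"]),
               "MEDIUM")  # tract of exactly 2,500,000 bp
  # brute-force interval membership agrees
  for (i in seq_len(nrow(cl))) {
    row <- cl[i, ]
    hit <- tracts[tracts$sample_id == row$sample_id &
                    tracts$start <= row$pos & tracts$end >= row$pos, ]
    expect_equal(nrow(hit) > 0, as.character(row$class) != "SUB")
  }
})

test_that("genome fractions sum to one per dog and are averaged, not pooled", {
  pos <- seq(1e6, 1.1e7, length.out = 300)
  # dog 1 fully ROH across the span; dog 2 has none
  panel <- toy_panel(list(rep(0L, 300), rep(1L, 300)), pos)
  tr <- scan_roh(panel)
  gf <- genome_fractions(tr, panel)
  expect_equal(sum(gf$genome_fraction), 1, tolerance = 1e-12)
  # averaged estimator: (1 + 0)/2 in LONG, not pooled length share
  expect_equal(gf$genome_fraction[gf$class == "LONG"], 0.5)
  expect_equal(gf$genome_fraction[gf$class == "SUB"], 0.5)
})

test_that("relative risk reproduces direct arithmetic and its invariances", {
  # two-class toy: 10 of 100 at-risk in a class covering 10% of the genome,
  # 90 in the 90% baseline: no enrichment
  toy <- tibble::tibble(class = c("SUB", "A"),
                        genome_fraction = c(0.9, 0.1),
                        atrisk_fraction = c(0.9, 0.1))
  expect_equal(relative_risk(toy)$rr, c(1, 1))

  # identical distributions always give RR 1
  gf <- c(0.7, 0.1, 0.05, 0.15)
  same <- tibble::tibble(class = c("SUB", "S", "M", "L"),
                         genome_fraction = gf, atrisk_fraction = gf)
  expect_equal(relative_risk(same)$rr, rep(1, 4))

  # rescaling genome fractions by a common factor leaves RR unchanged
  tab <- tibble::tibble(class = c("SUB", "S", "M", "L"),
                        genome_fraction = c(75.1, 4.7, 3.1, 17.1),
                        atrisk_fraction = c(7.8, 14.7, 11.4, 66.1))
  rr1 <- relative_risk(tab)$rr
  tab2 <- dplyr::mutate(tab, genome_fraction = genome_fraction / 100)
  expect_equal(relative_risk(tab2)$rr, rr1)

  # zero genome fraction: undefined
  tab3 <- tibble::tibble(class = c("SUB", "A"), genome_fraction = c(1, 0),
                         atrisk_fraction = c(0.5, 0.5))
  expect_true(is.na(relative_risk(tab3)$rr[2]))
})

test_that("cumulative curves match brute-force counting and are monotone", {
  set.seed(41)
  lens <- sample.int(1e7, 10)
  tr <- tibble::tibble(length = lens)
  cc <- cumulative_curve(tr)
  for (i in seq_len(nrow(cc))) {
    expect_equal(cc$frac_ge[i], sum(lens >= cc$length[i]) / 10)
  }
  expect_true(all(diff(cc$frac_ge) <= 0))
  # equal lengths: single step at that length
  cc2 <- cumulative_curve(tibble::tibble(length = rep(2e6, 5)))
  expect_equal(nrow(cc2), 1)
  expect_equal(cc2$frac_ge, 1)
  # length-weighted variant
  ccw <- cumulative_curve(tr, weight = "length")
  for (i in seq_len(nrow(ccw))) {
    expect_equal(ccw$frac_ge[i], sum(lens[lens >= ccw$length[i]]) / sum(lens))
  }
})

test_that("resampling null: k = full set reproduces the full curve; seeds fix draws", {
  set.seed(42)
  tr <- tibble::tibble(length = sample.int(8e6, 40))
  null_full <- resample_null(tr, k = 40, n_reps = 50, seed = 1)
  expect_equal(null_full$envelope$lo, null_full$full_curve$frac_ge)
  expect_equal(null_full$envelope$hi, null_full$full_curve$frac_ge)

  n1 <- resample_null(tr, k = 10, n_reps = 100, seed = 7)
  n2 <- resample_null(tr, k = 10, n_reps = 100, seed = 7)
  expect_identical(n1$envelope, n2$envelope)
  expect_error(resample_null(tr, k = 41, n_reps = 10, seed = 1), "exceeds")
})

test_that("enrichment table percentages are conserved and RR baseline is 1", {
  cfg <- sim_config(chrom_lengths = stats::setNames(rep(2e7, 3), 1:3),
                    markers_per_mb = 60, pedigree = "fullsib", n_offspring = 60,
                    error_rate = 0, seed = 43,
                    disease_loci = tibble::tibble(locus_id = "dz1", chrom = "2",
                                                  pos = 1e7, carrier_freq = 0.25))
  sim <- simulate_pedigree(cfg)
  tr <- scan_roh(sim$panel)
  et <- enrichment_table(sim$disease, tr, sim$panel)
  expect_equal(sum(et$genome_pct), 100, tolerance = 1e-9)
  expect_equal(sum(et$atrisk_pct), 100, tolerance = 1e-9)
  expect_equal(et$rr[1], 1)
  expect_equal(unique(et$caller), "SCAN")
})

test_that("planted disease alleles escape the resampling null; neutral loci do not", {
  # background: first-cousin loops; disease homozygotes mostly arise from two
  # recent carrier parents, so their tracts are much longer than background
  cfg <- sim_config(chrom_lengths = stats::setNames(rep(5e7, 4), 1:4),
                    markers_per_mb = 60, pedigree = "first_cousin",
                    n_offspring = 150, error_rate = 0, seed = 44,
                    disease_loci = tibble::tibble(locus_id = "dz1", chrom = "2",
                                                  pos = 2.5e7, carrier_freq = 0.4))
  sim <- simulate_pedigree(cfg)
  tr <- scan_roh(sim$panel)
  cl <- classify_at_risk(sim$disease, tr)
  dz_tracts <- cl[!is.na(cl$tract_length), ]
  k <- nrow(dz_tracts)
  expect_gt(k, 4)
  null <- resample_null(tr, k = k, n_reps = 500, seed = 45)
  res <- envelope_test(null, tibble::tibble(length = dz_tracts$tract_length))
  expect_true(res$outside)
  # a random subsample of all tracts stays inside the uniform null
  set.seed(46)
  rand <- tr[sample.int(nrow(tr), k), ]
  expect_false(envelope_test(null, rand)$outside)

  # a neutral locus is exchangeable with the random-locus null
  set.seed(47)
  map <- sim$panel$map
  repeat {
    j <- sample.int(nrow(map), 1)
    hom <- sim$panel$samples$sample_id[
      which(sim$panel$geno[, j] != 1L & !is.na(sim$panel$geno[, j]))]
    cov <- tr[tr$sample_id %in% hom & tr$chrom == map$chrom[j] &
                tr$start <= map$pos[j] & tr$end >= map$pos[j], ]
    if (nrow(cov) >= 2) break
  }
  if (nrow(cov) > k) cov <- cov[sample.int(nrow(cov), k), ]
  nl <- locus_null(tr, sim$panel, k = k, n_reps = 500, seed = 48)
  expect_false(envelope_test(nl, cov)$outside)
})
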