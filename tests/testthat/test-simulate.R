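small_cfg <- function(...) {
  sim_config(chrom_lengths = stats::setNames(rep(2e7, 3), 1:3),
             markers_per_mb = 50, n_offspring = 30, error_rate = 0, seed = 1, ...)
}

test_that("founder allele frequencies follow the configured Beta distribution", {
  cfg <- sim_config(chrom_lengths = c("1" = 2e7), markers_per_mb = 50,
                    beta_af = c(0.5, 0.5), n_founder_haps = 400, seed = 3,
                    error_rate = 0)
  pool <- simulate_founders(cfg)
  # E[MAF] for p ~ Beta(.5,.5) is E[min(p, 1-p)] = 1/2 - 1/pi (by symmetry of
  # the arcsine law: E|p - 1/2| = integral = 1/pi)
  maf <- pmin(pool$freq, 1 - pool$freq)
  expect_equal(mean(maf), 0.5 - 1 / pi, tolerance = 0.05)
  # realized haplotype frequencies track the drawn p
  realized <- colMeans(pool$haps)
  expect_gt(stats::cor(realized, pool$freq), 0.98)
})

test_that("a two-haplotype pool makes every offspring a mosaic of two founders", {
  cfg <- sim_config(chrom_lengths = c("1" = 2e7), markers_per_mb = 50,
                    n_founder_haps = 2, pedigree = "fullsib", n_offspring = 10,
                    error_rate = 0, seed = 4)
  sim <- simulate_pedigree(cfg)
  pool <- simulate_founders(cfg)
  for (i in seq_len(10)) {
    g <- sim$panel$geno[i, ]
    ok <- vapply(seq_along(g), function(j) {
      g[j] %in% c(pool$haps[1, j] + pool$haps[2, j],
                  2L * pool$haps[1, j], 2L * pool$haps[2, j])
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("same config and seed reproduce bit-identical output", {
  cfg <- small_cfg(pedigree = "first_cousin")
  s1 <- simulate_pedigree(cfg)
  s2 <- simulate_pedigree(cfg)
  expect_identical(s1$panel$geno, s2$panel$geno)
  expect_identical(s1$truth, s2$truth)
  pool1 <- simulate_founders(cfg)
  pool2 <- simulate_founders(cfg)
  expect_identical(pool1$haps, pool2$haps)
})

test_that("mean autozygous fraction matches pedigree expectation", {
  cfg_fs <- sim_config(chrom_lengths = stats::setNames(rep(5e7, 6), 1:6),
                       markers_per_mb = 20, pedigree = "fullsib",
                       n_offspring = 150, error_rate = 0, seed = 5)
  frac_fs <- truth_autozygous_fraction(simulate_pedigree(cfg_fs))$fraction
  expect_lt(abs(mean(frac_fs) - 0.25), 0.02)

  cfg_fc <- sim_config(chrom_lengths = stats::setNames(rep(5e7, 6), 1:6),
                       markers_per_mb = 20, pedigree = "first_cousin",
                       n_offspring = 150, error_rate = 0, seed = 6)
  frac_fc <- truth_autozygous_fraction(simulate_pedigree(cfg_fc))$fraction
  expect_lt(abs(mean(frac_fc) - 0.0625), 0.015)

  cfg_un <- small_cfg()
  expect_equal(mean(truth_autozygous_fraction(simulate_pedigree(cfg_un))$fraction), 0,
               tolerance = 0.01)
})

test_that("deeper consanguinity loops shift tract lengths shorter", {
  len_at_depth <- function(ped, seed) {
    cfg <- sim_config(chrom_lengths = stats::setNames(rep(5e7, 4), 1:4),
                      markers_per_mb = 20, pedigree = ped, n_offspring = 120,
                      error_rate = 0, seed = seed)
    tr <- simulate_pedigree(cfg)$truth
    tr <- tr[tr$autozygous, ]
    tr$end - tr$start + 1
  }
  shallow <- len_at_depth("fullsib", 7)  # ancestors one generation back
  deep <- len_at_depth("cousin2", 8)     # ancestors three generations back
  expect_gt(length(deep), 10)
  # stochastic dominance of the shallow-loop length distribution
  qs <- c(0.25, 0.5, 0.75, 0.9)
  expect_true(all(stats::quantile(shallow, qs) > stats::quantile(deep, qs)))
  expect_gt(mean(shallow), 2 * mean(deep))
})

test_that("every marker inside an error-free truth autozygous segment is non-HET", {
  sim <- simulate_pedigree(small_cfg(pedigree = "fullsib"))
  auto <- sim$truth[sim$truth$autozygous, ]
  map <- sim$panel$map
  for (i in seq_len(nrow(auto))) {
    mi <- which(map$chrom == auto$chrom[i] &
                  map$pos >= auto$start[i] & map$pos <= auto$end[i])
    g <- sim$panel$geno[auto$sample_id[i], mi]
    expect_false(any(g == 1L, na.rm = TRUE))
  }
})

test_that("truth segments tile each chromosome without overlap", {
  sim <- simulate_pedigree(small_cfg(pedigree = "fullsib"))
  lens <- sim$config$chrom_lengths
  sim$truth |>
    dplyr::group_split(.data$sample_id, .data$chrom) |>
    purrr::walk(function(d) {
      expect_equal(d$start[1], 1)
      expect_equal(d$end[nrow(d)], unname(lens[d$chrom[1]]))
      if (nrow(d) > 1) expect_equal(d$start[-1], d$end[-nrow(d)] + 1)
    })
})

test_that("the error model flips calls at the configured rate, after truth", {
  cfg0 <- small_cfg(pedigree = "fullsib")
  cfg_err <- sim_config(chrom_lengths = stats::setNames(rep(2e7, 3), 1:3),
                        markers_per_mb = 50, n_offspring = 30,
                        pedigree = "fullsib", error_rate = 0.02,
                        missing_rate = 0.01, seed = 1)
  s0 <- simulate_pedigree(cfg0)
  se <- simulate_pedigree(cfg_err)
  expect_identical(s0$truth, se$truth)  # truth recorded before errors
  changed <- mean(se$panel$geno != s0$panel$geno, na.rm = TRUE)
  expect_lt(abs(changed - 0.02), 0.005)
  expect_lt(abs(mean(is.na(se$panel$geno)) - 0.01), 0.005)
})

test_that("disease alleles have a single founder origin", {
  cfg <- small_cfg()
  pool <- simulate_founders(cfg)
  locus <- list(locus_id = "dz1", chrom = "1", pos = 1e7)
  pool <- plant_disease_allele(pool, locus, carrier_freq = 0.2)
  j <- pool$disease$marker_idx
  expect_equal(sum(pool$haps[, j]), 1L)
  expect_error(plant_disease_allele(pool, locus, carrier_freq = 0.2),
               "single founder origin")
})

test_that("carrier frequency zero yields no at-risk offspring", {
  cfg <- sim_config(chrom_lengths = stats::setNames(rep(2e7, 3), 1:3),
                    markers_per_mb = 50, n_offspring = 40, pedigree = "fullsib",
                    error_rate = 0, seed = 9,
                    disease_loci = tibble::tibble(locus_id = "dz1", chrom = "1",
                                                  pos = 1e7, carrier_freq = 0))
  sim <- simulate_pedigree(cfg)
  expect_equal(nrow(sim$disease$records), 0)
})

test_that("homozygous-risk offspring always sit on a truth autozygous segment", {
  cfg <- sim_config(chrom_lengths = stats::setNames(rep(2e7, 3), 1:3),
                    markers_per_mb = 50, n_offspring = 80, pedigree = "fullsib",
                    error_rate = 0, seed = 10,
                    disease_loci = tibble::tibble(locus_id = "dz1", chrom = "1",
                                                  pos = 1e7, carrier_freq = 0.3))
  sim <- simulate_pedigree(cfg)
  recs <- sim$disease$records
  expect_gt(nrow(recs), 0)
  locus_pos <- sim$disease$loci$pos[1]
  for (s in recs$sample_id) {
    seg <- sim$truth[sim$truth$sample_id == s & sim$truth$chrom == "1" &
                       sim$truth$start <= locus_pos & sim$truth$end >= locus_pos, ]
    expect_true(seg$autozygous)
  }
})

test_that("male X is hemizygous-homozygous and excluded from truth", {
  cfg <- sim_config(chrom_lengths = stats::setNames(rep(2e7, 2), 1:2),
                    x_length = 2e7, markers_per_mb = 50, n_offspring = 40,
                    pedigree = "fullsib", error_rate = 0, seed = 11)
  sim <- simulate_pedigree(cfg)
  males <- sim$panel$samples$sample_id[sim$panel$samples$sex == "M"]
  expect_gt(length(males), 0)
  xm <- sim$panel$map$chrom == "X"
  expect_false(any(sim$panel$geno[males, xm] == 1L, na.rm = TRUE))
  expect_false(any(sim$truth$sample_id %in% males & sim$truth$chrom == "X"))
  # females do get X truth
  expect_gt(sum(sim$truth$chrom == "X"), 0)
})
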