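# the synthetic genotype generator: ground truth, rates, reproducibility

test_that("zero-rate simulation leaves tracts fully homozygous and complete", {
  sim <- simulate_dataset(sim_config(
    seed = 101, n_chromosomes = 1, chromosome_length_bp = 2e7,
    populations = c(P = 3), tract_lengths_bp = 5e6,
    het_error_rate = 0, missing_rate = 0))
  ds <- sim$dataset
  expect_equal(genotyping_rate(ds), 1)
  tr <- sim$truth$tracts
  for (t in seq_len(nrow(tr))) {
    cols <- which(ds$map$chrom == tr$chrom[t] & ds$map$pos >= tr$start_bp[t] &
                    ds$map$pos <= tr$end_bp[t])
    expect_true(all(ds$geno[tr$sample[t], cols] %in% c(0L, 2L)))
  }
  expect_equal(nrow(sim$truth$errors), 0L)
  expect_equal(nrow(sim$truth$missing), 0L)
})

test_that("the same seed reproduces byte-identical PLINK files", {
  cfg <- sim_config(seed = 102, n_chromosomes = 2,
                    chromosome_length_bp = 5e6, populations = c(P = 4),
                    islands = list(list(chrom = 1, start_bp = 1e6,
                                        end_bp = 2.2e6,
                                        carrier_fraction = 0.5)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg); s2 <- simulate_dataset(cfg)
  write_fixture(s1$dataset, s1$truth, d1, dialects = "ped")
  write_fixture(s2$dataset, s2$truth, d2, dialects = "ped")
  for (f in c("sim.ped", "sim.map", "sim_truth_tracts.tsv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("fixtures round-trip through the PLINK reader", {
  sim <- simulate_dataset(sim_config(
    seed = 103, n_chromosomes = 2, chromosome_length_bp = 3e6,
    populations = c(A = 3, B = 3), tract_lengths_bp = 1e6))
  dir <- withr::local_tempdir()
  prefix <- write_fixture(sim$dataset, sim$truth, dir)
  for (dialect in c("ped", "bed")) {
    back <- read_plink(prefix, dialect = dialect)
    expect_equal(back$geno, sim$dataset$geno)
    expect_equal(back$map, sim$dataset$map)
    expect_equal(back$samples$population, sim$dataset$samples$population)
  }
  # truth table row count equals planted tracts
  tt <- read.delim(paste0(prefix, "_truth_tracts.tsv"))
  expect_equal(nrow(tt), nrow(sim$truth$tracts))
})

test_that("realized heterozygous-error rate sits within 3 binomial sd", {
  # ~110k tract SNP calls across individuals
  sim <- simulate_dataset(sim_config(
    seed = 104, n_chromosomes = 2, chromosome_length_bp = 3e7,
    populations = c(P = 14), tract_lengths_bp = c(1.2e7, 1.6e7)))
  tr <- sim$truth$tracts
  ds <- sim$dataset
  n_calls <- 0L; n_het <- 0L
  for (t in seq_len(nrow(tr))) {
    cols <- which(ds$map$chrom == tr$chrom[t] & ds$map$pos >= tr$start_bp[t] &
                    ds$map$pos <= tr$end_bp[t])
    g <- ds$geno[tr$sample[t], cols]
    n_calls <- n_calls + sum(!is.na(g))
    n_het <- n_het + sum(g == 1L, na.rm = TRUE)
  }
  p <- 0.0025
  expect_lt(abs(n_het - n_calls * p), 3 * sqrt(n_calls * p * (1 - p)))
  # every heterozygous call inside a tract is a recorded error (minus any
  # masked by missingness afterwards)
  expect_lte(n_het, nrow(sim$truth$errors))
})

test_that("realized missingness sits within 3 binomial sd of the rate", {
  sim <- simulate_dataset(sim_config(
    seed = 105, n_chromosomes = 2, chromosome_length_bp = 2e7,
    populations = c(P = 25), target_froh = 0.05))
  n_cells <- length(sim$dataset$geno)
  n_miss <- sum(is.na(sim$dataset$geno))
  p <- 0.0014
  expect_lt(abs(n_miss - n_cells * p), 3 * sqrt(n_cells * p * (1 - p)))
  expect_equal(n_miss, nrow(sim$truth$missing))
})

test_that("background heterozygosity follows 2p(1-p) in aggregate", {
  sim <- simulate_dataset(sim_config(
    seed = 106, n_chromosomes = 1, chromosome_length_bp = 1e7,
    populations = c(P = 40), missing_rate = 0))
  # no tracts planted: every call is background
  obs_het <- mean(sim$dataset$geno == 1L)
  # aggregate heterozygosity must match the mean of 2p(1-p) over
  # p ~ U(0.05, 0.95)
  f <- function(p) 2 * p * (1 - p)
  expected <- integrate(f, 0.05, 0.95)$value / 0.9
  expect_lt(abs(obs_het - expected), 0.01)
})

test_that("island carriers share the planted span at the stated fraction", {
  sim <- simulate_dataset(sim_config(
    seed = 107, n_chromosomes = 1, chromosome_length_bp = 2e7,
    populations = c(A = 20, B = 20),
    islands = list(list(chrom = 1, start_bp = 8e6, end_bp = 9.5e6,
                        carrier_fraction = c(A = 0.6, B = 0.1)))))
  isl <- sim$truth$islands
  expect_equal(isl$n_carriers[isl$population == "A"], 12L)
  expect_equal(isl$n_carriers[isl$population == "B"], 2L)
  carr <- sim$truth$tracts[sim$truth$tracts$kind == "island", ]
  expect_equal(nrow(carr), 14L)
  expect_true(all(carr$start_bp == 8e6 & carr$end_bp == 9.5e6))
})

test_that("impossible tract specifications raise a config error", {
  expect_error(sim_config(seed = 1, chromosome_length_bp = 5e6,
                          tract_lengths_bp = 5e5), "at least 1 Mb")
  cfg <- sim_config(seed = 1, n_chromosomes = 1,
                    chromosome_length_bp = 4e6, populations = c(P = 2),
                    tract_lengths_bp = c(3e6, 3e6))
  expect_error(simulate_dataset(cfg), "exceeds chromosome capacity")
  expect_error(sim_config(seed = 1, n_chromosomes = 1,
                          chromosome_length_bp = 5e6,
                          islands = list(list(chrom = 1, start_bp = 4e6,
                                              end_bp = 6e6,
                                              carrier_fraction = 0.5))),
               "exceeds chromosome bounds")
})
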