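# two-pass detection on synthetic data with known planted tracts

sim_clean <- function(seed, tract_lengths, n = 4L, chroms = 2L,
                      chrom_len = 3e7) {
  simulate_dataset(sim_config(
    seed = seed, n_chromosomes = chroms, chromosome_length_bp = chrom_len,
    populations = c(POP = n), tract_lengths_bp = tract_lengths,
    het_error_rate = 0, missing_rate = 0))
}

# detected segments of one sample overlapping a planted tract
seg_for_tract <- function(roh, tract) {
  roh[roh$sample == tract$sample & roh$chrom == tract$chrom &
        roh$start_bp <= tract$end_bp & roh$end_bp >= tract$start_bp, ,
      drop = FALSE]
}

test_that("error-free planted tracts are recovered with their classes", {
  sim <- sim_clean(21, c(3e6, 1e7))
  roh <- suppressWarnings(roh_detect(sim$dataset))
  tr <- sim$truth$tracts
  expect_equal(nrow(tr), 2L * nrow(sim$dataset$samples))
  for (t in seq_len(nrow(tr))) {
    hit <- seg_for_tract(roh, tr[t, ])
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$class, tr$class[t])
    # the segment covers every marker inside the tract; the greedy scan may
    # extend a short way into the homozygous flank (its het allowance is
    # spent on background calls), but never by much
    pos <- sim$dataset$map$pos[sim$dataset$map$chrom == tr$chrom[t]]
    inside <- pos[pos >= tr$start_bp[t] & pos <= tr$end_bp[t]]
    expect_lte(hit$start_bp, min(inside))
    expect_gte(hit$end_bp, max(inside))
    expect_lt(min(inside) - hit$start_bp, 1e6)
    expect_lt(hit$end_bp - max(inside), 1e6)
  }
})

test_that("an error-free tract is identical under pass 1 and pass 2", {
  # an entirely autozygous 5 Mb chromosome: nothing for either pass to trim
  set.seed(22)
  m <- 1400L
  g <- matrix(sample(c(0L, 2L), 3L * m, TRUE), 3L, m)
  ds <- make_ds(g, positions = round(seq(1, 5e6, length.out = m)))
  cfg <- roh_config()
  p1 <- first_pass_roh(ds, cfg)
  params <- suppressWarnings(calibrate_class_params(p1, cfg))
  p2 <- second_pass_roh(ds, params, cfg)
  expect_equal(p1$start_bp, p2$start_bp)
  expect_equal(p1$end_bp, p2$end_bp)
  expect_equal(p1$n_snp, p2$n_snp)
  expect_equal(p2$class, rep("4-8Mb", 3L))
})

# plant heterozygous calls at chosen quantile positions inside each tract
inject_hets <- function(sim, where) {
  ds <- sim$dataset
  tr <- sim$truth$tracts
  for (t in seq_len(nrow(tr))) {
    cols <- which(ds$map$chrom == tr$chrom[t] &
                    ds$map$pos >= tr$start_bp[t] &
                    ds$map$pos <= tr$end_bp[t])
    pick <- cols[pmax(1L, round(where * length(cols)))]
    ds$geno[tr$sample[t], pick] <- 1L
  }
  ds
}

test_that("a >16 Mb tract with 10 scattered errors stays one segment", {
  # 20 Mb autozygous chromosome at HD density (5600 SNPs); 10 error calls
  # must be absorbed by the large-class allowance, not fragment the run
  set.seed(23)
  m <- 5600L
  g <- matrix(sample(c(0L, 2L), 2L * m, TRUE), 2L, m)
  err_at <- round(seq(0.08, 0.92, length.out = 10) * m)
  g[1, err_at] <- 1L
  g[2, err_at] <- 1L
  ds <- make_ds(g, positions = round(seq(1, 2e7, length.out = m)))
  roh <- suppressWarnings(roh_detect(ds))
  expect_equal(nrow(roh), 2L)
  expect_equal(roh$class, rep(">16Mb", 2L))
  expect_equal(roh$n_het, rep(10L, 2L))
  # allowance for the largest class: round(mean SNPs x 0.0025) = 14
  expect_equal(attr(roh, "class_params")$max_het[5L], 14L)
})

test_that("a 1.5 Mb tract with 2 errors yields no call (allowance 1)", {
  sim <- sim_clean(24, 1.5e6, n = 4L, chroms = 1L)
  # hets at 0.38/0.62 of the tract: every window holding at most one of
  # them (0.57 + 0.36 Mb at most) stays under the 1 Mb class minimum
  ds <- inject_hets(sim, c(0.38, 0.62))
  cfg <- roh_config()
  p1 <- first_pass_roh(ds, cfg)
  params <- suppressWarnings(calibrate_class_params(p1, cfg))
  expect_equal(params$max_het[1L], 1L)
  p2 <- second_pass_roh(ds, params, cfg)
  expect_equal(nrow(p2), 0L)
})

test_that("a dataset with no long homozygous stretch yields an empty set", {
  set.seed(31)
  g <- matrix(sample(c(0L, 1L, 2L), 8 * 400, TRUE, prob = c(0.35, 0.4, 0.25)),
              8, 400)
  ds <- make_ds(g, positions = seq(1e5, by = 4e3, length.out = 400))
  p1 <- first_pass_roh(ds, roh_config())
  expect_s3_class(p1, "roh_set")
  expect_equal(nrow(p1), 0L)
})

test_that("detection is invariant to sample order", {
  sim <- simulate_dataset(sim_config(
    seed = 25, n_chromosomes = 1, chromosome_length_bp = 3e7,
    populations = c(POP = 6), tract_lengths_bp = c(2e6, 6e6)))
  ds <- sim$dataset
  perm <- c(4L, 1L, 6L, 3L, 2L, 5L)
  ds2 <- genotype_dataset(ds$map, ds$samples[perm, ],
                          ds$geno[perm, ], ds$alleles)
  strip <- function(x) {
    df <- as.data.frame(x)
    attributes(df) <- attributes(df)[c("names", "row.names", "class")]
    class(df) <- "data.frame"
    df
  }
  r1 <- suppressWarnings(roh_detect(ds))
  r2 <- suppressWarnings(roh_detect(ds2))
  expect_equal(strip(r1), strip(r2))
})

test_that("per-individual segments never overlap within a chromosome", {
  sim <- simulate_dataset(sim_config(
    seed = 26, n_chromosomes = 2, chromosome_length_bp = 2.5e7,
    populations = c(A = 8), target_froh = 0.12))
  roh <- suppressWarnings(roh_detect(sim$dataset))
  by <- split(roh, list(roh$sample, roh$chrom), drop = TRUE)
  for (b in by) {
    if (nrow(b) < 2L) next
    b <- b[order(b$start_bp), ]
    expect_true(all(b$start_bp[-1L] > b$end_bp[-nrow(b)]))
  }
  # and every segment respects its class allowances
  params <- attr(roh, "class_params")
  labs <- params$class
  expect_true(all(roh$n_snp >= 15L))
  expect_true(all(roh$length_bp >= params$min_length_bp[match(roh$class, labs)]))
})
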