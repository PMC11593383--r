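# incidence, z-score thresholding, island merging and cross-population sharing

island_map <- function(m = 200L, chrom = "1", by = 5e4) {
  data.frame(chrom = rep(chrom, m), snp = sprintf("%s_s%d", chrom, 1:m),
             pos = seq(1e5, by = by, length.out = m))
}

test_that("identical segments in every individual give counts = pop size", {
  map <- island_map()
  ids <- sprintf("i%d", 1:8)
  samples <- data.frame(id = ids, population = "P")
  seg <- make_segments(sample = ids, population = "P", chrom = "1",
                       start_bp = 2e6, end_bp = 4e6)
  counts <- incidence_matrix(seg, map, samples, "P")
  inside <- map$pos >= 2e6 & map$pos <= 4e6
  expect_true(all(counts[inside] == 8L))
  expect_true(all(counts[!inside] == 0L))
})

test_that("one individual with one segment marks an indicator vector", {
  map <- island_map(100L)
  samples <- data.frame(id = c("a", "b"), population = "P")
  # segment covering exactly 30 markers
  seg <- make_segments(sample = "a", population = "P", chrom = "1",
                       start_bp = map$pos[11], end_bp = map$pos[40])
  counts <- incidence_matrix(seg, map, samples, "P")
  expect_equal(sum(counts), 30L)
  expect_true(all(counts %in% 0:1))
})

test_that("incidence equals the brute-force double loop on random data", {
  set.seed(55)
  map <- island_map(200L)
  ids <- sprintf("i%02d", 1:20)
  samples <- data.frame(id = ids, population = "P")
  seg <- NULL
  for (id in ids) {
    k <- sample(0:3, 1L)
    if (!k) next
    st <- sort(sample(map$pos, k))
    seg <- rbind(seg, make_segments(
      sample = id, population = "P", chrom = "1", start_bp = st,
      end_bp = pmin(st + sample(2e5:2e6, k), max(map$pos))))
  }
  # keep per-individual segments disjoint, as the detector guarantees
  seg <- do.call(rbind, lapply(split(seg, seg$sample), function(b) {
    b <- b[order(b$start_bp), ]
    keep <- rep(TRUE, nrow(b))
    hi <- -Inf
    for (i in seq_len(nrow(b))) {
      if (b$start_bp[i] <= hi) keep[i] <- FALSE else hi <- b$end_bp[i]
    }
    b[keep, ]
  }))
  counts <- incidence_matrix(seg, map, samples, "P")
  expect_equal(as.integer(counts), oracle_incidence(seg, map, ids))
})

test_that("incidence is invariant to segment and sample order", {
  map <- island_map(50L)
  samples <- data.frame(id = c("a", "b", "c"), population = "P")
  seg <- make_segments(sample = c("a", "b", "c"), population = "P",
                       chrom = "1", start_bp = c(5e5, 1e6, 2e6),
                       end_bp = c(1.5e6, 2.5e6, 3e6))
  c1 <- incidence_matrix(seg, map, samples, "P")
  c2 <- incidence_matrix(seg[3:1, ], map, samples[c(2, 3, 1), ], "P")
  expect_equal(as.integer(c1), as.integer(c2))
})

test_that("uniform incidence has zero sd and no significant SNP", {
  map <- island_map(100L)
  counts <- structure(rep(3L, 100L), population = "P", population_size = 10L)
  expect_warning(scan <- zscore_scan(counts, map = map), "zero variance")
  expect_equal(sum(scan$significant), 0L)
  expect_equal(nrow(call_islands(scan, map)), 0L)
})

test_that("the z-score of an extreme SNP matches direct arithmetic", {
  map <- island_map(100L)
  counts <- structure(c(rep(1L, 99L), 10L), population = "P",
                      population_size = 10L)
  scan <- zscore_scan(counts, map = map)
  pct <- c(rep(10, 99), 100)
  expect_equal(scan$z[100L], (100 - mean(pct)) / sd(pct))
  expect_equal(attr(scan, "mean"), mean(pct))
})

test_that("the significance cut matches the normal quantile for tail 1e-5", {
  cfg <- island_config(tail_fraction = 1e-5)
  map <- island_map(100L)
  counts <- structure(rep(c(1L, 2L), 50L), population = "P",
                      population_size = 10L)
  scan <- zscore_scan(counts, map = map, config = cfg)
  expect_equal(attr(scan, "z_threshold"), qnorm(1 - 1e-5))
  expect_equal(round(attr(scan, "z_threshold"), 4), 4.2649)
  # significance is exactly p < tail on the upper tail
  expect_equal(scan$significant,
               pnorm(scan$z, lower.tail = FALSE) < 1e-5)
})

test_that("lowering the tail fraction never adds significant SNPs", {
  set.seed(66)
  map <- island_map(300L)
  counts <- structure(as.integer(rbinom(300, 20, 0.05) +
                                   c(rep(0, 280), rep(15, 20))),
                      population = "P", population_size = 20L)
  tails <- c(1e-3, 1e-4, 1e-5, 1e-6)
  nsig <- vapply(tails, function(tf)
    sum(zscore_scan(counts, map = map,
                    config = island_config(tail_fraction = tf))$significant),
    numeric(1L))
  expect_true(all(diff(nsig) <= 0))
})

fake_scan <- function(map, sig_idx, population = "P") {
  scan <- data.frame(chrom = map$chrom, snp = map$snp, pos = map$pos,
                     count = 0L, percentage = 0, z = 0, p = 1,
                     significant = seq_len(nrow(map)) %in% sig_idx)
  structure(scan, class = c("island_scan", "data.frame"),
            population = population, population_size = 10L,
            threshold_pct = 50)
}

test_that("contiguous significant SNPs form one island", {
  map <- island_map(200L)
  scan <- fake_scan(map, 51:100)  # 50 SNPs spanning 2.45 Mb
  isl <- call_islands(scan, map)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$n_significant_snp, 50L)
  expect_equal(isl$start_bp, map$pos[51])
  expect_equal(isl$end_bp, map$pos[100])
  expect_equal(isl$n_snp_span, 50L)
})

test_that("the merge gap controls whether clusters fuse, as the oracle says", {
  map <- island_map(200L, by = 5e4)
  sig <- c(10:20, 61:70)  # clusters 2 Mb apart
  for (gap in c(5e5, 3e6)) {
    cfg <- island_config(merge_gap_bp = gap)
    isl <- call_islands(fake_scan(map, sig), map, cfg)
    want <- oracle_merge(rep("1", length(sig)), map$pos[sig], gap, 2L)
    expect_equal(nrow(isl), nrow(want))
    expect_equal(isl$start_bp, want$start)
    expect_equal(isl$end_bp, want$end)
    expect_equal(isl$n_significant_snp, want$n)
  }
  expect_equal(nrow(call_islands(fake_scan(map, c(10:20, 61:70)), map,
                                 island_config(merge_gap_bp = 3e6))), 1L)
})

test_that("islands below the minimum SNP count are discarded", {
  map <- island_map(100L)
  isl <- call_islands(fake_scan(map, c(10, 50:55)), map,
                      island_config(min_island_snps = 2L))
  expect_equal(nrow(isl), 1L)   # the singleton at 10 is dropped
  expect_equal(isl$n_significant_snp, 6L)
})

test_that("identical islands in two populations merge into one region", {
  a <- data.frame(chrom = "1", start_bp = 1e6, end_bp = 2e6,
                  population = "A", n_significant_snp = 10L,
                  n_snp_span = 10L, threshold_pct = 40)
  b <- a; b$population <- "B"
  sh <- shared_islands(list(a, b))
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$populations, "A, B")
  expect_equal(sh$n_member_islands, 2L)
})

test_that("chained overlaps merge transitively into one region", {
  mk <- function(pop, s, e) data.frame(chrom = "2", start_bp = s, end_bp = e,
                                       population = pop,
                                       n_significant_snp = 5L,
                                       n_snp_span = 5L, threshold_pct = 40)
  sh <- shared_islands(list(mk("A", 1e6, 2e6), mk("B", 1.8e6, 3e6),
                            mk("C", 2.9e6, 4e6)))
  expect_equal(nrow(sh), 1L)
  expect_equal(sh$populations, "A, B, C")
  expect_equal(sh$start_bp, 1e6)
  expect_equal(sh$end_bp, 4e6)
  # and regions on different chromosomes or far apart stay separate
  sh2 <- shared_islands(list(mk("A", 1e6, 2e6), mk("B", 5e6, 6e6)))
  expect_equal(nrow(sh2), 2L)
})

test_that("membership bookkeeping: per-population counts sum to memberships", {
  set.seed(77)
  isl <- NULL
  for (p in c("A", "B", "C", "D")) {
    k <- sample(2:5, 1L)
    st <- sort(sample(seq(1e6, 5e7, by = 1e6), k))
    isl <- rbind(isl, data.frame(chrom = sample(c("1", "2"), k, TRUE),
                                 start_bp = st, end_bp = st + 8e5,
                                 population = p, n_significant_snp = 3L,
                                 n_snp_span = 3L, threshold_pct = 40))
  }
  sh <- shared_islands(isl)
  expect_equal(sum(sh$n_member_islands), nrow(isl))
})

test_that("a population shared by all is labelled All when requested", {
  mk <- function(pop) data.frame(chrom = "6", start_bp = 5207637,
                                 end_bp = 6694159, population = pop,
                                 n_significant_snp = 10L, n_snp_span = 61L,
                                 threshold_pct = 40)
  sh <- shared_islands(lapply(c("A", "B", "C"), mk),
                       all_populations = c("A", "B", "C"))
  expect_equal(sh$populations, "All")
})
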