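# Independent brute-force oracles and small fixture builders.
# The oracles recompute everything by direct enumeration/recounting and share
# no code with the package internals.

# Brute-force consecutive-runs reference: at each step take the first
# homozygous marker at/after the cursor, find by exhaustive window recounting
# the largest homozygous-bounded end whose window satisfies the het, missing
# and gap constraints, emit it if it meets the SNP-count and length minima,
# and continue after its end.
oracle_scan <- function(geno, pos, max_het, max_missing, min_snp, min_len_bp,
                        max_gap_bp) {
  n <- length(geno)
  hetv <- !is.na(geno) & geno == 1L
  misv <- is.na(geno)
  homv <- !hetv & !misv
  feasible <- function(s, e) {
    idx <- s:e
    gapok <- if (e > s) max(diff(pos[idx])) <= max_gap_bp else TRUE
    homv[e] && sum(hetv[idx]) <= max_het && sum(misv[idx]) <= max_missing &&
      gapok
  }
  out <- NULL
  cursor <- 1L
  while (cursor <= n) {
    s <- cursor
    while (s <= n && !homv[s]) s <- s + 1L
    if (s > n) break
    feas <- which(vapply(s:n, function(e) feasible(s, e), logical(1)))
    e <- s + max(feas) - 1L
    nhet <- sum(hetv[s:e])
    nmis <- sum(misv[s:e])
    if (e - s + 1L >= min_snp && pos[e] - pos[s] >= min_len_bp)
      out <- rbind(out, data.frame(start_idx = s, end_idx = e,
                                   start_bp = pos[s], end_bp = pos[e],
                                   n_snp = e - s + 1L, n_het = nhet,
                                   n_missing = nmis,
                                   length_bp = pos[e] - pos[s]))
    cursor <- e + 1L
  }
  if (is.null(out))
    out <- data.frame(start_idx = integer(), end_idx = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snp = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = integer())
  rownames(out) <- NULL
  out
}

# random chromosome for scan fuzzing: mostly homozygous with scattered
# heterozygous/missing calls and occasional large gaps
random_chromosome <- function(n_max = 200L) {
  n <- sample(20:n_max, 1L)
  geno <- sample(c(0L, 1L, 2L, NA_integer_), n, replace = TRUE,
                 prob = c(0.45, 0.2, 0.25, 0.1))
  spacing <- sample(c(3000:5000, 150000), n - 1L, replace = TRUE,
                    prob = c(rep(1, 2001), 80))
  pos <- cumsum(c(sample(1000:5000, 1L), spacing))
  list(geno = geno, pos = pos, n = n)
}

# brute-force per-SNP incidence: double loop over individuals and SNPs
oracle_incidence <- function(seg, map, ids) {
  counts <- integer(nrow(map))
  for (k in seq_len(nrow(map))) {
    for (id in ids) {
      s <- seg[seg$sample == id & seg$chrom == map$chrom[k], , drop = FALSE]
      if (nrow(s) && any(s$start_bp <= map$pos[k] & s$end_bp >= map$pos[k]))
        counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# brute-force merge of significant positions into islands
oracle_merge <- function(chrom, pos, merge_gap, min_snps) {
  out <- NULL
  for (ch in unique(chrom)) {
    p <- sort(pos[chrom == ch])
    cur <- p[1L]
    for (i in seq_along(p)[-1L]) {
      if (p[i] - p[i - 1L] > merge_gap) {
        out <- rbind(out, data.frame(chrom = ch, start = cur[1L],
                                     end = cur[length(cur)],
                                     n = length(cur)))
        cur <- p[i]
      } else cur <- c(cur, p[i])
    }
    out <- rbind(out, data.frame(chrom = ch, start = cur[1L],
                                 end = cur[length(cur)], n = length(cur)))
  }
  out[out$n >= min_snps, , drop = FALSE]
}

# small genotype_dataset straight from a code matrix
make_ds <- function(geno, positions = NULL, chrom = NULL,
                    populations = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(positions)) positions <- seq(1e5, by = 5e4, length.out = m)
  if (is.null(chrom)) chrom <- rep("1", m)
  map <- data.frame(chrom = chrom, snp = paste0("s", seq_len(m)),
                    pos = positions)
  samples <- data.frame(id = sprintf("ind%02d", seq_len(n)),
                        population = populations %||%
                          rep("POP", n))
  genotype_dataset(map, samples, geno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ROH-set-like plain data frame for island-stage oracles
make_segments <- function(...) {
  df <- data.frame(...)
  need <- c("sample", "population", "chrom", "start_bp", "end_bp")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$length_bp)) df$length_bp <- df$end_bp - df$start_bp
  df
}
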