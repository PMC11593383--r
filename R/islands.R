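#' ROH-island calling configuration
#'
#' @param tail_fraction one-sided upper-tail p-value cutoff on the incidence
#'   z-score (default \code{1e-5}, i.e. the extreme 0.001\% of the standard
#'   normal; the corresponding z threshold is
#'   \code{qnorm(1 - 1e-5)} = 4.2649). A two-sided variant is available via
#'   \code{two_sided = TRUE}.
#' @param merge_gap_bp maximum distance between consecutive significant SNPs
#'   merged into one island (default 500,000 bp).
#' @param min_island_snps minimum significant SNPs per island (default 2).
#' @param two_sided if \code{TRUE}, use \code{|z|} with tail
#'   \code{tail_fraction/2} per side; default \code{FALSE} (islands are
#'   high-homozygosity outliers, so the upper tail is the relevant one).
#' @param per_chromosome if \code{TRUE}, normalise z-scores per chromosome
#'   instead of over all autosomal SNPs pooled (default \code{FALSE}).
#' @return An object of class \code{island_config}.
#' @export
island_config <- function(tail_fraction = 1e-5, merge_gap_bp = 500000L,
                          min_island_snps = 2L, two_sided = FALSE,
                          per_chromosome = FALSE) {
  if (!is.numeric(tail_fraction) || length(tail_fraction) != 1L ||
      is.na(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 0.5)
    .stopf("tail_fraction must lie strictly between 0 and 0.5")
  merge_gap_bp <- .check_count(merge_gap_bp, "merge_gap_bp")
  min_island_snps <- .check_count(min_island_snps, "min_island_snps", min = 1L)
  structure(list(tail_fraction = tail_fraction, merge_gap_bp = merge_gap_bp,
                 min_island_snps = min_island_snps,
                 two_sided = isTRUE(two_sided),
                 per_chromosome = isTRUE(per_chromosome)),
            class = "island_config")
}

#' Per-SNP ROH incidence counts for one population
#'
#' For every autosomal SNP, the number of the population's individuals
#' having at least one ROH whose span contains the SNP position (the
#' column sums of the presence-absence matrix of SNPs in ROH).
#'
#' @param roh a \code{roh_set}.
#' @param map SNP map data frame; defaults to the map attached to
#'   \code{roh}.
#' @param samples sample table; defaults to the table attached to
#'   \code{roh}.
#' @param population population label to scan.
#' @return Integer vector of counts along the autosomal markers of
#'   \code{map}, with the marker names as names and attributes
#'   \code{population} and \code{population_size}.
#' @export
incidence_matrix <- function(roh, map = NULL, samples = NULL, population) {
  map <- map %||% attr(roh, "map")
  samples <- samples %||% attr(roh, "samples")
  ids <- samples$id[samples$population == population]
  if (!length(ids)) .stopf("population '%s' has no samples", population)
  map <- map[.is_autosome(map$chrom), , drop = FALSE]
  counts <- integer(nrow(map))
  seg <- roh[roh$population == population & .is_autosome(roh$chrom), ,
             drop = FALSE]
  for (ch in unique(seg$chrom)) {
    rows <- which(map$chrom == ch)
    if (!length(rows)) next
    pos <- map$pos[rows]
    s <- seg[seg$chrom == ch, , drop = FALSE]
    # segments of one individual are disjoint, so marking each segment's
    # marker range adds each (individual, SNP) membership at most once
    add <- integer(length(pos))
    i1 <- findInterval(s$start_bp - 1L, pos) + 1L  # first marker >= start
    i2 <- findInterval(s$end_bp, pos)              # last marker <= end
    ok <- i1 <= i2
    for (j in which(ok)) {
      rng <- i1[j]:i2[j]
      add[rng] <- add[rng] + 1L
    }
    counts[rows] <- add
  }
  structure(counts, names = map$snp, population = population,
            population_size = length(ids))
}

#' z-score scan of ROH incidence
#'
#' Converts per-SNP incidence counts into percentages of the population,
#' standardises them against the mean and standard deviation over all
#' autosomal SNPs (or per chromosome if configured) and flags SNPs whose
#' upper-tail normal p-value falls below the configured tail fraction.
#'
#' @param counts incidence counts from [incidence_matrix()].
#' @param population_size number of individuals in the population; defaults
#'   to the attribute carried by \code{counts}.
#' @param map SNP map data frame restricted or restrictable to autosomes;
#'   needed for chromosome/position columns of the scan.
#' @param config an [island_config()].
#' @return A data frame of class \code{island_scan}: \code{chrom},
#'   \code{snp}, \code{pos}, \code{count}, \code{percentage}, \code{z},
#'   \code{p}, \code{significant}, with attributes \code{population},
#'   \code{population_size}, \code{mean}, \code{sd}, \code{z_threshold} and
#'   \code{threshold_pct} (the minimum incidence percentage attained by any
#'   significant SNP).
#' @export
zscore_scan <- function(counts, population_size = attr(counts, "population_size"),
                        map, config = island_config()) {
  if (is.null(population_size) || population_size < 1L)
    .stopf("population_size must be >= 1")
  map <- map[.is_autosome(map$chrom), , drop = FALSE]
  if (nrow(map) != length(counts))
    .stopf("counts length (%d) does not match autosomal map (%d markers)",
           length(counts), nrow(map))
  pct <- as.numeric(counts) / population_size * 100
  if (config$per_chromosome) {
    mu <- stats::ave(pct, map$chrom)
    sdv <- stats::ave(pct, map$chrom, FUN = stats::sd)
  } else {
    mu <- rep(mean(pct), length(pct))
    sdv <- rep(stats::sd(pct), length(pct))
  }
  ok <- is.finite(sdv) & sdv > 0
  if (!all(ok))
    .warnf("incidence has zero variance%s; no SNP can be significant",
           if (config$per_chromosome) " on some chromosome" else "")
  z <- numeric(length(pct))
  z[ok] <- (pct[ok] - mu[ok]) / sdv[ok]
  p <- stats::pnorm(z, lower.tail = FALSE)
  sig <- if (config$two_sided)
    2 * stats::pnorm(abs(z), lower.tail = FALSE) < config$tail_fraction
  else p < config$tail_fraction
  sig <- sig & ok
  out <- data.frame(chrom = map$chrom, snp = map$snp, pos = map$pos,
                    count = as.integer(counts), percentage = pct, z = z,
                    p = p, significant = sig)
  structure(out, class = c("island_scan", "data.frame"),
            population = attr(counts, "population"),
            population_size = population_size,
            mean = if (config$per_chromosome) NA_real_ else mu[1L],
            sd = if (config$per_chromosome) NA_real_ else sdv[1L],
            z_threshold = stats::qnorm(1 - (if (config$two_sided)
              config$tail_fraction / 2 else config$tail_fraction)),
            threshold_pct = if (any(sig)) min(pct[sig]) else NA_real_,
            config = config)
}

#' @export
print.island_scan <- function(x, ...) {
  cat(sprintf("island_scan: population %s (n = %d), %d autosomal SNPs\n",
              attr(x, "population") %||% "?", attr(x, "population_size"),
              nrow(x)))
  cat(sprintf("  incidence mean %.3f%%, sd %.3f%%, z threshold %.4f\n",
              attr(x, "mean"), attr(x, "sd"), attr(x, "z_threshold")))
  cat(sprintf("  significant SNPs: %d (minimum shared percentage %.1f%%)\n",
              sum(x$significant),
              attr(x, "threshold_pct") %||% NA_real_))
  invisible(x)
}

#' Merge significant SNPs into ROH islands
#'
#' Significant SNPs on one chromosome are merged into a single island when
#' consecutive significant SNPs are at most \code{merge_gap_bp} apart;
#' island bounds are the positions of the first and last significant SNP.
#' Islands with fewer than \code{min_island_snps} significant SNPs are
#' discarded.
#'
#' @param scan an \code{island_scan} from [zscore_scan()].
#' @param map SNP map (used to count all mapped SNPs inside the island
#'   span, reported alongside the significant-SNP count).
#' @param config an [island_config()].
#' @return Data frame with one row per island: \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{population},
#'   \code{n_significant_snp}, \code{n_snp_span} (all mapped SNPs within the
#'   bounds), \code{threshold_pct}.
#' @export
call_islands <- function(scan, map = NULL, config = island_config()) {
  sig <- scan[scan$significant, , drop = FALSE]
  out <- data.frame(chrom = character(), start_bp = integer(),
                    end_bp = integer(), population = character(),
                    n_significant_snp = integer(), n_snp_span = integer(),
                    threshold_pct = numeric())
  if (!nrow(sig)) return(out)
  popl <- attr(scan, "population") %||% NA_character_
  thr <- attr(scan, "threshold_pct")
  res <- list(); k <- 0L
  for (ch in .chrom_order(sig$chrom)) {
    pos <- sort(sig$pos[sig$chrom == ch])
    grp <- cumsum(c(1L, as.integer(diff(pos) > config$merge_gap_bp)))
    for (g in unique(grp)) {
      p <- pos[grp == g]
      if (length(p) < config$min_island_snps) next
      span_n <- if (!is.null(map))
        sum(map$chrom == ch & map$pos >= p[1L] & map$pos <= p[length(p)])
      else NA_integer_
      k <- k + 1L
      res[[k]] <- data.frame(chrom = ch, start_bp = p[1L],
                             end_bp = p[length(p)], population = popl,
                             n_significant_snp = length(p),
                             n_snp_span = span_n, threshold_pct = thr)
    }
  }
  if (!k) return(out)
  do.call(rbind, res)
}

#' Cross-population sharing of ROH islands
#'
#' Islands from different populations whose bp intervals overlap on the
#' same chromosome are merged (transitively) into one region spanning their
#' union, labelled with the set of populations. Non-overlapping islands
#' pass through unchanged; the total count of (region, population)
#' memberships equals the summed per-population island counts.
#'
#' @param island_list list of per-population island data frames from
#'   [call_islands()] (or one combined data frame).
#' @param all_populations optional character vector; when given and a region
#'   is shared by every one of them, its population set is printed as
#'   \code{"All"}.
#' @return Data frame with one row per merged region: \code{chrom},
#'   \code{start_bp}, \code{end_bp}, \code{populations} (comma-separated),
#'   \code{n_populations}, \code{n_member_islands},
#'   \code{n_significant_snp} (summed over members).
#' @export
shared_islands <- function(island_list, all_populations = NULL) {
  isl <- if (is.data.frame(island_list)) island_list else
    do.call(rbind, island_list)
  if (is.null(isl) || !nrow(isl))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), populations = character(),
                      n_populations = integer(), n_member_islands = integer(),
                      n_significant_snp = integer()))
  res <- list(); k <- 0L
  for (ch in .chrom_order(isl$chrom)) {
    x <- isl[isl$chrom == ch, , drop = FALSE]
    x <- x[order(x$start_bp, x$end_bp), , drop = FALSE]
    # transitive interval components: a new component starts when an
    # interval begins after the running maximum end
    run_end <- cummax(x$end_bp)
    comp <- cumsum(c(1L, as.integer(x$start_bp[-1L] > run_end[-nrow(x)])))
    for (g in unique(comp)) {
      y <- x[comp == g, , drop = FALSE]
      pops <- sort(unique(y$population))
      lab <- if (!is.null(all_populations) &&
                 setequal(pops, all_populations)) "All"
      else paste(pops, collapse = ", ")
      k <- k + 1L
      res[[k]] <- data.frame(chrom = ch, start_bp = min(y$start_bp),
                             end_bp = max(y$end_bp), populations = lab,
                             n_populations = length(pops),
                             n_member_islands = nrow(y),
                             n_significant_snp = sum(y$n_significant_snp))
    }
  }
  do.call(rbind, res)
}

#' Scan all populations and call shared ROH islands
#'
#' Convenience driver over [incidence_matrix()], [zscore_scan()],
#' [call_islands()] and [shared_islands()] for every population present in
#' the sample table of \code{roh}.
#'
#' @param roh a second-pass \code{roh_set}.
#' @param config an [island_config()].
#' @return A list of class \code{roh_islands}: \code{scans} (per-population
#'   \code{island_scan}s), \code{islands} (per-population island table),
#'   \code{shared} (merged cross-population regions), \code{thresholds}
#'   (per-population minimum shared-SNP percentages).
#' @export
roh_islands <- function(roh, config = island_config()) {
  samples <- attr(roh, "samples")
  map <- attr(roh, "map")
  if (is.null(samples) || is.null(map))
    .stopf("roh must carry sample table and map attributes")
  pops <- sort(unique(samples$population))
  scans <- list(); islands <- list()
  for (p in pops) {
    cnt <- incidence_matrix(roh, map, samples, p)
    scans[[p]] <- zscore_scan(cnt, map = map, config = config)
    islands[[p]] <- call_islands(scans[[p]], map = map, config = config)
  }
  isl <- do.call(rbind, islands)
  rownames(isl) <- NULL
  structure(list(
    scans = scans,
    islands = isl,
    shared = shared_islands(isl, all_populations = pops),
    thresholds = stats::setNames(
      vapply(scans, function(s) attr(s, "threshold_pct") %||% NA_real_,
             numeric(1L)), pops),
    config = config
  ), class = "roh_islands")
}

#' @export
print.roh_islands <- function(x, ...) {
  npop <- length(x$scans)
  cat(sprintf("roh_islands: %d population(s), %d island(s), %d shared region(s)\n",
              npop, if (is.null(x$islands)) 0L else nrow(x$islands),
              if (is.null(x$shared)) 0L else nrow(x$shared)))
  cat("per-population minimum shared-SNP percentages:\n")
  print(round(x$thresholds, 1))
  if (!is.null(x$shared) && nrow(x$shared)) print(x$shared)
  invisible(x)
}

#' @export
plot.roh_islands <- function(x, population = names(x$scans)[1L], ...) {
  s <- x$scans[[population]]
  if (is.null(s)) .stopf("no scan for population '%s'", population)
  chroms <- .chrom_order(s$chrom)
  off <- c(0, cumsum(vapply(chroms, function(ch) max(s$pos[s$chrom == ch]),
                            numeric(1L))))
  xx <- s$pos + off[match(s$chrom, chroms)]
  col <- ifelse(s$significant, "firebrick",
                c("grey40", "grey70")[1L + match(s$chrom, chroms) %% 2L])
  graphics::plot(xx, s$percentage, pch = 16, cex = 0.4, col = col,
                 xlab = "genome position", ylab = "% individuals in ROH",
                 main = sprintf("ROH incidence scan: %s", population), ...)
  thr <- attr(s, "threshold_pct")
  if (!is.null(thr) && is.finite(thr))
    graphics::abline(h = thr, lty = 2, col = "firebrick")
  invisible(x)
}

#' Write per-population incidence scans and island tables
#'
#' @param islands a \code{roh_islands} object.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_islands <- function(islands, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(islands$scans))
    .write_tsv(as.data.frame(islands$scans[[p]]),
               file.path(dir, sprintf("scan_%s.tsv", p)))
  .write_tsv(islands$islands %||% data.frame(),
             file.path(dir, "islands.tsv"))
  .write_tsv(islands$shared %||% data.frame(),
             file.path(dir, "islands_shared.tsv"))
  invisible(dir)
}
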