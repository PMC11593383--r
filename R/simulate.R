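#' Configuration of the synthetic genotype generator
#'
#' Describes a multi-chromosome biallelic SNP map at high-density-chip
#' marker density, Hardy-Weinberg background genotypes with SNP-independent
#' allele frequencies, autozygous tracts planted per individual, optional
#' population-level island regions with a configurable carrier fraction,
#' heterozygous genotyping errors inside autozygous tracts and genome-wide
#' missingness. Everything is reproducible from the mandatory seed.
#'
#' Exactly one of \code{tract_lengths_bp}, \code{tracts_per_class} or
#' \code{target_froh} describes the per-individual planted tracts (or none,
#' for island-only / background-only data).
#'
#' @param seed integer random seed (mandatory).
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length_bp chromosome length in bp (scalar or one value
#'   per chromosome).
#' @param snp_density markers per Mb (default 280, the effective
#'   bovine-HD-chip density after QC).
#' @param populations named integer vector of population sizes.
#' @param tract_lengths_bp lengths (bp) of the tracts planted in every
#'   individual.
#' @param tracts_per_class integer vector, one count per length class, of
#'   tracts planted per individual; lengths are drawn uniformly inside the
#'   class bounds (the open top class spans 16-24 Mb).
#' @param target_froh target autozygous genome fraction per individual
#'   (scalar, or named per population); tract lengths are drawn from a
#'   class mixture (weights \code{class_mix}) until the target is reached.
#' @param class_mix mixture weights over the length classes used by
#'   \code{target_froh} (default \code{c(0.2, 0.25, 0.25, 0.2, 0.1)}).
#' @param islands list of island specifications, each a list with
#'   \code{chrom}, \code{start_bp}, \code{end_bp} and \code{carrier_fraction}
#'   (scalar or named per population), and optionally \code{jitter_bp} for
#'   staggered carrier boundaries.
#' @param het_error_rate probability that a genotype call inside a planted
#'   autozygous tract is corrupted to heterozygous (default 0.0025).
#' @param missing_rate genome-wide missing-call probability (default 0.0014).
#' @param freq_range background allele-frequency range, drawn uniformly
#'   (default \code{c(0.05, 0.95)}).
#' @param class_bounds_mb length-class lower bounds in Mb.
#' @param min_tract_gap_bp minimum distance between two planted tracts of
#'   one individual, so neighbouring tracts cannot fuse into a single run
#'   (default 1,000,000 bp).
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(seed,
                       n_chromosomes = 2L,
                       chromosome_length_bp = 5e7,
                       snp_density = 280,
                       populations = c(POP1 = 25L, POP2 = 25L),
                       tract_lengths_bp = NULL,
                       tracts_per_class = NULL,
                       target_froh = NULL,
                       class_mix = c(0.2, 0.25, 0.25, 0.2, 0.1),
                       islands = list(),
                       het_error_rate = 0.0025,
                       missing_rate = 0.0014,
                       freq_range = c(0.05, 0.95),
                       class_bounds_mb = c(1, 2, 4, 8, 16),
                       min_tract_gap_bp = 1e6) {
  if (missing(seed)) .stopf("sim_config: seed is mandatory")
  seed <- .check_count(seed, "seed")
  n_chromosomes <- .check_count(n_chromosomes, "n_chromosomes", min = 1L)
  chromosome_length_bp <- rep_len(as.numeric(chromosome_length_bp),
                                  n_chromosomes)
  if (any(chromosome_length_bp < 2e6))
    .stopf("chromosomes must be at least 2 Mb")
  if (is.null(names(populations)) || any(populations < 1))
    .stopf("populations must be a named vector of positive sizes")
  .check_fraction(het_error_rate, "het_error_rate", open_upper = TRUE)
  .check_fraction(missing_rate, "missing_rate", open_upper = TRUE)
  n_spec <- sum(!is.null(tract_lengths_bp), !is.null(tracts_per_class),
                !is.null(target_froh))
  if (n_spec > 1L)
    .stopf("give at most one of tract_lengths_bp, tracts_per_class, target_froh")
  if (!is.null(tract_lengths_bp) &&
      any(tract_lengths_bp < class_bounds_mb[1L] * 1e6))
    .stopf("planted tracts must be at least %g Mb", class_bounds_mb[1L])
  for (isl in islands) {
    if (!all(c("chrom", "start_bp", "end_bp", "carrier_fraction") %in%
             names(isl)))
      .stopf("each island needs chrom, start_bp, end_bp, carrier_fraction")
    if (isl$chrom > n_chromosomes ||
        isl$end_bp > chromosome_length_bp[isl$chrom])
      .stopf("island exceeds chromosome bounds")
    if (isl$end_bp - isl$start_bp < class_bounds_mb[1L] * 1e6)
      .stopf("island spans must be at least %g Mb", class_bounds_mb[1L])
  }
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chromosome_length_bp = chromosome_length_bp,
                 snp_density = snp_density, populations = populations,
                 tract_lengths_bp = tract_lengths_bp,
                 tracts_per_class = tracts_per_class,
                 target_froh = target_froh, class_mix = class_mix,
                 islands = islands, het_error_rate = het_error_rate,
                 missing_rate = missing_rate, freq_range = freq_range,
                 class_bounds_mb = class_bounds_mb,
                 min_tract_gap_bp = min_tract_gap_bp),
            class = "sim_config")
}

# draw one tract length for class ci, uniform within the class bounds
# (top class: lower bound to 1.5x lower bound)
.class_len <- function(ci, bounds_mb) {
  lo <- bounds_mb[ci] * 1e6
  hi <- if (ci < length(bounds_mb)) bounds_mb[ci + 1L] * 1e6 else 1.5 * lo
  stats::runif(1L, lo, hi)
}

# place a tract of length len avoiding existing intervals (with a buffer)
.place_tract <- function(len, chrom_len, existing, buffer) {
  for (try in seq_len(200L)) {
    ch <- sample.int(length(chrom_len), 1L, prob = chrom_len)
    if (len >= chrom_len[ch]) next
    start <- sample.int(as.integer(chrom_len[ch] - len), 1L)
    end <- start + as.integer(len)
    ex <- existing[[ch]]
    if (is.null(ex) ||
        !any(start - buffer <= ex[, 2L] & end + buffer >= ex[, 1L]))
      return(list(chrom = ch, start = start, end = end))
  }
  .stopf("could not place a %.0f bp tract: tract spec exceeds chromosome capacity",
         len)
}

#' Simulate a genotype dataset with known autozygosity ground truth
#'
#' Draws a SNP map per chromosome at the configured density, background
#' genotypes from Hardy-Weinberg proportions given per-SNP allele
#' frequencies, plants island tracts for sampled carriers and per-individual
#' autozygous tracts (homozygous stretches, allele chosen by frequency),
#' then corrupts tract calls to heterozygous at the genotyping-error rate
#' and masks calls genome-wide at the missing rate.
#'
#' @param config a [sim_config()].
#' @return A list with \code{dataset} (a [genotype_dataset()]) and
#'   \code{truth} (a \code{sim_truth} list: \code{tracts} data frame with
#'   one row per planted tract, \code{islands} data frame with realized
#'   carrier counts, \code{errors} and \code{missing} data frames of
#'   corrupted cells, and the config).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_chromosomes
  clen <- config$chromosome_length_bp

  maps <- lapply(seq_len(nc), function(ch) {
    n <- max(2L, round(config$snp_density * clen[ch] / 1e6))
    pos <- sort(sample.int(as.integer(clen[ch]), n))
    data.frame(chrom = as.character(ch),
               snp = sprintf("snp%d_%d", ch, seq_len(n)), pos = pos)
  })
  map <- do.call(rbind, maps)
  m <- nrow(map)
  chrom_rows <- lapply(seq_len(nc), function(ch)
    which(map$chrom == as.character(ch)))

  pops <- config$populations
  samples <- data.frame(
    id = unlist(lapply(names(pops), function(p)
      sprintf("%s_%03d", p, seq_len(pops[[p]])))),
    population = rep(names(pops), times = as.integer(pops)))
  n <- nrow(samples)

  p1 <- stats::runif(m, config$freq_range[1L], config$freq_range[2L])
  u <- matrix(stats::runif(n * m), n, m)
  hom1 <- rep(p1^2, each = n)
  het <- rep(2 * p1 * (1 - p1), each = n)
  geno <- matrix((u > hom1) + (u > hom1 + het), n, m)
  storage.mode(geno) <- "integer"

  # --- planted island tracts (population-level), then individual tracts
  tracts <- list(); tk <- 0L
  island_rows <- list()
  occupied <- lapply(seq_len(n), function(i) vector("list", nc))
  add_tract <- function(i, ch, start, end, kind, island_id) {
    tk <<- tk + 1L
    tracts[[tk]] <<- data.frame(
      sample = samples$id[i], population = samples$population[i],
      chrom = as.character(ch), start_bp = start, end_bp = end,
      length_bp = end - start,
      class = classify_roh(end - start, config$class_bounds_mb),
      kind = kind, island_id = island_id)
    occupied[[i]][[ch]] <<- rbind(occupied[[i]][[ch]], c(start, end))
  }
  for (ii in seq_along(config$islands)) {
    isl <- config$islands[[ii]]
    jit <- isl$jitter_bp %||% 0
    for (p in names(pops)) {
      frac <- if (length(isl$carrier_fraction) > 1L)
        isl$carrier_fraction[[p]] else isl$carrier_fraction
      idx <- which(samples$population == p)
      k <- round(frac * length(idx))
      carriers <- if (k) sort(sample(idx, k)) else integer(0)
      for (i in carriers) {
        s <- isl$start_bp; e <- isl$end_bp
        if (jit > 0) {
          s <- max(1L, as.integer(s + round(stats::runif(1L, -jit, jit))))
          e <- min(as.integer(clen[isl$chrom]),
                   as.integer(e + round(stats::runif(1L, -jit, jit))))
        }
        add_tract(i, isl$chrom, as.integer(s), as.integer(e), "island", ii)
      }
      island_rows[[length(island_rows) + 1L]] <- data.frame(
        island_id = ii, chrom = as.character(isl$chrom),
        start_bp = isl$start_bp, end_bp = isl$end_bp, population = p,
        n_carriers = length(carriers),
        carrier_fraction = length(carriers) / length(idx))
    }
  }

  genome_bp <- sum(clen)
  for (i in seq_len(n)) {
    lens <- numeric(0)
    if (!is.null(config$tract_lengths_bp)) {
      lens <- config$tract_lengths_bp
    } else if (!is.null(config$tracts_per_class)) {
      for (ci in seq_along(config$tracts_per_class))
        lens <- c(lens, vapply(seq_len(config$tracts_per_class[ci]),
                               function(x) .class_len(ci, config$class_bounds_mb),
                               numeric(1L)))
    } else if (!is.null(config$target_froh)) {
      tf <- if (length(config$target_froh) > 1L)
        config$target_froh[[samples$population[i]]] else config$target_froh
      planted <- sum(vapply(occupied[[i]], function(x)
        if (is.null(x)) 0 else sum(x[, 2L] - x[, 1L]), numeric(1L)))
      min_bp <- config$class_bounds_mb[1L] * 1e6
      repeat {
        rem <- tf * genome_bp - planted
        if (rem < min_bp) {
          # plant one minimum-size tract with probability rem/min_bp so the
          # expected planted fraction hits the target without bias
          if (rem > 0 && stats::runif(1L) < rem / min_bp)
            lens <- c(lens, min_bp)
          break
        }
        ci <- sample.int(length(config$class_mix), 1L,
                         prob = config$class_mix)
        l <- min(.class_len(ci, config$class_bounds_mb), rem)
        lens <- c(lens, l)
        planted <- planted + l
      }
    }
    for (l in sort(lens, decreasing = TRUE)) {  # longest first: placement
      pl <- .place_tract(l, clen, occupied[[i]], config$min_tract_gap_bp)
      add_tract(i, pl$chrom, pl$start, pl$end, "background", NA_integer_)
    }
  }
  tracts <- if (tk) do.call(rbind, tracts[seq_len(tk)]) else
    data.frame(sample = character(), population = character(),
               chrom = character(), start_bp = integer(),
               end_bp = integer(), length_bp = integer(), class = character(),
               kind = character(), island_id = integer())

  # --- impose homozygosity inside tracts, then errors and missingness
  err <- list(); ek <- 0L
  samp_idx <- stats::setNames(seq_len(n), samples$id)
  if (nrow(tracts)) {
    for (t in seq_len(nrow(tracts))) {
      ch <- as.integer(tracts$chrom[t])
      rows <- chrom_rows[[ch]]
      pos <- map$pos[rows]
      sel <- rows[pos >= tracts$start_bp[t] & pos <= tracts$end_bp[t]]
      if (!length(sel)) next
      i <- samp_idx[[tracts$sample[t]]]
      hom <- ifelse(stats::runif(length(sel)) < p1[sel], 0L, 2L)
      flip <- stats::runif(length(sel)) < config$het_error_rate
      hom[flip] <- 1L
      geno[i, sel] <- hom
      if (any(flip)) {
        ek <- ek + 1L
        err[[ek]] <- data.frame(sample = tracts$sample[t],
                                chrom = tracts$chrom[t],
                                pos = map$pos[sel[flip]])
      }
    }
  }
  errors <- if (ek) do.call(rbind, err[seq_len(ek)]) else
    data.frame(sample = character(), chrom = character(), pos = integer())

  miss <- which(stats::runif(n * m) < config$missing_rate)
  geno[miss] <- NA_integer_
  missing <- data.frame(sample = samples$id[(miss - 1L) %% n + 1L],
                        snp = map$snp[(miss - 1L) %/% n + 1L])

  ds <- genotype_dataset(map, samples, geno)
  truth <- structure(list(tracts = tracts,
                          islands = if (length(island_rows))
                            do.call(rbind, island_rows) else NULL,
                          errors = errors, missing = missing,
                          config = config), class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d planted tracts (%d island, %d background), %d het errors, %d missing calls\n",
              nrow(x$tracts), sum(x$tracts$kind == "island"),
              sum(x$tracts$kind == "background"), nrow(x$errors),
              nrow(x$missing)))
  invisible(x)
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Writes the PLINK fileset (text and/or binary dialect), a two-column
#' sample-to-population sidecar and the ground-truth tract table as TSV, so
#' the fixture round-trips through [read_plink()].
#'
#' @param ds a [genotype_dataset()].
#' @param truth a \code{sim_truth} from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @param name file-name prefix (default \code{"sim"}).
#' @param dialects subset of \code{c("ped", "bed")}.
#' @return The file prefix, invisibly.
#' @export
write_fixture <- function(ds, truth, dir, name = "sim",
                          dialects = c("ped", "bed")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(dir, name)
  for (d in dialects) write_plink(ds, prefix, d)
  .write_tsv(ds$samples[, c("id", "population")],
             paste0(prefix, "_populations.tsv"))
  .write_tsv(truth$tracts, paste0(prefix, "_truth_tracts.tsv"))
  if (!is.null(truth$islands))
    .write_tsv(truth$islands, paste0(prefix, "_truth_islands.tsv"))
  invisible(prefix)
}
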