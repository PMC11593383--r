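# Two-pass consecutive-runs ROH detection:
#   pass 1 (permissive) -> per-class calibration of allowances -> pass 2
#   (per-class scans reconciled into one disjoint segment set per individual)

.round_rule <- function(x, rule) {
  switch(rule,
         nearest = floor(x + 0.5),   # conventional half-up rounding
         floor = floor(x),
         ceiling = ceiling(x))
}

.roh_set <- function(segments, config, pass, class_params = NULL,
                     samples = NULL, map = NULL) {
  rownames(segments) <- NULL
  structure(segments, class = c("roh_set", "data.frame"),
            config = config, pass = pass, class_params = class_params,
            samples = samples, map = map)
}

# per-chromosome marker blocks of the autosomal map
.chrom_blocks <- function(ds) {
  ds <- .autosomal(ds)
  if (!nrow(ds$map)) .stopf("no autosomal markers in dataset")
  chroms <- .chrom_order(ds$map$chrom)
  lapply(chroms, function(ch) {
    idx <- which(ds$map$chrom == ch)
    list(chrom = ch, pos = ds$map$pos[idx],
         geno = ds$geno[, idx, drop = FALSE])
  })
}

.scan_all <- function(blocks, samples, max_het, max_missing, min_snp,
                      min_len_bp, max_gap_bp) {
  out <- vector("list", length(blocks) * nrow(samples))
  k <- 0L
  for (bl in blocks) {
    for (i in seq_len(nrow(samples))) {
      runs <- scan_consecutive(bl$geno[i, ], bl$pos, max_het, max_missing,
                               min_snp, min_len_bp, max_gap_bp)
      if (nrow(runs)) {
        runs$sample <- samples$id[i]
        runs$population <- samples$population[i]
        runs$chrom <- bl$chrom
        k <- k + 1L
        out[[k]] <- runs
      }
    }
  }
  if (!k) return(NULL)
  do.call(rbind, out[seq_len(k)])
}

# canonical segment order: by sample id, then chromosome, then position,
# so the result is byte-identical whatever the input sample order
.order_segments <- function(seg) {
  seg[order(seg$sample, match(seg$chrom, .chrom_order(seg$chrom)),
            seg$start_bp), , drop = FALSE]
}

.seg_columns <- c("sample", "population", "chrom", "start_bp", "end_bp",
                  "start_idx", "end_idx", "n_snp", "n_het", "n_missing",
                  "length_bp", "class")

.empty_segments <- function() {
  df <- data.frame(sample = character(), population = character(),
                   chrom = character(), start_bp = integer(),
                   end_bp = integer(), start_idx = integer(),
                   end_idx = integer(), n_snp = integer(), n_het = integer(),
                   n_missing = integer(), length_bp = integer(),
                   class = character())
  df[, .seg_columns]
}

#' Permissive first-pass ROH detection
#'
#' Detects all potential runs with the permissive allowances
#' (\code{pass1_max_het}, \code{pass1_max_missing} of the configuration) and
#' the smallest class bound as minimum length, labelling each run with its
#' length class. The per-class mean SNP counts of this pass feed
#' [calibrate_class_params()].
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param config a [roh_config()].
#' @return A \code{roh_set} (data frame of segments with detection metadata).
#' @export
first_pass_roh <- function(ds, config = roh_config()) {
  stopifnot(inherits(config, "roh_config"))
  blocks <- .chrom_blocks(ds)
  seg <- .scan_all(blocks, ds$samples, config$pass1_max_het,
                   config$pass1_max_missing, config$min_snp_count,
                   config$class_bounds_mb[1L] * 1e6, config$max_gap_bp)
  if (is.null(seg)) {
    seg <- .empty_segments()
  } else {
    seg$class <- classify_roh(seg$length_bp, config$class_bounds_mb)
    seg <- .order_segments(seg[, .seg_columns])
  }
  .roh_set(seg, config, pass = 1L, samples = ds$samples, map = ds$map)
}

#' Calibrate per-class heterozygote and missing-call allowances
#'
#' For each length class, the allowance of heterozygous calls is the mean
#' SNP count of the class's first-pass runs multiplied by the assumed
#' genotyping-error rate, rounded under the configured rule; the allowance
#' of missing calls uses the assumed missing-call rate in the same way. Both
#' are floored at \code{min_allowance} for populated classes. Classes with
#' no first-pass runs inherit the nearest populated class's parameters, with
#' a warning.
#'
#' @param pass1 a first-pass \code{roh_set} from [first_pass_roh()].
#' @param config a [roh_config()].
#' @return A \code{roh_class_params} data frame with one row per class:
#'   \code{class}, \code{n_runs}, \code{mean_snp_count},
#'   \code{mean_length_bp}, \code{max_het}, \code{max_missing},
#'   \code{min_length_bp}.
#' @export
calibrate_class_params <- function(pass1, config = attr(pass1, "config")) {
  stopifnot(inherits(config, "roh_config"))
  labs <- roh_class_labels(config$class_bounds_mb)
  k <- length(labs)
  n_runs <- integer(k); mean_snp <- rep(NA_real_, k)
  mean_len <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    sel <- pass1$class == labs[i]
    n_runs[i] <- sum(sel)
    if (n_runs[i]) {
      mean_snp[i] <- mean(pass1$n_snp[sel])
      mean_len[i] <- mean(pass1$length_bp[sel])
    }
  }
  if (!any(n_runs > 0)) .stopf("calibration impossible: no first-pass runs in any class")
  pop <- which(n_runs > 0)
  for (i in which(n_runs == 0)) {
    near <- pop[which.min(abs(pop - i))]
    .warnf("length class %s has no first-pass runs; inheriting parameters from %s",
           labs[i], labs[near])
    mean_snp[i] <- mean_snp[near]
    mean_len[i] <- mean_len[near]
  }
  basis <- if (config$calibration_basis == "snp") mean_snp else mean_len
  max_het <- pmax(config$min_allowance,
                  .round_rule(basis * config$genotype_error_rate,
                              config$rounding_rule))
  max_missing <- pmax(config$min_allowance,
                      .round_rule(basis * config$missing_rate,
                                  config$rounding_rule))
  structure(data.frame(
    class = labs, n_runs = n_runs,
    mean_snp_count = mean_snp, mean_length_bp = mean_len,
    max_het = as.integer(max_het), max_missing = as.integer(max_missing),
    min_length_bp = as.integer(config$class_bounds_mb * 1e6)
  ), class = c("roh_class_params", "data.frame"), config = config)
}

# greedy reconciliation of the five per-class scans for one sample/chromosome:
# candidates whose realized length class matches their scan's class win over
# mismatched ones, then longer segments, then fewer heterozygotes; accepted
# segments never overlap
.reconcile <- function(cand) {
  ord <- order(!cand$matched, -cand$length_bp, cand$n_het, cand$start_bp,
               cand$scan_class)
  cand <- cand[ord, , drop = FALSE]
  acc_s <- integer(0); acc_e <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start_bp[i] <= acc_e & cand$end_bp[i] >= acc_s)) {
      keep[i] <- TRUE
      acc_s <- c(acc_s, cand$start_bp[i])
      acc_e <- c(acc_e, cand$end_bp[i])
    }
  }
  cand[keep, , drop = FALSE]
}

#' Calibrated second-pass ROH detection
#'
#' Runs one consecutive scan per length class with that class's calibrated
#' allowances and minimum length, assigns every candidate run to the class
#' matching its realized length, and reconciles the per-class scans so each
#' genomic stretch of an individual yields exactly one segment: candidates
#' whose realized length falls inside their scan's class bounds win, ties
#' are broken by longer segment and then by fewer heterozygotes; accepted
#' segments never overlap.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param params a \code{roh_class_params} from [calibrate_class_params()].
#' @param config a [roh_config()].
#' @return A second-pass \code{roh_set}.
#' @export
second_pass_roh <- function(ds, params, config = attr(params, "config")) {
  stopifnot(inherits(config, "roh_config"), inherits(params, "data.frame"))
  blocks <- .chrom_blocks(ds)
  labs <- roh_class_labels(config$class_bounds_mb)
  samples <- ds$samples
  out <- list(); k <- 0L
  for (bl in blocks) {
    for (i in seq_len(nrow(samples))) {
      g <- bl$geno[i, ]
      cand <- NULL
      for (ci in seq_len(nrow(params))) {
        runs <- scan_consecutive(g, bl$pos, params$max_het[ci],
                                 params$max_missing[ci],
                                 config$min_snp_count,
                                 params$min_length_bp[ci],
                                 config$max_gap_bp)
        if (nrow(runs)) {
          runs$scan_class <- ci
          cand <- if (is.null(cand)) runs else rbind(cand, runs)
        }
      }
      if (is.null(cand)) next
      cand$class <- classify_roh(cand$length_bp, config$class_bounds_mb)
      cand$matched <- cand$class == labs[cand$scan_class]
      cand <- .reconcile(cand)
      if (nrow(cand)) {
        cand$sample <- samples$id[i]
        cand$population <- samples$population[i]
        cand$chrom <- bl$chrom
        k <- k + 1L
        out[[k]] <- cand
      }
    }
  }
  seg <- if (k) .order_segments(do.call(rbind, out)[, .seg_columns]) else
    .empty_segments()
  .roh_set(seg, config, pass = 2L, class_params = params,
           samples = ds$samples, map = ds$map)
}

#' Detect runs of homozygosity (two-pass, class-calibrated)
#'
#' The main fitting function: a permissive first pass determines the mean
#' SNP count of each length class, per-class heterozygote/missing allowances
#' are calibrated from the assumed genotyping-error and missing-call rates,
#' and a calibrated second pass produces the final segment set.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param config a [roh_config()].
#' @return A \code{roh_set}: a data frame of ROH segments (columns
#'   \code{sample}, \code{population}, \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{start_idx}, \code{end_idx}, \code{n_snp},
#'   \code{n_het}, \code{n_missing}, \code{length_bp}, \code{class}) with
#'   the configuration, calibrated class parameters, sample table and map
#'   attached as attributes. Methods: \code{print}, \code{summary} (breed
#'   summary), \code{plot} (class composition).
#' @examples
#' sim <- simulate_dataset(sim_config(seed = 1, n_chromosomes = 1,
#'   chromosome_length_bp = 2e7, populations = c(POP = 4),
#'   tract_lengths_bp = c(3e6, 8e6)))
#' roh <- roh_detect(sim$dataset)
#' summary(roh)
#' @export
roh_detect <- function(ds, config = roh_config()) {
  pass1 <- first_pass_roh(ds, config)
  params <- calibrate_class_params(pass1, config)
  out <- second_pass_roh(ds, params, config)
  attr(out, "pass1_n") <- nrow(pass1)
  out
}

#' @export
print.roh_set <- function(x, ...) {
  cat(sprintf("roh_set: %d segments in %d individual(s) (pass %d)\n",
              nrow(x), length(unique(x$sample)), attr(x, "pass")))
  if (nrow(x)) {
    cat(sprintf("  mean %.1f SNPs, mean length %s bp\n", mean(x$n_snp),
                format(round(mean(x$length_bp)), big.mark = ",")))
    print(table(population = x$population, class = x$class))
  }
  invisible(x)
}

#' @export
summary.roh_set <- function(object, ...) {
  breed_summary(object, attr(object, "samples"))
}

#' @export
plot.roh_set <- function(x, ...) {
  if (!nrow(x)) {
    graphics::plot.new()
    graphics::title("no ROH segments")
    return(invisible(x))
  }
  tab <- table(x$class, x$population)
  labs <- roh_class_labels(attr(x, "config")$class_bounds_mb)
  tab <- tab[intersect(labs, rownames(tab)), , drop = FALSE]
  pct <- sweep(tab, 2L, colSums(tab), "/") * 100
  graphics::barplot(pct, beside = TRUE, legend.text = rownames(pct),
                    ylab = "% of ROH", xlab = "population",
                    main = "ROH length-class composition", ...)
  invisible(x)
}

#' Write ROH segments as tab-separated text
#'
#' Column layout is a superset of the detectRUNS output table
#' (sample, population, chromosome, bp span, SNP counts, class).
#'
#' @param roh a \code{roh_set}.
#' @param path output file path.
#' @export
write_roh <- function(roh, path) .write_tsv(as.data.frame(roh), path)
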