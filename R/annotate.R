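#' Read a gene-annotation interval table
#'
#' Accepts either BED (0-based half-open; converted to the internal 1-based
#' inclusive convention by adding 1 to starts) or a tab-separated table with
#' columns chrom/start/end/name already 1-based inclusive. Format is chosen
#' by file extension unless given.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"bed"} or \code{"tsv"}.
#' @return Data frame: \code{chrom}, \code{start_bp}, \code{end_bp},
#'   \code{gene}, \code{source}.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 4L) .stopf("%s: need at least 4 columns (chrom start end name)", path)
  out <- data.frame(chrom = df[[1L]],
                    start_bp = as.integer(df[[2L]]),
                    end_bp = as.integer(df[[3L]]),
                    gene = df[[4L]],
                    source = format)
  if (anyNA(out$start_bp) || anyNA(out$end_bp))
    .stopf("%s: non-integer interval bounds", path)
  if (format == "bed") out$start_bp <- out$start_bp + 1L
  if (any(out$start_bp > out$end_bp))
    .stopf("%s: interval with start > end", path)
  out
}

#' Genes overlapping ROH islands
#'
#' Offline interval overlap between called islands and a user-supplied gene
#' annotation table: a gene is reported for an island if and only if the two
#' 1-based inclusive intervals share at least one bp on the same chromosome.
#'
#' @param islands island data frame (\code{chrom}, \code{start_bp},
#'   \code{end_bp}, ...), e.g. from [call_islands()] or [shared_islands()].
#' @param genes gene interval data frame from [read_gene_intervals()].
#' @return \code{islands} with two added columns: \code{n_genes} and
#'   \code{genes} (comma-separated symbols).
#' @export
overlap_genes <- function(islands, genes) {
  if (nrow(islands) && nrow(genes) &&
      !length(intersect(unique(islands$chrom), unique(genes$chrom)))) {
    hint <- if (any(grepl("^chr", genes$chrom)) != any(grepl("^chr", islands$chrom)))
      " (one input uses a 'chr' prefix, the other does not)" else ""
    .stopf("no chromosome label shared between islands (%s) and genes (%s)%s",
           paste(utils::head(unique(islands$chrom), 3), collapse = ","),
           paste(utils::head(unique(genes$chrom), 3), collapse = ","), hint)
  }
  hits <- character(nrow(islands))
  nh <- integer(nrow(islands))
  for (i in seq_len(nrow(islands))) {
    g <- genes[genes$chrom == islands$chrom[i] &
                 genes$start_bp <= islands$end_bp[i] &
                 genes$end_bp >= islands$start_bp[i], , drop = FALSE]
    nh[i] <- nrow(g)
    hits[i] <- paste(g$gene, collapse = ", ")
  }
  islands$n_genes <- nh
  islands$genes <- hits
  islands
}

#' Per-population ROH summary statistics
#'
#' The standard per-breed ROH description: total segment count (N_ROH),
#' mean and sd of per-individual counts (A_ROH; individuals without any ROH
#' count as zero), mean and sd of SNPs per segment, the maximum SNP count,
#' mean/sd/max segment length in Mb, and the percentage of segments per
#' length class.
#'
#' @param roh a second-pass \code{roh_set}.
#' @param samples sample table; defaults to the one attached to \code{roh}.
#' @return Data frame of class \code{breed_summary}, one row per population,
#'   with per-class percentage columns summing to 100.
#' @export
breed_summary <- function(roh, samples = attr(roh, "samples")) {
  if (is.null(samples)) .stopf("no sample table available")
  cfg <- attr(roh, "config") %||% roh_config()
  labs <- roh_class_labels(cfg$class_bounds_mb)
  pops <- sort(unique(samples$population))
  rows <- lapply(pops, function(p) {
    ids <- samples$id[samples$population == p]
    seg <- roh[roh$population == p, , drop = FALSE]
    if (!nrow(seg)) {
      .warnf("population %s has no ROH segments", p)
      cls <- rep(0, length(labs))
    } else {
      cls <- as.numeric(table(factor(seg$class, levels = labs))) /
        nrow(seg) * 100
    }
    per_ind <- table(factor(seg$sample, levels = ids))
    base <- data.frame(
      population = p,
      n_individuals = length(ids),
      n_roh = nrow(seg),
      a_roh_mean = mean(per_ind),
      a_roh_sd = if (length(ids) > 1L) stats::sd(per_ind) else 0,
      n_snp_mean = if (nrow(seg)) mean(seg$n_snp) else 0,
      n_snp_sd = if (nrow(seg) > 1L) stats::sd(seg$n_snp) else 0,
      max_snp = if (nrow(seg)) max(seg$n_snp) else 0,
      mean_length_mb = if (nrow(seg)) mean(seg$length_bp) / 1e6 else 0,
      sd_length_mb = if (nrow(seg) > 1L) stats::sd(seg$length_bp) / 1e6 else 0,
      max_length_mb = if (nrow(seg)) max(seg$length_bp) / 1e6 else 0)
    cls <- as.data.frame(as.list(cls))
    names(cls) <- paste0("pct_", gsub("[^0-9A-Za-z]+", "_", labs))
    cbind(base, cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("breed_summary", "data.frame"))
}

#' @export
print.breed_summary <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], function(v) round(v, 1))  # Mb shown to 1 decimal
  print(y)
  invisible(x)
}
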