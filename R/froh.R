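#' Map-covered autosomal genome length
#'
#' Sum over autosomes of the span between the first and last mapped SNP.
#' This is the default denominator of F_ROH: numerator and denominator then
#' refer to the same chip coverage. A fixed assembly length can be supplied
#' to [compute_froh()] instead.
#'
#' @param map a SNP map data frame (\code{chrom}, \code{snp}, \code{pos}).
#' @return Total length in bp. Single-marker chromosomes contribute 0, with
#'   a warning.
#' @export
genome_length_from_map <- function(map) {
  map <- map[.is_autosome(map$chrom), , drop = FALSE]
  if (!nrow(map)) .stopf("no autosomal markers in map")
  spans <- vapply(unique(map$chrom), function(ch) {
    p <- map$pos[map$chrom == ch]
    if (length(p) < 2L) {
      .warnf("chromosome %s has a single marker; it contributes 0 bp", ch)
      return(0)
    }
    diff(range(p))
  }, numeric(1L))
  sum(spans)
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH of an individual is the sum of its ROH lengths divided by the
#' considered genome length: the proportion of the (mapped) genome that lies
#' in runs of homozygosity. Samples present in the sample table but without
#' any ROH get F_ROH = 0.
#'
#' @param roh a \code{roh_set} from [roh_detect()].
#' @param genome_length_bp denominator in bp; defaults to
#'   [genome_length_from_map()] on the map attached to \code{roh}. Pass a
#'   fixed assembly length to override.
#' @param samples sample table (\code{id}, \code{population}); defaults to
#'   the table attached to \code{roh}.
#' @return A data frame of class \code{froh}: \code{sample},
#'   \code{population}, \code{sum_roh_bp}, \code{genome_length_bp},
#'   \code{f_roh}.
#' @export
compute_froh <- function(roh, genome_length_bp = NULL, samples = NULL) {
  samples <- samples %||% attr(roh, "samples")
  if (is.null(samples)) .stopf("no sample table available")
  if (is.null(genome_length_bp)) {
    map <- attr(roh, "map")
    if (is.null(map)) .stopf("no map attached to roh; supply genome_length_bp")
    genome_length_bp <- genome_length_from_map(map)
  }
  if (genome_length_bp <= 0) .stopf("genome_length_bp must be positive")
  unknown <- setdiff(unique(roh$sample), samples$id)
  if (length(unknown))
    .stopf("segments from sample(s) absent from the sample table: %s",
           paste(utils::head(unknown, 5), collapse = ", "))
  sums <- tapply(roh$length_bp, roh$sample, sum)
  sum_bp <- as.numeric(sums[samples$id])
  sum_bp[is.na(sum_bp)] <- 0
  out <- data.frame(sample = samples$id, population = samples$population,
                    sum_roh_bp = sum_bp,
                    genome_length_bp = genome_length_bp,
                    f_roh = sum_bp / genome_length_bp)
  structure(out, class = c("froh", "data.frame"))
}

#' Per-population F_ROH summaries
#'
#' @param records a \code{froh} data frame from [compute_froh()].
#' @return Data frame with one row per population (ordered by descending
#'   mean F_ROH): \code{n}, \code{mean}, \code{sd}, \code{min}, \code{q25},
#'   \code{median}, \code{q75}, \code{max}.
#' @export
summarize_froh <- function(records) {
  sp <- split(records$f_roh, records$population)
  out <- do.call(rbind, lapply(names(sp), function(p) {
    x <- sp[[p]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(population = p, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else 0,
               min = min(x), q25 = q[1L], median = q[2L], q75 = q[3L],
               max = max(x))
  }))
  out <- out[order(-out$mean, out$population), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
summary.froh <- function(object, ...) summarize_froh(object)

#' @export
print.froh <- function(x, ...) {
  cat(sprintf("F_ROH for %d individuals (genome length %s bp)\n", nrow(x),
              format(x$genome_length_bp[1L], big.mark = ",")))
  print(summarize_froh(x))
  invisible(x)
}

#' @export
plot.froh <- function(x, ...) {
  s <- summarize_froh(x)
  graphics::boxplot(f_roh ~ factor(population, levels = s$population),
                    data = x, xlab = "population", ylab = expression(F[ROH]),
                    main = "Genomic inbreeding by population", ...)
  invisible(x)
}
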