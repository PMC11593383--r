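#' Overall genotyping rate
#'
#' Fraction of non-missing cells in the genotype matrix.
#'
#' @param ds a [genotype_dataset()].
#' @return A fraction in \code{[0, 1]}.
#' @export
genotyping_rate <- function(ds) {
  if (!length(ds$geno)) .stopf("empty dataset")
  1 - mean(is.na(ds$geno))
}

#' Apply marker- and sample-level missingness filters
#'
#' Mirrors the common SNP-array QC of removing markers with too many missing
#' calls and then individuals with too many missing calls (the \code{--geno}
#' then \code{--mind} convention): markers with missing fraction above
#' \code{max_marker_missing} are removed first, then samples whose missing
#' fraction computed on the surviving markers exceeds
#' \code{max_sample_missing}. No minor-allele-frequency filter is applied
#' anywhere: rare alleles are informative for runs of homozygosity.
#'
#' @param ds a [genotype_dataset()].
#' @param max_marker_missing maximum tolerated per-marker missing fraction
#'   (default 0.1).
#' @param max_sample_missing maximum tolerated per-sample missing fraction
#'   (default 0.1).
#' @return A list with elements \code{dataset} (the filtered
#'   [genotype_dataset()]) and \code{report} (a \code{qc_report}: counts
#'   before/after, per-marker and per-sample missing fractions, and the
#'   post-QC overall genotyping rate).
#' @export
apply_qc <- function(ds, max_marker_missing = 0.1, max_sample_missing = 0.1) {
  .check_fraction(max_marker_missing, "max_marker_missing")
  .check_fraction(max_sample_missing, "max_sample_missing")
  miss <- is.na(ds$geno)
  marker_missing <- colMeans(miss)
  keep_m <- marker_missing <= max_marker_missing
  if (!any(keep_m)) .stopf("all data filtered: no marker passes --geno %.3g",
                           max_marker_missing)
  geno2 <- ds$geno[, keep_m, drop = FALSE]
  sample_missing <- rowMeans(is.na(geno2))
  keep_s <- sample_missing <= max_sample_missing
  if (!any(keep_s)) .stopf("all data filtered: no sample passes --mind %.3g",
                           max_sample_missing)
  out <- ds
  out$map <- ds$map[keep_m, , drop = FALSE]
  out$alleles <- ds$alleles[keep_m, , drop = FALSE]
  out$samples <- ds$samples[keep_s, , drop = FALSE]
  out$geno <- geno2[keep_s, , drop = FALSE]
  rownames(out$map) <- NULL
  rownames(out$samples) <- NULL
  report <- structure(list(
    markers_before = ncol(ds$geno), markers_after = ncol(out$geno),
    samples_before = nrow(ds$geno), samples_after = nrow(out$geno),
    max_marker_missing = max_marker_missing,
    max_sample_missing = max_sample_missing,
    marker_missing = stats::setNames(marker_missing, ds$map$snp),
    sample_missing = stats::setNames(sample_missing, ds$samples$id),
    genotyping_rate = genotyping_rate(out)
  ), class = "qc_report")
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP-array QC report\n")
  cat(sprintf("  markers: %d -> %d (--geno %.3g)\n",
              x$markers_before, x$markers_after, x$max_marker_missing))
  cat(sprintf("  samples: %d -> %d (--mind %.3g)\n",
              x$samples_before, x$samples_after, x$max_sample_missing))
  cat(sprintf("  overall genotyping rate (post-QC): %.4f\n",
              x$genotyping_rate))
  invisible(x)
}

#' @describeIn apply_qc write the QC report as tab-separated text
#' @param report a \code{qc_report}.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    metric = c("markers_before", "markers_after", "samples_before",
               "samples_after", "genotyping_rate"),
    value = c(report$markers_before, report$markers_after,
              report$samples_before, report$samples_after,
              report$genotyping_rate))
  .write_tsv(df, path)
}
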