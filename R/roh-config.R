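#' ROH detection configuration
#'
#' Parameters of consecutive-runs ROH detection and of the two-pass
#' calibration of per-length-class heterozygote and missing-call allowances.
#' Defaults follow the high-density-chip settings in common use: a run must
#' contain at least 15 SNPs, consecutive SNPs may be at most 100 kb apart,
#' the assumed genotyping-error rate (heterozygous calls inside truly
#' autozygous tracts) is 0.25% and the assumed missing-call rate is 0.14%.
#' Runs are stratified into five length classes: 1-2, 2-4, 4-8, 8-16 and
#' >16 Mb.
#'
#' The first, permissive pass uses the allowances of the most permissive
#' class (\code{pass1_max_het}, \code{pass1_max_missing}) so it never
#' under-segments relative to the calibrated second pass.
#'
#' @param min_snp_count minimum SNPs per run (default 15).
#' @param max_gap_bp maximum gap between consecutive SNPs in a run, bp
#'   (default 100,000).
#' @param genotype_error_rate assumed heterozygous-error rate (default
#'   0.0025).
#' @param missing_rate assumed missing-call rate (default 0.0014).
#' @param class_bounds_mb ascending lower bounds of the length classes in Mb
#'   (default \code{c(1, 2, 4, 8, 16)}; the last class is open-ended).
#' @param rounding_rule how calibrated allowances are rounded:
#'   \code{"nearest"}, \code{"floor"} or \code{"ceiling"}.
#' @param min_allowance lower floor for calibrated allowances of populated
#'   classes (default 1; set 0 to allow zero-tolerance classes).
#' @param calibration_basis \code{"snp"} (allowance = rounded mean SNP count
#'   per class times the rate; default) or \code{"bp"} (mean bp length times
#'   the rate, offered for sensitivity analysis only).
#' @param pass1_max_het,pass1_max_missing allowances used by the permissive
#'   first pass (defaults 12 and 8).
#' @return An object of class \code{roh_config}.
#' @export
roh_config <- function(min_snp_count = 15L,
                       max_gap_bp = 100000L,
                       genotype_error_rate = 0.0025,
                       missing_rate = 0.0014,
                       class_bounds_mb = c(1, 2, 4, 8, 16),
                       rounding_rule = c("nearest", "floor", "ceiling"),
                       min_allowance = 1L,
                       calibration_basis = c("snp", "bp"),
                       pass1_max_het = 12L,
                       pass1_max_missing = 8L) {
  rounding_rule <- match.arg(rounding_rule)
  calibration_basis <- match.arg(calibration_basis)
  min_snp_count <- .check_count(min_snp_count, "min_snp_count", min = 2L)
  max_gap_bp <- .check_count(max_gap_bp, "max_gap_bp", min = 1L)
  .check_fraction(genotype_error_rate, "genotype_error_rate", open_upper = TRUE)
  .check_fraction(missing_rate, "missing_rate", open_upper = TRUE)
  if (length(class_bounds_mb) < 1L || any(diff(class_bounds_mb) <= 0) ||
      any(class_bounds_mb <= 0))
    .stopf("class_bounds_mb must be positive and strictly increasing")
  min_allowance <- .check_count(min_allowance, "min_allowance")
  structure(list(
    min_snp_count = min_snp_count,
    max_gap_bp = max_gap_bp,
    genotype_error_rate = genotype_error_rate,
    missing_rate = missing_rate,
    class_bounds_mb = as.numeric(class_bounds_mb),
    rounding_rule = rounding_rule,
    min_allowance = min_allowance,
    calibration_basis = calibration_basis,
    pass1_max_het = .check_count(pass1_max_het, "pass1_max_het"),
    pass1_max_missing = .check_count(pass1_max_missing, "pass1_max_missing")
  ), class = "roh_config")
}

#' @export
print.roh_config <- function(x, ...) {
  cat("ROH detection configuration (consecutive-runs)\n")
  cat(sprintf("  min SNPs/run %d, max gap %s bp\n", x$min_snp_count,
              format(x$max_gap_bp, big.mark = ",")))
  cat(sprintf("  genotype error rate %.4g, missing rate %.4g (%s-based, %s rounding)\n",
              x$genotype_error_rate, x$missing_rate, x$calibration_basis,
              x$rounding_rule))
  cat("  length classes:", paste(roh_class_labels(x$class_bounds_mb),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Length-class labels
#'
#' @param class_bounds_mb ascending class lower bounds in Mb.
#' @return Character labels, e.g. \code{"1-2Mb"}, \code{">16Mb"}.
#' @export
roh_class_labels <- function(class_bounds_mb = c(1, 2, 4, 8, 16)) {
  k <- length(class_bounds_mb)
  c(if (k > 1L) sprintf("%g-%gMb", class_bounds_mb[-k], class_bounds_mb[-1L]),
    sprintf(">%gMb", class_bounds_mb[k]))
}

#' Assign a run length to its length class
#'
#' Classes are half-open \code{[lower, upper)} in Mb; the top class is
#' open-ended.
#'
#' @param length_bp run length in bp.
#' @param class_bounds_mb ascending class lower bounds in Mb.
#' @return The class label (factor level ordering follows the bounds).
#' @examples
#' classify_roh(1999999) # "1-2Mb"
#' classify_roh(2000000) # "2-4Mb"
#' @export
classify_roh <- function(length_bp, class_bounds_mb = c(1, 2, 4, 8, 16)) {
  bounds_bp <- class_bounds_mb * 1e6
  if (any(length_bp < bounds_bp[1L]))
    .stopf("length %s bp is below the smallest class bound (%g Mb)",
           format(min(length_bp), big.mark = ","), class_bounds_mb[1L])
  labs <- roh_class_labels(class_bounds_mb)
  labs[findInterval(length_bp, bounds_bp)]
}
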