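# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# autosome labels are plain integers ("1".."29"); sex chromosomes and
# anything non-numeric are excluded from ROH scans
.is_autosome <- function(chrom) grepl("^[0-9]+$", as.character(chrom))

.check_fraction <- function(x, name, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (open_upper) x >= 1 else x > 1))
    .stopf("'%s' must be a single fraction in [0,%s], got %s",
           name, if (open_upper) "1)" else "1]", format(x))
  invisible(x)
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    .stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

# stable order of chromosome labels: numeric labels first in numeric order,
# then the rest alphabetically
.chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), ifelse(is.na(num), Inf, num), u)]
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
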