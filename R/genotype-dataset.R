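#' Assemble a genotype dataset
#'
#' Container for a SNP map, a sample table and a genotype-code matrix, the
#' substrate of every downstream stage (QC, ROH detection, inbreeding,
#' islands). Genotypes are stored allele-order-free as integer codes:
#' \code{0} = homozygous for the first allele, \code{1} = heterozygous,
#' \code{2} = homozygous for the second allele, \code{NA} = missing. ROH
#' detection only distinguishes homozygous / heterozygous / missing, but both
#' homozygote codes (plus the per-marker allele labels) are preserved so that
#' files round-trip exactly.
#'
#' @param map data frame with columns \code{chrom} (chromosome label,
#'   character), \code{snp} (unique marker name) and \code{pos} (1-based bp
#'   position, strictly increasing within a chromosome).
#' @param samples data frame with columns \code{id} (unique sample id),
#'   \code{population} (label, required for every sample) and optionally
#'   \code{sex}.
#' @param geno integer matrix, samples in rows and markers in columns, codes
#'   in \code{c(0, 1, 2, NA)}.
#' @param alleles optional data frame with per-marker allele labels
#'   \code{a1}, \code{a2}; defaults to "A"/"B".
#'
#' @return An object of class \code{genotype_dataset}.
#' @seealso [read_plink()], [apply_qc()], [roh_detect()]
#' @export
genotype_dataset <- function(map, samples, geno, alleles = NULL) {
  map <- as.data.frame(map)
  samples <- as.data.frame(samples)
  if (!all(c("chrom", "snp", "pos") %in% names(map)))
    .stopf("map needs columns chrom, snp, pos")
  if (!all(c("id", "population") %in% names(samples)))
    .stopf("samples needs columns id, population")
  map$chrom <- as.character(map$chrom)
  map$snp <- as.character(map$snp)
  if (anyNA(suppressWarnings(as.integer(map$pos))))
    .stopf("map positions must be integers")
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$snp))
    .stopf("duplicate marker names in map (e.g. '%s')",
           map$snp[duplicated(map$snp)][1L])
  if (anyDuplicated(samples$id))
    .stopf("duplicate sample ids (e.g. '%s')",
           samples$id[duplicated(samples$id)][1L])
  if (any(is.na(samples$population) | samples$population == ""))
    .stopf("every sample needs a population label")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples) || ncol(geno) != nrow(map))
    .stopf("genotype matrix is %d x %d but there are %d samples and %d markers",
           nrow(geno), ncol(geno), nrow(samples), nrow(map))
  bad <- geno[!is.na(geno)]
  if (length(bad) && !all(bad %in% 0:2))
    .stopf("genotype codes must be 0, 1, 2 or NA")
  if (is.null(alleles))
    alleles <- data.frame(a1 = rep("A", nrow(map)), a2 = rep("B", nrow(map)))

  # enforce chromosome grouping and ascending positions
  ord <- order(match(map$chrom, .chrom_order(map$chrom)), map$pos)
  if (any(ord != seq_along(ord))) {
    .warnf("map not sorted by chromosome/position; reordering markers")
    map <- map[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    alleles <- alleles[ord, , drop = FALSE]
    rownames(map) <- NULL
    rownames(alleles) <- NULL
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (anyDuplicated(p))
      .stopf("duplicate bp position on chromosome %s", ch)
  }
  rownames(geno) <- samples$id
  colnames(geno) <- map$snp
  structure(list(map = map, samples = samples, geno = geno, alleles = alleles),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers on %d chromosome(s)\n",
              nrow(x$samples), nrow(x$map), length(unique(x$map$chrom))))
  tab <- table(x$samples$population)
  cat("populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  cat(sprintf("genotyping rate: %.4f\n", genotyping_rate(x)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$geno)

# markers restricted to autosomes, as used by every ROH stage
.autosomal <- function(ds) {
  keep <- .is_autosome(ds$map$chrom)
  if (all(keep)) return(ds)
  ds$map <- ds$map[keep, , drop = FALSE]
  ds$geno <- ds$geno[, keep, drop = FALSE]
  ds$alleles <- ds$alleles[keep, , drop = FALSE]
  rownames(ds$map) <- NULL
  ds
}
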