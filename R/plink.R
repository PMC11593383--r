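#' Read PLINK-format genotype data
#'
#' Reads either the whitespace-separated text dialect (\code{.ped}/\code{.map})
#' or the SNP-major binary dialect (\code{.bed}/\code{.bim}/\code{.fam},
#' magic bytes \code{0x6c 0x1b 0x01}). Population labels are taken from the
#' family-id column, or from a two-column sample-to-population sidecar file.
#' Markers are re-sorted per chromosome by ascending position if needed, with
#' a warning.
#'
#' @param prefix path prefix of the fileset (without extension).
#' @param dialect \code{"auto"} (default: binary preferred if present),
#'   \code{"ped"} or \code{"bed"}.
#' @param pop_file optional path to a whitespace-separated two-column file
#'   (sample id, population) overriding the family-id column.
#' @return A [genotype_dataset()].
#' @export
read_plink <- function(prefix, dialect = c("auto", "ped", "bed"),
                       pop_file = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (file.exists(paste0(prefix, ".bed"))) "bed" else "ped"
  ds <- if (dialect == "ped") .read_ped(prefix) else .read_bed(prefix)
  if (!is.null(pop_file)) {
    pops <- utils::read.table(pop_file, header = FALSE,
                              col.names = c("id", "population"),
                              colClasses = "character")
    m <- match(ds$samples$id, pops$id)
    if (anyNA(m))
      .stopf("samples missing from population file '%s': %s", pop_file,
             paste(utils::head(ds$samples$id[is.na(m)], 5), collapse = ", "))
    ds$samples$population <- pops$population[m]
  }
  ds
}

.read_map <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  mp <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(mp) == 4L) mp <- mp[, c(1L, 2L, 4L)]
  if (ncol(mp) != 3L)
    .stopf("%s: expected 3 or 4 columns, found %d", path, ncol(mp))
  names(mp) <- c("chrom", "snp", "pos")
  pos <- suppressWarnings(as.integer(mp$pos))
  if (anyNA(pos))
    .stopf("%s line %d: position '%s' is not an integer",
           path, which(is.na(pos))[1L], mp$pos[which(is.na(pos))[1L]])
  mp$pos <- pos
  mp
}

.read_fam_cols <- function(tok) {
  data.frame(id = tok[, 2L], population = tok[, 1L],
             sex = c("1" = "M", "2" = "F")[tok[, 5L]],
             stringsAsFactors = FALSE, row.names = NULL)
}

.read_ped <- function(prefix) {
  pedf <- paste0(prefix, ".ped")
  map <- .read_map(paste0(prefix, ".map"))
  if (!file.exists(pedf)) .stopf("file not found: %s", pedf)
  lines <- readLines(pedf)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  want <- 6L + 2L * m
  nt <- lengths(toks)
  if (any(nt != want))
    .stopf("%s line %d: expected %d fields (6 + 2 x %d markers), found %d",
           pedf, which(nt != want)[1L], want, m, nt[nt != want][1L])
  tok <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  samples <- .read_fam_cols(tok)
  n <- nrow(samples)
  geno <- matrix(NA_integer_, n, m)
  a1 <- character(m); a2 <- character(m)
  for (j in seq_len(m)) {
    x <- tok[, 6L + 2L * j - 1L]
    y <- tok[, 6L + 2L * j]
    miss <- x == "0" | y == "0"
    al <- sort(unique(c(x[!miss], y[!miss])))
    if (length(al) > 2L)
      .stopf("%s: marker %s has %d alleles (%s); biallelic input required",
             pedf, map$snp[j], length(al), paste(al, collapse = "/"))
    a1[j] <- if (length(al) >= 1L) al[1L] else "A"
    a2[j] <- if (length(al) == 2L) al[2L] else "B"
    g <- (x == a2[j]) + (y == a2[j])
    g[miss] <- NA_integer_
    geno[, j] <- g
  }
  genotype_dataset(map, samples, geno, data.frame(a1 = a1, a2 = a2))
}

# 2-bit codes in .bed: 00 hom a1, 01 missing, 10 het, 11 hom a2
.BED_DECODE <- {
  dec <- rep(NA_integer_, 4L)
  dec[0L + 1L] <- 0L; dec[2L + 1L] <- 1L; dec[3L + 1L] <- 2L
  dec
}

.read_bed <- function(prefix) {
  bimf <- paste0(prefix, ".bim"); famf <- paste0(prefix, ".fam")
  bedf <- paste0(prefix, ".bed")
  for (f in c(bimf, famf, bedf))
    if (!file.exists(f)) .stopf("file not found: %s", f)
  bim <- utils::read.table(bimf, header = FALSE, colClasses = "character")
  if (ncol(bim) != 6L) .stopf("%s: expected 6 columns", bimf)
  names(bim) <- c("chrom", "snp", "cm", "pos", "a1", "a2")
  pos <- suppressWarnings(as.integer(bim$pos))
  if (anyNA(pos))
    .stopf("%s line %d: position '%s' is not an integer",
           bimf, which(is.na(pos))[1L], bim$pos[which(is.na(pos))[1L]])
  map <- data.frame(chrom = bim$chrom, snp = bim$snp, pos = pos)
  fam <- utils::read.table(famf, header = FALSE, colClasses = "character")
  if (ncol(fam) < 5L) .stopf("%s: expected >= 5 columns", famf)
  samples <- .read_fam_cols(as.matrix(fam))
  n <- nrow(samples); m <- nrow(map)
  raw <- readBin(bedf, "raw", n = file.size(bedf))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    .stopf("%s: missing PLINK bed magic bytes", bedf)
  if (raw[3L] != as.raw(0x01))
    .stopf("%s: only SNP-major bed files are supported", bedf)
  bpm <- ceiling(n / 4)  # bytes per marker
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpm * m)
    .stopf("%s: size mismatch (%d data bytes for %d samples x %d markers)",
           bedf, length(body), n, m)
  bytes <- matrix(body, nrow = bpm, ncol = m)
  geno <- matrix(NA_integer_, n, m)
  for (off in 0:3) {
    if (off + 1L > n) break
    rows <- seq.int(off + 1L, n, by = 4L)
    two <- (bytes[ceiling(rows / 4), , drop = FALSE] %/% (4L^off)) %% 4L
    geno[rows, ] <- .BED_DECODE[two + 1L]
  }
  genotype_dataset(map, samples, geno, bim[, c("a1", "a2")])
}

#' Write a genotype dataset in PLINK format
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix.
#' @param dialect \code{"ped"} for \code{.ped}/\code{.map} text,
#'   \code{"bed"} for \code{.bed}/\code{.bim}/\code{.fam} binary.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(ds, prefix, dialect = c("ped", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "ped") .write_ped(ds, prefix) else .write_bed(ds, prefix)
  invisible(prefix)
}

.fam_lines <- function(samples) {
  sex <- c(M = "1", F = "2")[as.character(samples$sex %||% NA)]
  sex[is.na(sex)] <- "0"
  paste(samples$population, samples$id, "0", "0", sex, "-9")
}

.write_ped <- function(ds, prefix) {
  writeLines(paste(ds$map$chrom, ds$map$snp, "0", ds$map$pos, sep = "\t"),
             paste0(prefix, ".map"))
  m <- nrow(ds$map)
  a1 <- ds$alleles$a1; a2 <- ds$alleles$a2
  lines <- .fam_lines(ds$samples)
  out <- vapply(seq_len(nrow(ds$geno)), function(i) {
    g <- ds$geno[i, ]
    x <- ifelse(is.na(g), "0", ifelse(g == 2L, a2, a1))
    y <- ifelse(is.na(g), "0", ifelse(g == 0L, a1, a2))
    paste(c(rbind(x, y)), collapse = " ")
  }, character(1L))
  writeLines(paste(lines, out), paste0(prefix, ".ped"))
}

.write_bed <- function(ds, prefix) {
  writeLines(paste(ds$map$chrom, ds$map$snp, "0", ds$map$pos,
                   ds$alleles$a1, ds$alleles$a2, sep = "\t"),
             paste0(prefix, ".bim"))
  writeLines(.fam_lines(ds$samples), paste0(prefix, ".fam"))
  n <- nrow(ds$geno); m <- ncol(ds$geno)
  enc <- c(0L, 2L, 3L)  # genotype code 0/1/2 -> 2-bit value
  codes <- matrix(1L, nrow = 4L * ceiling(n / 4), ncol = m)  # pad = missing
  g <- ds$geno
  v <- enc[g + 1L]
  v[is.na(g)] <- 1L
  codes[seq_len(n), ] <- v
  i <- seq.int(1L, nrow(codes), by = 4L)
  bytes <- codes[i, , drop = FALSE] + 4L * codes[i + 1L, , drop = FALSE] +
    16L * codes[i + 2L, , drop = FALSE] + 64L * codes[i + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
}
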