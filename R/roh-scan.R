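#' Consecutive-runs scan of one chromosome of one individual
#'
#' Core of the consecutive-runs ROH method: markers are scanned in map
#' order and a run is extended until its allowance of heterozygous calls
#' (\code{max_het}) or missing calls (\code{max_missing}) would be exceeded,
#' or until two consecutive markers are more than \code{max_gap_bp} apart.
#' The call that would exceed an allowance terminates the run before that
#' call. Runs always start and end on a homozygous non-missing call (leading
#' and trailing heterozygous/missing calls are trimmed), and the next run is
#' sought after the previous run's trimmed end, so returned runs are disjoint
#' and ordered. Runs with fewer than \code{min_snp} markers or spanning less
#' than \code{min_len_bp} are discarded. No sliding windows are involved.
#'
#' Run length is defined as \code{end_bp - start_bp} (positions of the last
#' and first SNP of the run, both 1-based).
#'
#' @param geno integer genotype codes for one sample on one chromosome
#'   (0/2 homozygous, 1 heterozygous, NA missing), in map order.
#' @param positions bp positions, strictly ascending, same length as
#'   \code{geno}.
#' @param max_het maximum heterozygous calls tolerated inside a run.
#' @param max_missing maximum missing calls tolerated inside a run.
#' @param min_snp minimum number of SNPs per reported run.
#' @param min_len_bp minimum reported run length in bp.
#' @param max_gap_bp maximum gap between consecutive run SNPs in bp.
#' @return A data frame with one row per run: \code{start_idx},
#'   \code{end_idx} (marker indices), \code{start_bp}, \code{end_bp},
#'   \code{n_snp}, \code{n_het}, \code{n_missing}, \code{length_bp}.
#' @export
scan_consecutive <- function(geno, positions, max_het, max_missing,
                             min_snp = 15L, min_len_bp = 1e6,
                             max_gap_bp = 100000L) {
  n <- length(geno)
  if (length(positions) != n)
    .stopf("geno and positions differ in length (%d vs %d)", n,
           length(positions))
  if (n > 1L && any(diff(positions) <= 0))
    .stopf("positions must be strictly ascending")
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snp = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = integer())
  if (n == 0L) return(empty)

  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  hom <- !het & !mis
  homidx <- which(hom)
  if (!length(homidx)) return(empty)
  cumhet <- cumsum(het)
  cummis <- cumsum(mis)
  hetpos <- which(het)
  mispos <- which(mis)
  nhet <- length(hetpos)
  nmis <- length(mispos)
  # last homozygous marker at or before each index (0 if none)
  lh <- cummax(seq_len(n) * hom)
  # end of the gap-free block containing each marker
  gapafter <- which(diff(positions) > max_gap_bp)
  blockend <- if (length(gapafter)) {
    ends <- c(gapafter, n)
    ends[findInterval(seq_len(n), c(0L, gapafter) + 1L)]
  } else rep.int(n, n)

  cap <- 16L
  r_s <- integer(cap); r_e <- integer(cap); cnt <- 0L
  hp <- 1L
  nh <- length(homidx)
  cursor <- 1L
  repeat {
    while (hp <= nh && homidx[hp] < cursor) hp <- hp + 1L
    if (hp > nh) break
    s <- homidx[hp]
    rh <- cumhet[s] + max_het + 1L
    e_h <- if (rh <= nhet) hetpos[rh] - 1L else n
    rm <- cummis[s] + max_missing + 1L
    e_m <- if (rm <= nmis) mispos[rm] - 1L else n
    e <- min(e_h, e_m, blockend[s])
    ee <- lh[e]  # >= s because s itself is homozygous
    if (ee - s + 1L >= min_snp && positions[ee] - positions[s] >= min_len_bp) {
      cnt <- cnt + 1L
      if (cnt > cap) {
        cap <- cap * 2L
        length(r_s) <- cap; length(r_e) <- cap
      }
      r_s[cnt] <- s; r_e[cnt] <- ee
    }
    cursor <- ee + 1L
  }
  if (!cnt) return(empty)
  s <- r_s[seq_len(cnt)]; e <- r_e[seq_len(cnt)]
  data.frame(
    start_idx = s, end_idx = e,
    start_bp = positions[s], end_bp = positions[e],
    n_snp = e - s + 1L,
    n_het = cumhet[e] - cumhet[s] + as.integer(het[s]),
    n_missing = cummis[e] - cummis[s] + as.integer(mis[s]),
    length_bp = positions[e] - positions[s])
}
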