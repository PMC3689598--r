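# Independent oracles and fixture builders used across the suite.
# The oracles deliberately avoid the package's Biostrings-based machinery:
# they scan plain character vectors position by position.

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

.rc_chr <- function(s) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# every 0-based start where the IUPAC pattern matches the character vector
oracle_occurrences <- function(seqchar, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  L <- length(pat)
  n <- length(seqchar)
  if (n < L) return(integer())
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & seqchar[seq_len(n - L + 1L) + j - 1L] %in% .IUPAC_SETS[[pat[j]]]
  }
  which(ok) - 1L
}

# unblocked cut positions of one enzyme, both strands for non-palindromes
oracle_cuts <- function(seqchar, enzyme, track = NULL, chrom = "chr1") {
  L <- nchar(enzyme$recognition)
  blocked_at <- function(occ) {
    if (is.null(track) || !nrow(track) || !length(enzyme$blocked_by)) {
      return(rep(FALSE, length(occ)))
    }
    t <- track[track$chrom == chrom & track$mark %in% enzyme$blocked_by, ,
               drop = FALSE]
    vapply(occ, function(o) any(t$pos >= o & t$pos < o + L), logical(1))
  }
  occ <- oracle_occurrences(seqchar, enzyme$recognition)
  cuts <- (occ + enzyme$cut_offset)[!blocked_at(occ)]
  pal <- enzyme$recognition == .rc_chr(enzyme$recognition)
  if (!pal && enzyme$double_stranded_scan) {
    occm <- oracle_occurrences(seqchar, .rc_chr(enzyme$recognition))
    cuts <- c(cuts, (occm + (L - enzyme$cut_offset))[!blocked_at(occm)])
  }
  sort(unique(cuts))
}

oracle_digest <- function(seqchar, enzymes, track = NULL, chrom = "chr1") {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  n <- length(seqchar)
  cuts <- sort(unique(unlist(lapply(enzymes, oracle_cuts, seqchar = seqchar,
                                    track = track, chrom = chrom))))
  cuts <- cuts[cuts > 0 & cuts < n]
  b <- c(0L, cuts, n)
  data.frame(start = b[-length(b)], end = b[-1L])
}

# brute-force re-derivation of the RDA enrichment on one chromosome
oracle_rda <- function(seqchar, track, tester, driver, window = c(100, 1000),
                       chrom = "chr1") {
  tcuts <- oracle_cuts(seqchar, tester, track, chrom)
  dcuts <- oracle_cuts(seqchar, driver, track, chrom)
  fr <- oracle_digest(seqchar, tester, track, chrom)
  n <- length(seqchar)
  keep <- logical(nrow(fr))
  for (i in seq_len(nrow(fr))) {
    s <- fr$start[i]; e <- fr$end[i]
    if (s == 0 || e == n) next                     # terminal
    len <- e - s
    if (len < window[1] || len > window[2]) next
    if (!(s %in% dcuts) || !(e %in% dcuts)) keep[i] <- TRUE
  }
  sprintf("%s:%d-%d", chrom, fr$start[keep], fr$end[keep])
}

random_seqchar <- function(n, gc = 0.45) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# random mark track over the cytosines of a character sequence
random_track <- function(seqchar, rate = 0.05, chrom = "chr1") {
  plusC <- which(seqchar == "C") - 1L
  minusC <- which(seqchar == "G") - 1L
  pos <- c(plusC, minusC)
  strand <- c(rep("+", length(plusC)), rep("-", length(minusC)))
  hit <- runif(length(pos)) < rate
  if (!any(hit)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), mark = character()))
  }
  data.frame(chrom = chrom, pos = pos[hit], strand = strand[hit],
             mark = sample(c("5mC", "5hmC"), sum(hit), replace = TRUE),
             stringsAsFactors = FALSE)
}

mutate_seq <- function(s, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(s, "")[[1]]
  at <- sample(length(ch), k)
  for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
  paste(ch, collapse = "")
}

# exhaustive two-sided rank-sum p-value by listing every group assignment
brute_wilcoxon <- function(a, b) {
  x <- c(a, b)
  r <- rank(x)
  na <- length(a)
  w <- sum(r[seq_len(na)])
  all_w <- apply(combn(length(x), na), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(all_w <= w + 1e-9), mean(all_w >= w - 1e-9)))
}
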