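.gr <- function(chrom, start, end) {
  # 0-based half-open -> GRanges (1-based inclusive)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

#' Classify sites into promoter / exon / intron / intergenic regions
#'
#' Promoters are the strand-aware window `[TSS - promoter_len, TSS)` (for
#' minus-strand genes the window extends downstream in genome coordinates
#' from the gene end). When a site hits several annotations the precedence is
#' exon > intron > promoter > intergenic, gene-body evidence outranking a
#' neighboring gene's promoter window; ties between genes within one category
#' go to the smallest gene id. Intergenic regions are the maximal intervals
#' covered by neither a gene span nor a promoter window, identified by their
#' coordinates. Every site receives exactly one category and one owner.
#'
#' @param sites data.frame with `chrom` and `pos` (0-based) columns.
#' @param genes data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param exons data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @param chrom_lengths named vector of chromosome lengths (bp), used to
#'   enumerate intergenic intervals.
#' @param promoter_len promoter window size in bp (default the 5 kb
#'   convention).
#' @return `sites` with added `category` and `owner` columns; category
#'   fractions are attached as `attr(, "fractions")`.
#' @export
classify_regions <- function(sites, genes, exons, chrom_lengths,
                             promoter_len = 5000L) {
  if (nrow(sites) && !all(sites$chrom %in% names(chrom_lengths))) {
    stop("site chromosome absent from annotation: ",
         setdiff(unique(sites$chrom), names(chrom_lengths))[1])
  }
  n <- nrow(sites)
  category <- rep("intergenic", n)
  owner <- rep(NA_character_, n)
  pos_gr <- .gr(sites$chrom, sites$pos, sites$pos + 1L)

  promoters <- .promoter_intervals(genes, chrom_lengths, promoter_len)
  layers <- list(
    exon = exons,
    intron = .intron_intervals(genes, exons),
    promoter = promoters
  )
  assigned <- rep(FALSE, n)
  for (cat in names(layers)) {
    iv <- layers[[cat]]
    if (is.null(iv) || !nrow(iv)) next
    hits <- GenomicRanges::findOverlaps(pos_gr, .gr(iv$chrom, iv$start, iv$end))
    if (!length(hits)) next
    h <- data.frame(q = S4Vectors::queryHits(hits),
                    gene = iv$gene_id[S4Vectors::subjectHits(hits)])
    h <- h[!assigned[h$q], , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(h$q, h$gene), , drop = FALSE]   # smallest gene id wins ties
    h <- h[!duplicated(h$q), , drop = FALSE]
    category[h$q] <- cat
    owner[h$q] <- h$gene
    assigned[h$q] <- TRUE
  }

  inter <- intergenic_regions(genes, chrom_lengths, promoter_len)
  if (any(!assigned) && nrow(inter)) {
    hits <- GenomicRanges::findOverlaps(pos_gr,
                                        .gr(inter$chrom, inter$start, inter$end))
    h <- data.frame(q = S4Vectors::queryHits(hits),
                    id = inter$region_id[S4Vectors::subjectHits(hits)])
    h <- h[!assigned[h$q], , drop = FALSE]
    owner[h$q] <- h$id
  }
  # a site inside a gene span but in no exon/intron/promoter (e.g. exactly on
  # a boundary base not covered by the strandwise layout) stays intergenic by
  # construction of the layers; ownership falls back to its coordinates
  owner[is.na(owner)] <- sprintf("%s:%d", sites$chrom[is.na(owner)],
                                 sites$pos[is.na(owner)])
  sites$category <- category
  sites$owner <- owner
  fr <- table(factor(category,
                     levels = c("promoter", "exon", "intron", "intergenic")))
  attr(sites, "fractions") <- if (n) as.numeric(fr) / n else as.numeric(fr)
  names(attr(sites, "fractions")) <- names(fr)
  sites
}

.promoter_intervals <- function(genes, chrom_lengths, promoter_len) {
  if (!nrow(genes)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer()))
  }
  start <- ifelse(genes$strand == "+", genes$start - promoter_len, genes$end)
  end <- ifelse(genes$strand == "+", genes$start, genes$end + promoter_len)
  start <- pmax(0L, start)
  end <- pmin(end, chrom_lengths[genes$chrom])
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  out[out$end > out$start, , drop = FALSE]
}

.intron_intervals <- function(genes, exons) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    if (!nrow(ex)) next
    gaps <- IRanges::setdiff(IRanges::IRanges(g$start + 1L, g$end),
                             IRanges::IRanges(ex$start + 1L, ex$end))
    if (!length(gaps)) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom,
      start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(gene_id = character(), chrom = character(), start = integer(),
               end = integer())
}

#' Enumerate intergenic regions
#'
#' Maximal intervals not covered by any gene span or promoter window, per
#' chromosome, with coordinate-based identifiers.
#'
#' @inheritParams classify_regions
#' @return data.frame `region_id`, `chrom`, `start`, `end`.
#' @export
intergenic_regions <- function(genes, chrom_lengths, promoter_len = 5000L) {
  proms <- .promoter_intervals(genes, chrom_lengths, promoter_len)
  out <- list()
  for (ch in names(chrom_lengths)) {
    cov <- IRanges::IRanges()
    g <- genes[genes$chrom == ch, , drop = FALSE]
    p <- proms[proms$chrom == ch, , drop = FALSE]
    if (nrow(g)) cov <- c(cov, IRanges::IRanges(g$start + 1L, g$end))
    if (nrow(p)) cov <- c(cov, IRanges::IRanges(p$start + 1L, p$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, chrom_lengths[[ch]]),
                             IRanges::reduce(cov))
    if (!length(gaps)) next
    out[[length(out) + 1L]] <- data.frame(
      region_id = sprintf("%s:%d-%d", ch, IRanges::start(gaps) - 1L,
                          IRanges::end(gaps)),
      chrom = ch, start = IRanges::start(gaps) - 1L,
      end = IRanges::end(gaps), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(region_id = character(), chrom = character(),
               start = integer(), end = integer())
}

#' Genomic baseline of region-category fractions
#'
#' Base-coverage fractions of promoter/exon/intron/intergenic over the whole
#' genome under the same precedence as [classify_regions()], so a synthetic
#' run produces its own neutral reference column.
#'
#' @inheritParams classify_regions
#' @return named numeric vector of four fractions summing to 1.
#' @export
genomic_baseline <- function(genes, exons, chrom_lengths,
                             promoter_len = 5000L) {
  total <- sum(chrom_lengths)
  cnt <- c(promoter = 0, exon = 0, intron = 0, intergenic = 0)
  for (ch in names(chrom_lengths)) {
    sel <- function(df) df[df$chrom == ch, , drop = FALSE]
    r <- function(df) if (nrow(df)) IRanges::reduce(
      IRanges::IRanges(df$start + 1L, df$end)) else IRanges::IRanges()
    ex <- r(sel(exons))
    inr <- r(sel(.intron_intervals(genes, exons)))
    pr <- r(sel(.promoter_intervals(genes, chrom_lengths, promoter_len)))
    inr <- IRanges::setdiff(inr, ex)
    pr <- IRanges::setdiff(IRanges::setdiff(pr, ex), inr)
    cnt["exon"] <- cnt["exon"] + sum(IRanges::width(ex))
    cnt["intron"] <- cnt["intron"] + sum(IRanges::width(inr))
    cnt["promoter"] <- cnt["promoter"] + sum(IRanges::width(pr))
  }
  cnt["intergenic"] <- total - sum(cnt)
  cnt / total
}

#' Repeat and CpG-island composition of sequence intervals
#'
#' An interval "has repetitive content" when at least one of its bases
#' overlaps a repeat; per-class base fractions are overlapped repeat-class
#' bases over total interval bases. Repeat classes not among SINE / LINE /
#' LTR / Satellite fall into an "other" bin. With an island annotation the
#' count and fraction of intervals overlapping a CpG island are reported too.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. aligned contig placements or site intervals.
#' @param repeats data.frame with `chrom`, `start`, `end`, `class`.
#' @param islands optional data.frame with `chrom`, `start`, `end`.
#' @return list: `n_sequences`, `n_with_repeat`, `frac_with_repeat`,
#'   `class_base_fraction` (named, incl. `total`), and when islands are given
#'   `n_in_island`, `frac_in_island`.
#' @export
summarize_repeats <- function(intervals, repeats, islands = NULL) {
  known <- c("SINE", "LINE", "LTR", "Satellite")
  n <- nrow(intervals)
  total_bases <- sum(intervals$end - intervals$start)
  cls <- ifelse(repeats$class %in% known, repeats$class, "other")
  out_frac <- setNames(numeric(length(known) + 1L), c(known, "other"))
  with_rep <- rep(FALSE, n)
  if (n && nrow(repeats)) {
    q <- .gr(intervals$chrom, intervals$start, intervals$end)
    s <- .gr(repeats$chrom, repeats$start, repeats$end)
    hits <- GenomicRanges::findOverlaps(q, s)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      with_rep[unique(qh)] <- TRUE
      ov <- pmin(intervals$end[qh], repeats$end[sh]) -
        pmax(intervals$start[qh], repeats$start[sh])
      for (k in unique(cls[sh])) {
        out_frac[k] <- sum(ov[cls[sh] == k]) / total_bases
      }
    }
  }
  res <- list(n_sequences = n, n_with_repeat = sum(with_rep),
              frac_with_repeat = if (n) sum(with_rep) / n else 0,
              class_base_fraction = c(out_frac, total = sum(out_frac)))
  if (!is.null(islands)) {
    in_isl <- rep(FALSE, n)
    if (n && nrow(islands)) {
      hits <- GenomicRanges::findOverlaps(
        .gr(intervals$chrom, intervals$start, intervals$end),
        .gr(islands$chrom, islands$start, islands$end))
      in_isl[unique(S4Vectors::queryHits(hits))] <- TRUE
    }
    res$n_in_island <- sum(in_isl)
    res$frac_in_island <- if (n) sum(in_isl) / n else 0
  }
  res
}

#' Partition two site sets into exclusive and shared members
#'
#' Compares two called site sets either by exact position (chrom, position,
#' mark) or by the owning region from [classify_regions()] (both sets must
#' then carry an `owner` column). The three counts always sum to the size of
#' the union, and swapping the arguments swaps the exclusive parts.
#'
#' @param set_a,set_b site data.frames.
#' @param by "position" or "owner-region".
#' @return list: `n_only_a`, `n_shared`, `n_only_b`, and the member key
#'   vectors `only_a`, `shared`, `only_b`.
#' @export
compare_site_sets <- function(set_a, set_b, by = c("position", "owner-region")) {
  by <- match.arg(by)
  key <- function(x) {
    if (by == "position") {
      unique(paste(x$chrom, x$pos, x$mark, sep = ":"))
    } else {
      if (is.null(x$owner)) stop("owner-region comparison requires annotated sites")
      unique(x$owner)
    }
  }
  a <- key(set_a); b <- key(set_b)
  list(n_only_a = length(setdiff(a, b)), n_shared = length(intersect(a, b)),
       n_only_b = length(setdiff(b, a)),
       only_a = sort(setdiff(a, b)), shared = sort(intersect(a, b)),
       only_b = sort(setdiff(b, a)))
}

#' Bin site counts along chromosomes
#'
#' Counts sites in fixed half-open windows (a site at an exact bin boundary
#' belongs to the higher bin). Bin totals always sum to the site count.
#'
#' @param sites data.frame with `chrom` and `pos`.
#' @param chrom_lengths named chromosome lengths.
#' @param bin_bp bin width in bp.
#' @return data.frame `chrom`, `start`, `end`, `count` (bedGraph-writable).
#' @export
coverage_bins <- function(sites, chrom_lengths, bin_bp = 1000000L) {
  stopifnot(bin_bp > 0)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = bin_bp)
    ends <- pmin(starts + bin_bp, len)
    pos <- sites$pos[sites$chrom == ch]
    cnt <- tabulate(pos %/% bin_bp + 1L, nbins = length(starts))
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts,
                                          end = ends, count = cnt,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
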