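#' Sequence input/output
#'
#' Thin wrappers around the Biostrings readers/writers keeping the package's
#' conventions: genomes are named [Biostrings::DNAStringSet]s, reads are
#' data.frames with `id` and `seq` columns. FASTA/FASTQ are auto-detected by
#' extension (`.fastq`/`.fq` read as FASTQ).
#'
#' @param path file path.
#' @return `read_fasta` a named DNAStringSet; `read_reads` a data.frame.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param seqs named character vector or DNAStringSet.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(id = names(ss), seq = unname(as.character(ss)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param reads data.frame with `id` and `seq`.
#' @export
write_reads_fasta <- function(reads, path) {
  write_fasta(setNames(reads$seq, reads$id), path)
}

#' BED / bedGraph / GFF3 input-output
#'
#' Interval files go through rtracklayer; at this boundary the 1-based
#' inclusive GRanges convention is converted to the package-internal 0-based
#' half-open data.frames (and back on write). `read_bed` validates intervals
#' against chromosome bounds when a genome is supplied.
#'
#' @param path file path.
#' @param genome optional named DNAStringSet for bounds validation.
#' @return `read_bed`: data.frame `chrom`, `start`, `end` plus `name`,
#'   `score`, `strand` when present.
#' @export
read_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) df$name <- mc$name
  if ("score" %in% names(mc)) df$score <- mc$score
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    bad <- which(!(df$chrom %in% names(lens)) | df$start < 0 |
                   df$end > lens[df$chrom])
    if (length(bad)) stop("BED interval out of chromosome bounds at record ",
                          bad[1])
  }
  df
}

#' @rdname read_bed
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  gr <- .gr(intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$strand)) {
    GenomicRanges::strand(gr) <- intervals$strand
  }
  mc <- list()
  mc$name <- if (!is.null(intervals$name)) intervals$name else
    rep(".", nrow(intervals))
  mc$score <- if (!is.null(intervals$score)) intervals$score else
    rep(0L, nrow(intervals))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_bed
#' @param bins data.frame from [coverage_bins()].
#' @export
write_bedgraph <- function(bins, path) {
  gr <- .gr(bins$chrom, bins$start, bins$end)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(score = bins$count)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname read_bed
#' @return `read_gff3`: list with `genes` and `exons` data.frames in internal
#'   coordinates (GFF3's 1-based inclusive converted to 0-based half-open).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type), stringsAsFactors = FALSE)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  parents <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, nrow(df))
  genes <- df[df$type == "gene", c("chrom", "start", "end", "strand")]
  genes$gene_id <- ids[df$type == "gene"]
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
  ex <- df[df$type == "exon", c("chrom", "start", "end")]
  ex$gene_id <- parents[df$type == "exon"]
  ex <- ex[, c("gene_id", "chrom", "start", "end")]
  ex$exon_number <- stats::ave(seq_len(nrow(ex)), ex$gene_id,
                               FUN = seq_along)
  rownames(genes) <- rownames(ex) <- NULL
  list(genes = genes, exons = ex)
}

#' @rdname read_bed
#' @param genes,exons gene-model data.frames as produced by
#'   [generate_genome()].
#' @export
write_gff3 <- function(genes, exons, path) {
  g <- .gr(genes$chrom, genes$start, genes$end)
  GenomicRanges::strand(g) <- genes$strand
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    type = rep("gene", nrow(genes)), ID = genes$gene_id)
  e <- .gr(exons$chrom, exons$start, exons$end)
  GenomicRanges::strand(e) <- genes$strand[match(exons$gene_id, genes$gene_id)]
  S4Vectors::mcols(e) <- S4Vectors::DataFrame(
    type = rep("exon", nrow(exons)),
    ID = sprintf("%s.exon%d", exons$gene_id, exons$exon_number),
    Parent = exons$gene_id)
  all <- c(g, e)
  all <- all[order(as.character(GenomicRanges::seqnames(all)),
                   GenomicRanges::start(all))]
  rtracklayer::export(all, path, format = "GFF3")
  invisible(path)
}

.psl_numeric_cols <- c(1:8, 11:13, 15:17)

#' Read a PSL alignment file
#'
#' Parses the 21-column tabular output of BLAT-style aligners, skipping any
#' header block. Each record is validated: the number of block sizes must
#' equal the block count and the block sizes must sum to the counted bases
#' (matches + mismatches + repeat matches + Ns); inconsistent records raise an
#' error naming the line.
#'
#' @param path file path.
#' @return data.frame of PSL fields (coordinates left as in the file: 0-based
#'   half-open).
#' @export
read_psl <- function(path) {
  lines <- readLines(path)
  is_data <- grepl("^[0-9]+\t", lines)
  cols <- c("matches", "misMatches", "repMatches", "nCount", "qNumInsert",
            "qBaseInsert", "tNumInsert", "tBaseInsert", "strand", "qName",
            "qSize", "qStart", "qEnd", "tName", "tSize", "tStart", "tEnd",
            "blockCount", "blockSizes", "qStarts", "tStarts")
  proto <- as.data.frame(setNames(rep(list(character()), 21), cols),
                         stringsAsFactors = FALSE)
  if (!any(is_data)) return(proto)
  rows <- strsplit(lines[is_data], "\t", fixed = TRUE)
  lineno <- which(is_data)
  bad <- which(lengths(rows) != 21L)
  if (length(bad)) stop("malformed PSL record at line ", lineno[bad[1]],
                        ": expected 21 fields")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  for (k in .psl_numeric_cols) df[[k]] <- as.integer(df[[k]])
  for (i in seq_len(nrow(df))) {
    sizes <- as.integer(strsplit(df$blockSizes[i], ",")[[1]])
    if (length(sizes) != df$blockCount[i]) {
      stop("malformed PSL record at line ", lineno[i],
           ": blockSizes count differs from blockCount")
    }
    counted <- df$matches[i] + df$misMatches[i] + df$repMatches[i] +
      df$nCount[i]
    if (sum(sizes) != counted) {
      stop("malformed PSL record at line ", lineno[i],
           ": block sizes inconsistent with counted bases")
    }
  }
  df
}

#' Convert PSL records to pipeline alignment records
#'
#' Computes per-alignment identity (matched bases over aligned bases) and
#' query coverage (aligned query span over query size), applies the
#' configured inclusive thresholds, merges a query's passing placements that
#' overlap more than 50% reciprocally, and reports one record per query with
#' its count of distinct passing loci -- the same shape [align_contigs()]
#' produces, so the downstream unique-placement filter applies unchanged.
#'
#' @param psl data.frame from [read_psl()].
#' @param config a [pipeline_config()].
#' @return alignment-record data.frame (see [align_contigs()]).
#' @export
psl_to_alignments <- function(psl, config) {
  proto <- data.frame(contig_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      n_best_loci = integer(), stringsAsFactors = FALSE)
  if (!nrow(psl)) {
    attr(proto, "n_contigs") <- 0L
    return(proto)
  }
  aligned <- psl$matches + psl$misMatches + psl$repMatches
  identity <- ifelse(aligned > 0, (psl$matches + psl$repMatches) / aligned, 0)
  coverage <- (psl$qEnd - psl$qStart) / psl$qSize
  pass <- identity >= config$align_min_identity &
    coverage >= config$align_min_coverage
  p <- data.frame(contig_id = psl$qName, chrom = psl$tName,
                  start = psl$tStart, end = psl$tEnd, strand = psl$strand,
                  identity = identity, coverage = coverage,
                  stringsAsFactors = FALSE)[pass, , drop = FALSE]
  out <- list()
  for (cid in unique(p$contig_id)) {
    q <- p[p$contig_id == cid, , drop = FALSE]
    q <- q[order(q$chrom, q$start), , drop = FALSE]
    grp <- character(nrow(q))
    for (ch in unique(q$chrom)) {
      sel <- which(q$chrom == ch)
      grp[sel] <- paste0(ch, ":", .merge_placements(q$start[sel], q$end[sel]))
    }
    best <- q[order(-q$identity, q$chrom, q$start), , drop = FALSE][1L, ]
    best$n_best_loci <- length(unique(grp))
    out[[length(out) + 1L]] <- best
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_contigs") <- length(unique(psl$qName))
  res
}

#' Write called sites as BED6
#'
#' One record per putative site (a single base), name `method:mark:stage`,
#' score the supporting contig's member count when available.
#'
#' @param sites data.frame from [call_sites()].
#' @param path file path.
#' @param member_counts optional named vector (contig_id -> member count).
#' @export
write_sites_bed <- function(sites, path, member_counts = NULL) {
  score <- rep(0L, nrow(sites))
  if (!is.null(member_counts) && nrow(sites)) {
    sc <- member_counts[sites$contig_id]
    score <- ifelse(is.na(sc), 0L, as.integer(sc))
  }
  write_bed(data.frame(chrom = sites$chrom, start = sites$pos,
                       end = sites$pos + 1L,
                       name = paste(sites$method, sites$mark, sites$stage,
                                    sep = ":"),
                       score = score, strand = sites$strand,
                       stringsAsFactors = FALSE), path)
}

.report_row_names <- c(
  raw_reads = "Raw reads from library",
  cleaned_reads = "Cleaned reads",
  validated_reads = "Validated reads",
  contigs = "Contigs",
  aligned_contigs = "Sequences with genomic alignments",
  unique_alignments = "Sequences with unique alignment",
  putative_sites = "Putative methylated restriction sites")

#' Write the library funnel report
#'
#' Tab-separated step/count table of the read-to-site funnel.
#'
#' @param report named counts from [call_sites_pipeline()].
#' @param path file path.
#' @export
write_funnel_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#step\tcount\t(methylsieve ",
                    as.character(utils::packageVersion("methylsieve")), ")"),
             con)
  for (k in names(report)) {
    label <- if (k %in% names(.report_row_names)) .report_row_names[[k]] else k
    writeLines(sprintf("%s\t%d", label, report[[k]]), con)
  }
  invisible(path)
}
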