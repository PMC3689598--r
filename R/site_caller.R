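#' Configuration of the read-to-site calling pipeline
#'
#' Collects the thresholds of the identification pipeline: reads are trimmed
#' and length-filtered, clustered into consensus contigs at an identity
#' threshold, aligned to the reference, kept only when uniquely placed at the
#' identity/coverage thresholds, extended to the nearest occurrence of the
#' protocol's primary recognition sequence, and labeled. All thresholds are
#' inclusive (a value exactly at the threshold passes).
#'
#' @param protocol one of "ME_RDA", "HME_RDA", "HELP_COCKTAIL".
#' @param cluster_identity read clustering identity threshold (default 0.97).
#' @param align_min_identity,align_min_coverage alignment acceptance
#'   thresholds as fractions of the contig (default 0.92 each; placements
#'   below either are discarded).
#' @param extension_max maximum in-silico extension to the nearest primary
#'   recognition site, in bp (default 1000; inclusive).
#' @param min_read_len reads shorter than this after trimming are dropped.
#' @param primary_site_enzyme [enzyme_spec()] whose recognition defines the
#'   fragment-end sites (HpaII for ME_RDA, BfaI's CTAG for HME_RDA, TasI for
#'   HELP); defaulted from the protocol.
#' @param help_filter_enzymes cocktail [enzyme_spec()] list used by the HELP
#'   read filter and internal-site labeling.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(protocol = c("ME_RDA", "HME_RDA", "HELP_COCKTAIL"),
                            cluster_identity = 0.97,
                            align_min_identity = 0.92,
                            align_min_coverage = 0.92,
                            extension_max = 1000L,
                            min_read_len = 50L,
                            primary_site_enzyme = NULL,
                            help_filter_enzymes = NULL) {
  protocol <- match.arg(protocol)
  enz <- default_enzymes()
  if (is.null(primary_site_enzyme)) {
    primary_site_enzyme <- switch(protocol, ME_RDA = enz$HpaII,
                                  HME_RDA = enz$BfaI, HELP_COCKTAIL = enz$TasI)
  }
  if (is.null(help_filter_enzymes)) {
    help_filter_enzymes <- enz[c("HpaII", "AciI", "HinP1I")]
  }
  stopifnot(cluster_identity > 0, cluster_identity <= 1,
            align_min_identity > 0, align_min_identity <= 1,
            align_min_coverage > 0, align_min_coverage <= 1,
            extension_max > 0)
  structure(list(protocol = protocol, cluster_identity = cluster_identity,
                 align_min_identity = align_min_identity,
                 align_min_coverage = align_min_coverage,
                 extension_max = as.integer(extension_max),
                 min_read_len = as.integer(min_read_len),
                 primary_site_enzyme = primary_site_enzyme,
                 help_filter_enzymes = help_filter_enzymes),
            class = "pipeline_config")
}

.trim_end <- function(seqs, adaptor, prefix) {
  La <- nchar(adaptor)
  long <- nchar(seqs) >= La
  piece <- if (prefix) substr(seqs, 1L, La) else
    substr(seqs, nchar(seqs) - La + 1L, nchar(seqs))
  hit <- long
  hit[long] <- .hamming(piece[long], adaptor) <= 1L
  seqs[hit] <- if (prefix) substring(seqs[hit], La + 1L) else
    substr(seqs[hit], 1L, nchar(seqs[hit]) - La)
  seqs
}

#' Trim adaptors and drop short reads
#'
#' Removes leading/trailing adaptor occurrences (exact or one mismatch; each
#' adaptor and its reverse complement are tried at both ends) and drops reads
#' shorter than `min_read_len`. The raw/cleaned counts of the library funnel
#' are attached as `attr(, "report")`.
#'
#' @param reads data.frame with `id` and `seq` columns (extra columns kept).
#' @param adaptors character vector of adaptor sequences; may be empty.
#' @param config a [pipeline_config()].
#' @return the cleaned reads data.frame.
#' @export
clean_reads <- function(reads, adaptors = character(), config) {
  raw_n <- nrow(reads)
  if (raw_n) {
    seqs <- reads$seq
    variants <- unique(c(unlist(adaptors),
                         vapply(unlist(adaptors), .revcomp, "")))
    for (a in variants) {
      seqs <- .trim_end(seqs, a, prefix = TRUE)
      seqs <- .trim_end(seqs, a, prefix = FALSE)
    }
    reads$seq <- seqs
    reads <- reads[nchar(reads$seq) >= config$min_read_len, , drop = FALSE]
    rownames(reads) <- NULL
  }
  attr(reads, "report") <- c(raw_reads = raw_n, cleaned_reads = nrow(reads))
  reads
}

#' Retain HELP reads containing a cocktail recognition site
#'
#' HELP fragments lacking any internal methyl-sensitive site carry no
#' information on methylation status; reads without at least one cocktail
#' recognition occurrence on either strand are excluded. Calling this for a
#' non-HELP protocol is an error: the filter applies to HELP libraries only.
#'
#' @inheritParams clean_reads
#' @return the filtered reads data.frame with a `validated_reads` count in
#'   `attr(, "report")`.
#' @export
filter_help_reads <- function(reads, config) {
  if (config$protocol != "HELP_COCKTAIL") {
    stop("filter_help_reads applies to the HELP_COCKTAIL protocol only")
  }
  recs <- vapply(config$help_filter_enzymes, function(e) e$recognition, "")
  pats <- unique(c(recs, vapply(recs, .revcomp, "")))
  keep <- rep(FALSE, nrow(reads))
  for (p in pats) keep <- keep | grepl(p, reads$seq, fixed = TRUE)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- c(validated_reads = nrow(out))
  out
}

.KMER <- 16L

.kmer_tiles <- function(s, k = .KMER) {
  L <- nchar(s)
  if (L < k) return(character())
  at <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
  substring(s, at, at + k - 1L)
}

.overlap_identity <- function(a, b) {
  if (a == b) return(1)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "overlap")
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0L) return(0)
  Biostrings::nmatch(aln) / cols
}

#' Greedy centroid clustering of reads into consensus contigs
#'
#' Reads are processed in decreasing length order (ties broken by id, so the
#' result is invariant under input shuffling). Each read joins the first
#' existing centroid whose pairwise identity -- matching columns over
#' alignment columns of an end-gap-free global alignment -- reaches the
#' clustering threshold (inclusive), otherwise it founds a new centroid.
#' The consensus is the per-column majority over members aligned to the
#' centroid, ties resolved to the centroid base. Candidate centroids are
#' pre-screened by shared 16-mers; at the default 97% threshold matching
#' pairs always share an exact 16-mer run.
#'
#' @inheritParams clean_reads
#' @return data.frame with `contig_id`, `consensus`, `n_members` and a list
#'   column `members` of read ids.
#' @export
cluster_reads <- function(reads, config) {
  proto <- data.frame(contig_id = character(), consensus = character(),
                      n_members = integer(), stringsAsFactors = FALSE)
  proto$members <- list()
  if (!nrow(reads)) return(proto)
  ord <- order(-nchar(reads$seq), reads$id)
  seqs <- reads$seq[ord]; ids <- reads$id[ord]

  # centroid tiles are indexed; a query read probes every overlapping k-mer,
  # so any substitution-free 16-mer shared at a common offset is found (at
  # >= 97% identity at least one centroid tile always survives)
  index <- new.env(parent = emptyenv())
  cent_seq <- character(); members <- list()
  add_to_index <- function(s, ci) {
    for (w in .kmer_tiles(s)) index[[w]] <- c(index[[w]], ci)
  }
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    L <- nchar(s)
    probes <- if (L >= .KMER) {
      unique(substring(s, 1:(L - .KMER + 1L), .KMER:L))
    } else character()
    cand <- sort(unique(unlist(lapply(probes, function(w) index[[w]]))))
    placed <- FALSE
    for (ci in cand) {
      if (.overlap_identity(s, cent_seq[ci]) >= config$cluster_identity) {
        members[[ci]] <- c(members[[ci]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      cent_seq <- c(cent_seq, s)
      members[[length(cent_seq)]] <- i
      add_to_index(s, length(cent_seq))
    }
  }

  consensus <- vapply(seq_along(cent_seq), function(ci) {
    .consensus_seq(cent_seq[ci], seqs[members[[ci]]])
  }, character(1))
  out <- data.frame(contig_id = sprintf("contig_%05d", seq_along(cent_seq)),
                    consensus = consensus,
                    n_members = lengths(members), stringsAsFactors = FALSE)
  out$members <- lapply(members, function(ix) ids[ix])
  out
}

# majority vote over centroid columns; ties and uncovered columns keep the
# centroid base
.consensus_seq <- function(centroid, member_seqs) {
  if (all(member_seqs == centroid)) return(centroid)
  Lc <- nchar(centroid)
  bases <- c("A", "C", "G", "T")
  votes <- matrix(0L, 4L, Lc)
  for (m in member_seqs) {
    if (m == centroid) {
      v <- match(strsplit(centroid, "")[[1]], bases)
      ok <- !is.na(v)
      votes[cbind(v[ok], which(ok))] <- votes[cbind(v[ok], which(ok))] + 1L
      next
    }
    aln <- Biostrings::pairwiseAlignment(m, centroid, type = "overlap")
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    spos <- Biostrings::start(Biostrings::subject(aln)) - 1L
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        spos <- spos + 1L
        b <- match(pa[k], bases)
        if (!is.na(b)) votes[b, spos] <- votes[b, spos] + 1L
      }
    }
  }
  cb <- strsplit(centroid, "")[[1]]
  out <- vapply(seq_len(Lc), function(j) {
    mx <- max(votes[, j])
    if (mx == 0L) return(cb[j])
    top <- bases[votes[, j] == mx]
    if (cb[j] %in% top) cb[j] else top[1L]
  }, character(1))
  paste(out, collapse = "")
}

# group placements of one contig that overlap >50% reciprocally; returns group id
.merge_placements <- function(start, end) {
  n <- length(start)
  grp <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ov <- min(end[i], end[j]) - max(start[i], start[j])
      if (ov > 0.5 * (end[i] - start[i]) && ov > 0.5 * (end[j] - start[j])) {
        grp[grp == grp[j]] <- grp[i]
      }
    }
  }
  match(grp, unique(grp))
}

#' Seed-and-extend alignment of contigs to a genome
#'
#' Exact 16-mer seeding (tiled over the contig, both orientations) followed by
#' full-length ungapped verification; a placement passes when its identity and
#' coverage both reach the configured thresholds (inclusive). Placements of
#' one contig overlapping more than 50% reciprocally are merged before
#' counting distinct loci. Gapped alignment is deliberately absent: at the
#' 92/92 thresholds on substitution-only reads it is not needed, and external
#' alignments can be supplied as PSL via [read_psl()] / [psl_to_alignments()].
#'
#' @param contigs data.frame from [cluster_reads()] (needs `contig_id`,
#'   `consensus`).
#' @param genome named [Biostrings::DNAStringSet].
#' @param config a [pipeline_config()].
#' @return data.frame with one row per contig having at least one passing
#'   placement: `contig_id`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `identity`, `coverage`, `n_best_loci` (distinct passing loci).
#'   Total contig count is attached as `attr(, "n_contigs")`.
#' @export
align_contigs <- function(contigs, genome, config) {
  proto <- data.frame(contig_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      identity = numeric(), coverage = numeric(),
                      n_best_loci = integer(), stringsAsFactors = FALSE)
  if (!nrow(contigs)) {
    attr(proto, "n_contigs") <- 0L
    return(proto)
  }
  queries <- data.frame(
    contig_id = rep(contigs$contig_id, 2L),
    strand = rep(c("+", "-"), each = nrow(contigs)),
    seq = c(contigs$consensus,
            vapply(contigs$consensus, .revcomp, "")),
    stringsAsFactors = FALSE)
  queries$len <- nchar(queries$seq)
  queries <- queries[queries$len >= .KMER, , drop = FALSE]

  seed_at <- lapply(queries$len, function(L) {
    unique(c(seq(1L, L - .KMER + 1L, by = .KMER), L - .KMER + 1L))
  })
  seed_q <- rep(seq_len(nrow(queries)), lengths(seed_at))
  seed_off <- unlist(seed_at) - 1L
  seed_s <- substring(queries$seq[seed_q], unlist(seed_at),
                      unlist(seed_at) + .KMER - 1L)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_s))

  hits <- list()
  for (ch in names(genome)) {
    mp <- Biostrings::matchPDict(pd, genome[[ch]])
    st <- Biostrings::startIndex(mp)
    st[vapply(st, is.null, logical(1))] <- list(integer())
    nh <- lengths(st)
    if (!sum(nh)) next
    si <- rep(seq_along(nh), nh)
    hits[[ch]] <- data.frame(q = seed_q[si],
                             start = unlist(st) - 1L - seed_off[si],
                             chrom = ch, stringsAsFactors = FALSE)
  }
  placements <- proto[, c("contig_id", "chrom", "start", "end", "strand",
                          "identity", "coverage")]
  if (length(hits)) {
    cand <- do.call(rbind, hits)
    cand <- cand[cand$start >= 0L, , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$q, cand$chrom, cand$start)), ,
                 drop = FALSE]
    keep_rows <- list()
    by_q <- split(seq_len(nrow(cand)), cand$q)
    for (qn in names(by_q)) {
      qi <- as.integer(qn)
      rows <- cand[by_q[[qn]], , drop = FALSE]
      L <- queries$len[qi]
      qdna <- Biostrings::DNAString(queries$seq[qi])
      for (ch in unique(rows$chrom)) {
        st <- rows$start[rows$chrom == ch]
        st <- st[st + L <= length(genome[[ch]])]
        if (!length(st)) next
        ned <- Biostrings::neditStartingAt(qdna, genome[[ch]],
                                           starting.at = st + 1L,
                                           with.indels = FALSE)
        idy <- (L - ned) / L
        ok <- idy >= config$align_min_identity
        if (any(ok)) {
          keep_rows[[length(keep_rows) + 1L]] <- data.frame(
            contig_id = queries$contig_id[qi], chrom = ch, start = st[ok],
            end = st[ok] + L, strand = queries$strand[qi],
            identity = idy[ok], coverage = 1, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(keep_rows)) placements <- do.call(rbind, keep_rows)
  }

  out <- list()
  for (cid in unique(placements$contig_id)) {
    p <- placements[placements$contig_id == cid, , drop = FALSE]
    p <- p[order(p$chrom, p$start, p$strand), , drop = FALSE]
    # merge within chromosome; different chromosomes are always distinct loci
    grp <- character(nrow(p))
    for (ch in unique(p$chrom)) {
      sel <- which(p$chrom == ch)
      g <- .merge_placements(p$start[sel], p$end[sel])
      grp[sel] <- paste0(ch, ":", g)
    }
    n_loci <- length(unique(grp))
    best <- p[order(-p$identity, p$chrom, p$start), , drop = FALSE][1L, ]
    best$n_best_loci <- n_loci
    out[[length(out) + 1L]] <- best
  }
  res <- if (length(out)) do.call(rbind, out) else proto
  res <- res[match(contigs$contig_id[contigs$contig_id %in% res$contig_id],
                   res$contig_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_contigs") <- nrow(contigs)
  res
}

#' Keep only uniquely placed contigs
#'
#' A contig with more than one distinct passing placement is excluded
#' entirely, all of its alignments with it. Attaches the
#' aligned/uniquely-aligned funnel counts as `attr(, "report")`.
#'
#' @param records output of [align_contigs()] or [psl_to_alignments()].
#' @param config a [pipeline_config()].
#' @return the uniquely placed records.
#' @export
filter_alignments <- function(records, config) {
  out <- records[records$n_best_loci == 1L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- c(aligned_contigs = nrow(records),
                           unique_alignments = nrow(out))
  out
}

.primary_occurrences <- function(genome, config) {
  rec <- config$primary_site_enzyme$recognition
  lapply(setNames(names(genome), names(genome)), function(ch) {
    sort(.occurrences(genome[[ch]], rec))
  })
}

#' Extend aligned contigs to the nearest primary restriction site
#'
#' For each end of a uniquely placed contig: if the boundary already lies
#' within an occurrence of the primary recognition sequence, that occurrence
#' is the end's site; otherwise the interval is extended outward to the
#' nearest occurrence, up to `extension_max` bp (inclusive: an occurrence
#' starting exactly `extension_max` away is accepted). Ends with no occurrence
#' within the cap are left site-less (`NA`) and yield no label downstream.
#'
#' @param records uniquely placed alignment records.
#' @inheritParams align_contigs
#' @return records with added `left_site`, `right_site` (occurrence starts or
#'   `NA`) and the extended interval `ext_start`, `ext_end`.
#' @export
extend_to_site <- function(records, genome, config) {
  occs <- .primary_occurrences(genome, config)
  L <- nchar(config$primary_site_enzyme$recognition)
  n <- nrow(records)
  left_site <- right_site <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ch <- records$chrom[i]
    if (records$start[i] < 0L || records$end[i] > length(genome[[ch]])) {
      stop("alignment interval outside chromosome bounds for ",
           records$contig_id[i])
    }
    occ <- occs[[ch]]
    if (!length(occ)) next
    b <- records$start[i]
    k <- findInterval(b, occ)
    if (k >= 1L) {
      if (occ[k] + L >= b) left_site[i] <- occ[k]
      else if (b - occ[k] <= config$extension_max) left_site[i] <- occ[k]
    }
    b <- records$end[i]
    k <- findInterval(b, occ)
    if (k >= 1L && occ[k] + L >= b) {
      right_site[i] <- occ[k]
    } else if (k < length(occ) && occ[k + 1L] - b <= config$extension_max) {
      right_site[i] <- occ[k + 1L]
    }
  }
  records$left_site <- left_site
  records$right_site <- right_site
  records$ext_start <- ifelse(is.na(left_site), records$start,
                              pmin(left_site, records$start))
  records$ext_end <- ifelse(is.na(right_site), records$end,
                            pmax(right_site + L, records$end))
  records
}

#' Label putative methylated / hydroxymethylated restriction sites
#'
#' Applies the protocol-specific labeling rules to extended records. For
#' ME_RDA the CpG cytosine inside each end's CCGG occurrence is labeled 5mC;
#' for HME_RDA the cytosine of each end's CTAG occurrence is labeled 5hmC
#' (CTAG contains no CpG, so the recognition cytosine is the labeled base);
#' for HELP every CpG cytosine of every cocktail occurrence lying strictly
#' between the two bounding TasI sites is labeled 5mC (records lacking either
#' bounding site yield no internal calls). Duplicate
#' (chrom, position, mark, method, stage) records are collapsed.
#'
#' @param records output of [extend_to_site()].
#' @inheritParams align_contigs
#' @param stage stage label carried on the calls.
#' @return data.frame of putative sites: `chrom`, `pos` (0-based position of
#'   the labeled cytosine), `strand`, `mark`, `method`, `stage`,
#'   `contig_id`, `end` (left/right/internal).
#' @export
call_sites <- function(records, genome, config, stage = "D7") {
  proto <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), mark = character(),
                      method = character(), stage = character(),
                      contig_id = character(), end = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(records)) return(proto)
  L <- nchar(config$primary_site_enzyme$recognition)
  out <- list()
  emit <- function(chrom, pos, mark, contig, end_lab) {
    data.frame(chrom = chrom, pos = pos, strand = "+", mark = mark,
               method = config$protocol, stage = stage, contig_id = contig,
               end = end_lab, stringsAsFactors = FALSE)
  }
  if (config$protocol %in% c("ME_RDA", "HME_RDA")) {
    mark <- if (config$protocol == "ME_RDA") "5mC" else "5hmC"
    off <- if (config$protocol == "ME_RDA") 1L else 0L  # C of CpG / C of CTAG
    for (i in seq_len(nrow(records))) {
      if (!is.na(records$left_site[i])) {
        out[[length(out) + 1L]] <- emit(records$chrom[i],
                                        records$left_site[i] + off, mark,
                                        records$contig_id[i], "left")
      }
      if (!is.na(records$right_site[i])) {
        out[[length(out) + 1L]] <- emit(records$chrom[i],
                                        records$right_site[i] + off, mark,
                                        records$contig_id[i], "right")
      }
    }
  } else {
    recs <- vapply(config$help_filter_enzymes, function(e) e$recognition, "")
    cocc <- lapply(setNames(names(genome), names(genome)), function(ch) {
      o <- lapply(recs, function(r) {
        occ <- .occurrences(genome[[ch]], r)
        if (!.is_palindromic(r)) occ <- sort(c(occ, .occurrences(genome[[ch]],
                                                                 .revcomp(r))))
        data.frame(occ = occ, len = rep(nchar(r), length(occ)))
      })
      do.call(rbind, o)
    })
    for (i in seq_len(nrow(records))) {
      if (is.na(records$left_site[i]) || is.na(records$right_site[i])) next
      ch <- records$chrom[i]
      lo <- records$left_site[i] + L
      hi <- records$right_site[i]
      o <- cocc[[ch]]
      sel <- o$occ >= lo & (o$occ + o$len) <= hi
      if (any(sel)) {
        # the CpG cytosine of CCGG/CCGC/GCGC (and of the GCGG minus-strand
        # occurrence of CCGC) sits one base into the occurrence
        out[[length(out) + 1L]] <- emit(ch, unique(sort(o$occ[sel] + 1L)),
                                        "5mC", records$contig_id[i],
                                        "internal")
      }
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else proto
  key <- paste(sites$chrom, sites$pos, sites$mark, sites$method, sites$stage)
  sites <- sites[!duplicated(key), , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Verify called sites against the reference
#'
#' Checks the defining invariant of a putative site: its position lies inside
#' an occurrence of the method's relevant recognition sequence on the
#' reference genome.
#'
#' @param sites data.frame from [call_sites()].
#' @inheritParams align_contigs
#' @return logical vector, one element per site.
#' @export
verify_sites <- function(sites, genome, config) {
  recs <- if (config$protocol == "HELP_COCKTAIL") {
    vapply(config$help_filter_enzymes, function(e) e$recognition, "")
  } else config$primary_site_enzyme$recognition
  ok <- rep(FALSE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    sel <- sites$chrom == ch
    cov <- rep(FALSE, length(genome[[ch]]))
    for (r in recs) {
      for (pat in unique(c(r, .revcomp(r)))) {
        for (o in .occurrences(genome[[ch]], pat)) {
          cov[(o + 1L):(o + nchar(pat))] <- TRUE
        }
      }
    }
    ok[sel] <- cov[sites$pos[sel] + 1L]
  }
  ok
}

#' Run the full read-to-site pipeline
#'
#' Convenience wrapper chaining [clean_reads()], [filter_help_reads()] (HELP
#' only), [cluster_reads()], [align_contigs()], [filter_alignments()],
#' [extend_to_site()] and [call_sites()], accumulating the library funnel
#' counts.
#'
#' @inheritParams clean_reads
#' @inheritParams align_contigs
#' @param stage stage label.
#' @return list with `sites`, `contigs`, `records`, and `report` (named
#'   funnel counts: raw, cleaned, validated (HELP), contigs, aligned, unique,
#'   putative sites).
#' @export
call_sites_pipeline <- function(reads, genome, config,
                                adaptors = character(), stage = "D7") {
  cleaned <- clean_reads(reads, adaptors, config)
  report <- attr(cleaned, "report")
  if (config$protocol == "HELP_COCKTAIL") {
    cleaned <- filter_help_reads(cleaned, config)
    report <- c(report, attr(cleaned, "report"))
  }
  contigs <- cluster_reads(cleaned, config)
  report <- c(report, contigs = nrow(contigs))
  aligned <- align_contigs(contigs, genome, config)
  unique_rec <- filter_alignments(aligned, config)
  report <- c(report, attr(unique_rec, "report"))
  extended <- extend_to_site(unique_rec, genome, config)
  sites <- call_sites(extended, genome, config, stage)
  report <- c(report, putative_sites = nrow(sites))
  list(sites = sites, contigs = contigs, records = extended, report = report)
}
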