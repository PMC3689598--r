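#' Specification of a synthetic genome
#'
#' Declares the structure of a reproducible toy genome: chromosome lengths,
#' background base composition, genes with exon/intron structure, CpG islands
#' (synthesized by locally raising G+C and CpG density), tandem satellite
#' arrays built from a fixed monomer, and interspersed SINE/LINE/LTR-like
#' repeat families. The same spec and seed always regenerate byte-identical
#' sequences and annotations.
#'
#' @param chromosome_lengths named or unnamed integer vector of chromosome
#'   lengths (bp); unnamed chromosomes are called chr1, chr2, ...
#' @param background_gc background G+C fraction.
#' @param n_genes number of genes to place.
#' @param exons_per_gene length-2 range of exon counts per gene.
#' @param exon_len,intron_len length-2 ranges (bp) for exon and intron sizes.
#' @param promoter_len promoter window upstream of the TSS (bp); the
#'   conventional 5 kb window is the default.
#' @param n_cpg_islands number of CpG islands.
#' @param island_len length-2 range of island sizes (bp).
#' @param island_gc G+C fraction inside islands.
#' @param satellite_monomer monomer sequence for tandem satellite arrays; the
#'   default is a fixed arbitrary 23-mer labeled "SAT-like" (class structure,
#'   not sequence identity, is what matters downstream).
#' @param satellite_array_count number of tandem arrays.
#' @param satellite_array_len monomer copies per array.
#' @param interspersed_repeat_classes named list mapping a class name (e.g.
#'   "SINE") to `c(consensus_length, copy_count)`.
#' @param seed integer seed.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(chromosome_lengths,
                        background_gc = 0.42,
                        n_genes = 0L,
                        exons_per_gene = c(2L, 6L),
                        exon_len = c(100L, 300L),
                        intron_len = c(200L, 1500L),
                        promoter_len = 5000L,
                        n_cpg_islands = 0L,
                        island_len = c(500L, 1500L),
                        island_gc = 0.65,
                        satellite_monomer = "TGGAATCCATGGAACGGAGAACC",
                        satellite_array_count = 0L,
                        satellite_array_len = 50L,
                        interspersed_repeat_classes = list(),
                        seed = 1L) {
  stopifnot(all(chromosome_lengths > 0), background_gc >= 0, background_gc <= 1,
            island_gc >= 0, island_gc <= 1, promoter_len > 0,
            nchar(satellite_monomer) > 0)
  if (is.null(names(chromosome_lengths))) {
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 background_gc = background_gc, n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 promoter_len = as.integer(promoter_len),
                 n_cpg_islands = as.integer(n_cpg_islands),
                 island_len = as.integer(island_len), island_gc = island_gc,
                 satellite_monomer = toupper(satellite_monomer),
                 satellite_array_count = as.integer(satellite_array_count),
                 satellite_array_len = as.integer(satellite_array_len),
                 interspersed_repeat_classes = interspersed_repeat_classes,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

.random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# island-like sequence: raised G+C plus planted CpG dinucleotides
.island_dna <- function(n, gc) {
  s <- strsplit(.random_dna(n, gc), "")[[1]]
  if (n >= 2L) {
    n_cpg <- max(1L, floor(n / 12))
    at <- sample(seq_len(n - 1L), n_cpg)
    s[at] <- "C"; s[at + 1L] <- "G"
  }
  paste(s, collapse = "")
}

# non-overlapping placement over per-chromosome occupancy lists
.place <- function(occ, chrom_lengths, len, max_tries = 200L) {
  ok_chroms <- names(chrom_lengths)[chrom_lengths >= len]
  if (!length(ok_chroms)) return(NULL)
  w <- chrom_lengths[ok_chroms] / sum(chrom_lengths[ok_chroms])
  for (i in seq_len(max_tries)) {
    ch <- sample(ok_chroms, 1L, prob = w)
    start <- sample.int(chrom_lengths[[ch]] - len + 1L, 1L) - 1L
    iv <- occ[[ch]]
    if (is.null(iv) || !nrow(iv) ||
        all(start + len <= iv$start | start >= iv$end)) {
      return(list(chrom = ch, start = start, end = start + len))
    }
  }
  NULL
}

#' Generate a synthetic genome with annotations
#'
#' Realizes a [genome_spec()]: random background sequence per chromosome, then
#' CpG islands, satellite arrays and interspersed repeats written into the
#' sequence at non-overlapping positions, and gene models placed on top.
#' Every declared feature count is realized or a placement failure is raised
#' after bounded retries.
#'
#' @param spec a [genome_spec()].
#' @return list with elements `genome` ([Biostrings::DNAStringSet]),
#'   `genes` (data.frame: gene_id, chrom, start, end, strand),
#'   `exons` (data.frame: gene_id, chrom, start, end, exon_number),
#'   `repeats` (data.frame: chrom, start, end, class, name),
#'   `islands` (data.frame: chrom, start, end), and `spec`.
#'   All coordinates 0-based half-open.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  cl <- spec$chromosome_lengths
  seqs <- lapply(cl, function(n) strsplit(.random_dna(n, spec$background_gc),
                                          "")[[1]])
  occ <- setNames(vector("list", length(cl)), names(cl))
  iv_proto <- data.frame(start = integer(), end = integer())
  for (ch in names(cl)) occ[[ch]] <- iv_proto
  fail <- function(what) stop("placement failure: could not place ", what,
                              " (chromosomes too small for requested features)")
  overwrite <- function(ch, start, dna) {
    seqs[[ch]][(start + 1L):(start + nchar(dna))] <<- strsplit(dna, "")[[1]]
  }
  note <- function(ch, start, end) {
    occ[[ch]] <<- rbind(occ[[ch]], data.frame(start = start, end = end))
  }

  islands <- data.frame(chrom = character(), start = integer(), end = integer())
  if (spec$n_cpg_islands > 0L) {
    for (i in seq_len(spec$n_cpg_islands)) {
      len <- sample(spec$island_len[1]:spec$island_len[2], 1L)
      p <- .place(occ, cl, len)
      if (is.null(p)) fail("CpG island")
      overwrite(p$chrom, p$start, .island_dna(len, spec$island_gc))
      note(p$chrom, p$start, p$end)
      islands <- rbind(islands, data.frame(chrom = p$chrom, start = p$start,
                                           end = p$end))
    }
  }

  repeats <- data.frame(chrom = character(), start = integer(),
                        end = integer(), class = character(),
                        name = character())
  if (spec$satellite_array_count > 0L) {
    arr <- strrep(spec$satellite_monomer, spec$satellite_array_len)
    for (i in seq_len(spec$satellite_array_count)) {
      p <- .place(occ, cl, nchar(arr))
      if (is.null(p)) fail("satellite array")
      overwrite(p$chrom, p$start, arr)
      note(p$chrom, p$start, p$end)
      repeats <- rbind(repeats, data.frame(chrom = p$chrom, start = p$start,
                                           end = p$end, class = "Satellite",
                                           name = "SAT-like"))
    }
  }
  for (cls in names(spec$interspersed_repeat_classes)) {
    par <- spec$interspersed_repeat_classes[[cls]]
    consensus <- .random_dna(par[[1]], spec$background_gc)
    for (i in seq_len(par[[2]])) {
      p <- .place(occ, cl, nchar(consensus))
      if (is.null(p)) fail(paste0(cls, " repeat"))
      overwrite(p$chrom, p$start, consensus)
      note(p$chrom, p$start, p$end)
      repeats <- rbind(repeats, data.frame(chrom = p$chrom, start = p$start,
                                           end = p$end, class = cls,
                                           name = paste0(cls, "-like")))
    }
  }

  genes <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character())
  exons <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      exon_number = integer())
  if (spec$n_genes > 0L) {
    gene_occ <- setNames(rep(list(iv_proto), length(cl)), names(cl))
    for (g in seq_len(spec$n_genes)) {
      n_ex <- sample(spec$exons_per_gene[1]:spec$exons_per_gene[2], 1L)
      ex_len <- sample(spec$exon_len[1]:spec$exon_len[2], n_ex, replace = TRUE)
      in_len <- if (n_ex > 1L) {
        sample(spec$intron_len[1]:spec$intron_len[2], n_ex - 1L, replace = TRUE)
      } else integer()
      span <- sum(ex_len) + sum(in_len)
      placed <- FALSE
      for (try in seq_len(200L)) {
        # keep gene spans plus their upstream promoter windows disjoint so
        # region ownership in downstream annotation is unambiguous
        total <- span + spec$promoter_len
        ok <- names(cl)[cl >= total]
        if (!length(ok)) break
        ch <- sample(ok, 1L, prob = cl[ok] / sum(cl[ok]))
        strand <- sample(c("+", "-"), 1L)
        a <- sample.int(cl[[ch]] - total + 1L, 1L) - 1L
        gstart <- if (strand == "+") a + spec$promoter_len else a
        gend <- gstart + span
        iv <- gene_occ[[ch]]
        if (!nrow(iv) || all(a + total <= iv$start | a >= iv$end)) {
          gene_occ[[ch]] <- rbind(iv, data.frame(start = a, end = a + total))
          gid <- sprintf("gene%03d", g)
          genes <- rbind(genes, data.frame(gene_id = gid, chrom = ch,
                                           start = gstart, end = gend,
                                           strand = strand))
          # exon coordinates laid out 5'->3' along the strand
          offs <- cumsum(c(0L, head(as.integer(ex_len + c(in_len, 0L)),
                                    n_ex - 1L)))
          es <- gstart + offs
          ee <- es + ex_len
          if (strand == "-") {
            es2 <- gend - (ee - gstart); ee2 <- gend - (es - gstart)
            es <- rev(es2); ee <- rev(ee2)
          }
          exons <- rbind(exons, data.frame(gene_id = gid, chrom = ch,
                                           start = as.integer(es),
                                           end = as.integer(ee),
                                           exon_number = seq_len(n_ex)))
          placed <- TRUE
          break
        }
      }
      if (!placed) fail("gene")
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- names(cl)
  list(genome = genome, genes = genes, exons = exons, repeats = repeats,
       islands = islands, spec = spec)
}

#' Context-specific cytosine mark model
#'
#' Probabilities of assigning 5mC / 5hmC to a cytosine by sequence and
#' annotation context. CpG-context marks are strand-symmetric (both cytosines
#' of the palindromic CpG receive the same mark); non-CpG (CHG/CHH) cytosines
#' are marked per strand. Repeat-class multipliers scale both mark
#' probabilities inside annotated repeats (rescaled proportionally if the sum
#' would exceed 1). Stage overrides replace any base probability for a named
#' developmental stage.
#'
#' @param p_mC_cpg_island,p_mC_cpg probability of 5mC at a CpG inside /
#'   outside a CpG island.
#' @param p_mC_chh probability of 5mC at a CHG/CHH cytosine.
#' @param p_hmC_cpg probability of 5hmC at a CpG.
#' @param p_hmC_chh_ctag probability of 5hmC at a non-CpG cytosine lying
#'   within a CTAG occurrence (the hydroxymethylation-sensitive site context).
#' @param repeat_multipliers named numeric vector of per-repeat-class
#'   multipliers.
#' @param stages named list of per-stage overrides, each a named list of the
#'   probability fields above (e.g. `list(D7 = list(), D12 =
#'   list(p_hmC_cpg = 0.1))`).
#' @return object of class `mark_model`.
#' @export
mark_model <- function(p_mC_cpg_island = 0.1, p_mC_cpg = 0.7,
                       p_mC_chh = 0.02, p_hmC_cpg = 0.05,
                       p_hmC_chh_ctag = 0.02,
                       repeat_multipliers = c(Satellite = 1),
                       stages = list(D7 = list(), D12 = list())) {
  base <- list(p_mC_cpg_island = p_mC_cpg_island, p_mC_cpg = p_mC_cpg,
               p_mC_chh = p_mC_chh, p_hmC_cpg = p_hmC_cpg,
               p_hmC_chh_ctag = p_hmC_chh_ctag)
  ok <- function(p) all(unlist(p) >= 0) && all(unlist(p) <= 1)
  if (!ok(base)) stop("probabilities must lie in [0,1]")
  for (s in stages) if (length(s) && !ok(s)) stop("probabilities must lie in [0,1]")
  if (p_mC_cpg_island + p_hmC_cpg > 1 || p_mC_cpg + p_hmC_cpg > 1) {
    stop("p(5mC) + p(5hmC) must not exceed 1 in any context")
  }
  structure(c(base, list(repeat_multipliers = repeat_multipliers,
                         stages = stages)),
            class = "mark_model")
}

.stage_params <- function(model, stage) {
  if (!stage %in% names(model$stages)) {
    stop("unknown stage name: ", stage, " (defined: ",
         paste(names(model$stages), collapse = ", "), ")")
  }
  p <- model[c("p_mC_cpg_island", "p_mC_cpg", "p_mC_chh", "p_hmC_cpg",
               "p_hmC_chh_ctag")]
  ov <- model$stages[[stage]]
  p[names(ov)] <- ov
  p
}

.in_intervals <- function(pos, iv) {
  # pos 0-based points; iv data.frame(start,end) half-open
  if (is.null(iv) || !nrow(iv)) return(rep(FALSE, length(pos)))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(pos + 1L, pos + 1L),
    IRanges::IRanges(iv$start + 1L, iv$end))
  out <- rep(FALSE, length(pos))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

.repeat_multiplier_at <- function(pos, reps, multipliers) {
  mult <- rep(1, length(pos))
  if (is.null(reps) || !nrow(reps) || !length(multipliers)) return(mult)
  for (cls in intersect(names(multipliers), unique(reps$class))) {
    inr <- .in_intervals(pos, reps[reps$class == cls, , drop = FALSE])
    mult[inr] <- mult[inr] * multipliers[[cls]]
  }
  mult
}

#' Assign a ground-truth methylome to a genome
#'
#' Draws a mark (none / 5mC / 5hmC) independently for every cytosine from the
#' context-resolved probabilities of a [mark_model()]: CpG context split by
#' CpG-island membership, CHG/CHH context with 5hmC restricted to CTAG
#' occurrences, repeat-class multipliers, and per-stage overrides. CpG marks
#' are mirrored to the opposite-strand cytosine of the dinucleotide.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param annotations list with `islands` and `repeats` data.frames (as from
#'   [generate_genome()]); may be empty data.frames.
#' @param model a [mark_model()].
#' @param stage stage name defined in the model.
#' @param seed integer seed.
#' @return a `methylome_track`: data.frame (`chrom`, `pos` 0-based, `strand`,
#'   `mark`) holding only marked cytosines, sorted by chrom/pos/strand, with
#'   generation parameters in `attr(,"metadata")`.
#' @export
assign_methylome <- function(genome, annotations, model, stage, seed = 1L) {
  stopifnot(inherits(genome, "DNAStringSet"), inherits(model, "mark_model"))
  p <- .stage_params(model, stage)
  set.seed(derive_seed(seed, paste0("methylome:", stage)))
  out <- list()
  for (ch in names(genome)) {
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    n <- length(s)
    isl <- annotations$islands[annotations$islands$chrom == ch, , drop = FALSE]
    reps <- annotations$repeats[annotations$repeats$chrom == ch, , drop = FALSE]

    # CpG dinucleotides on the plus strand (0-based position of the C)
    cpg <- which(s[-n] == "C" & s[-1L] == "G") - 1L
    if (length(cpg)) {
      in_isl <- .in_intervals(cpg, isl)
      p5 <- ifelse(in_isl, p$p_mC_cpg_island, p$p_mC_cpg)
      ph <- rep(p$p_hmC_cpg, length(cpg))
      mult <- .repeat_multiplier_at(cpg, reps, model$repeat_multipliers)
      p5 <- p5 * mult; ph <- ph * mult
      tot <- p5 + ph
      over <- tot > 1
      p5[over] <- p5[over] / tot[over]; ph[over] <- ph[over] / tot[over]
      u <- runif(length(cpg))
      mk <- ifelse(u < p5, "5mC", ifelse(u < p5 + ph, "5hmC", "none"))
      hit <- mk != "none"
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          pos = c(cpg[hit], cpg[hit] + 1L),
          strand = rep(c("+", "-"), each = sum(hit)),
          mark = rep(mk[hit], 2L), stringsAsFactors = FALSE)
      }
    }

    # non-CpG cytosines, per strand
    ctag_cov <- rep(FALSE, n)
    m <- Biostrings::matchPattern("CTAG", genome[[ch]])
    for (st in IRanges::start(m)) ctag_cov[st:(st + 3L)] <- TRUE
    non_cpg <- function(pos0, strand) {
      if (!length(pos0)) return(NULL)
      p5 <- rep(p$p_mC_chh, length(pos0))
      ph <- ifelse(ctag_cov[pos0 + 1L], p$p_hmC_chh_ctag, 0)
      mult <- .repeat_multiplier_at(pos0, reps, model$repeat_multipliers)
      p5 <- p5 * mult; ph <- ph * mult
      tot <- p5 + ph; over <- tot > 1
      p5[over] <- p5[over] / tot[over]; ph[over] <- ph[over] / tot[over]
      u <- runif(length(pos0))
      mk <- ifelse(u < p5, "5mC", ifelse(u < p5 + ph, "5hmC", "none"))
      hit <- mk != "none"
      if (!any(hit)) return(NULL)
      data.frame(chrom = ch, pos = pos0[hit], strand = strand,
                 mark = mk[hit], stringsAsFactors = FALSE)
    }
    plusC <- which(s == "C")
    plusC <- plusC[!(plusC %in% (cpg + 1L))] - 1L
    minusC <- which(s == "G")                       # C on the minus strand
    minusC <- minusC[!(minusC %in% (cpg + 2L))] - 1L
    out[[length(out) + 1L]] <- non_cpg(plusC, "+")
    out[[length(out) + 1L]] <- non_cpg(minusC, "-")
  }
  out <- out[!vapply(out, is.null, logical(1))]
  track <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), pos = integer(), strand = character(),
               mark = character(), stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$pos, track$strand), , drop = FALSE]
  rownames(track) <- NULL
  attr(track, "metadata") <- list(stage = stage, seed = seed, params = p)
  class(track) <- c("methylome_track", "data.frame")
  track
}

#' Write / read a ground-truth methylome track
#'
#' Tab-separated file with a commented header line and columns chrom, pos
#' (0-based), strand, mark, sorted by chromosome then position. Reading back a
#' written track reproduces it exactly.
#'
#' @param track a `methylome_track` (or compatible data.frame).
#' @param path file path.
#' @export
write_truth <- function(track, path) {
  track <- track[order(track$chrom, track$pos, track$strand), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tstrand\tmark", con)
  if (nrow(track)) {
    writeLines(sprintf("%s\t%d\t%s\t%s", track$chrom, track$pos,
                       track$strand, track$mark), con)
  }
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth` returns a `methylome_track` data.frame.
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    track <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), mark = character(),
                        stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 4L)
    if (length(bad)) stop("malformed truth record at line ", bad[1] + 1L)
    track <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                        pos = as.integer(vapply(parts, `[`, "", 2L)),
                        strand = vapply(parts, `[`, "", 3L),
                        mark = vapply(parts, `[`, "", 4L),
                        stringsAsFactors = FALSE)
    if (!all(track$mark %in% c("5mC", "5hmC"))) {
      stop("truth file contains an unknown mark")
    }
  }
  class(track) <- c("methylome_track", "data.frame")
  track
}
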