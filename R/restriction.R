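#' Restriction enzyme specification
#'
#' An enzyme is modeled by its IUPAC recognition sequence, the top-strand cut
#' offset (bases from the 5' edge of a recognition occurrence), and the set of
#' cytosine marks that block cleavage when present anywhere in the recognition
#' footprint on either strand. Non-palindromic recognitions can be scanned on
#' both strands.
#'
#' @param name enzyme name.
#' @param recognition IUPAC DNA string, non-empty.
#' @param cut_offset integer in `[0, nchar(recognition)]`.
#' @param blocked_by character subset of `c("5mC", "5hmC")`.
#' @param double_stranded_scan scan the minus strand for non-palindromic
#'   recognitions (ignored for palindromes, which are reported once).
#' @return an object of class `enzyme_spec`.
#' @examples
#' hpaii <- enzyme_spec("HpaII", "CCGG", 1L, c("5mC", "5hmC"))
#' @export
enzyme_spec <- function(name, recognition, cut_offset, blocked_by = character(),
                        double_stranded_scan = !.is_palindromic(recognition)) {
  recognition <- toupper(recognition)
  if (!nzchar(recognition)) stop("recognition must be non-empty")
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", recognition)) {
    stop("malformed IUPAC pattern: ", recognition)
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within [0, length(recognition)]")
  }
  if (!all(blocked_by %in% c("5mC", "5hmC"))) {
    stop("blocked_by must be a subset of {5mC, 5hmC}")
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset,
                 blocked_by = unique(blocked_by),
                 double_stranded_scan = isTRUE(double_stranded_scan)),
            class = "enzyme_spec")
}

#' @export
print.enzyme_spec <- function(x, ...) {
  cat(sprintf("<enzyme %s: %s^ at +%d, blocked by {%s}%s>\n", x$name,
              x$recognition, x$cut_offset,
              paste(x$blocked_by, collapse = ","),
              if (x$double_stranded_scan) ", both strands" else ""))
  invisible(x)
}

.default_enzyme_table <- function() {
  data.frame(
    name = c("MspI", "HpaII", "FspBI", "BfaI", "TasI", "AciI", "HinP1I"),
    recognition = c("CCGG", "CCGG", "CTAG", "CTAG", "AATT", "CCGC", "GCGC"),
    cut_offset = c(1L, 1L, 1L, 1L, 0L, 1L, 1L),
    blocked_by = c("5hmC", "5mC,5hmC", "", "5hmC", "", "5mC,5hmC",
                   "5mC,5hmC"),
    double_stranded_scan = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default enzyme registry
#'
#' The seven enzymes used across the three chemistries, with their documented
#' mark sensitivities: MspI cuts CCGG regardless of 5mC but is blocked by an
#' internal 5hmC; its isoschizomer HpaII is blocked by either mark. FspBI cuts
#' CTAG regardless of marks while BfaI is blocked by 5hmC. TasI (AATT) is the
#' mark-insensitive frequent cutter. AciI (CCGC, non-palindromic, scanned on
#' both strands) and HinP1I (GCGC) complete the methyl-sensitive cocktail and
#' are treated like HpaII (blocked by both marks); their 5hmC sensitivity is
#' configurable through the registry file.
#'
#' @return named list of [enzyme_spec()] objects.
#' @export
default_enzymes <- function() {
  tab <- .default_enzyme_table()
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    blocked <- strsplit(tab$blocked_by[i], ",", fixed = TRUE)[[1]]
    enzyme_spec(tab$name[i], tab$recognition[i], tab$cut_offset[i],
                blocked[nzchar(blocked)], tab$double_stranded_scan[i])
  })
  setNames(specs, tab$name)
}

#' Read / write an enzyme registry TSV
#'
#' Editable tab-separated registry with columns name, recognition, cut_offset,
#' blocked_by (comma-separated, may be empty) and double_stranded_scan. The
#' shipped default lives at
#' `system.file("extdata", "enzyme_registry.tsv", package = "methylsieve")`.
#'
#' @param path file path.
#' @return `read_enzyme_registry` returns a named list of [enzyme_spec()].
#' @export
read_enzyme_registry <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  .stop_if_missing_cols(tab, c("name", "recognition", "cut_offset",
                               "blocked_by", "double_stranded_scan"),
                        "enzyme registry")
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    blocked <- strsplit(as.character(tab$blocked_by[i]), ",", fixed = TRUE)[[1]]
    enzyme_spec(tab$name[i], tab$recognition[i], tab$cut_offset[i],
                blocked[nzchar(blocked)], as.logical(tab$double_stranded_scan[i]))
  })
  setNames(specs, tab$name)
}

#' @rdname read_enzyme_registry
#' @param enzymes named list of [enzyme_spec()] objects.
#' @export
write_enzyme_registry <- function(enzymes, path) {
  tab <- do.call(rbind, lapply(enzymes, function(e) {
    data.frame(name = e$name, recognition = e$recognition,
               cut_offset = e$cut_offset,
               blocked_by = paste(e$blocked_by, collapse = ","),
               double_stranded_scan = e$double_stranded_scan,
               stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-position mark code vectors (0 none / 1 5mC / 2 5hmC) for one chromosome
.track_codes <- function(track, chrom, chromlen) {
  plus <- integer(chromlen)
  minus <- integer(chromlen)
  if (!is.null(track) && nrow(track)) {
    t <- track[track$chrom == chrom, , drop = FALSE]
    if (nrow(t)) {
      if (any(t$pos < 0L | t$pos >= chromlen)) {
        stop("methylome track position outside sequence bounds on ", chrom)
      }
      code <- .mark_code(t$mark)
      isp <- t$strand == "+"
      plus[t$pos[isp] + 1L] <- code[isp]
      minus[t$pos[!isp] + 1L] <- code[!isp]
    }
  }
  list(plus = plus, minus = minus)
}

.occurrences <- function(seq, recognition) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(recognition), seq,
                                fixed = FALSE)
  st <- IRanges::start(m)
  if (length(st)) {
    # an undefined base cannot be asserted as a site
    has_n <- vapply(st, function(s) {
      grepl("N", as.character(Biostrings::subseq(seq, s, s + nchar(recognition) - 1L)),
            fixed = TRUE)
    }, logical(1))
    st <- st[!has_n]
  }
  st - 1L  # 0-based occurrence starts
}

#' Locate recognition occurrences and their blocking status
#'
#' Scans a sequence for occurrences of an enzyme's recognition site and marks
#' each occurrence as blocked when any cytosine inside the recognition
#' footprint, on either strand, carries a mark the enzyme is sensitive to.
#' Palindromic recognitions are reported once (strand "+"); non-palindromic
#' ones are also scanned on the minus strand when the enzyme requests it.
#' Occurrences containing N never cut and are skipped.
#'
#' @param sequence a [Biostrings::DNAString] or character scalar.
#' @param enzyme an [enzyme_spec()].
#' @param track optional methylome track data.frame
#'   (`chrom`, `pos` 0-based, `strand`, `mark`).
#' @param chrom chromosome name used for the track lookup and the output.
#' @return data.frame with columns `chrom`, `occ_start` (0-based), `strand`,
#'   `cut_pos` (0-based top-strand cut), `blocked`, and a list column
#'   `blocking_marks` (each element a data.frame of position/strand/mark).
#' @export
find_sites <- function(sequence, enzyme, track = NULL, chrom = "chr1") {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  stopifnot(inherits(enzyme, "enzyme_spec"))
  L <- nchar(enzyme$recognition)
  chromlen <- length(sequence)

  occ_plus <- .occurrences(sequence, enzyme$recognition)
  occ <- occ_plus
  strand <- rep("+", length(occ_plus))
  cut <- occ_plus + enzyme$cut_offset
  if (!.is_palindromic(enzyme$recognition) && enzyme$double_stranded_scan) {
    occ_minus <- .occurrences(sequence, .revcomp(enzyme$recognition))
    occ <- c(occ, occ_minus)
    strand <- c(strand, rep("-", length(occ_minus)))
    # mirror of the offset: top-strand coordinate of the staggered cut
    cut <- c(cut, occ_minus + (L - enzyme$cut_offset))
  }
  o <- order(occ, strand)
  occ <- occ[o]; strand <- strand[o]; cut <- cut[o]

  blocked <- rep(FALSE, length(occ))
  marks_list <- rep(list(.empty_df(data.frame(pos = integer(), strand = character(),
                                              mark = character()))), length(occ))
  if (length(occ) && length(enzyme$blocked_by)) {
    codes <- .track_codes(track, chrom, chromlen)
    want <- .mark_code(enzyme$blocked_by)
    hit <- (codes$plus %in% want) | (codes$minus %in% want)
    cs <- c(0L, cumsum(hit))
    blocked <- (cs[occ + L + 1L] - cs[occ + 1L]) > 0L
    for (i in which(blocked)) {
      span <- (occ[i] + 1L):(occ[i] + L)
      pmk <- codes$plus[span]; mmk <- codes$minus[span]
      pw <- pmk %in% want; mw <- mmk %in% want
      bm <- data.frame(
        pos = c(span[pw], span[mw]) - 1L,
        strand = c(rep("+", sum(pw)), rep("-", sum(mw))),
        mark = c("5mC", "5hmC")[c(pmk[pw], mmk[mw])],
        stringsAsFactors = FALSE)
      marks_list[[i]] <- bm
    }
  }
  out <- data.frame(chrom = rep(chrom, length(occ)), occ_start = occ,
                    strand = strand, cut_pos = cut, blocked = blocked,
                    stringsAsFactors = FALSE)
  out$blocking_marks <- marks_list
  out
}

#' Mark-aware in-silico digestion
#'
#' Cuts a sequence at every unblocked cut site of every supplied enzyme
#' (positions deduplicated across enzymes) and returns the resulting fragment
#' tiling. Fragments carry their bounding cut positions; chromosome termini are
#' recorded as `NA` (the TERMINUS sentinel). Zero-length fragments from
#' adjacent cut positions are suppressed.
#'
#' @inheritParams find_sites
#' @param enzymes a single [enzyme_spec()] or list of them.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based half-open),
#'   `length`, `left_cut`, `right_cut`.
#' @export
digest <- function(sequence, enzymes, track = NULL, chrom = "chr1") {
  if (inherits(enzymes, "enzyme_spec")) enzymes <- list(enzymes)
  if (!length(enzymes)) stop("enzymes must be non-empty")
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  len <- length(sequence)
  cuts <- unlist(lapply(enzymes, function(e) {
    s <- find_sites(sequence, e, track, chrom)
    s$cut_pos[!s$blocked]
  }))
  cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
  bounds <- c(0L, cuts, len)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(chrom = rep(chrom, length(starts)), start = starts, end = ends,
             length = ends - starts,
             left_cut = ifelse(starts == 0L, NA_integer_, starts),
             right_cut = ifelse(ends == len, NA_integer_, ends),
             stringsAsFactors = FALSE)
}

#' Digest every chromosome of a genome
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @inheritParams digest
#' @return row-bound [digest()] output across chromosomes.
#' @export
digest_genome <- function(genome, enzymes, track = NULL) {
  stopifnot(inherits(genome, "DNAStringSet"), !is.null(names(genome)))
  do.call(rbind, lapply(names(genome), function(ch) {
    digest(genome[[ch]], enzymes, track, chrom = ch)
  }))
}

#' Cut positions present in the tester digest but absent from the driver
#'
#' The set-theoretic core of the RDA subtraction: positions cleaved by the
#' mark-insensitive tester enzyme but protected from the sensitive driver
#' isoschizomer. Inputs are either numeric cut-position vectors or
#' [find_sites()] data.frames restricted to one chromosome.
#'
#' @param tester_cuts,driver_cuts numeric vectors of 0-based cut positions, or
#'   data.frames with `chrom` and `cut_pos` columns (unblocked rows are used).
#' @return sorted numeric vector of tester-only cut positions.
#' @export
subtract_cut_sets <- function(tester_cuts, driver_cuts) {
  as_cuts <- function(x) {
    if (is.data.frame(x)) {
      ch <- unique(x$chrom)
      if (length(ch) > 1L) stop("chromosome mismatch: multiple chromosomes")
      list(chrom = if (length(ch)) ch else NA_character_,
           cuts = if ("blocked" %in% names(x)) x$cut_pos[!x$blocked] else x$cut_pos)
    } else {
      list(chrom = NA_character_, cuts = as.numeric(x))
    }
  }
  a <- as_cuts(tester_cuts); b <- as_cuts(driver_cuts)
  if (!is.na(a$chrom) && !is.na(b$chrom) && a$chrom != b$chrom) {
    stop("chromosome mismatch: ", a$chrom, " vs ", b$chrom)
  }
  sort(setdiff(a$cuts, b$cuts))
}
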