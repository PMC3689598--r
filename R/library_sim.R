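#' Protocol configuration for the enrichment chemistries
#'
#' Three idealized chemistries are modeled. The two subtractive protocols
#' (`ME_RDA`, `HME_RDA`) digest tester DNA with a mark-insensitive enzyme and
#' driver DNA with its mark-sensitive isoschizomer; tester fragments whose
#' bounding sites the driver could not cut escape subtraction and are
#' amplified. The `HELP_COCKTAIL` protocol digests with a frequent cutter
#' (TasI) and removes every fragment that a methyl-sensitive cocktail can cut
#' internally, enriching fragments whose internal sites are all protected.
#'
#' @param protocol one of "ME_RDA", "HME_RDA", "HELP_COCKTAIL".
#' @param tester_enzyme,driver_enzyme [enzyme_spec()]s for the RDA protocols;
#'   must share an identical recognition sequence. Defaults: MspI/HpaII for
#'   ME_RDA, FspBI/BfaI for HME_RDA.
#' @param frequent_cutter the HELP fragmenting enzyme (default TasI).
#' @param cocktail list of methyl-sensitive [enzyme_spec()]s for HELP
#'   (default HpaII, AciI, HinP1I).
#' @param size_window amplifiable fragment length window in bp; the default
#'   100-1000 bp is the validated amplicon range.
#' @param exclude_terminal_fragments drop fragments touching chromosome ends
#'   (termini cannot ligate adaptors at both ends).
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(protocol = c("ME_RDA", "HME_RDA", "HELP_COCKTAIL"),
                            tester_enzyme = NULL, driver_enzyme = NULL,
                            frequent_cutter = NULL, cocktail = NULL,
                            size_window = c(100L, 1000L),
                            exclude_terminal_fragments = TRUE) {
  protocol <- match.arg(protocol)
  enz <- default_enzymes()
  if (protocol == "ME_RDA") {
    if (is.null(tester_enzyme)) tester_enzyme <- enz$MspI
    if (is.null(driver_enzyme)) driver_enzyme <- enz$HpaII
  } else if (protocol == "HME_RDA") {
    if (is.null(tester_enzyme)) tester_enzyme <- enz$FspBI
    if (is.null(driver_enzyme)) driver_enzyme <- enz$BfaI
  } else {
    if (is.null(frequent_cutter)) frequent_cutter <- enz$TasI
    if (is.null(cocktail)) cocktail <- enz[c("HpaII", "AciI", "HinP1I")]
  }
  if (protocol %in% c("ME_RDA", "HME_RDA") &&
      tester_enzyme$recognition != driver_enzyme$recognition) {
    stop("tester/driver recognition mismatch: ", tester_enzyme$recognition,
         " vs ", driver_enzyme$recognition)
  }
  stopifnot(length(size_window) == 2L, size_window[1] < size_window[2])
  structure(list(protocol = protocol, tester_enzyme = tester_enzyme,
                 driver_enzyme = driver_enzyme,
                 frequent_cutter = frequent_cutter, cocktail = cocktail,
                 size_window = as.integer(size_window),
                 exclude_terminal_fragments = isTRUE(exclude_terminal_fragments)),
            class = "protocol_config")
}

# highest-priority mark present in a recognition footprint (either strand):
# 5hmC > 5mC > none
.footprint_mark <- function(codes, occ, L) {
  vapply(occ, function(o) {
    if (is.na(o)) return(NA_character_)
    span <- (o + 1L):(o + L)
    v <- c(codes$plus[span], codes$minus[span])
    if (any(v == 2L)) "5hmC" else if (any(v == 1L)) "5mC" else "none"
  }, character(1))
}

#' Simulate a subtractive (RDA) enrichment
#'
#' Digests each chromosome with the tester enzyme under the supplied methylome
#' and retains exactly the fragments with at least one bounding cut position
#' that the driver isoschizomer cannot produce (the subtraction is modeled as
#' ideal and complete). Terminal fragments and fragments outside the size
#' window are excluded per the configuration. Each enriched fragment carries
#' the true mark status of its bounding recognition footprints as provenance.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param track methylome track data.frame.
#' @param config a [protocol_config()] with an RDA protocol.
#' @return data.frame of enriched fragments: `chrom`, `start`, `end`,
#'   `length`, `left_cut`, `right_cut`, `true_left_mark`, `true_right_mark`,
#'   `protocol`, `fragment_id`.
#' @export
simulate_rda <- function(genome, track, config) {
  stopifnot(inherits(config, "protocol_config"),
            config$protocol %in% c("ME_RDA", "HME_RDA"))
  tester <- config$tester_enzyme; driver <- config$driver_enzyme
  L <- nchar(tester$recognition)
  out <- lapply(names(genome), function(ch) {
    seq <- genome[[ch]]
    tsites <- find_sites(seq, tester, track, ch)
    frags <- digest(seq, tester, track, ch)
    dsites <- find_sites(seq, driver, track, ch)
    driver_cuts <- dsites$cut_pos[!dsites$blocked]
    left_escapes <- !is.na(frags$left_cut) & !(frags$left_cut %in% driver_cuts)
    right_escapes <- !is.na(frags$right_cut) & !(frags$right_cut %in% driver_cuts)
    keep <- (left_escapes | right_escapes)
    if (config$exclude_terminal_fragments) {
      keep <- keep & !is.na(frags$left_cut) & !is.na(frags$right_cut)
    }
    keep <- keep & frags$length >= config$size_window[1] &
      frags$length <= config$size_window[2]
    frags <- frags[keep, , drop = FALSE]
    if (!nrow(frags)) return(NULL)
    codes <- .track_codes(track, ch, length(seq))
    occ_of_cut <- setNames(tsites$occ_start, tsites$cut_pos)
    frags$true_left_mark <- .footprint_mark(
      codes, unname(occ_of_cut[as.character(frags$left_cut)]), L)
    frags$true_right_mark <- .footprint_mark(
      codes, unname(occ_of_cut[as.character(frags$right_cut)]), L)
    frags
  })
  out <- out[!vapply(out, is.null, logical(1))]
  frags <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               length = integer(), left_cut = integer(),
               right_cut = integer(), true_left_mark = character(),
               true_right_mark = character(), stringsAsFactors = FALSE)
  frags$protocol <- rep(config$protocol, nrow(frags))
  frags$fragment_id <- if (nrow(frags)) {
    sprintf("%s:%d-%d", frags$chrom, frags$start, frags$end)
  } else character()
  rownames(frags) <- NULL
  frags
}

#' Simulate the HELP-cocktail enrichment
#'
#' Digests each chromosome with the frequent cutter, then removes every
#' fragment in which any cocktail enzyme has an unblocked cut strictly inside
#' the fragment. Fragments containing no cocktail recognition occurrence at
#' all survive the digestion trivially; they are retained here with
#' `no_internal_site = TRUE` and are removed downstream by the read filter,
#' mirroring the in-silico exclusion of uninformative fragments.
#'
#' @inheritParams simulate_rda
#' @param config a [protocol_config()] with `protocol = "HELP_COCKTAIL"`.
#' @return data.frame of retained fragments: fragment coordinates plus
#'   `n_internal_sites`, `no_internal_site`, `internal_site_marks` (list
#'   column of footprint marks of the internal occurrences), `protocol`,
#'   `fragment_id`.
#' @export
simulate_help <- function(genome, track, config) {
  stopifnot(inherits(config, "protocol_config"),
            config$protocol == "HELP_COCKTAIL")
  out <- lapply(names(genome), function(ch) {
    seq <- genome[[ch]]
    frags <- digest(seq, config$frequent_cutter, track, ch)
    sites <- lapply(config$cocktail, function(e) find_sites(seq, e, track, ch))
    cuts <- sort(unique(unlist(lapply(sites, function(s) s$cut_pos[!s$blocked]))))
    occs <- lapply(sites, function(s) sort(unique(s$occ_start)))
    occ_lens <- vapply(config$cocktail, function(e) nchar(e$recognition),
                       integer(1))

    n_inside_cuts <- findInterval(frags$end - 1L, cuts) -
      findInterval(frags$start, cuts)
    n_occ <- rep(0L, nrow(frags))
    for (k in seq_along(occs)) {
      o <- occs[[k]]; Lk <- occ_lens[k]
      if (!length(o)) next
      n_occ <- n_occ + pmax(0L, findInterval(frags$end - Lk, o) -
                              findInterval(frags$start - 1L, o))
    }
    keep <- n_inside_cuts == 0L
    if (config$exclude_terminal_fragments) {
      keep <- keep & !is.na(frags$left_cut) & !is.na(frags$right_cut)
    }
    keep <- keep & frags$length >= config$size_window[1] &
      frags$length <= config$size_window[2]
    frags$n_internal_sites <- n_occ
    frags <- frags[keep, , drop = FALSE]
    if (!nrow(frags)) return(NULL)

    codes <- .track_codes(track, ch, length(seq))
    frags$internal_site_marks <- lapply(seq_len(nrow(frags)), function(i) {
      s <- frags$start[i]; e <- frags$end[i]
      unlist(lapply(seq_along(occs), function(k) {
        o <- occs[[k]]; Lk <- occ_lens[k]
        o <- o[o >= s & o + Lk <= e]
        .footprint_mark(codes, o, Lk)
      }))
    })
    frags
  })
  out <- out[!vapply(out, is.null, logical(1))]
  frags <- if (length(out)) do.call(rbind, out) else {
    f <- data.frame(chrom = character(), start = integer(), end = integer(),
                    length = integer(), left_cut = integer(),
                    right_cut = integer(), n_internal_sites = integer(),
                    stringsAsFactors = FALSE)
    f$internal_site_marks <- list()
    f
  }
  frags$no_internal_site <- frags$n_internal_sites == 0L
  frags$protocol <- rep("HELP_COCKTAIL", nrow(frags))
  frags$fragment_id <- if (nrow(frags)) {
    sprintf("%s:%d-%d", frags$chrom, frags$start, frags$end)
  } else character()
  rownames(frags) <- NULL
  frags
}

#' Default library adaptor pair
#'
#' The 24-mer amplification adaptor used on both fragment ends by the
#' simulated libraries (the J-1B oligonucleotide sequence).
#'
#' @return list with elements `left` and `right`.
#' @export
default_adaptors <- function() {
  list(left = "ACCGACGTCGACTATCCATGAACC", right = "ACCGACGTCGACTATCCATGAACC")
}

#' Emit sequencing reads from enriched fragments
#'
#' Each fragment is emitted `coverage` times on a random strand, optionally
#' with adaptor sequences flanking the insert, and with i.i.d. base
#' substitutions at `error_rate`. Deterministic under `seed`. Read ids encode
#' the source fragment so recovery can be scored against the truth.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param fragments data.frame from [simulate_rda()] / [simulate_help()].
#' @param coverage copies per fragment.
#' @param error_rate substitution probability per base, in `[0, 0.2)`.
#' @param adaptors `NULL` or a list with `left` / `right` DNA strings (see
#'   [default_adaptors()]).
#' @param stage stage label stored with the reads.
#' @param seed integer seed.
#' @return data.frame of reads: `id`, `seq`, `chrom`, `start`, `end`,
#'   `strand`, `n_errors`, `stage`.
#' @export
fragments_to_reads <- function(genome, fragments, coverage = 5L,
                               error_rate = 0, adaptors = NULL,
                               stage = "D7", seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.2)
  proto <- data.frame(id = character(), seq = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      n_errors = integer(), stage = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(fragments)) return(proto)
  set.seed(derive_seed(seed, paste0("reads:", stage)))
  inserts <- vapply(seq_len(nrow(fragments)), function(i) {
    as.character(Biostrings::subseq(genome[[fragments$chrom[i]]],
                                    fragments$start[i] + 1L,
                                    fragments$end[i]))
  }, character(1))
  n <- nrow(fragments) * coverage
  idx <- rep(seq_len(nrow(fragments)), each = coverage)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n); nerr <- integer(n)
  for (j in seq_len(n)) {
    s <- inserts[idx[j]]
    if (!is.null(adaptors)) s <- paste0(adaptors$left, s, adaptors$right)
    if (strand[j] == "-") s <- .revcomp(s)
    if (error_rate > 0) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < error_rate)
      for (k in hit) ch[k] <- sample(setdiff(bases, ch[k]), 1L)
      nerr[j] <- length(hit)
      s <- paste(ch, collapse = "")
    }
    seqs[j] <- s
  }
  data.frame(
    id = sprintf("r%06d|%s|%s|%s|%s", seq_len(n),
                 fragments$protocol[idx], fragments$fragment_id[idx],
                 strand, stage),
    seq = seqs, chrom = fragments$chrom[idx], start = fragments$start[idx],
    end = fragments$end[idx], strand = strand, n_errors = nerr,
    stage = rep(stage, n), stringsAsFactors = FALSE)
}
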