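# A deterministic construct: three CCGG sites with 200/300 bp spacing inside
# CCGG-free filler, 150 bp of terminal filler on each side.
.three_site_genome <- function() {
  filler <- function(n) strrep("CA", n / 2)
  seq <- paste0(filler(150), "CCGG", filler(196), "CCGG", filler(296),
                "CCGG", filler(150))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chr1"
  list(genome = genome, occ = c(150L, 350L, 650L))
}

test_that("Me-RDA enriches exactly the fragments flanking a methylated site", {
  g <- .three_site_genome()
  mid_cpg <- g$occ[2] + 1L
  track <- data.frame(chrom = "chr1", pos = c(mid_cpg, mid_cpg + 1L),
                      strand = c("+", "-"), mark = "5mC")
  fr <- simulate_rda(g$genome, track, protocol_config("ME_RDA"))
  expect_equal(sort(fr$fragment_id), c("chr1:151-351", "chr1:351-651"))
  expect_true(all(fr$true_left_mark == "5mC" | fr$true_right_mark == "5mC"))
  expect_false(any(fr$true_left_mark == "5hmC" | fr$true_right_mark == "5hmC"))
})

test_that("an unmethylated genome yields no enrichment", {
  g <- .three_site_genome()
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), mark = character())
  expect_equal(nrow(simulate_rda(g$genome, empty, protocol_config("ME_RDA"))),
               0L)
})

test_that("a 5hmC-bearing CCGG blocks MspI itself and never bounds output", {
  g <- .three_site_genome()
  mid_cpg <- g$occ[2] + 1L
  track <- data.frame(chrom = "chr1", pos = c(mid_cpg, mid_cpg + 1L),
                      strand = c("+", "-"), mark = "5hmC")
  # the neighboring MspI fragments merge across the blocked site
  frags <- digest(g$genome[["chr1"]], default_enzymes()$MspI, track)
  expect_true("chr1:151-651" %in% sprintf("chr1:%d-%d", frags$start, frags$end))
  fr <- simulate_rda(g$genome, track, protocol_config("ME_RDA"))
  expect_equal(nrow(fr), 0L)   # 5hmC sites are invisible to Me-RDA
})

test_that("HMe-RDA enriches 5hmC-bearing CTAG sites", {
  filler <- function(n) strrep("CA", n / 2)
  seq <- paste0(filler(150), "CTAG", filler(196), "CTAG", filler(296),
                "CTAG", filler(150))
  genome <- Biostrings::DNAStringSet(seq); names(genome) <- "chr1"
  track <- data.frame(chrom = "chr1", pos = 350L, strand = "+", mark = "5hmC")
  fr <- simulate_rda(genome, track, protocol_config("HME_RDA"))
  expect_equal(sort(fr$fragment_id), c("chr1:151-351", "chr1:351-651"))
  expect_true(all(fr$true_left_mark == "5hmC" | fr$true_right_mark == "5hmC"))
})

test_that("Me-RDA equals the brute-force re-derivation on random genomes", {
  set.seed(33)
  for (i in 1:5) {
    sc <- random_seqchar(20000, gc = 0.5)
    tr <- random_track(sc, rate = 0.1)
    genome <- Biostrings::DNAStringSet(paste(sc, collapse = ""))
    names(genome) <- "chr1"
    enz <- default_enzymes()
    got <- simulate_rda(genome, tr, protocol_config("ME_RDA"))
    want <- oracle_rda(sc, tr, enz$MspI, enz$HpaII)
    expect_setequal(got$fragment_id, want)
  }
})

.help_fixture <- function() {
  pad <- function(n) strrep("CA", ceiling(n / 2))
  seg_marked <- paste0(pad(60), "CCGG", pad(60))     # internal site, protected
  seg_unmarked <- paste0(pad(60), "CCGG", pad(60))   # internal site, cut
  seg_bare <- pad(124)                               # no cocktail site
  seq <- paste0(pad(50), "AATT", seg_marked, "AATT", seg_unmarked, "AATT",
                seg_bare, "AATT", pad(50))
  genome <- Biostrings::DNAStringSet(seq); names(genome) <- "chr1"
  occ_aatt <- methylsieve:::.occurrences(genome[["chr1"]], "AATT")
  ccgg <- methylsieve:::.occurrences(genome[["chr1"]], "CCGG")
  list(genome = genome, aatt = occ_aatt, ccgg = ccgg)
}

test_that("HELP retains protected fragments and flags site-less ones", {
  f <- .help_fixture()
  cpg1 <- f$ccgg[1] + 1L   # CpG of the first (protected) internal CCGG
  track <- data.frame(chrom = "chr1", pos = c(cpg1, cpg1 + 1L),
                      strand = c("+", "-"), mark = "5mC")
  fr <- simulate_help(f$genome, track, protocol_config("HELP_COCKTAIL"))
  # fragment 1 (marked CCGG) kept, fragment 2 (unmarked CCGG) cut away,
  # fragment 3 (no site) kept with the flag
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$no_internal_site, c(FALSE, TRUE))
  expect_equal(fr$n_internal_sites[1], 1L)
  expect_equal(fr$internal_site_marks[[1]], "5mC")
  expect_equal(fr$start[1], f$aatt[1])
})

test_that("HELP retention is monotone in methylation", {
  set.seed(91)
  for (i in 1:5) {
    sc <- random_seqchar(15000, gc = 0.5)
    genome <- Biostrings::DNAStringSet(paste(sc, collapse = ""))
    names(genome) <- "chr1"
    tr <- random_track(sc, rate = 0.03)
    cfg <- protocol_config("HELP_COCKTAIL")
    before <- simulate_help(genome, tr, cfg)$fragment_id
    # add marks at further cytosines
    extra <- random_track(sc, rate = 0.03)
    tr2 <- unique(rbind(tr, extra))
    tr2 <- tr2[!duplicated(tr2[, c("chrom", "pos", "strand")]), ]
    after <- simulate_help(genome, tr2, cfg)$fragment_id
    expect_true(all(before %in% after))
  }
})

test_that("reads mirror fragments at zero error and count correctly", {
  g <- .three_site_genome()
  track <- data.frame(chrom = "chr1", pos = 351L, strand = "+", mark = "5mC")
  fr <- simulate_rda(g$genome, track, protocol_config("ME_RDA"))
  reads <- fragments_to_reads(g$genome, fr, coverage = 1, error_rate = 0,
                              seed = 2)
  for (i in seq_len(nrow(reads))) {
    insert <- substr(as.character(g$genome[["chr1"]]), reads$start[i] + 1L,
                     reads$end[i])
    expect_true(reads$seq[i] %in%
                  c(insert, as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(insert)))))
  }
  reads5 <- fragments_to_reads(g$genome, fr[rep(1, 10), ], coverage = 5,
                               seed = 3)
  expect_equal(nrow(reads5), 50L)
})

test_that("substitution counts follow the binomial expectation", {
  seq <- paste(random_seqchar(700), collapse = "")
  genome <- Biostrings::DNAStringSet(seq); names(genome) <- "chr1"
  fr <- data.frame(chrom = "chr1", start = 100L, end = 600L, length = 500L,
                   protocol = "ME_RDA", fragment_id = "chr1:100-600")
  reads <- fragments_to_reads(genome, fr[rep(1, 1000), ], coverage = 1,
                              error_rate = 0.01, seed = 5)
  se <- sqrt(500 * 0.01 * 0.99 / 1000)
  expect_lt(abs(mean(reads$n_errors) - 5), 3 * se)
  expect_error(fragments_to_reads(genome, fr, error_rate = 0.5), "0.2")
})
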