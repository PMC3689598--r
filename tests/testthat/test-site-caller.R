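cfg_me <- pipeline_config("ME_RDA")
J1B <- default_adaptors()$left

test_that("adaptor trimming recovers inserts and drops short reads", {
  set.seed(4)
  insert <- paste(random_seqchar(200), collapse = "")
  reads <- data.frame(id = "r1", seq = paste0(J1B, insert, J1B))
  out <- clean_reads(reads, J1B, cfg_me)
  expect_equal(out$seq, insert)
  expect_equal(attr(out, "report"), c(raw_reads = 1L, cleaned_reads = 1L))

  # one mismatch in the adaptor still trims; reverse-complement ends too
  mut_ad <- mutate_seq(J1B, 1, seed = 1)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  reads2 <- data.frame(id = c("r2", "r3"),
                       seq = c(paste0(mut_ad, insert),
                               rc(paste0(J1B, insert, J1B))))
  out2 <- clean_reads(reads2, J1B, cfg_me)
  expect_equal(out2$seq, c(insert, rc(insert)))

  short <- data.frame(id = "r4", seq = paste0(J1B, strrep("A", 30), J1B))
  out3 <- clean_reads(short, J1B, cfg_me)
  expect_equal(nrow(out3), 0L)
  expect_equal(attr(out3, "report")[["cleaned_reads"]], 0L)

  empty <- clean_reads(data.frame(id = character(), seq = character()),
                       J1B, cfg_me)
  expect_equal(unname(attr(empty, "report")), c(0L, 0L))
})

test_that("HELP read validation keeps cocktail-site reads on either strand", {
  cfg <- pipeline_config("HELP_COCKTAIL")
  pad <- strrep("CA", 30)
  reads <- data.frame(
    id = c("ccgg", "gcgg", "none"),
    seq = c(paste0(pad, "CCGG", pad),
            paste0(pad, "GCGG", pad),   # reverse complement of AciI's CCGC
            paste0(pad, pad)))
  out <- filter_help_reads(reads, cfg)
  expect_setequal(out$id, c("ccgg", "gcgg"))
  expect_equal(attr(out, "report")[["validated_reads"]], 2L)
  expect_error(filter_help_reads(reads, cfg_me), "HELP")
})

test_that("clustering merges at the inclusive 97% identity threshold", {
  set.seed(10)
  base <- paste(random_seqchar(100), collapse = "")

  ten <- data.frame(id = sprintf("r%02d", 1:10), seq = rep(base, 10))
  cc <- cluster_reads(ten, cfg_me)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$n_members, 10L)
  expect_equal(cc$consensus, base)

  two90 <- data.frame(id = c("a", "b"), seq = c(base, mutate_seq(base, 10, 2)))
  expect_equal(nrow(cluster_reads(two90, cfg_me)), 2L)

  # 3 substitutions in a 100-mer: identity exactly 0.97 -> merged
  two97 <- data.frame(id = c("a", "b"), seq = c(base, mutate_seq(base, 3, 3)))
  cc97 <- cluster_reads(two97, cfg_me)
  expect_equal(nrow(cc97), 1L)
  expect_equal(cc97$n_members, 2L)
  # 4 substitutions (0.96) -> two contigs
  two96 <- data.frame(id = c("a", "b"), seq = c(base, mutate_seq(base, 4, 4)))
  expect_equal(nrow(cluster_reads(two96, cfg_me)), 2L)
})

test_that("clustering output is invariant under input shuffling", {
  set.seed(20)
  pool <- replicate(6, paste(random_seqchar(sample(80:120, 1)), collapse = ""))
  reads <- data.frame(id = sprintf("r%02d", 1:18),
                      seq = c(pool, vapply(pool, mutate_seq, "", k = 1),
                              vapply(pool, mutate_seq, "", k = 2)))
  a <- cluster_reads(reads, cfg_me)
  for (perm in 1:3) {
    b <- cluster_reads(reads[sample(nrow(reads)), ], cfg_me)
    expect_equal(b$consensus, a$consensus)
    expect_equal(lapply(b$members, sort), lapply(a$members, sort))
  }
})

# genome with a unique 100-mer planted at a known position
.aligner_fixture <- function(seed = 30, dup = FALSE) {
  set.seed(seed)
  sc <- random_seqchar(20000)
  contig <- paste(random_seqchar(100), collapse = "")
  s <- paste(sc, collapse = "")
  s <- paste0(substr(s, 1, 5000), contig, substr(s, 5101, 20000))
  if (dup) s <- paste0(substr(s, 1, 12000), contig,
                       substr(s, 12101, nchar(s)))
  genome <- Biostrings::DNAStringSet(s)
  names(genome) <- "chr1"
  list(genome = genome, contig = contig, at = 5000L)
}

test_that("verbatim contigs place uniquely with full identity", {
  f <- .aligner_fixture()
  contigs <- data.frame(contig_id = "c1", consensus = f$contig)
  rec <- align_contigs(contigs, f$genome, cfg_me)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$start, f$at)
  expect_equal(rec$identity, 1)
  expect_equal(rec$coverage, 1)
  expect_equal(rec$n_best_loci, 1L)
  expect_equal(rec$strand, "+")
})

test_that("alignment thresholds are inclusive at 92% identity", {
  f <- .aligner_fixture()
  c91 <- mutate_seq(f$contig, 9, seed = 5)   # 91% -> discarded
  c92 <- mutate_seq(f$contig, 8, seed = 6)   # 92% -> kept
  recs <- align_contigs(data.frame(contig_id = c("c91", "c92"),
                                   consensus = c(c91, c92)),
                        f$genome, cfg_me)
  expect_false("c91" %in% recs$contig_id)
  expect_true("c92" %in% recs$contig_id)
  expect_equal(recs$identity[recs$contig_id == "c92"], 0.92)
})

test_that("reverse-complement contigs are placed on the minus strand", {
  f <- .aligner_fixture()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(f$contig)))
  rec <- align_contigs(data.frame(contig_id = "c1", consensus = rc),
                       f$genome, cfg_me)
  expect_equal(rec$strand, "-")
  expect_equal(rec$start, f$at)
})

test_that("a contig from a duplicated locus is excluded as multi-mapping", {
  f <- .aligner_fixture(dup = TRUE)
  rec <- align_contigs(data.frame(contig_id = "c1", consensus = f$contig),
                       f$genome, cfg_me)
  expect_equal(rec$n_best_loci, 2L)
  filt <- filter_alignments(rec, cfg_me)
  expect_equal(nrow(filt), 0L)
  expect_equal(unname(attr(filt, "report")),
               c(1L, 0L))
})

# CCGG occurrences at controlled distances from a site-free core
.extension_fixture <- function(left_gap, right_gap, core_len = 200L) {
  pad <- function(n) strrep("CA", ceiling(n / 2))
  seq <- paste0(pad(60), "CCGG", pad(left_gap), pad(core_len), pad(right_gap),
                "CCGG", pad(60))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chr1"
  core_start <- 60L + 4L + left_gap
  list(genome = genome,
       rec = data.frame(contig_id = "c1", chrom = "chr1",
                        start = core_start, end = core_start + core_len,
                        strand = "+", identity = 1, coverage = 1,
                        n_best_loci = 1L),
       left_occ = 60L, right_occ = 60L + 4L + left_gap + core_len + right_gap)
}

test_that("extension finds the nearest site and honors the inclusive cap", {
  # boundary already on an occurrence: fragment cut at occ+1
  f0 <- .extension_fixture(0, 0)
  r0 <- f0$rec; r0$start <- f0$left_occ + 1L
  ext0 <- extend_to_site(r0, f0$genome, cfg_me)
  expect_equal(ext0$left_site, f0$left_occ)

  f400 <- .extension_fixture(400, 400)
  e400 <- extend_to_site(f400$rec, f400$genome, cfg_me)
  expect_equal(e400$left_site, f400$left_occ)
  expect_equal(e400$right_site, f400$right_occ)
  expect_equal(e400$ext_start, f400$left_occ)
  expect_equal(e400$ext_end, f400$right_occ + 4L)

  # left distance is (boundary - occurrence start) = left_gap + 4;
  # right distance is (occurrence start - boundary) = right_gap
  cap <- cfg_me$extension_max
  fcap <- .extension_fixture(cap - 4L, cap)   # both exactly 1000 away
  ecap <- extend_to_site(fcap$rec, fcap$genome, cfg_me)
  expect_equal(ecap$left_site, fcap$left_occ)          # exactly 1000 -> accepted
  expect_equal(ecap$right_site, fcap$right_occ)

  fover <- .extension_fixture(cap - 2L, cap + 2L)       # 1002 -> unlabeled
  eover <- extend_to_site(fover$rec, fover$genome, cfg_me)
  expect_true(is.na(eover$left_site))
  expect_true(is.na(eover$right_site))
})

test_that("site labeling follows the per-protocol rules", {
  f <- .extension_fixture(100, 100)
  ext <- extend_to_site(f$rec, f$genome, cfg_me)
  sites <- call_sites(ext, f$genome, cfg_me, stage = "D7")
  expect_equal(nrow(sites), 2L)
  expect_setequal(sites$pos, c(f$left_occ + 1L, f$right_occ + 1L))
  expect_true(all(sites$mark == "5mC"))
  expect_setequal(sites$end, c("left", "right"))
  expect_true(all(verify_sites(sites, f$genome, cfg_me)))

  # both ends site-less -> no calls
  fna <- .extension_fixture(1200, 1200)
  extna <- extend_to_site(fna$rec, fna$genome, cfg_me)
  expect_equal(nrow(call_sites(extna, fna$genome, cfg_me)), 0L)
})

test_that("HELP labels every internal cocktail CpG between the TasI ends", {
  cfg <- pipeline_config("HELP_COCKTAIL")
  pad <- function(n) strrep("CA", ceiling(n / 2))
  mid <- paste0(pad(30), "CCGG", pad(30), "CCGG", pad(30), "CCGG", pad(30),
                "CCGC", pad(30))
  seq <- paste0(pad(50), "AATT", mid, "AATT", pad(50))
  genome <- Biostrings::DNAStringSet(seq); names(genome) <- "chr1"
  aatt <- methylsieve:::.occurrences(genome[["chr1"]], "AATT")
  rec <- data.frame(contig_id = "c1", chrom = "chr1", start = aatt[1],
                    end = aatt[2] + 4L, strand = "+", identity = 1,
                    coverage = 1, n_best_loci = 1L)
  ext <- extend_to_site(rec, genome, cfg)
  expect_equal(ext$left_site, aatt[1])
  expect_equal(ext$right_site, aatt[2])
  sites <- call_sites(ext, genome, cfg, stage = "D7")
  expect_equal(nrow(sites), 4L)          # 3 CCGG + 1 CCGC
  expect_true(all(sites$mark == "5mC"))
  expect_true(all(sites$end == "internal"))
  expect_true(all(verify_sites(sites, genome, cfg)))
})

test_that("the pipeline funnel is monotone and sites verify on the genome", {
  spec <- genome_spec(c(chr1 = 60000L), seed = 14)
  gen <- generate_genome(spec)
  model <- mark_model(p_mC_cpg = 0.4, p_mC_cpg_island = 0.4, p_mC_chh = 0,
                      p_hmC_cpg = 0, p_hmC_chh_ctag = 0)
  track <- assign_methylome(gen$genome, gen, model, "D7", seed = 15)
  fr <- simulate_rda(gen$genome, track, protocol_config("ME_RDA"))
  reads <- fragments_to_reads(gen$genome, fr, coverage = 2,
                              adaptors = default_adaptors(), seed = 16)
  res <- call_sites_pipeline(reads, gen$genome, cfg_me,
                             adaptors = unlist(default_adaptors()))
  rep <- res$report
  expect_lte(rep[["contigs"]], rep[["cleaned_reads"]])
  expect_lte(rep[["unique_alignments"]], rep[["aligned_contigs"]])
  expect_lte(rep[["aligned_contigs"]], rep[["contigs"]])
  expect_true(all(verify_sites(res$sites, gen$genome, cfg_me)))
})
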