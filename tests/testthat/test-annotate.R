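# Two-gene toy annotation on one 60 kb chromosome:
#   geneA (+): [20000, 24000), exons [20000,20500) and [23500,24000)
#   geneB (-): [30000, 33000), single exon spanning the gene
.toy_annotation <- function() {
  genes <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                      start = c(20000L, 30000L), end = c(24000L, 33000L),
                      strand = c("+", "-"))
  exons <- data.frame(gene_id = c("geneA", "geneA", "geneB"), chrom = "chr1",
                      start = c(20000L, 23500L, 30000L),
                      end = c(20500L, 24000L, 33000L),
                      exon_number = c(1L, 2L, 1L))
  list(genes = genes, exons = exons, chrom_lengths = c(chr1 = 60000L))
}

test_that("promoter windows are 5 kb, strand-aware, and exclusive", {
  a <- .toy_annotation()
  sites <- data.frame(chrom = "chr1",
                      pos = c(20000L - 4999L,  # inside + promoter
                              20000L - 5001L,  # just beyond the window
                              33000L + 4999L,  # inside - promoter (downstream coords)
                              20250L,          # geneA exon 1
                              21000L,          # geneA intron
                              45000L))         # open intergenic space
  ann <- classify_regions(sites, a$genes, a$exons, a$chrom_lengths)
  expect_equal(ann$category,
               c("promoter", "intergenic", "promoter", "exon", "intron",
                 "intergenic"))
  expect_equal(ann$owner[1], "geneA")
  expect_equal(ann$owner[3], "geneB")
  expect_equal(ann$owner[4], "geneA")
  expect_true(all(!is.na(ann$owner)))
  expect_equal(sum(attr(ann, "fractions")), 1)
})

test_that("exon evidence outranks another gene's promoter window", {
  genes <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                      start = c(10000L, 13000L), end = c(12000L, 15000L),
                      strand = c("+", "+"))
  # geneB's promoter [8000,13000) overlaps geneA entirely
  exons <- data.frame(gene_id = c("geneA", "geneB"), chrom = "chr1",
                      start = c(10000L, 13000L), end = c(12000L, 15000L),
                      exon_number = 1L)
  sites <- data.frame(chrom = "chr1", pos = c(11000L, 12500L))
  ann <- classify_regions(sites, genes, exons, c(chr1 = 30000L))
  expect_equal(ann$category, c("exon", "promoter"))
  expect_equal(ann$owner, c("geneA", "geneB"))
})

test_that("unknown chromosomes are rejected and owners are unique", {
  a <- .toy_annotation()
  expect_error(classify_regions(data.frame(chrom = "chrX", pos = 1L),
                                a$genes, a$exons, a$chrom_lengths),
               "absent")
  set.seed(2)
  sites <- data.frame(chrom = "chr1", pos = sort(sample(0:59999, 300)))
  ann <- classify_regions(sites, a$genes, a$exons, a$chrom_lengths)
  expect_true(all(table(ann$category) >= 0))
  expect_equal(sum(attr(ann, "fractions")), 1)
  expect_false(any(is.na(ann$owner)))
  # intergenic owners point at enumerated intergenic intervals
  inter <- intergenic_regions(a$genes, a$chrom_lengths)
  expect_true(all(ann$owner[ann$category == "intergenic"] %in%
                    inter$region_id))
})

test_that("genomic baseline fractions cover the genome exactly once", {
  a <- .toy_annotation()
  base <- genomic_baseline(a$genes, a$exons, a$chrom_lengths)
  expect_equal(sum(base), 1)
  expect_equal(unname(base["exon"]), 4000 / 60000)
  expect_equal(unname(base["intron"]), 3000 / 60000)
  expect_equal(unname(base["promoter"]), 10000 / 60000)
})

test_that("repeat composition arithmetic matches the constructed fixture", {
  # 10 contigs of 100 bp; 4 overlap satellite intervals by exactly half
  intervals <- data.frame(chrom = "chr1",
                          start = seq(0L, 9000L, by = 1000L),
                          end = seq(0L, 9000L, by = 1000L) + 100L)
  reps <- data.frame(chrom = "chr1",
                     start = intervals$start[1:4] + 50L,
                     end = intervals$start[1:4] + 150L,
                     class = "Satellite")
  comp <- summarize_repeats(intervals, reps)
  expect_equal(comp$frac_with_repeat, 0.4)
  expect_equal(unname(comp$class_base_fraction["Satellite"]), 0.2)
  expect_equal(unname(comp$class_base_fraction["total"]), 0.2)

  none <- summarize_repeats(intervals, reps[0, ])
  expect_equal(none$frac_with_repeat, 0)
  expect_true(all(none$class_base_fraction == 0))

  # unknown classes fall into "other"; islands counted when provided
  reps2 <- rbind(reps, data.frame(chrom = "chr1", start = 5000L, end = 5100L,
                                  class = "DNA_transposon"))
  isl <- data.frame(chrom = "chr1", start = 9000L, end = 9100L)
  comp2 <- summarize_repeats(intervals, reps2, islands = isl)
  expect_equal(unname(comp2$class_base_fraction["other"]), 0.1)
  expect_equal(comp2$n_in_island, 1L)
})

test_that("site-set comparison is an exact symmetric partition", {
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos, mark = "5mC")
  A <- mk(c(1, 2, 3)); B <- mk(c(2, 3, 4))
  cmp <- compare_site_sets(A, B)
  expect_equal(c(cmp$n_only_a, cmp$n_shared, cmp$n_only_b), c(1, 2, 1))

  same <- compare_site_sets(A, A)
  expect_equal(c(same$n_only_a, same$n_shared, same$n_only_b), c(0, 3, 0))
  disj <- compare_site_sets(mk(1:3), mk(7:9))
  expect_equal(c(disj$n_only_a, disj$n_shared, disj$n_only_b), c(3, 0, 3))

  # owner-region comparison
  A$owner <- c("r1", "r2", "r3"); B$owner <- c("r2", "r3", "r4")
  cmpo <- compare_site_sets(A, B, by = "owner-region")
  expect_equal(c(cmpo$n_only_a, cmpo$n_shared, cmpo$n_only_b), c(1, 2, 1))
  expect_error(compare_site_sets(mk(1), mk(2), by = "owner-region"), "annotated")

  set.seed(77)
  for (i in 1:50) {
    A <- mk(sample(100, sample(1:30, 1)))
    B <- mk(sample(100, sample(1:30, 1)))
    ab <- compare_site_sets(A, B); ba <- compare_site_sets(B, A)
    expect_equal(ab$n_only_a, ba$n_only_b)
    expect_equal(ab$n_shared, ba$n_shared)
    expect_equal(ab$n_only_a + ab$n_shared + ab$n_only_b,
                 length(union(unique(A$pos), unique(B$pos))))
  }
})

test_that("coverage bins partition sites with half-open boundaries", {
  cl <- c(chr1 = 5000L)
  zero <- coverage_bins(data.frame(chrom = character(), pos = integer()),
                        cl, bin_bp = 1000L)
  expect_true(all(zero$count == 0))
  expect_equal(nrow(zero), 5L)

  ten <- coverage_bins(data.frame(chrom = "chr1", pos = rep(1500L, 10)),
                       cl, bin_bp = 1000L)
  expect_equal(ten$count, c(0L, 10L, 0L, 0L, 0L))

  edge <- coverage_bins(data.frame(chrom = "chr1", pos = 1000L), cl, 1000L)
  expect_equal(edge$count, c(0L, 1L, 0L, 0L, 0L))   # boundary -> higher bin
  expect_equal(sum(edge$count), 1L)
})
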