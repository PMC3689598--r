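---
title: "Models and methods behind methylsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylsieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models implemented by methylsieve, the
assumptions behind them, the tunable parameters and their defaults, and the
design decisions taken where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The digestion model

An enzyme is `(recognition, cut_offset, blocked_by, double_stranded_scan)`.
Digestion scans for IUPAC recognition occurrences; a site is **blocked** when
any cytosine inside the recognition footprint, on either strand, carries a
mark in `blocked_by`. The literature describes inhibition by an "internal"
modified cytosine without defining a position, so the footprint-wide reading
is adopted as the conservative choice; it is configurable per enzyme through
the registry (`inst/extdata/enzyme_registry.tsv`).

Defaults encode the documented sensitivities: MspI (CCGG) blocked only by
5hmC; HpaII (CCGG) blocked by 5mC and 5hmC; FspBI (CTAG) insensitive; BfaI
(CTAG) blocked by 5hmC; TasI (AATT) insensitive; AciI (CCGC) and HinP1I
(GCGC) treated like HpaII. Two published details are ambiguous and resolved
as follows: the 5hmC sensitivity of AciI and HinP1I is not documented, so
they default to HpaII-like blocking (editable in the registry); and HinP1I
is stored with the standard G^CGC cut offset 1 even though the source
notation prints "GC/GC".

Further conventions: all coordinates are 0-based half-open internally
(GFF3's 1-based inclusive convention is converted only at the reader/writer
boundary); zero-length fragments from adjacent cuts are suppressed;
occurrences containing N never cut (an undefined base cannot be asserted as
a site); palindromic recognitions are scanned once, non-palindromic ones on
both strands when the enzyme requests it, with the single reported
top-strand cut coordinate of a minus occurrence at `s` defined as
`s + L - offset` (the mirror of the offset). Fragment-level logic never
depends on that choice.

## The chemistry simulators

The RDA subtraction is modeled as **ideal and complete**: a tester fragment
is enriched exactly when at least one bounding cut position is absent from
the driver's unblocked cut set. The hybridization-kinetics arguments for the
real protocol (large driver excess, long hybridization) justify treating the
set difference as the limiting behavior; kinetic enrichment, the
single-strand nuclease step and PCR bias are deliberately outside the model.
Terminal fragments are excluded by default because chromosome termini cannot
ligate adaptors at both ends, and a 100-1000 bp amplifiable size window is
applied — the validated amplicon range for the CCGG system; the same window
is used for HELP for symmetry (no HELP-specific window is documented) and
both are configurable.

HELP retention keeps a TasI fragment when no cocktail enzyme has an
unblocked cut strictly inside it. Fragments containing no cocktail
occurrence at all survive trivially; they are retained with
`no_internal_site = TRUE` and removed downstream by the read filter,
mirroring the in-silico exclusion of uninformative fragments. Retention is
monotone in methylation: adding a mark can only block cuts.

Population-level partial methylation cannot be represented by a single
per-position mark; it lives in the q-PCR module instead, where the
resistant fraction is a continuous proportion.

Read simulation emits each fragment a fixed number of times on a random
strand, optionally flanked by the 24-mer amplification adaptor on both
ends, with i.i.d. substitutions (no indels — the downstream aligner is
ungapped by design). The error rate is capped below 0.2.

## The synthetic genome and mark model

The generator emulates the feature classes the protocols interact with:
genes with exons/introns (for annotation), CpG islands (synthesized by
locally raising G+C and planting CpG dinucleotides — the island BED written
at generation time is the ground truth; no island caller is implemented),
tandem satellite arrays from a fixed arbitrary 23-mer labeled "SAT-like"
(class structure matters, not sequence identity), and interspersed
SINE/LINE/LTR-like families as exact copies of a random consensus. Features
that rewrite sequence are placed without overlap with bounded retries;
exceeding the retry budget raises a placement failure rather than silently
dropping features. Identical specs and seeds regenerate byte-identical
output.

Marks are drawn independently per cytosine from context-resolved
probabilities: CpG split by island membership, CHG/CHH with 5hmC restricted
to CTAG contexts (so the hydroxymethylation-sensitive chemistry has
non-CpG targets), repeat-class multipliers scaling both marks, and
per-stage overrides. CpG marks are mirrored to the opposite-strand cytosine;
hemimethylation and spatial autocorrelation are non-goals. No quantitative
context rates are documented for the source system, so the defaults are
chosen as biologically sensible placeholders — islands mostly unmethylated
(p(5mC|CpG, island) = 0.1), non-island CpGs largely methylated (0.7), low
non-CpG methylation (0.02), a modest 5hmC component (0.05) that doubles at
the later stage in the default two-stage model to emulate a developmental
5hmC transition — and every test states its own rates.

## The identification pipeline

*Trimming.* Leading/trailing adaptor occurrences (each adaptor and its
reverse complement, exact or one mismatch) are removed and reads shorter
than 50 bp dropped.

*Clustering.* Greedy centroid clustering with identity defined as matching
columns over alignment columns of an end-gap-free global alignment
(`pairwiseAlignment(type = "overlap")`), threshold 0.97 inclusive. Reads are
processed in decreasing length order with ties broken by id, so the result
is invariant under input shuffling; consensus is the per-column majority
over members aligned to the centroid with ties resolved to the centroid
base. This scheme is a stated stand-in for USEARCH-style clustering, not a
claim of bit-parity. Candidate centroids are pre-screened by shared exact
16-mers (centroids are indexed by non-overlapping 16-mer tiles and each
read probes all of its overlapping 16-mers); with substitutions at up to 3%
of positions, fewer tiles can be hit than exist, so at least one centroid
tile always survives intact and the screen cannot lose a qualifying pair.
Clustering has no reverse-complement
awareness: reads from opposite strands of one fragment form two contigs,
both of which align (one per strand) and label the same sites.

*Alignment.* Exact 16-mer seeds tiled over the contig in both orientations,
full-length ungapped verification, inclusive thresholds of 0.92 identity
and 0.92 coverage (the published filter discards alignments *below* 92%,
hence inclusive). Gapped alignment is unnecessary for substitution-only
synthetic reads at these thresholds; externally produced PSL alignments can
be imported for real data. Placements of one contig overlapping more than
50% reciprocally are merged before counting loci — whether overlapping
self-hits were counted separately in the original analysis is unknowable,
so the merge is the package's own choice — and any contig with more than
one distinct passing locus is excluded entirely.

*Extension and labeling.* Each end of a uniquely placed contig is extended
to the nearest occurrence of the protocol's primary recognition sequence up
to 1,000 bp. The cap is inclusive and a capped-out end is left unlabeled
rather than dropping the contig, keeping the other end usable. For Me-RDA
the CpG cytosine of each end's CCGG is labeled 5mC. For HMe-RDA the
published labeling sentence mentions CpGs although CTAG contains none; the
implemented rule labels the cytosine of the CTAG occurrence as 5hmC. For
HELP every cocktail-site CpG strictly between the two bounding TasI sites is
labeled 5mC (in all three cocktail recognitions, and in the minus-strand
occurrence of the non-palindromic CCGC, that cytosine sits one base into
the occurrence); records lacking either bounding TasI site yield no
internal calls. Duplicates are collapsed on
(chrom, position, mark, method, stage) — the same position found by two
methods intentionally remains two records, since methods are compared
downstream.

End-labeling both fragment ends is the method's documented false-positive
mechanism: enrichment only certifies that *at least one* bounding site was
protected. The end-to-end tests and the acceptance script measure both the
recovery of truly marked bounding sites and this unmarked-partner-end
fraction.

## Annotation and comparisons

Promoters are the strand-aware 5 kb window upstream of the TSS. Category
precedence is exon > intron > promoter > intergenic: the categories are
exclusive but unordered in the source description, and gene-body evidence is
ranked above a neighboring gene's promoter window because the site
physically lies in transcribed sequence. Ties between genes go to the
smallest gene id. Intergenic regions are the maximal intervals covered by
neither gene spans nor promoter windows, identified by coordinates. The
genomic baseline column is computed from the supplied annotation by base
coverage, so synthetic runs produce their own neutral reference. Coverage
binning is half-open (a boundary site belongs to the higher bin); set
comparisons are exact partitions by position or by owning region.

## q-PCR estimation and the rank-sum test

The resistant (marked) fraction is `efficiency^(-ΔCt)` with
`ΔCt = Ct(digested) − Ct(undigested)`; the transform itself is not printed
in the source description (only that ΔCt was used to analyse proportions),
so the standard digestion-resistance form is adopted, with perfect doubling
(efficiency 2) as the configurable default. Values above 1 (negative ΔCt)
are clamped and flagged. The between-stage test enumerates every assignment
of the pooled observations into the observed group sizes (mid-ranks for
ties, two-sided p as the doubled smaller tail capped at 1), falling back to
a tie-corrected normal approximation with a warning beyond combined n = 12.
What "simplified" meant in the cited Wilcoxon variant is not specified; the
exact two-sided rank-sum is implemented. A consequence worth noting: with
three pools per stage the smallest attainable two-sided p is 0.1, so fully
separated 3-vs-3 data are never significant at 0.05.

## Problem sizes, determinism, and limitations

The test suite validates the digestion kernel against an independent
position-scan oracle (200 random 10 kb sequences, all seven enzymes), the
RDA simulators against brute-force re-derivation on a repeat-free 2 Mb
genome with p(5mC|CpG) = 0.3, HELP retention against hand enumeration over
100 designed fragments, and the full read-to-site path at 5x error-free
coverage — sizes chosen so the whole suite runs comfortably on one CPU.
A single run seed fans out to stage-salted child seeds (`derive_seed`), so
any stage can be re-run in isolation and two identical runs produce
byte-identical artifacts.

What passing these tests does *not* show: the generator draws marks
independently per cytosine, emits repeats as exact copies, and models no
PCR bias, chimeras, indel errors or partial digestion, so performance on
real libraries — where clustering confronts sequencing error profiles and
repeats confront the aligner with families rather than identical copies —
is not established by the synthetic recovery numbers. The pipeline's
structural guarantees (threshold inclusivity, unique-placement exclusion,
site-position invariants, funnel monotonicity) are what the suite
certifies.
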