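---
title: "Discriminating coding from noncoding ORFs with SNP-level microdiversity"
author: "MicroDiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating coding from noncoding ORFs with SNP-level microdiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroDiv)
```

# The model

Viral populations carry abundant within-population single-nucleotide
variation. When reads or closely related sequences are mapped onto a
reference genome, that variation appears as SNPs, and the *kind* of amino
acid change each SNP would induce is informative about whether the region
is translated. In a real gene, purifying selection removes damaging
replacements: synonymous changes and biochemically tolerated replacements
persist, while unfavorable replacements and stop changes are depleted. In
a random noncoding ORF there is no such filter and the substitution
spectrum matches the neutral expectation of the local codon composition.

MicroDiv quantifies this per ORF with two count ratios. Writing `pS` for
synonymous SNP alleles and splitting nonsynonymous alleles by their
BLOSUM62 substitution score into favorable (`pPos`, score ≥ 0) and
unfavorable (`pNeg`, score < 0, plus stop gains/losses):

$$\mathrm{pN/pS} = \frac{pPos + pNeg}{pS}, \qquad
  \mathrm{pNeg/pS} = \frac{pNeg}{pS}.$$

The refinement to pNeg/pS matters because favorable nonsynonymous changes
are frequent both in genes and in noncoding sequence, so they dilute
pN/pS; restricting the numerator to unfavorable changes sharpens the
contrast. Ratios are plain count ratios without site-count normalization
or pseudocounts (an optional pseudocount argument exists for sparse data
but defaults to 0): a zero denominator yields `Inf` with a positive
numerator and `NA` at 0/0, and both sentinels propagate into the result
tables as literal `Inf`/`NA`.

## Classification of one SNP allele

Each alternate allele of each SNP is classified independently against
*every* ORF covering its position — overlapping and overprinted genes
make it essential that a SNP can be synonymous in one frame and
unfavorable in another. For a minus-strand ORF both alleles are
complemented before the codon substitution. The categories are:

* `SYN` — equal, non-stop amino acids;
* `STOP` — exactly one side is a stop (gain or loss). Stops have no
  BLOSUM62 score; they are counted with `NEG` in both ratio numerators
  because a premature stop is the strongest evidence against constrained
  coding;
* `NEG` / `POS` — unequal amino acids with negative / non-negative
  BLOSUM62 score. A score of exactly 0 counts as `POS`: the numerator of
  pNeg/pS is defined by *negative* scores, and zero is not negative;
* `UNKNOWN` — the codon contains N; excluded from every count and from
  the bar charts, but retained in the effect table.

One boundary case follows from these definitions rather than from
biology: a substitution turning one stop codon into another (e.g.
TAA→TGA) has equal amino acids but is excluded from `SYN` (which requires
non-stop) and from `STOP` (which requires exactly one stop), so it falls
through to the matrix rule and, since score(\*,\*) = +1, lands in `POS`.
The case is vanishingly rare (it requires a SNP inside the terminal stop)
and does not move either ratio's numerator.

# ORF detection

All six reading frames of both strands are scanned. The default mode
(`start2stop`) reports, for each open stretch between consecutive in-frame
stops, the ORF from the stretch's leftmost ATG to the terminating stop
(stop included in the coordinates); `stop2stop` reports the entire open
stretch. ATG is the only start codon by default — well-defined start
positions are required by the first-50-nt start diagnostic — and the
genetic code table is configurable (standard table 1 by default, table 11
for phage work). Partial ORFs at linear sequence edges are suppressed:
without a defined start and stop the per-ORF statistics are ill-defined.

On circular genomes frames continue across the origin and ORFs may wrap
it. Internally the scan runs over a repeated copy of the sequence so that
the codon walk threads through the origin even when the genome length is
not a multiple of 3 (in which case the six "frames" merge into longer
cycles); ORFs are deduplicated modulo the genome length, none longer than
the genome is emitted, and when an open stretch exceeds the genome length
the reported ORF starts at the leftmost start codon that still fits. The
length filter (`min_orf_nt`, default 90) tests the full ORF length
including the stop codon — the package's small worked examples fix this
reading. The entire scan is verified in the test suite against an
independent brute-force enumerator that walks every position of every
strand codon by codon.

Coordinates are 1-based inclusive on the forward strand, the R and
Bioconductor convention; VCF and GFF3 input are 1-based natively so no
conversion is exposed to the user. Offsets *within* an ORF are 0-based in
reading orientation, so `codon_index = offset %/% 3` and
`codon_pos = offset %% 3`.

# SNP evidence

Two evidence routes feed the classifier:

* **SAM** — alignments of reads or related sequences (e.g. from bwa mem).
  A minimal pileup walks each CIGAR (M/=/X advance both sequences and
  contribute the query base; I/S advance the query only; D/N the
  reference only) and per-position A/C/G/T counts are thresholded: an
  alternate base is called when supported by **at least 2 reads** that
  make up **at least 1% of the position's depth**, both conjunctive and
  both configurable. Depth counts A/C/G/T only; base qualities are
  ignored (database contigs carry no meaningful qualities), and the
  mapping-quality filter defaults to off. All qualifying alternates of a
  position form one multi-allelic SNP.
* **VCF** — pre-called variants; only SNVs are kept (indels/MNVs are
  counted and skipped, as the statistic is strictly SNP-based), `INFO/DP`
  and the first sample's `FORMAT/AD` are used when present, and every
  reference allele is checked against the genome — a mismatch aborts the
  run naming the first offending position, since it signals a VCF called
  against a different reference.

The two routes are exchangeable: on simulated data the test suite checks
that pileup + thresholds on the SAM reproduces the truth VCF exactly and
that both routes give identical per-ORF statistics.

# Decision rules

Candidate selection uses pNeg/pS ≤ 1 (`candidate_max_ratio`), requiring at
least `min_snps = 4` classified effects — below that the ratio is noise
and the ORF is flagged `insufficient_data` instead. Known borderline true
genes slightly above 1 are deliberately *not* special-cased; they remain
visible in the table with their exact ratio and the threshold is a
parameter.

**Mirror discard.** Synonymous variation concentrates at third codon
positions, and third positions of a gene are first/second positions of the
reverse-strand frames, so a true gene manufactures an apparently
constrained ORF on the complementary strand. Since bidirectional coding is
rare, a candidate B is discarded when a surviving candidate A on the
opposite strand is longer and covers at least `containment_frac = 0.9` of
B (strict containment would be fragile to start-position noise).
Candidates are examined longest-first, so an ORF discarded by a larger
mirror cannot itself discard others; the filter is idempotent and leaves
no violating pair. Equal-length mutual overlaps — unseen in practice —
break deterministically: the higher pNeg/pS loses, then the minus-strand
ORF. Whether the shadowing ORF must itself be a candidate is a genuine
design choice; requiring candidacy was chosen because the artifact's
source is a *selected* gene.

**Overprint allowance.** Selection on the ancestral gene constrains an
overprinted gene's substitutions, inflating its pNeg/pS above 1. ORFs with
1 < pNeg/pS ≤ `overprint_max_ratio = 1.5` that overlap a candidate in a
different frame or strand are flagged `overprint_candidate` rather than
rejected. The overlap requirement exists because the 1.5 allowance is only
justified where an ancestral gene is present.

**Suspect start.** When an ORF's detected start lies upstream of the true
one, its 5' stretch is effectively noncoding. The flag fires when the
pNeg/pS of the first `first_nt = 50` nucleotides is at least
`start_fold = 2` times the whole-ORF ratio, with three guards: both ratios
finite and defined, whole-ORF ratio > 0 (a zero ratio makes the fold
undefined), and at least `min_first50_snps = 3` classified effects in the
window (a single unfavorable SNP would otherwise produce an infinite
5' ratio). The start is only reported, never moved.

# The synthetic-data generator

`simulateMicrodiversity()` builds complete, parseable studies with known
truth: a random circular genome with planted genes (ATG, stop-free body,
terminal stop), a haplotype population, and the corresponding FASTA, GFF3,
SAM and VCF files plus a JSON manifest of all parameters. The default
conditions — one choice, used everywhere — are a 3000-nt genome, two
600-nt genes on opposite strands, 200 haplotypes, a per-site substitution
proposal rate of 0.05 per haplotype and nonsynonymous acceptance
`omega = 0.1` with stop changes rejected. At 200 haplotypes the pileup
depth is 200, so the 2-read / 1% thresholds coincide, and the proposal
rate yields several hundred called SNP alleles per gene, far above the
≥ 30 the recovery experiments require.

Design choices worth stating: each planted gene carries an upstream
in-frame guard stop so that the discovered ORF start coincides with the
planted start, making recovery truth exact rather than fuzzy; gene
positions are evenly spaced (content is random) so placement never fails;
haplotypes diverge from the reference independently (a star phylogeny)
and proposals are evaluated against the reference codon context, so sites
are independent — with ≤ 15% of sites mutated per haplotype, double hits
in one codon are rare and the approximation is immaterial. Acceptance is
a single `omega`, not BLOSUM-graded, which still produces realistic
POS/NEG mixtures because the *proposals* follow the codon composition.
The `extension_nt` option plants an in-frame, stop-free, ATG-initiated
stretch immediately 5' of a gene that evolves neutrally — the
erroneous-start scenario: the ORF finder then reports the gene
`extension_nt` too long and the first-50-nt diagnostic should fire.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: sequencing error, fragmented and partially
overlapping reads (haplotypes are full length and ungapped), indels,
recombination, phylogenetic structure among the mapped sequences, and
uneven coverage. The pileup's CIGAR logic is therefore tested separately
with handcrafted records rather than through the generator.

# Numerical and reporting choices

Ratios are rendered with two decimals in the TSVs (`NA`/`Inf` as
literals); tables are tab-separated, UTF-8, LF, and byte-deterministic,
as is the SVG report — determinism is asserted by the test suite. The
report linearizes circular genomes at position 1, drawing wrapping ORFs
as two segments joined by a dashed connector; ORF fill follows a monotone
green (0) → grey (1) → orange (1.5) → red (saturating at 3) scale over
pNeg/pS, mirror-discarded ORFs are outlined red, and suspect starts carry
a red square at the ORF's 5' end. The six bar charts count SYN, POS and
NEG+STOP effects per 15-nt window, one triplet per strand; the bar-chart
grouping (3 categories × 2 strands rather than 6 frames) is one of two
defensible readings and is configurable only through the data model.

Problem sizes in the shipped experiments were chosen so the whole suite
runs in about two minutes on a single core: recovery uses 20 seeded
replicates of the default 3-kb / 200-haplotype study, ORF-finder
equivalence uses 200 random ~300-nt genomes, and the classifier
cross-check uses > 1000 random (genome, ORF, SNP) triples including
minus-strand and origin-wrapping cases. On this synthetic benchmark the
planted genes are recovered as candidates, their opposite-strand shadows
are discarded, noncoding ORFs sit near the neutral pNeg/pS of ≈ 2, and
45-nt extensions are flagged — the acceptance script
(`scripts/acceptance.R`) recomputes all of these rates from scratch for
any seed.

# Limitations

The method needs microdiversity: without enough mapped variation
(tens of SNPs per ORF) ratios are undefined or flagged
`insufficient_data`, and the package deliberately reports rather than
guesses. Ratios are raw counts, not site-normalized rates, so they are
not comparable across genomes with very different codon composition.
Overprinted genes are only *suggested* (ratio ≤ 1.5 over a candidate),
start positions are only *reported* as suspect, and bidirectional coding
— rare but real — is discarded by construction. Multi-contig input is
out of scope for a single run: loop over contigs.
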