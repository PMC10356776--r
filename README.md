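# MicroDiv

Coding-region discrimination from SNP-level microdiversity in viral
genomes.

## The problem

Viral genomes are packed with short, overlapping and even overprinted
genes, which ab initio gene predictors routinely miss: short ORFs are hard
to tell from random open reading frames, and large overlaps are penalized
by most gene models. MicroDiv takes a different route that needs nothing
but the genome and its natural population diversity: metagenomic reads (or
closely related database sequences) mapped onto the reference reveal SNPs,
and inside a real protein-coding region purifying selection shapes those
SNPs — synonymous changes accumulate freely while damaging amino-acid
replacements are purged.

## The statistic

Every alternate allele of every SNP is classified against every ORF
covering its position, in that ORF's own frame and strand:

* **SYN** — synonymous (identical amino acid),
* **POS** — nonsynonymous with a BLOSUM62 score ≥ 0 (tolerated
  replacement; these are common even in noncoding sequence and carry
  little signal),
* **NEG** — nonsynonymous with a negative BLOSUM62 score (unfavorable),
* **STOP** — stop gained or lost (counted with NEG),
* **UNKNOWN** — codon contains an N (excluded from all counts).

Per ORF the package computes

```
pN/pS   = (POS + NEG + STOP) / SYN
pNeg/pS = (NEG + STOP) / SYN
```

as plain count ratios. Under purifying selection pNeg/pS falls well below
1; in noncoding ORFs it sits near its neutral value (around 2). Decision
rules on top of the ratio:

* **candidate** — pNeg/pS ≤ 1 (with at least 4 classified SNPs);
* **mirror discard** — synonymous changes concentrate at third codon
  positions, so a true gene imprints an apparently constrained ORF on the
  complementary strand; a candidate contained (≥ 90%) in a longer
  opposite-strand candidate is discarded as this mirror artifact;
* **overprint candidate** — ORFs with 1 < pNeg/pS ≤ 1.5 that overlap a
  candidate in another frame/strand: overprinted genes inherit constraint
  from the ancestral gene and legitimately sit above 1;
* **suspect start** — if the pNeg/pS of the first 50 nt is at least twice
  the whole-ORF value, the true start codon likely lies downstream.

SNPs come either from a SAM of mapped sequences — piled up internally and
called with the default thresholds *2 supporting reads AND ≥ 1% of the
position's depth* — or from a pre-called VCF (SNVs only).

## Worked example

Simulate a study (3 kb circular genome, two planted 600-nt genes on
opposite strands, 200 haplotypes evolved with nonsynonymous acceptance
omega = 0.1) and run the full pipeline on the emitted SAM:

```r
library(MicroDiv)
cfg <- simulationConfig(seed = 42)
sim <- simulateMicrodiversity(cfg, "demo_fix")
res <- runMicrodiv(sim$reference, "demo_out", sam_path = sim$sam,
                   circular = TRUE)
```

The run log prints the stage counters:

```
genome: sim_genome, 3000 nt, circular
ORFs found: 19 (+: 9, -: 10)
alignments: 200 kept, 0 skipped by flag, 0 below mapq
SNPs called: 2313 positions, 5496 alleles
effects: 5145 (SYN 1806, POS 1413, NEG 1685, STOP 241, UNKNOWN 0)
flags: candidate 2, overprint_candidate 0, mirror_discarded 3, suspect_start 0, insufficient_data 0
```

and the larger ORFs of `orfStats(res)` show the separation:

```
    orf_id start  end strand length_nt n_syn n_pos n_neg n_stop pneg_ps            flags
2  ORF_002   406  579      -       174   113   130   188     22  1.8584
4  ORF_004   602 1201      +       600   377    29    28      0  0.0743        candidate
5  ORF_005   709  909      -       201    82    43    22      5  0.3293 mirror_discarded
9  ORF_009  1803 2402      -       600   375    29    46      0  0.1227        candidate
13 ORF_013  2068 2223      +       156    80    24    15      4  0.2375 mirror_discarded
14 ORF_014  2071 2235      -       165    13    52    54     10  4.9231
```

The two candidates are exactly the planted genes (602–1201 `+` and
1803–2402 `-`, pNeg/pS 0.07 and 0.12); the low-ratio ORFs nested in them
on the opposite strand (ORF_005, ORF_013) are recognized as mirror
artifacts and discarded; everything else sits near the neutral ratio of
~2. `demo_out/` contains the two result tables (`orfs.tsv`,
`effects.tsv`), the mirror-relationship table, the run log and the
multi-track SVG report (`report.svg`): annotation lanes, ORFs colored by
pNeg/pS (green → grey → orange → red), coverage, and six windowed
substitution bar charts (SYN / POS / NEG+STOP per strand, 15-nt windows).

A thin command-line wrapper lives at `inst/scripts/microdiv.R`
(`microdiv.R run ...` / `microdiv.R simulate ...`).

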