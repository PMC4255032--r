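# tepoly

Comparative detection of species-specific transposable element (TE)
insertions between two closely related genomes.

## The problem

When two genomes are closely related (say, ~98–99% nucleotide identity —
two sister species, or two strains), recent transposition shows up as
**insertion polymorphisms**: a locus "filled" by a TE copy in one genome
that is orthologous to an "empty" site in the other. Counting and
characterizing such sites measures how much of the ongoing genome
divergence is driven by mobile elements, identifies the currently active
TE families, and exposes related mechanisms such as solo-LTR formation by
ectopic recombination between the long terminal repeats of an endogenous
retrovirus (ERV). `tepoly` implements this comparative protocol as a
reusable, fully tested pipeline for people studying TE activity and
genome divergence in any pair of related assemblies (or assembly vs BAC
set).

The protocol, stage by stage:

1. **Repeat annotation** (`annotateRepeats`). TE copies are located by
   seed-and-extend local alignment against a consensus library
   (RepeatMasker-style `id#superfamily` FASTA). Hits are kept when their
   length is ≥ 100 nt and their divergence to the consensus is ≤ 20%,
   where divergence is the mismatch fraction over aligned non-gap
   columns. Close hits matching contiguous parts of one consensus are
   merged under a common element number, so a fragmented copy counts as
   one insertion. Low-complexity sequence is masked with a DUST-style
   triplet score.
2. **Orthology mapping** (`buildOrthoMap`). High-identity anchors
   (maximal exact matches, merged across isolated substitutions) are
   chained along alignment diagonals into orthologous fragments with a
   defined orientation; the map supports coordinate liftover in both
   directions, with interpolation refused across length-discordant gaps.
3. **Insertion calling** (`callInsertions`). Annotations of the two
   genomes are listed "face to face" across the map: an insertion is
   shared when its lifted span reciprocally overlaps a same-superfamily
   insertion in the other genome; every unpaired annotation becomes a
   candidate. Candidates opposite assembly N-stretches whose length
   matches the insertion are flagged as artifacts. The rest are refined
   by global alignment of the filled and empty windows — the insertion is
   the maximal gap block in the empty sequence — and searched for target
   site duplications (TSDs).
4. **Structural features** (`featureTable`). TSD / poly-A / AT-rich
   classification, LTR and TIR detection, solo-LTR recombination calling
   (empty site ≈ one LTR, same TSD on both structures), composite
   decomposition, copy number under the classical family filters (hit
   length ≥ 80% of the element, identity ≥ 80%), transcriptome
   representation (hits ≥ 80 nt at ≥ 95% identity), and ≥ 98%-identity
   subfamily clustering.
5. **Summary statistics** (`divergenceSummary`, `extrapolateGenome`,
   `genomicContext`). Shared-insertion density per Mb, per-species kb and
   percent contributions of specific insertions to the analyzed span,
   genome-wide extrapolations, and intron/intergenic context with
   distances to the nearest exon.

A synthetic genome-pair simulator (`simulationConfig`,
`simulateGenomePair`) plants shared and species-specific insertions,
5'-truncated LINEs, TSDs, poly-A tails, an ERV whose orthologous site is
a solo LTR, and N-stretch artifact mimics into a common ancestor, and
records every event in a ground-truth manifest so the entire pipeline can
be scored (`scorePipeline`) without any external data.

## Worked example

```r
library(tepoly)

cfg <- simulationConfig(seed = 11, ancestorLength = 120000,
                        specificTECount = 10, nStretchCount = 3)
sim <- simulateGenomePair(cfg)
res <- runAll(sim, outdir = "demo_out")
res$calls
#> InsertionCalls: 65 shared pair(s); 21 specific call(s) (A: 10, B: 11)
#> analyzed span on A: 0.178 Mb
#>  species               status  n
#>        A             artifact  0
#>        B             artifact  3
#>        A solo_ltr_counterpart  1
#>        B solo_ltr_counterpart  0
#>        A             specific 10
#>        B             specific 11

res$divsum
#> Analyzed span: 0.178 Mb; shared insertions: 65 (~370 per Mb)
#>   A: 10 specific insertion(s), 16.6 kb, 9.30% of analyzed span
#>   B: 11 specific insertion(s), 9.4 kb, 5.30% of analyzed span
#> combined: 14.60% (sum of rounded per-species values; raw 14.61%)
#> specific insertion length: mean 1238, range 225-4629 nt

unlist(res$score[c("recall", "precision", "artifact_flagged_fraction",
                   "tsd_exact_fraction", "solo_recovered")])
#>                    recall                 precision artifact_flagged_fraction
#>                         1                         1                         1
#>        tsd_exact_fraction            solo_recovered
#>                         1                         1
```

Every planted specific insertion was recovered with exact boundaries and
TSDs, all three N-stretch mimics were flagged as assembly artifacts, and
the programmed ERV/solo-LTR recombination event was identified. The
reports directory contains the per-superfamily count table, the
per-insertion feature table, BED/JSON call exports and a summary.

To run the same stages on real data, point `runAnnotate` / `runMap` /
`runCall` at your own FASTA files (see `inst/scripts/tepoly.R` for a
command-line wrapper).

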