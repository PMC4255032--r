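---
title: "Detecting TE insertion polymorphisms between close genomes: models and choices"
author: "tepoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TE insertion polymorphisms between close genomes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `tepoly`, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## The comparative model

Two genomes descend from a recent common ancestor and differ by (i)
point substitutions and small indels accumulated independently in each
lineage, and (ii) structural events, among which transposable element
insertions dominate. A TE insertion present in one genome at a locus
whose ortholog in the other genome is "empty" is an insertion
polymorphism. The package cannot, and does not try to, distinguish
post-speciation transposition from ancestral allelic polymorphism, nor —
for DNA transposons — insertion in one lineage from excision in the
other; all three are evidence of recent transposition activity, and the
call records carry the carrier species and structural evidence, not a
claim about the generating process.

The unit of analysis is the **orthologous fragment**: a pair of
intervals, one per genome, descended from one ancestral segment, with an
orientation. Annotated TE copies inside fragments are paired "face to
face"; unpaired copies are candidate polymorphisms; candidates are
verified by aligning the filled site against the lifted empty site.

## Stage models and tunable parameters

### Repeat annotation

Copies are found by exact k-mer seeding (default `k = 12`) followed by
banded gapped extension with x-drop termination (match +1, mismatch -2,
gap open 5, gap extension 1, x-drop 20, band 50 nt — BLASTN-like
scores). Identity is matches over aligned non-gap columns; divergence is
its complement, uncorrected (a Kimura-style correction changes nothing at
the ≤ 20% divergences kept here and the thresholded quantity is the raw
fraction). Hits shorter than 100 nt or more than 20% diverged from the
consensus are discarded, both bounds inclusive. Seeds falling fully
inside low-complexity intervals are dropped; the masker is a DUST-style
triplet over-representation score (window 64 nt, threshold 2.0), the
field's standard approach. tRNA/rRNA pseudogene exclusion is delegated to
the library: such records are simply not in a TE consensus library.

Split hits of one copy — interrupted by a nested insertion, a masked
stretch, or extension break-up in diverged regions — are merged into one
insertion when they share consensus and strand, lie within 5 kb on the
genome and advance consistently along the consensus (overlap ≤ 50 nt),
taking the transitive closure. This reproduces the "common element
number" accounting of standard annotation pipelines; the exact joining
heuristic of those tools is unpublished, so the gap/collinearity rule
here is a declared approximation, and the merge is exercised against a
brute-force closure oracle in the tests.

### Orthology map

Anchors are maximal exact matches of at least `seedLen = 20` nt (exact
k-mer runs merged across isolated substitutions while identity stays
≥ 0.95; seeds occurring more than 10 times in either genome are ignored,
which keeps interspersed repeats from flooding the anchor set). Chains
maximize total anchor length × identity. A chain step must be monotone
on both genomes with both gaps ≤ 10 kb. Diagonal drift beyond 200 nt is
*penalized* (0.02 per nt) rather than forbidden: a one-sided gap is
exactly what an insertion polymorphism looks like, and a map that breaks
at every polymorphic insertion cannot support the analysis it exists
for. Colinear explanations therefore win whenever one exists, while
insertions are crossed as explicit indel steps.

Chains are extracted best-first. A secondary chain is kept when its
anchors do not overlap an accepted chain's anchors and, if it lies
inside an accepted chain's inter-anchor gap, when its b-side interval
fills the corresponding b-side gap between the bracketing anchors'
inner edges — true for a nested inversion, false for repeat-induced
matches between non-orthologous loci. Fragments are split around kept
nested chains, so reported fragments never overlap on genome A.

Liftover maps positions inside anchors exactly and interpolates linearly
between anchors, but only when the two gap lengths agree within 20%
(with a 10 nt floor); positions inside discordant gaps are unmapped,
which prevents false empty-site calls inside rearrangements. Window
extraction for calling uses a clamping variant that always returns the
nearest defensible coordinate.

### Calling and refinement

Pairing is 1-to-1 and greedy by descending reciprocal overlap with a 0.5
threshold and a same-superfamily requirement. The reciprocal overlap is
additionally capped by the ratio of the two elements' native lengths:
interpolation across a one-sided gap can stretch a lifted 0.5 kb span
over a 5 kb element, and such a pair (a solo LTR opposite its full
element) must not count as shared.

Each unpaired annotation is evaluated at its lifted site. The
assembly-artifact screen runs first: an empty-site window containing a
run of ≥ 90% N whose length matches the candidate within ±10% flags the
candidate, mirroring the observation that draft-assembly gaps
length-match the insertions they hide. Remaining candidates are refined
by global affine alignment of the filled window (span ± 500 nt) against
the empty window. The gap opening penalty here is 25: with weak opening
penalties the optimal global alignment of a multi-kb insertion against
surplus empty-side sequence shatters the insertion gap into dozens of
blocks to collect chance matches, and the single-maximal-gap-block rule
then fails; 25 is far above the shatter threshold observed in practice
while leaving boundary placement untouched. A candidate whose empty
window shows no gap block of ≥ 100 nt is reclassified (it is present in
both genomes after all, or too short to count); flanking identity below
0.90 on either side flags the call unrefined but keeps it.

### TSDs

A refined insertion interval is the *difference* between filled and
empty sites, so it contains the element plus one copy of the target site
duplication, and its placement can slide wherever sequence repeats
across the breakpoint. `insertionTSD` therefore tests, at every
equivalent placement, three configurations — duplication outside both
ends (the solo-LTR situation), duplication at the leading edge, and at
the trailing edge — and returns the longest exact duplication, reporting
the element interval with the duplicated copy excluded (which is the
length convention of the per-insertion table: an element's length never
includes its TSD). Boundaries that come from heuristic extension rather
than from a flank-anchored alignment can be off by a few nt on each side
independently; for those the search scans small independent boundary
displacements by increasing total displacement and stops at the first
level yielding a duplication. TSD matching is exact-string only —
published examples show exact framed repeats — with a length range of
2–25 nt; mismatch-tolerant TSDs are deliberately out of scope. When no
duplication exists, 20-nt abutting windows that are ≥ 80% A (or T)
classify the site as a poly-A region and 30-nt windows ≥ 85% A+T as
AT-rich; these windows must be full-width, so degenerate tiny flanks
return "not detected".

### Solo LTRs, composites, copy number, expression, subfamilies

LTR/TIR detection aligns the element's two terminal windows (each
min(1.5 kb, half the element)) locally, in direct and reverse-complement
orientation, accepting repeats ≥ 100 nt at ≥ 80% identity ending within
50 nt of the termini. A solo-LTR recombination event is called when a
specific LTR-element call's empty site aligns to one LTR at ≥ 90%
identity, length within ±10%, and both structures are framed by the same
TSD string — the signature of ectopic homologous recombination having
deleted the internal region plus one LTR. Because the refined interval
of such a call excludes one LTR, the structural tests run on the full
annotated element span. Composite insertions are decomposed by greedy
highest-score non-overlapping tiling with library hits (coverage below
60% is flagged partial), with nested TSDs searched per component. Copy
number counts collapsed local hits with length ≥ 80% of the query and
identity ≥ 80% (≥ 98% for the high-identity count); transcriptome
representation counts transcripts with a hit ≥ 80 nt at ≥ 95% identity;
subfamily clustering is single-linkage at ≥ 98% global identity, with
pairs that cannot reach that identity (length ratio < 0.8 or no shared
20-mer) skipped without alignment.

### Summaries

Percent contributions are reported per species rounded to two decimals,
and the combined figure both as the sum of the rounded values (how such
numbers are conventionally added in print) and as the raw quotient; the
shared density is reported raw and rounded to the nearest ten. The
genome-wide extrapolation divides the per-species average by the
analyzed genome fraction and reports a band obtained by rounding down
and up to the nearest half leading decade (6,750 → 6,500–7,000). The
denominator of all percentages is the orthologous-fragment total on
genome A — the quantity the pipeline actually measures — rather than the
raw input length. Report files are byte-deterministic: fixed ordering,
fixed rounding, and no timestamps anywhere, including the provenance
logs.

## The synthetic-data generator

`simulateGenomePair` emulates the statistical structure of a comparison
between two genomes at ~98.7% identity:

* i.i.d. ancestor at GC 0.42 (vertebrate-like);
* shared insertions planted in the ancestor at 540 per Mb, lengths
  log-normal (median ≈ 600 nt, SINE-dominated landscape) clipped to
  [120 nt, consensus length], divergence to consensus uniform on
  [0, 0.15];
* independent lineage substitutions at half the pairwise rate each
  (default pairwise 0.013, so ~98.7% identity outside events) and small
  indels at a tenth of that rate with geometric lengths of mean 3 nt —
  the simplest model consistent with a single printed identity figure;
  no rate heterogeneity, no CpG effect;
* species-specific insertions planted *after* lineage mutation (they are
  post-speciation events, hence young): 100 per species by default,
  lengths log-normal (median ≈ 1.1 kb, fit to the published table of 27
  insertions) clipped to [225, 5091] nt, divergence uniform on
  [0, 0.05]; LINE and Gypsy copies are 5'-truncated to their target
  length; 15% of LINE plants carry a poly-A tail instead of a TSD;
* TSDs are *host* sequence: the target site is read from the genome at
  the insertion point and the novel material (element + duplicated site)
  is inserted next to the existing copy — inserting a random duplication
  wholesale would leave no copy at the empty site and produce
  structurally wrong filled/empty differences. Insertion sites are
  probed a few bases downstream when the element's terminal base would
  coincidentally extend the duplication, so the maximal duplication
  equals the programmed one and elements are never altered;
* one ERV with ~99% mutual LTR identity planted in genome B whose
  orthologous site in genome A carries a solo LTR with the same
  (ancestral, substitution-shielded) TSD;
* 20 N-stretch artifact mimics: a real TE insertion in genome B paired
  with a length-matched N run in genome A.

`simulateAnnotationTracks` optionally adds simple gene models (exons
placed off the planted blocks) and a transcript set mixing spliced gene
transcripts with fragments of planted elements, so the genomic-context
and transcriptome columns can be exercised offline as well
(`rtracklayer::export` writes the models as GFF3). Events keep a minimum
spacing of 300 nt in the ancestor, so nested
insertions are not simulated; the manifest records exact final
coordinates and the realized block sequence of every event, and the test
suite asserts substring equality for all of them. What passing tests on
this generator do **not** show: behavior under nested/overlapping
insertions, segmental duplications, satellite arrays, sequencing error,
or repeat landscapes with realistic age structure. The pipeline's
recall/precision numbers are statements about this generative model, not
about any particular pair of real genomes.

## Numerical choices and degenerate inputs

Internal coordinates are 1-based inclusive throughout (the convention of
the host ecosystem's interval classes); text reports are 1-based
inclusive and BED exports 0-based half-open. Sequences shorter than the
DUST window yield an empty mask; empty libraries are allowed with a
warning; candidates whose empty window cannot be built are excluded with
a warning and reported in the accounting. Ties: equidistant exons break
to the lower coordinate; equal-length TSD configurations prefer
outside-duplication, then leading-edge; equal-score chains break to the
leftmost a-coordinate. The k-mer hash is exact for k ≤ 26 in double
precision; windows containing non-ACGT characters produce no seeds,
which is also why N runs are invisible to the anchor and annotation
stages and must be handled by the explicit artifact screen.

Problem sizes used by the test suite were chosen to exercise every event
type at the smallest scale that keeps the statistics meaningful: unit
tests run on 30–120 kb simulations, the property-based acceptance check
on the full 1 Mb / 200-insertion configuration, and the determinism
check on a 120 kb configuration run twice.

## Known limitations

* Shared-insertion pairing keys on superfamily and position only; two
  different elements of one superfamily inserted independently at
  near-orthologous positions would be paired as shared.
* Copy-number counting collapses overlapping hits greedily by score;
  tandem arrays of a query are counted approximately.
* The boundary-refinement alignment is global over fixed windows; an
  insertion within ~500 nt of a fragment edge gets asymmetric flanks
  and may be flagged unrefined.
* Protein-level evidence (ORF/domain annotation) is out of scope; the
  per-insertion notes carry library classification metadata instead.
* The automated "best hit" selection and flank-identity floor formalize
  steps that were manual in the original protocol; both are parameters,
  not ground truth.
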