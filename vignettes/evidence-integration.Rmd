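---
title: "Evidence integration for genome annotation: methods and design"
author: "annoweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence integration for genome annotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoweave)
```

# Scope and model

`annoweave` implements the evidence-integration layer of a BRAKER-style
plant-genome annotation workflow and the marker-filtering step of a
polyploid linkage-mapping workflow. The external predictors and aligners
(GeneMark, AUGUSTUS, ProtHint, STAR, GMAP, RepeatMasker, variant callers)
are deliberately *not* invoked: their outputs — predictions, aligned
isoforms, hints, dosage calls — are the package's inputs, in the standard
formats those tools emit (GFF3, BED12, soft-masked FASTA, hint GFF, TSV).
Each stage is a pure function over these inputs, so any stage's input can
be swapped between real tool output and synthetic data.

Coordinates are stored 0-based half-open internally; all GFF3/BED I/O
converts to and from the 1-based inclusive file convention at the boundary.
This makes length arithmetic unambiguous (`length = end - start`) and is
pinned by round-trip tests. Minus-strand transcripts store exons in
ascending genomic order; biological order is derived, so there is exactly
one canonical storage form.

## Longest ORF

The lORF of a spliced, sense-oriented cDNA is the longest complete reading
frame — ATG through an in-frame stop (stop included) — over the three
forward frames. Reverse frames are never scanned because full-length
Iso-Seq reads are orientation-resolved upstream by primer/polyA
classification; scanning them would contradict the data-generation
contract. Three conservative choices make the definition reproducible:

* ATG is the only accepted start; ORFs lacking a stop within the transcript
  are discarded rather than extended to the transcript end;
* codons containing ambiguity codes (N etc.) qualify neither as start nor
  as stop;
* a length tie breaks to the smallest transcript-relative start.

The implementation is validated against an exhaustive enumeration oracle
(every ATG walked codon-by-codon to its first stop) on random sequences.

## Iso-Seq reduction

Alignment filtering keeps isoforms at identity ≥ 0.95 and coverage ≥ 0.90,
both inclusive; attribute values above 1 are auto-detected as percentages.
A *locus* is a connected component of same-strand genomic-span overlap
(≥ 1 bp). Span overlap, rather than exon-level overlap, matches the locus
granularity at which a single representative is chosen; grouping is
strand-aware because sense and antisense transcription are distinct loci.
Both points are design decisions where the procedure description is silent,
and both are pinned by tests.

Each locus keeps the isoform with the longest lORF (ties: smaller span
start, then lexicographic id — determinism matters more than the specific
rule). The lORF ≥ 300 nt and intron ≤ 10,000 nt filters run *after*
representative choice. The order is observable: a locus whose longest-lORF
isoform fails a filter produces no representative at all, even if a
shorter-lORF isoform in the locus would have passed. A regression test pins
this order.

## Mask refinement

Soft-masking (lowercase FASTA) hides repeats from downstream predictors,
but repeat libraries routinely shadow real coding exons. Bases that are
masked *and* lie inside an Iso-Seq ORF supported by RNA-Seq or protein
evidence are unmasked. Two decisions:

* Only the **intersection** of masked runs with ORF intervals is unmasked,
  never the whole repeat run: it is the minimal, conservative reading of
  "masked regions overlapping the ORFs", and it is idempotent.
* "Supported" reuses the package's own support levels: an isoform counts
  when its RNA-Seq or protein level is at least partial (≥ 1 intron hint
  match, or a start/stop protein hint on a single-exon lORF). No separate
  support notion is introduced.

Residues are never touched (case-insensitive identity is asserted before
and after); masking is monotonically non-increasing; loci are counted
against the mask state at entry so the count is independent of processing
order. Changed bases are verified against a per-base oracle.

## Hint sets

A hint is a located evidence atom — an intron (full span) or a start/stop
codon (3-bp interval) — with a source (`rnaseq`/`protein`) and a
multiplicity. Identity is the exact key (sequence, kind, start, end,
strand): both hint producers emit exact splice coordinates, so no fuzz
window is defensible. Filtering is inclusive (`mult >= threshold`;
standard 3, training tier 100) and monotone in the threshold. Merging
unions keys, keeping the same key from two sources as two source-tagged
records and summing multiplicities of identical (key, source) records.
The high-confidence intersection keeps intron keys present in both sets
with the pairwise-minimum multiplicity — membership is what matters
downstream, and the minimum is the conservative combined weight.

## Seeds

Predictions and representative Iso-Seq ORFs combine into one seed set.
Overlap is tested on same-strand **CDS** genomic spans: seeds parameterize
coding regions, so untranslated overlap is irrelevant; accordingly the
extent of an Iso-Seq seed is its ORF projection, not the full transcript
span (the alternative was considered and rejected as inconsistent with the
CDS-length comparison the rule makes). On overlap the Iso-Seq seed is kept
iff its ORF is strictly more than 50 nt longer — the boundary diff = 50
keeps the prediction, diff = 51 keeps the isoform, and both boundaries are
tested exactly. When one isoform overlaps several predictions the rule is
applied once against the longest-CDS prediction, and every overlapped
member of the losing side is removed; this one-vs-many resolution is local
and deterministic. Overlapping members *within* either input violate the
upstream contracts and abort.

## Support classification

Per evidence class, a coding prediction is `full`, `partial` or `none`:

| class | multiexon full | single-exon full |
|---|---|---|
| Iso-Seq | one isoform contains the whole intron chain; its extra introns lie outside the prediction's CDS span | a projected lORF whose start *and* end equal the CDS bounds |
| RNA-Seq | every intron has a matching intron hint | — (no intron to match) |
| protein | every intron has a matching protein intron hint | start *and* stop codon hints |

"Extra introns only in the UTRs" is interpreted against the *prediction's*
CDS genomic span, because the supporting isoform's own UTRs are only
definable relative to coding extent. The single-exon Iso-Seq match is exact
boundary equality — any fuzz window would need an unstated tolerance.
`partial` means not full but at least one matched element: an intron key, a
start/stop hint, or ≥ 1 bp of same-strand CDS overlap with an Iso-Seq ORF
(1 bp is the minimal defensible floor for "a part of the gene structure";
it is exposed as `min_overlap`). Classification is monotone: adding hints
never demotes a level. Training genes are Iso-Seq-full or protein-full;
RNA-Seq support alone is excluded from training.

Category counts always satisfy the partition
`fully_supported_any + partial_only + unsupported = total`; the package
enforces this identity rather than reproducing any particular published
partition (published partitions of this kind are not always internally
consistent).

## Summary statistics

`summarize_annotation()` reports gene/transcript totals, the
isoforms-per-gene histogram (the identity `sum(k * count_k) =
n_transcripts` is asserted), mean gene length (union span of a gene's
isoforms), mean introns per gene (distinct intron keys across isoforms),
and median intron/exon lengths over all transcripts, with even counts using
the midpoint rule. Protein length in amino acids is `CDS_nt / 3 - 1` (stop
codon excluded). Printed proportions and ratios use **half-up** decimal
rounding (`round_half_up()`): banker's rounding would alter several
conventionally printed values, and the package's own outputs should match
what a reader computes by hand. Empty input returns a zero-count sentinel
rather than an error.

## Single-dose markers

For a maternal haplotype map of an autotetraploid F1 cross, markers pass
three rules in order, and the audit table records the first rule failed:

1. **dosage** — simplex × nulliplex (maternal 0/0/0/1, paternal 0/0/0/0);
2. **missing** — missing-call fraction strictly below 0.05 (6 of 119
   progeny — 5.04% — fails; 5 of 119 passes; tested exactly);
3. **segregation** — χ² goodness-of-fit of present/absent counts against
   1:1, kept when p ≥ α = 0.05, no continuity correction, no multiplicity
   adjustment. The source procedure names no specific test; the χ² GOF
   test is the field default, and α is exposed as a parameter.

Retention is monotone in both knobs: raising `max_missing` or lowering
`alpha` can only grow the kept set. With ~119 non-missing binary calls, the
discreteness of the binomial makes the realized type-I rate of rule 3
slightly below the nominal 5% (about 4.4%); the validation suite allows for
this known offset.

# The synthetic-data generator

`generate_annotation_fixture()` and `generate_marker_fixture()` stand in
for the sequencing data a real annotation project would download. They are
first-class, tested code, and their defaults *are* the study conditions the
package targets — they are not tuning knobs:

* genome 800 kb with 120 genes by default (the validation suite uses 300
  genes on 2.5 Mb for parameter recovery, 20–60 genes elsewhere; sizes
  chosen so the full suite and the acceptance script each run in well under
  a minute of generator time);
* exon lengths U(60, 300), introns U(80, 400) — bracketing median exon and
  intron lengths in the low-100s of bp as observed in compact rosaceous
  genomes — and 1–8 exons per gene (≈ 3.5 introns/gene on average);
* repeat fraction 0.45, matching the masked fraction of the genome the
  package was built around; runs U(200, 2000) bp placed uniformly, freely
  overlapping genes so mask refinement has work to do;
* Iso-Seq emission probability 0.6 per gene, UTRs U(30, 200) bp, identity
  U(0.95, 1) and coverage U(0.90, 1) (within the alignment filters), and
  with probability 0.1 an extra 20-bp intron inside the gene's CDS span —
  exactly the defect that demotes Iso-Seq support from full to partial;
* RNA-Seq intron hints at probability 0.7 with shifted-negative-binomial
  coverage (mean 20, heavily overdispersed, so a realistic minority of
  junctions clears the coverage-100 training tier); protein intron hints at
  0.6, start/stop hints at 0.5 each;
* markers: 500 markers × 119 progeny (an F1 population of the size the
  mapping application uses), 60% simplex × nulliplex, 2% missing calls,
  10% of simplex markers distorted to presence probability 0.75;
  non-simplex markers are duplex-maternal (presence 5/6 under random
  chromatid pairing) or simplex-paternal (presence 1/2).

Two constructions make the fixtures *provably* analyzable:

* **CDS = lORF by construction.** UTRs and all non-coding transcript
  sequence are sampled from an adenine-free alphabet (C/G/T). Since ATG and
  all three stop codons contain A, every start and stop in a spliced
  isoform lies inside the planted CDS, so the planted CDS is the unique
  longest ORF. The extra-intron cut of 20 bp (not a codon multiple) makes
  it impossible for any ORF of the altered isoform to reproduce the CDS
  boundaries.
* **Analytic expectations.** With independent emissions, the expected count
  of each full-support category is a sum of per-gene Bernoulli
  probabilities: `P(full Iso-Seq) = p_iso (1 - p_extra)`;
  `P(full RNA-Seq) = p_rna^k` and `P(full protein) = p_prot^k` for a gene
  with k introns; `P(full protein | single-exon) = p_start * p_stop`. The
  generator writes these expectations (with binomial standard deviations)
  next to the data, and the validation suite checks observed counts within
  3 SD. Expectations are defined at *emission* level — classify against the
  raw emitted hint sets, before coverage filtering.

What the generator does **not** emulate — and therefore what passing tests
do and do not show: no alignment error or spurious mappings (identity and
coverage are attributes, not measured quantities), no alternative isoforms
in the truth set, no fragmented or chimeric isoforms, no hint noise at
wrong coordinates, a single chromosome, uniform base composition outside
the A-free regions, and no linkage structure between markers (each marker
segregates independently; building an actual map is out of scope). Passing
the suite demonstrates that the *rules* are implemented exactly as stated,
not that the thresholds are optimal for any particular genome.

# Degenerate inputs and numerical conventions

* Empty inputs: empty isoform sets, hint sets and marker tables flow
  through every stage (the pipeline completes with all Iso-Seq categories
  `none` when no isoforms are supplied); `summarize_annotation(list())`
  returns the zero sentinel.
* Hard errors, not silent repair: duplicate feature IDs, unresolvable
  `Parent` references, CDS outside exons, ORFs past the transcript end,
  out-of-bounds mask intervals, overlapping seed inputs, transcripts
  without CDS in the classifier, and thresholds below their domain.
* All thresholds are inclusive/strict exactly as documented, and each
  boundary (0.95/0.90 identity/coverage, 300 nt lORF, 10,000 nt intron,
  coverage 3/100, 50 nt seed margin, 5% missingness) has an exact test on
  both sides where both sides are defined.
* Determinism: one integer seed drives each generator call; the same
  configuration and seed reproduce all outputs byte-identically, and the
  pipeline manifest counts are reproducible run to run.

# Interface note

The package's stages are exposed as R functions plus `run_pipeline()`,
which wires them in order over files and writes a JSON manifest of
per-stage record counts; stage outputs are plain standard-format files so
that any stage can be replaced by real external-tool output. No shell
wrapper is shipped: R users drive the pipeline from R, and
`scripts/acceptance.R` shows the end-to-end invocation.

# Known limitations

* GFF3 input is limited to the gene/mRNA/exon/CDS hierarchy (plus
  `transcript` as an mRNA synonym); GTF dialects are out of scope.
* Alignments must arrive pre-projected (GFF3/BED12); SAM/BAM is not read.
* The classifier treats evidence classes independently; it does not model
  correlated evidence or partial intron-chain orderings beyond the
  full/partial/none levels.
* The marker filter consumes integer dosages; calling dosages from read
  depths is upstream of this package.
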