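---
title: "Methods: characterizing TE-derived regulatory elements with tecre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing TE-derived regulatory elements with tecre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tecre` packages the statistical procedures used to ask whether a
transposable-element (TE) family supplies regulatory DNA to a gene
array: enhancer/promoter-like enrichment across many ChIP-seq peak
sets, donation of a polyadenylation signal to 3' isoforms, the protein
consequences of the resulting isoform switch, combined
transcription-factor dosage effects on a target gene, and copy-number
burden at the locus. This vignette records the models, the parameters
that matter, and the design choices made where the design was genuinely
open.

## Coordinate model

All internal coordinates are 0-based half-open, the BED convention.
GTF and RepeatMasker `.out` (both 1-based inclusive) are converted on
read; writers emit BED unchanged. A single convention prevents
off-by-one drift between stages. Two deliberate conventions are worth
stating:

* `closest_distance()` assigns distance 0 to an anchor that lies inside
  *or abuts* the half-open interval (anchor `pos == end` is distance
  0). Some bedtools builds report 1 for abutting features; a fixed,
  testable rule was preferred. Ties between equidistant anchors go to
  the smaller coordinate, then the lexicographically smaller id.
* `overlap_join(a, b, min_fraction_of_a)` measures fractional overlap
  against the **first** argument. The 70%-of-peak rule used for
  stringent peak-in-TE testing is therefore `overlap_join(peaks, te,
  0.7)`; whether such a rule should be fraction-of-peak, fraction-of-TE
  or reciprocal is not settled usage, so the direction is an explicit
  parameter (`fraction_of` in `family_enrichment()`), with
  fraction-of-peak the default. `min_fraction_of_a = 0` is exactly
  any-overlap mode.

Queries on chromosomes absent from the anchor set are skipped with a
warning rather than erroring: repeat annotations routinely include
scaffolds that gene models lack.

## Family enrichment (peaks × repeat families)

For one peak dataset and each repeat family with at least
`min_instances` copies (default 10), the 2×2 table is

|            | overlapped by ≥1 qualifying peak | not |
|------------|----------------------------------|-----|
| family     | a                                | b   |
| background | c                                | d   |

where the background is *all other TE instances*, and the one-sided
Fisher's exact p tests over-representation. Counting TE instances
rather than peaks keeps families of wildly different sizes comparable.
BH adjustment is applied within the dataset across tested families.
The choice of Fisher's exact against an instance background is the
classical enrichment statistic for this design and is exactly testable
(the 2/2-vs-0/2 case has p = 1/6 by hypergeometric enumeration); an
empirical peak-shuffling background could be substituted but offers no
exactness.

The per-dataset tables assemble into a families × datasets matrix of
`-log10(adj p)`, capped at 300 to avoid infinities in downstream
clustering; untested or absent cells are 0. A family enters the
"significant" subset iff `adj p < alpha` in at least one dataset.
The cutoff defaults to BH 0.05 — a conventional choice, exposed as
`alpha` — since no canonical value exists for this rule.

Downstream operations are deliberately thin, reproducible layers:
k-means on the matrix rows (fixed seed, 10 restarts, labels renumbered
by descending cluster mean so labellings are comparable across runs;
`k` equal to the row count degenerates to one row per cluster),
Spearman correlation of dataset columns (tie-average ranks; a constant
column yields NA rather than an error), set algebra on significance
flags for two-factor co-occupancy, and rule-based activity labels with
precedence promoter > enhancer > repressed:

* promoter-like: significant for a promoter mark (H3K4me3) **and** the
  designated pioneer factor (TFAP2C by default);
* enhancer-like: an enhancer mark (H3K4me1/H3K27ac) **and** a cofactor
  (P300/MED1);
* repressed: H3K9me3 and neither of the above.

The dataset-role mapping is configuration
(`default_activity_rules()`), not hard-coded biology. Shortlisting
requires significance in *every* required dataset (typically two TFs
plus the pioneer), filters by allowed labels, and ranks by summed
`-log10(adj p)` with lexicographic tie-breaks.

## Proximity and CNV burden

`gene_end_proximity()` measures each TE copy's distance to the nearest
strand-aware gene 3' terminus (max coordinate on `+`, min on `-`) and
flags copies within 50 bp by default — the criterion for "this family
sits at gene ends". Output is sorted ascending by distance, the
natural ordering for locus-specificity plots. A TSS mode exists for
completeness.

CNV/SV records are filtered to ≥ 1000 bp and any overlap with the
locus window (the PSG-array default window
chr19:43,203,459–43,802,656 ships as `psg_locus_window()`, but every
analysis takes the window as a parameter). Loss:gain ratios are
reduced to unit form at one decimal (`12:1`, `2.8:1`, `1:1.9`); ratios
count events, not samples — the alternative reading — because
event counts are what a per-population table of CNV calls contains.
The burden test compares per-sample gain (duplication) counts — or
summed gained bp — between two groups with the Mann–Whitney U test.
For combined n ≤ 16 the two-sided p is exact by full enumeration of
group labelings (handles ties, unlike the textbook exact formula);
above that, the normal approximation with tie correction. Samples with
zero events are genuine zeros, which is why the test takes the full
sample roster rather than only samples that had events.

## PolyA windows, consensus mapping, and the paired test

A polyA window is the 200 bp centred on a transcript's polyadenylation
site, clipped at chromosome ends, reverse-complemented to sense for
minus-strand transcripts. Window-to-consensus alignment is global with
free end gaps, scored +2/−2 with gap open −5 and extend −1 — a
conventional nucleotide scheme; the substitution-only simulated
fixtures make the truth alignment insensitive to these values. The
mapping keeps matched/mismatched columns only, so it is strictly
increasing in both coordinates, and positions (e.g. a hexamer) lift
through it with `lift_to_consensus()`. One numerical caveat: with free
end gaps, a noisy window *end* can align a few columns off the truth
diagonal when terminal mismatches make a shifted end score higher;
interior positions, including any planted signal, are unaffected.
Alignments below 50% identity are flagged low-confidence rather than
rejected.

Hexamer scanning reports **all** occurrences, overlapping included,
of each motif; the motif set defaults to the single canonical AAUAAA
(scanned as AATAAA on DNA), with the 12 common PAS variants available
as an extended set reported per motif.

The co-occurrence statistic pairs, per instance, the motif count in
the window with the motif count in the consensus region covered by its
alignment, and applies a paired t-test (`t = mean(d)/(sd(d)/sqrt(n))`,
n−1 denominator, df n−1). Counts rather than presence flags are the
paired value: with 200-nt windows they are nearly always 0/1, and
counts keep the statistic well defined; presence mode is available.
All-zero differences return p = 1 with a warning instead of NaN.

Isoform grouping intersects each transcript's terminal exon with one
family's copies, ranked proximal→distal along the gene's transcription
direction; `no-TE` marks transcripts whose terminal exon misses every
copy. Group label strings are configuration (defaults `TE-proximal`,
`TE-distal`), since published group letterings for such isoform
families are not consistent enough to hard-code. A terminal exon over
two copies takes the larger overlap, with a message.

## Hydropathy and isoform topology

Profiles are sliding-window means of per-residue hydrophobicity,
Kyte–Doolittle by default (Hopp–Woods negated also ships; both
orientated so larger = more hydrophobic; `X` scores 0). Defaults —
window 19, threshold 1.6, minimum span 15 — are the classical settings
for transmembrane-segment calling, and all four knobs are arguments.
A qualifying run of window centers is mapped back to the residue span
its windows cover; overlapping spans merge, so output segments are
disjoint and sorted. The C-terminal membrane-anchor flag asks whether
a called segment ends within the final 40 residues.
`compare_isoform_topology()` refuses sequence pairs sharing a common
prefix shorter than half the shorter sequence — such pairs are not
isoforms of one locus. Deep-learning topology predictors are out of
scope; this module is the classical hydropathy analysis only.

## Dosage statistics

Z-standardization is `(x − mean)/sd` with the n−1 denominator (the
conventional sample sd; the choice is documented because "sample sd"
alone is ambiguous). The combined dosage score per sample is
`Z(TF1) + Z(TF2)` — standardizing first puts TFs expressed at very
different absolute levels on a common scale — and is Pearson-correlated
with the target's log2 expression; p-values use the exact t transform
`t = r·sqrt((n−2)/(1−r²))`. Raw TPM-like input is transformed as
`log2(x + offset)` with offset 1 by default (0 recovers an exact
latent log2 scale). Fisher's combined test is `X = −2Σ ln p` against
chi-square with 2k df. `|r| = 1` reports p = 0 rather than an
underflowed number.

## What the generators emulate — and what they do not

Every generator is a pure function of its explicit seed;
`child_seed()` expands one global seed into per-stage seeds by fixed
offsets. The generators encode the structural assumptions each
analysis makes:

* `simulate_te_annotation()`: non-overlapping instances of ~30
  families (fixed width per family, drawn from 200–400 bp; 10%
  divergence from a per-family random consensus) on a ~10 Mb genome.
* `simulate_peakset()`: uniform background peak placement; planted
  families get their footprint's placement density multiplied by a
  fold ≥ 1, so the overlapped-instance fraction rises monotonically
  with the fold. Peak widths are normal around 400 bp (floored at
  50 bp).
* `simulate_polya_instances()`: substitution-only divergence (8% in
  the study design) of 200-bp windows taken at random offsets of a
  motif-scrubbed 300-bp consensus, with the exact AATAAA written at a
  fixed consensus position in planted instances; accidental motifs are
  scrubbed so unplanted windows are genuinely motif-free. The
  no-indel model gives an unambiguous truth alignment — the clean
  oracle comes first; indel stress tests would need a separate truth
  representation. An `exact` option plants a fixed count (the
  12-of-14 design) instead of Bernoulli draws.
* `simulate_expression()`: TF latent values i.i.d. standard normal
  across samples; target `a·Z(TF1) + b·Z(TF2) + N(0, σ)`; raw values
  `2^latent` mimic TPM. At a = b = 1, σ = 1 the population combined
  correlation is `sqrt(2/3) ≈ 0.816`, giving a closed-form recovery
  check at the study's n = 18 scale.
* `simulate_cnv_table()`: per-sample Poisson event counts with
  group-specific loss/gain rates, uniform sizes, all events inside the
  locus window; a 21-vs-76-sample design with a 3× gain-rate
  difference mirrors a two-cohort duplication-burden comparison.
* `simulate_isoform_pair()`: a 120-residue hydrophilic core shared by
  both isoforms plus a 25-residue poly-leucine tail on the membrane
  form.

None of these emulate real chromatin's spatial autocorrelation, real
repeat-family length/divergence distributions, indels, read-level
noise, or covariate structure in expression data. Tests passing on
these fixtures demonstrate that the statistics recover exactly the
structure they assume — planted enrichment, planted motifs, planted
dosage effects — not that the assumptions hold in any given real
dataset.

## Problem sizes and runtime choices

The test suite exercises the full enrichment chain at 30 families ×
100 instances on a 10 Mb two-chromosome genome with 2000-peak datasets
over 20 seeds, the paired co-occurrence design at 14 windows over 20
seeds, dosage recovery over 200 seeds at n = 18, and CNV burden at
21 + 76 samples over 20 seeds — sizes chosen so the planted effects
sit at realistic desk-scale power while the whole suite stays fast
enough to run routinely.

## Known limitations

* Peak calling, read alignment, differential expression, variant
  calling and assembly liftover are out of scope; peaks, gene models,
  expression matrices and CNV tables are inputs.
* The enrichment background is all-other-TE-instances; a
  genomic-shuffle background would answer a subtly different question
  (enrichment relative to the whole genome rather than to the repeat
  complement).
* The consensus aligner reports one optimal alignment; co-optimal
  alignments (possible at high divergence) are resolved by the
  aligner's internal tie-breaking.
* Bit scores are reported without E-values: the comparisons the module
  supports are between candidate targets of one short oligo, where the
  search-space term cancels.
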