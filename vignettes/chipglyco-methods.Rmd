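---
title: "Methods: promoter peak annotation, motif matching and the lectin-array protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter peak annotation, motif matching and the lectin-array protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipglyco)
```

chipglyco implements the analysis chain by which a transcription
factor's promoter binding is established from ChIP peaks and traced to
a downstream glycan phenotype: region classification of peaks with
dual-control enrichment filtering, degenerate consensus-motif matching
in candidate promoter fragments, the lectin-microarray normalization
and differential protocol, and the small quantification formulas
(2^−ΔΔCt, ChIP-qPCR fold over IgG, dual-luciferase normalization) used
to validate individual targets. This vignette documents the models,
the tunable parameters, the numerical conventions and the design
decisions, and states precisely what the synthetic-data generators do
and do not emulate.

## Coordinates

All tibbles in and out of the package use **1-based fully-closed**
coordinates, the convention of R's genomic containers
(IRanges/GenomicRanges) that back the interval logic internally.
File-format converters live at the boundary: BED6 I/O converts to and
from 0-based half-open (delegated to rtracklayer), and the compact
`assembly:chrom:start:end:strand` specifier is parsed as 1-based
closed, so `GRCh38:11:94541840:94543879:1` spans
`94543879 − 94541840 + 1 = 2040` bp. An interval with `start == end`
is one base; `start > end` is a parse error.

## Region classification

Given stranded gene models, five classes partition the genome:

* `UP2K` — the `flank` (default 2000) bp **strictly upstream** of the
  TSS on the gene's strand. For a `+` gene with TSS *t* this is
  `[t − 2000, t − 1]`; for a `−` gene, `[t + 1, t + 2000]`. The TSS
  itself belongs to the gene body.
* `DOWN2K` — symmetric, strictly downstream of the transcription end
  site.
* `EXON` / `INTRON` — from the exon structure inside the gene body
  (introns are the body's complement of the exons).
* `INTERGENIC` — everything else.

A **peak is classified by its midpoint**, `floor((start + end) / 2)`.
The classification rule had to be chosen (an any-overlap rule is the
obvious alternative): the midpoint rule is deterministic, assigns each
peak exactly one class, and respects the genome partition, so class
counts over a peak set sum to the set size. When the midpoint lies in
regions of more than one gene, the priority
`UP2K > DOWN2K > EXON > INTRON > INTERGENIC` resolves the tie —
promoter assignment wins because promoter binding is the biological
question the classification serves. Two properties are enforced by
tests: every position maps to exactly one class (checked against an
exhaustive per-position oracle over random layouts), and mirroring a
gene's coordinates and strand about a point maps its `UP2K` onto the
mirrored `DOWN2K`.

## Fold enrichment, filtering and intersection

Fold enrichment of a peak against a control is the depth-normalized
count ratio with a pseudocount `p` (default 1) added to **both**
counts: `((t + p)/D_t) / ((c + p)/D_c)`. The pseudocount keeps the
ratio finite for zero control counts with minimal bias; `p = 0`
recovers the plain ratio.

The filter keeps peaks with fold **strictly greater** than the
threshold (default 2). The source protocol wording mixes "over
2-fold" and "> 2-fold"; strict inequality implements both readings,
and `strict = FALSE` switches to `>=` where a closed threshold is
wanted. Peaks passing in both contrasts are intersected by genomic
overlap: two peaks are common when they share a chromosome and
overlap by at least `min_overlap` (default 1) bp. Pairing is 1:1 and
greedy — largest overlap first, ties broken by leftmost start in each
list — which makes the result deterministic and independent of input
row order after the canonical sort. Raising the threshold can only
shrink the filtered and common sets (tested as a property).

## Degenerate motif matching

A pattern is an ordered list of per-position base sets, written in
bracket notation: a literal base, a bracket group (`[AT]`), or the
wildcard `x` (any base). Parsing is case-insensitive and rejects
unbalanced brackets, empty groups and foreign characters with the
0-based offset of the problem. Position sets preserve the order in
which bases are written, so the strict reverse complement of
`CCTC[AT][GC]CC[TA]CC[CT]` renders as `[GA]GG[AT]GG[CG][TA]GAGG`
(complement each set in place, then reverse). Reverse complementation
is an involution, tested over 1000 random patterns.

Scanning tests every window of pattern length on the forward strand,
and, with `both_strands = TRUE`, the reverse-complement pattern as
well; minus-strand hits are reported at their forward-strand offset
(0-based, following the common match-report convention). `N` in a
target satisfies only wildcard positions — the conservative choice for
ambiguous bases. A pattern longer than its target yields an empty
result rather than an error. The scanner is validated against an
independent oracle (Biostrings IUPAC ambiguity matching) on random
sequences.

`classify_sequence()` grades a target `EXACT` when any pattern matches
full-length on either strand; otherwise `PARTIAL` when some alignment
of a pattern (overhangs allowed) has a contiguous run of at least
`partial_min` matching pattern positions; otherwise `NONE`.
`partial_min` defaults to 7 because the canonical partial-match
example in this workflow is a 7-mer (`GCCTCCA`) agreeing with 7
consecutive positions of a 12-position consensus. The best match is
reported with a deterministic tie-break: longest run, then smallest
offset, then `+` strand.

Only the first consensus motif of the original six-motif set was ever
published as text, together with a looser printed form of its reverse
complement (`[GA][GA][GC][AT]GG[CG]xxAGG`, wider than the strict
algebraic reverse complement). The package ships both as
configuration (`consensus_motifs()`) and refuses to invent the
unpublished motifs 2–6; they can be appended via the `extra` argument
when a user has them.

## The lectin-array protocol

The pipeline follows the published protocol stage by stage:

1. **Background subtraction.** The mean of the spot-local background
   readings over a scope is subtracted from every foreground in that
   scope. The protocol does not state the scope; per **block** is the
   default here because the normalization that follows is per block,
   and a per-slide option is provided. Corrected values may be
   negative at this stage.
2. **Effectiveness filter.** The removal rule "values less than the
   average background ± 2 SD" cannot define a single threshold as
   written ("±" gives two); it is implemented as the conventional
   microarray validity cut — a spot is effective iff its raw
   foreground ≥ mean background + `k`·SD (default `k = 2`). Raising
   `k` never increases the effective count. A scope with a single
   background reading gets SD 0 with a warning.
3. **Per-block global-median normalization.** Within a block, each
   lectin's median over effective spots is divided by the sum of those
   medians: the normalized fluorescence intensity (NFI). NFIs sum to
   1 over a block's lectins and are invariant to scaling all of a
   block's intensities by a constant. A block with no effective spots
   is dropped with a message.
4. **Aggregation.** Per lectin and condition, the mean and SD of the
   block NFIs (nine blocks at the default 3 slides × 3 blocks), with
   the contributing block count recorded.
5. **Differential calling.** Fold change = treatment mean NFI /
   control mean NFI; significance from a two-sided **paired** t-test
   on block NFIs, paired by (slide, block) across conditions —
   block-level pairing (n = 9) rather than slide-level (n = 3) because
   the protocol aggregates nine repeated blocks with a consistent
   layout. A call requires both the fold criterion and p < 0.05.
   Both published threshold tiers are first-class outputs: `STRICT`
   (≥ 2.0 / ≤ 0.5, inclusive) and `REPORTED` (> 1.5 / < 0.67,
   exclusive), since both appear in the source workflow. No
   multiple-testing correction is applied by default, matching the
   protocol; Benjamini–Hochberg is available via `p_adjust = "BH"`.
   Degenerate inputs are handled deterministically: zero-variance
   paired differences give p = 1 when the difference is zero and p = 0
   otherwise, and a zero control mean defers the call (fold
   undefined).

Note that global-median normalization is **compositional**: scaling
one lectin's signal changes every NFI in the block. A raw fold change
*f* on lectin *l* therefore appears after normalization as
*f·Σs / Σ(f s)* where *s* are the base intensities — slightly
attenuated toward 1 when the changed lectins are a small share of the
block total. The simulator's truth table records this expected
post-normalization fold, and exactness tests assert against it.

## Quantification formulas

* **2^−ΔΔCt** — replicates are averaged on the Ct scale before
  differencing (the conventional order of operations; the source
  protocol does not state its order): ΔCt = mean Ct(target) − mean
  Ct(reference) per condition, ΔΔCt = ΔCt(treatment) − ΔCt(control),
  ratio = 2^−ΔΔCt. Identities tested: self-comparison gives 1, and
  the ratio is invariant to adding a constant to all four mean Cts.
* **ChIP-qPCR fold over IgG** — `2^(mean Ct_IgG − mean Ct_IP)`. With
  an input-chromatin Ct each arm is first expressed as percent input,
  `2^(Ct_input_adjusted − Ct_arm)`; with a shared input the two routes
  are algebraically identical (verified numerically), so the choice —
  unstated in the source protocol — does not affect results.
* **Dual luciferase** — firefly and Renilla are each scaled to
  activity per 1000 cells before the firefly/Renilla ratio, then
  expressed relative to the designated control construct. The
  per-1000-cells scaling cancels in the ratio whenever both readings
  come from the same well; it is kept for fidelity to the protocol
  and matters only if the readings were acquired at different cell
  counts.

## The synthetic-data generators

The generators produce every input with known planted truth; each has
its own RNG stream derived from `(seed, generator tag)` so adding one
call to a script does not perturb the others, and identical
parameters plus seed give byte-identical output.

* `sim_gene_models()` places non-overlapping genes with all pairwise
  gaps ≥ `min_gap` (default 4000 bp, so 2-kb flanks of neighbours can
  never overlap) and a 2.5-kb margin from chromosome ends; gene
  bodies are 2–10 kb with 1–5 exons. Requests exceeding the genome's
  capacity raise an explicit error.
* `sim_peak_experiment()` plants signal peaks wholly inside region
  instances of their assigned class (one instance per peak, so planted
  peaks never overlap each other and midpoint classification recovers
  the planted class by construction), with signal folds in
  [2.5, 8] — safely above the 2-fold cut — and optional noise peaks
  with folds in [0.2, 1.8], safely below it. `frac_common` of each
  class's peaks are shared intervals between the two contrast lists.
  `sim_chip_study()` is the promoter-focused wrapper that plants
  prescribed M1/M2/common list sizes (defaults 212/162/57) in the
  Up2k regions of distinct genes.
* `sim_motif_sequences()` writes one sampled realization of a motif
  into each sequence at a random offset and strand.
* `sim_lectin_dataset()` emulates 37 lectins × 2 conditions ×
  3 slides × 3 blocks × 3 spots: spot signal is base intensity ×
  planted fold × multiplicative Gaussian noise (CV-parameterized,
  default 5 %, a typical fluorescence-array spot CV), plus an
  additive background around `bg_mean = 100` ± `bg_sd = 10` a.u.
  (roughly 2 % of the 5000 a.u. default signal, a clean-slide
  regime). Each foreground carries its own background draw, so "zero
  noise" means `noise_cv = 0` **and** `bg_sd = 0`; in that limit the
  whole pipeline is exact.
* `sim_ct_dataset()` encodes a planted ratio *r* as a target-gene Ct
  shift of −log2(*r*) cycles against a reference gene at Ct ≈ 20,
  with Gaussian replicate noise in cycles.

What the simulations do **not** emulate: read-level ChIP coverage,
peak-calling uncertainty or ragged peak boundaries (simulation starts
at the interval/count level, as the pipeline does); spatial artefacts,
saturation or print-tip effects on arrays; PCR efficiency differences
(the ΔΔCt model assumes 100 % efficiency, and the Pfaffl correction
is out of scope). Passing tests therefore demonstrate correctness of
the computational chain under its stated model, not robustness to
those real-data pathologies.

## Problem sizes and numerical tolerances

The test suite runs the classification oracle on 10-gene layouts with
5,000–10,000 random positions, the scan oracle on 200 random 500-bp
sequences, block-normalization checks on 100 random blocks,
reverse-complement involution on 1000 random patterns, and the
differential-call accuracy tally on 100 simulated arrays at 5 % spot
noise (the planted UEA-I 0.4 / WFA 2.5 design) — sizes chosen so the
suite exercises each property densely while completing in a few
minutes on one core. Exactness assertions use a tolerance of 1e−12;
Monte-Carlo recovery of a planted ratio of 4.0 from noisy Ct tables is
required within 5 % of truth over 200 replicate datasets.

## Known limitations

* The five-class genome partition ignores overlapping gene models on
  opposite strands only insofar as the priority rule arbitrates them;
  a position in one gene's intron and another's exon is EXON by
  priority, which is a convention, not biology.
* The greedy overlap pairing is 1:1; a peak straddling two peaks of
  the other contrast contributes a single pair (the larger overlap).
* Partial-match grading reports contiguous agreement only; a gapped
  alignment model is deliberately out of scope.
* The lectin pipeline assumes a consistent block layout across
  conditions (required for paired testing); experiments with missing
  blocks lose those pairs.
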