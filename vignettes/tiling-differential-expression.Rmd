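---
title: "Strand-specific differential expression from tiling microarrays: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific differential expression from tiling microarrays: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilearray)
```

This vignette is the package's own account of the methods it implements:
the probe-filtering model behind custom chip description files (CDFs),
the robust multiarray average (RMA) expression measure, the segmentation
algorithm for differentially transcribed regions (dTRs), the synthetic
data model used to validate everything, and the design decisions taken
where the methods left genuine freedom.

## Coordinates

Every interval inside the package is **0-based, half-open** `[start,
end)`. The only places where any other convention appears are the
readers and writers: GFF3 input/output converts to and from 1-based
inclusive coordinates, bedGraph output is natively 0-based half-open.
Holding one convention internally removes the usual off-by-one drift
between containment tests, gap arithmetic and region lengths.

## Custom CDF construction

A CDF maps physical array positions to named probesets, the unit of
expression summarization. Vendor CDFs reflect the annotation available
when an array was designed; `build_cdf()` rebuilds that mapping from
scratch against any genome and annotation, in five steps.

1. **Sequence deduplication.** Arrays may carry several probes with the
   same 25-mer. Exactly one probe per distinct sequence is retained —
   the first in `(y, x)` array order, a deterministic choice the method
   descriptions leave open.
2. **Exact genome mapping.** Each probe is matched exactly against both
   strands of the genome with a Karp–Rabin rolling-hash search adapted
   to the four-letter DNA alphabet: bases encode as 0–3, a window's
   base-4 polynomial hash modulo the Mersenne prime $2^{61}-1$ is
   updated in O(1) per shift, one hash table per distinct pattern
   length, and every hash hit is verified by direct byte comparison, so
   collisions cannot corrupt results. A reverse-strand match means the
   probe sequence equals the reverse complement of the genomic window.
   Windows containing `N` never match, and matches starting inside a
   masked region (the mechanism for excluding repeated loci such as
   rDNA arrays from the uniqueness assessment) are discarded.
3. **Uniqueness.** Probes with two or more matches — counted over both
   strands — are discarded. An even-length palindromic probe matching
   one locus on both strands therefore counts as multi-mapping; for
   strand-specific analysis, a probe whose strand cannot be determined
   is not usable, so discarding is the conservative choice (25-mers,
   being odd, can never be palindromic; the case matters only for
   unusual designs).
4. **Annotation intersection.** A probe is assigned to a gene iff its
   genomic interval is fully contained in a single exon of that gene
   and (by default) its match strand equals the gene strand. Full
   containment is the reading consistent with exact genomic matching: a
   probe spanning a splice junction matches neither exon as a genomic
   interval. Probes assignable to two overlapping genes are dropped —
   probesets must partition probes, or summaries would share signal.
   Both rules are parameters (`containment_rule`, `strand_rule`);
   the strand rule is `"ignore"` for amplicon references, where the
   PCR product is double-stranded.
5. **Probeset assembly.** One probeset per gene, dropping genes with
   fewer than `min_probes_per_set = 4` probes, the smallest probeset
   size reported to give statistically reliable summaries.

The per-step counts (`total`, `unique_seq`, `in_genome`,
`unique_in_genome`, `intragenic`, `n_probesets`) are recorded and are
monotone non-increasing by construction; the test suite verifies that
each decrement equals the planted anomaly count on synthetic designs.

`build_cdf_from_amplicons()` implements the amplicon-reference variant:
each amplicon is located in the genome by the same exact search,
amplicons absent or repeated are skipped with a warning, and the located
intervals act as single-exon pseudo-features for steps 4–5.

The probe map is written as a documented flat TSV (`probeset_id,
probe_id, x, y, chrom, start, end, strand`) rather than a binary vendor
CDF: the summarization code in this package consumes it directly, and a
text dialect keeps fixtures and diffs readable. The `end` column is
carried so that write → read is the identity even for mixed-length
probes.

## RMA expression measure

Expression follows the standard RMA order: background adjustment →
quantile normalization → log2 → median-polish summarization.

**Background adjustment** (`background_adjust()`) uses the convolution
model: observed intensity $O = S + B$ with signal
$S \sim \mathrm{Exp}(\alpha)$ and background $B \sim N(\mu, \sigma^2)$.
Each intensity is replaced by the posterior mean
$E[S \mid O]$, a strictly positive, monotone transformation.
The three parameters are estimated per array by maximum likelihood on
the closed-form convolution density (initialized from the density mode,
lower-tail spread and mean exceedance). The customary mode-based moment
estimator was measured to misestimate the signal mean by roughly 17% on
simulated exponential-plus-normal mixtures — the density mode of the
convolution sits well to the right of the background mean — while the
MLE recovers the planted signal mean to within 1%; the test suite
asserts recovery within 10% at $n = 50{,}000$. Degenerate (constant)
arrays pass through unchanged. Background adjustment is on by default
for gene-level quantification and is *not* applied to the segmentation
input, which is defined on quantile-normalized signal only (see below);
the `background` flag of `rma()` exposes the choice.

**Quantile normalization** (`quantile_normalize()`) forces every array
to the mean of the order statistics, ties averaged (delegated to
`limma::normalizeQuantiles`). It is idempotent, and two hand-checkable
facts pin the contract: columns `(1,2,3)` and `(4,5,6)` both become
`(2.5, 3.5, 4.5)`, and all sorted columns are identical afterwards.

**Median polish** (`median_polish()`) alternates row and column median
sweeps on the log2 probes-by-arrays matrix until the largest absolute
sweep adjustment falls below `eps = 0.01` or `maxiter = 10` iterations —
standard RMA practice; both are configurable. The expression value of a
probeset on an array is the overall effect plus that array's column
effect. The implementation is checked against an independently coded
sweep oracle and against `stats::medpolish` on additive matrices. (The
package carries its own implementation because its convergence contract
— maximum absolute sweep change — differs from `stats::medpolish`'s
residual-sum criterion.)

**Differential expression** (`differential_expression()`) is
`log2_ratio = mean(treated) − mean(control)` over replicate arrays, with
a two-sided Welch t-test p-value on the per-array expression values.
How the reference analyses computed their p-values is not documented;
the Welch test on summarized values is the simplest defensible default
and is reported as such (a moderated-variance test would slot in at the
same interface). With a single replicate per condition the ratio is
still defined but the p-value is reported missing. Raw p-values are
reported without multiple-testing adjustment, matching the reference
output format.

## dTR segmentation

The segmentation input is the **probe-level differential track**: for
every uniquely mapping probe, `log2_diff = mean log2(treated) − mean
log2(control)` on the quantile-normalized matrix, placed at the probe's
genomic position on its match strand. Each (chromosome, strand) track
is segmented separately for up- and down-regulation:

1. select probes with `log2_diff > 0.8` (up) or `< −0.8` (down);
2. cluster consecutive selected probes whose gap (next start − previous
   end, half-open arithmetic) is **less than 60 nt** — about three
   tiling probes at 20–25 nt spacing, so a single noisy probe cannot
   split a region;
3. bound each region by its first member's start and last member's end;
   keep regions **longer than 180 nt** whose members' mean |log2
   difference| exceeds 0.8;
4. fuse surviving regions whose gap is **shorter than 120 nt**,
   iterating to a fixed point; fused regions inherit the union of
   members and their mean is recomputed.

All four comparisons are strict, as printed in the source descriptions.
Two readings of the region-mean rule exist: the mean over the *selected*
member probes (an algorithm that only ever admits above-threshold probes
has no other members) or over *every* tiled probe inside the
boundaries. The first is the default; the second is available as
`mean_over = "spanned"`, where the rule genuinely bites (sub-threshold
interior probes can dilute the mean below 0.8 and reject the region).
Fused regions are not re-tested against the length rule — fusion can
only grow a region, so the test would be vacuous. Up- and down-regions
are never fused with each other and strands never mix.

Region identifiers follow `dTR` + chromosome index + strand code (0 =
forward, 1 = reverse) + a 4-digit per-(chromosome, strand) ordinal, e.g.
`dTR110092` for the 92nd region on the reverse strand of chromosome 1.
The true numbering scheme of the reference implementation is
undocumented; this scheme is format-compatible and deterministic.

`dtr_cdf()` turns the detected regions into probesets (every uniquely
mapping probe fully contained in the region on the region's strand, ≥ 4
probes), which flow through the same RMA machinery; a two-fold
(`|log2_ratio| > 1`) reporting filter is conventionally applied to the
quantified output, not inside segmentation. `classify_overlap()`
annotates each region against ORF spans geometrically (strand-agnostic,
since antisense overlap is exactly what one wants to see): `> g <` ORF
inside the region, `< g >` region inside the ORF, `<g` / `g>` one ORF
end inside; one record per overlapping gene.

The segmentation is validated against a brute-force enumeration oracle
on random tracks and against hand-worked examples (an 11-probe block
spanning 225 nt is kept; a 7-probe block spanning 145 nt fails the
length rule; two qualifying clusters 100 nt apart fuse; a uniform 0.5
track yields nothing). Raising the probe threshold could in principle
split a region into more regions than before, but with ~20 nt tiling a
split requires seven or more consecutive member probes to drop out —
the clustering and fusion gaps re-absorb anything smaller — so in
practice the dTR count is non-increasing in the threshold; the suite
checks this across random and planted fixtures.

## Synthetic data model

`simulation_spec()` fixes the study conditions; the defaults are the
reference desk-scale configuration used by the acceptance checks and
were chosen once to emulate a compact fungal-genome tiling study:

| parameter | default | rationale |
|---|---|---|
| chromosomes | 2 × 100 kb | large enough for ~3,400 intragenic probes, small enough for seconds-scale runs |
| genes | 60, single-exon, 500–2000 nt | ≥ 23 sense probes per gene at 20 nt tiling |
| DE genes | 10, \|log2 effect\| ∈ [1, 2], alternating sign | comfortably above the 0.8 detection threshold |
| planted transcripts | 5 intergenic (300–800 nt, effect ±1.5) + 1 antisense | the non-annotated and antisense cases the strand-specific protocol exists for |
| probes | 25-mers every 20 nt, both strands | ~3 probes per 60 nt clustering gap |
| replicates | 2 per condition | biological duplicates, the minimal replicated design |
| noise | log-normal, σ = 0.15 (log2) | replicate correlations ~0.98, on par with good array duplicates |

Intensities are built additively on the log2 scale: a per-feature
expression level (N(10, 0.5)) or background level (7) per probe, a
per-probe affinity offset (N(0, 0.3), constant across arrays — absorbed
by median polish), ± half the planted effect per condition so the
treated − control difference equals the effect exactly, and per-array
Gaussian noise. Only sense-strand probes of a feature carry its signal,
which is what makes the antisense test discriminating. Anomalies
(duplicate, multi-mapping, unmapped, intergenic probes) are planted on
gene-restricted designs (`tile = "genic"`) where each anomaly maps to
exactly one step-count decrement.

What the generator deliberately does **not** model: cross-hybridization,
probe GC/affinity bias correlated with sequence, saturation, spatial
array artifacts, and overlapping transcription on the same strand.
Passing tests therefore demonstrate the correctness of the bookkeeping,
the matcher, the normalization/summarization arithmetic and the
segmentation logic — not robustness to the full messiness of real
hybridizations. Conclusions about vendor data still require the usual
array QC.

## Numerical and degenerate-input choices

* Rolling-hash verification makes collision probability irrelevant to
  correctness (only to speed).
* `quantile_normalize()` is a no-op for a single array; `median_polish()`
  of a 1×1 matrix returns the value itself.
* Constant arrays skip background adjustment (no mixture is
  identifiable); the MLE falls back to its moment initializers if the
  optimizer fails.
* A t-test on numerically constant groups returns a missing p-value
  rather than an error.
* Ties in quantile normalization are averaged; equal-start bedGraph
  intervals are averaged and overlapping probe intervals truncated at
  the next start so exported tracks are disjoint and sorted.
* Empty inputs (no qualifying probes, no overlapping genes, genomes
  shorter than the pattern) return empty results, not errors; malformed
  files, out-of-bounds masks, unknown strands and non-positive
  intensities raise validation errors at the boundary.

## Problem sizes

The shipped checks run the matcher oracle on 100 random instances (≤ 50
kb genomes, ≤ 2,000 probes), the segmentation oracle on 100 random
tracks (≤ 200 probes), the end-to-end recovery on the default 2 × 100 kb
study (~20,000 probes, 4 arrays), and the determinism check on two full
command-line runs of a 2 × 30 kb study — sizes chosen so the whole suite
completes in a few minutes on one CPU while still exercising every code
path at realistic probe densities.

## Known limitations

* Exact matching only: no mismatch-tolerant mapping, by design.
* Binary vendor formats (CEL/CDF/BPMAP) are out of scope; inputs are
  the documented TSV/FASTA/GFF3 stand-ins.
* The Welch test with two replicates per condition has little power;
  ratios are the primary quantitative output, p-values are indicative.
* `dtr_cdf()` quantification inherits the ≥ 4-probe rule, so regions
  detected from 1–3 probes are reported by the segmenter but not
  quantified.
* The segmentation mean under the default `"selected"` reading can
  overstate the region mean when many interior probes sit just below
  threshold; the `"spanned"` reading is provided for sensitivity
  analysis.
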