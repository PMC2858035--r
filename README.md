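# tilearray

Strand-specific differential expression analysis for high-density tiling
microarrays.

## The problem

Expression microarrays (EMAs) carry a handful of probes per annotated open
reading frame and make probeset summarization straightforward; tiling
microarrays (TMAs) instead cover the whole genome at 20–35 nt resolution on
both DNA strands. That coverage is what makes TMAs attractive — any locus
can be interrogated, including loci with no annotation — but it means the
millions of probes are not pre-assigned to genes. `tilearray` closes that
gap for quantitative, strand-specific differential expression work:

1. **Custom CDF construction** (`build_cdf()`): a five-step filter turns a
   probe table, a genome and a GFF3 annotation into a chip description
   file (probe → probeset map):
   - *Step 1* — drop all but one probe per distinct 25-mer sequence;
   - *Step 2* — map every probe exactly to the genome on both strands
     with a Karp–Rabin rolling-hash search adapted to the four-letter
     alphabet (base-4 polynomial hash, every hash hit verified by direct
     comparison);
   - *Step 3* — discard probes matching more than one genomic position;
   - *Step 4* — keep probes fully contained in an annotated exon on the
     annotated strand;
   - *Step 5* — assemble one probeset per gene, dropping genes with fewer
     than 4 probes.
   A variant (`build_cdf_from_amplicons()`) uses PCR amplicon sequences as
   the reference instead of an annotation, for cross-platform comparisons.
2. **RMA differential expression** (`rma()`,
   `differential_expression()`): convolution background adjustment
   (observed = exponential signal + Gaussian noise, fitted by maximum
   likelihood), quantile normalization across arrays, log2 transform, and
   Tukey median-polish summarization per probeset; the per-probeset
   statistic is `log2_ratio = mean(treated) − mean(control)` with a Welch
   two-sided t-test p-value.
3. **dTR segmentation** (`build_diff_track()`, `segment_track()`):
   non-annotated differentially transcribed regions (dTRs) are detected
   per chromosome, strand and direction from the probe-level log2
   differential signal after quantile normalization: probes with
   |log2 difference| > 0.8 are selected, selected probes less than 60 nt
   apart are clustered, regions longer than 180 nt whose member mean
   exceeds 0.8 are kept, and surviving regions closer than 120 nt are
   fused. `dtr_cdf()` then builds a dTR probeset collection so the same
   RMA machinery quantifies each region, and `classify_overlap()` labels
   each dTR against annotated ORFs (`> g <` ORF inside dTR, `< g >` dTR
   inside ORF, `<g` / `g>` partial overlaps).
4. **Synthetic data** (`simulate_dataset()`): seeded generators for
   genomes, annotations, tiling probe designs and replicated two-condition
   intensity matrices with planted ground truth (differentially expressed
   genes, intergenic and antisense transcripts, duplicate / multi-mapping
   / unmapped probes), so the whole pipeline is testable offline.

Browser-style bedGraph tracks are exported with the conventional
1.75-fold display threshold (`export_tracks()`).

## Worked example

```r
library(tilearray)

spec <- simulation_spec(seed = 1)   # 2 x 100 kb, 60 genes, 10 DE, 6 planted transcripts
sim  <- simulate_dataset(spec)

cdf <- build_cdf(sim$probes, sim$genome, sim$features)
cdf
#> cdf_result:
#>   total              19996
#>   unique_seq         19996
#>   in_genome          19996
#>   unique_in_genome   19996
#>   intragenic         3372
#>   n_probesets        60

expr <- rma(cdf$probesets, sim$intensities)
de   <- differential_expression(expr, sim$design)
head(de[order(de$p_value), ], 3)
# probesets with |log2_ratio| > 0.8 are the recovered DE genes (10/10 here)

norm  <- quantile_normalize(sim$intensities)
um    <- unique_matches(classify_matches(
           karp_rabin_search(dedupe_probes(sim$probes), sim$genome),
           dedupe_probes(sim$probes)))
track <- build_diff_track(norm, um, sim$design)
dtrs  <- name_dtrs(segment_track(track), names(sim$genome$sequences))
nrow(dtrs)
#> [1] 16
```

The 16 dTRs are the 10 differentially expressed genes plus the 6 planted
non-annotated transcripts; `classify_overlap(dtrs, sim$features)` labels
the gene-overlapping ones `< gene >` and leaves the intergenic ones
unlabelled. The interval columns of every table are 0-based half-open;
conversion to 1-based GFF3 happens only in the readers/writers.

A command-line wrapper over the same functions ships at
`inst/cli/tilearray.R`:

```sh
Rscript inst/cli/tilearray.R simulate --outdir sim --seed 1
Rscript inst/cli/tilearray.R build-cdf --probes sim/probes.tsv \
    --genome sim/genome.fasta --annotation sim/annotation.gff3 \
    --out probe-map.tsv --counts counts.tsv
Rscript inst/cli/tilearray.R rma --probe-map probe-map.tsv \
    --intensities sim/intensities.tsv --design sim/design.tsv --out expr.tsv
Rscript inst/cli/tilearray.R diffexp --expr expr.tsv --design sim/design.tsv --out de.tsv
Rscript inst/cli/tilearray.R segment --probes sim/probes.tsv --genome sim/genome.fasta \
    --intensities sim/intensities.tsv --design sim/design.tsv \
    --annotation sim/annotation.gff3 --out dtrs.tsv
```

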