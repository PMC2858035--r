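#' Parameters of the CDF-building pipeline
#'
#' @param min_probes_per_set minimum probes per probeset; genes (or
#'   regions) represented by fewer probes are not incorporated into the
#'   CDF. Default 4, the smallest set size reported to give statistically
#'   significant summaries.
#' @param containment_rule `"full"` (a probe must lie entirely inside one
#'   exon) or `"any-overlap"`.
#' @param strand_rule `"require-sense"` (probe match strand must equal the
#'   annotated transcript strand, keeping sense and antisense signal
#'   separable), `"require-antisense"`, or `"ignore"`.
#' @return a list of class `pipeline_params`.
#' @export
pipeline_params <- function(min_probes_per_set = 4L,
                            containment_rule = c("full", "any-overlap"),
                            strand_rule = c("require-sense",
                                            "require-antisense", "ignore")) {
  min_probes_per_set <- as.integer(min_probes_per_set)
  if (is.na(min_probes_per_set) || min_probes_per_set < 1L)
    stop("min_probes_per_set must be >= 1")
  structure(list(min_probes_per_set = min_probes_per_set,
                 containment_rule = match.arg(containment_rule),
                 strand_rule = match.arg(strand_rule)),
            class = "pipeline_params")
}

#' Remove probes with duplicated sequences (pipeline step 1)
#'
#' Exactly one probe is retained per distinct sequence: the first in
#' (y, x) order. The output keeps the input's row order.
#'
#' @param probes probe `data.frame` (`probe_id`, `x`, `y`, `sequence`).
#' @return the deduplicated probe `data.frame`.
#' @export
dedupe_probes <- function(probes) {
  if (nrow(probes) == 0L) return(probes)
  ord <- order(probes$y, probes$x)
  first <- !duplicated(probes$sequence[ord])
  keep_ids <- probes$probe_id[ord][first]
  out <- probes[probes$probe_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign uniquely mapping probes to annotated genes (pipeline step 4)
#'
#' Under the default containment rule a probe is assigned to a gene iff
#' its genomic interval is fully contained in one exon of that gene (a
#' probe straddling an exon boundary or a splice junction is assigned to
#' nothing); under the default strand rule the probe's match strand must
#' equal the gene strand. Probes assignable to more than one gene are
#' dropped so that probesets partition the probes.
#'
#' @param matches unique-in-genome match table (may carry extra columns
#'   such as `x`, `y`, which are passed through).
#' @param features exon table from [read_annotation()].
#' @param params a [pipeline_params()] object.
#' @return the match rows that were assigned, with a `gene_id` column;
#'   probes dropped for ambiguity are listed in attribute
#'   `dropped_ambiguous`.
#' @export
intersect_annotation <- function(matches, features, params = pipeline_params()) {
  if (nrow(matches) == 0L || nrow(features) == 0L) {
    out <- cbind(matches[0, , drop = FALSE], gene_id = character(0))
    attr(out, "dropped_ambiguous") <- character(0)
    return(out)
  }
  q <- GenomicRanges::GRanges(matches$chrom,
                              IRanges::IRanges(matches$start + 1L, matches$end))
  s <- GenomicRanges::GRanges(features$chrom,
                              IRanges::IRanges(features$start + 1L, features$end))
  type <- if (params$containment_rule == "full") "within" else "any"
  h <- GenomicRanges::findOverlaps(q, s, type = type)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  keep <- switch(params$strand_rule,
                 "require-sense" = matches$strand[qi] == features$strand[si],
                 "require-antisense" = matches$strand[qi] != features$strand[si],
                 "ignore" = rep(TRUE, length(qi)))
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) == 0L) {
    out <- cbind(matches[0, , drop = FALSE], gene_id = character(0))
    attr(out, "dropped_ambiguous") <- character(0)
    return(out)
  }
  gene <- features$gene_id[si]
  # number of distinct genes each probe row is assignable to
  ngenes <- tapply(gene, qi, function(g) length(unique(g)))
  amb_rows <- as.integer(names(ngenes)[ngenes > 1L])
  pairs <- unique(data.frame(qi = qi, gene_id = gene, stringsAsFactors = FALSE))
  pairs <- pairs[!(pairs$qi %in% amb_rows), , drop = FALSE]
  out <- matches[pairs$qi, , drop = FALSE]
  out$gene_id <- pairs$gene_id
  rownames(out) <- NULL
  attr(out, "dropped_ambiguous") <- unique(matches$probe_id[amb_rows])
  out
}

#' Group assigned probes into probesets (pipeline step 5)
#'
#' One probeset per gene with at least `min_probes_per_set` probes; genes
#' below that are dropped and listed in attribute `dropped_genes`.
#'
#' @param assignments output of [intersect_annotation()].
#' @param params a [pipeline_params()] object.
#' @return probe-map `data.frame` (`probeset_id`, `probe_id`, `x`, `y`,
#'   `chrom`, `start`, `end`, `strand`), ordered by probeset id then
#'   genomic position.
#' @export
assemble_probesets <- function(assignments, params = pipeline_params()) {
  empty <- data.frame(probeset_id = character(0), probe_id = character(0),
                      x = integer(0), y = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (nrow(assignments) == 0L) {
    attr(empty, "dropped_genes") <- character(0)
    return(empty)
  }
  if (!"x" %in% names(assignments)) assignments$x <- NA_integer_
  if (!"y" %in% names(assignments)) assignments$y <- NA_integer_
  sizes <- table(assignments$gene_id)
  keep <- names(sizes)[sizes >= params$min_probes_per_set]
  dropped <- setdiff(names(sizes), keep)
  sub <- assignments[assignments$gene_id %in% keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    attr(empty, "dropped_genes") <- dropped
    return(empty)
  }
  out <- data.frame(probeset_id = sub$gene_id, probe_id = sub$probe_id,
                    x = sub$x, y = sub$y, chrom = sub$chrom,
                    start = sub$start, end = sub$end, strand = sub$strand,
                    stringsAsFactors = FALSE)
  out <- out[order(out$probeset_id, out$chrom, out$start, out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_genes") <- dropped
  out
}

.run_cdf_pipeline <- function(probes, genome, features, params) {
  validate_probes(probes)
  step1 <- dedupe_probes(probes)
  matches <- karp_rabin_search(setNames(step1$sequence, step1$probe_id), genome)
  report <- classify_matches(matches, step1)
  um <- unique_matches(report)
  um$x <- step1$x[match(um$probe_id, step1$probe_id)]
  um$y <- step1$y[match(um$probe_id, step1$probe_id)]
  assignments <- intersect_annotation(um, features, params)
  probesets <- assemble_probesets(assignments, params)
  counts <- c(total = nrow(probes),
              unique_seq = nrow(step1),
              in_genome = report$n_unique + report$n_multi,
              unique_in_genome = report$n_unique,
              intragenic = length(unique(assignments$probe_id)),
              n_probesets = length(unique(probesets$probeset_id)))
  if (any(diff(counts[1:5]) > 0L))
    stop("internal error: step counts are not monotone non-increasing")
  structure(list(probesets = probesets, counts = counts, report = report,
                 params = params,
                 dropped_ambiguous = attr(assignments, "dropped_ambiguous"),
                 dropped_genes = attr(probesets, "dropped_genes")),
            class = "cdf_result")
}

#' Build a custom CDF from a probe table, genome and annotation
#'
#' Runs the five-step filtering pipeline: (1) deduplicate probe sequences,
#' (2) map every probe exactly to the genome on both strands, (3) discard
#' probes mapping to more than one position, (4) keep probes contained in
#' annotated exons (sense strand by default), (5) assemble probesets and
#' drop genes represented by fewer than `min_probes_per_set` probes.
#'
#' @param probes probe `data.frame` (`probe_id`, `x`, `y`, `sequence`).
#' @param genome a [genome_seq()] object.
#' @param features exon table from [read_annotation()].
#' @param params a [pipeline_params()] object.
#' @return a `cdf_result`: list with `probesets` (probe map), `counts`
#'   (per-step probe counts, monotone non-increasing), `report` (the
#'   `match_report`), and the dropped-probe/gene logs.
#' @export
build_cdf <- function(probes, genome, features, params = pipeline_params()) {
  .run_cdf_pipeline(probes, genome, features, params)
}

#' @export
print.cdf_result <- function(x, ...) {
  cat("cdf_result:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Build a custom CDF using amplicon sequences as the reference
#'
#' Variant of [build_cdf()] for comparisons against PCR-amplicon arrays:
#' each amplicon is located in the genome by exact search and converted to
#' a single-exon pseudo-feature named after the amplicon; the standard
#' step-4/5 path then runs against those pseudo-features with the strand
#' rule set to `"ignore"` (PCR products are double-stranded). Amplicons
#' absent from the genome, or occurring more than once, are skipped with a
#' warning.
#'
#' @param probes probe `data.frame`.
#' @param genome a [genome_seq()] object.
#' @param amplicons named character vector of amplicon sequences, a
#'   `DNAStringSet`, or the path of an amplicon FASTA file.
#' @param params a [pipeline_params()] object; its `strand_rule` is forced
#'   to `"ignore"`.
#' @return a `cdf_result`, as for [build_cdf()].
#' @export
build_cdf_from_amplicons <- function(probes, genome, amplicons,
                                     params = pipeline_params()) {
  if (is.character(amplicons) && length(amplicons) == 1L &&
      file.exists(amplicons) && is.null(names(amplicons))) {
    amplicons <- Biostrings::readDNAStringSet(amplicons)
  }
  if (methods::is(amplicons, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(amplicons))
    amplicons <- setNames(toupper(as.character(amplicons)), nm)
  }
  if (is.null(names(amplicons))) stop("amplicons must be named")
  am <- karp_rabin_search(amplicons, genome)
  nhit <- table(factor(am$probe_id, levels = names(amplicons)))
  missing <- names(nhit)[nhit == 0L]
  multi <- names(nhit)[nhit > 1L]
  if (length(missing))
    warning("amplicon(s) not found in genome, skipped: ",
            paste(missing, collapse = ", "))
  if (length(multi))
    warning("amplicon(s) matching the genome more than once, skipped: ",
            paste(multi, collapse = ", "))
  am <- am[am$probe_id %in% names(nhit)[nhit == 1L], , drop = FALSE]
  pseudo <- data.frame(gene_id = am$probe_id, chrom = am$chrom,
                       strand = am$strand, start = am$start, end = am$end,
                       stringsAsFactors = FALSE)
  params$strand_rule <- "ignore"
  .run_cdf_pipeline(probes, genome, pseudo, params)
}
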