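#' Specification of a synthetic tiling-array experiment
#'
#' Deterministic, seeded description of a simulated study: a random
#' genome, single-exon gene annotation, a tiling (or gene-restricted)
#' probe design, planted differential expression, planted non-annotated
#' transcripts, and planted probe-level anomalies with known ground
#' truth. The defaults describe the reference desk-scale study: two
#' 100 kb chromosomes, 60 genes, 10 differentially expressed genes with
#' absolute log2 effects between 1 and 2, five intergenic transcripts of
#' at least 300 nt and one antisense transcript (log2 effect 1.5), 25-mer
#' probes tiled every 20 nt on both strands (about three probes per
#' 60 nt), two replicates per condition and multiplicative log-normal
#' noise of 0.15 on the log2 scale.
#'
#' @param seed integer seed; every random choice flows from it.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_genes number of single-exon genes.
#' @param gene_length_range min/max gene length (nt).
#' @param probe_length probe length (nt), default 25.
#' @param tiling_step distance between consecutive probe starts (nt),
#'   default 20; must stay below the 60 nt clustering gap.
#' @param tile `"genome"` (tile both strands of the whole genome) or
#'   `"genic"` (sense-strand probes inside genes only, plus planted
#'   extras — the layout used for pipeline bookkeeping fixtures).
#' @param n_de_genes number of differentially expressed genes.
#' @param de_effect_range min/max absolute log2 effect of DE genes
#'   (signs alternate).
#' @param n_intergenic_transcripts planted non-annotated transcripts.
#' @param transcript_length_range min/max planted transcript length (nt).
#' @param transcript_effect absolute log2 effect of planted transcripts.
#' @param n_antisense_transcripts planted transcripts antisense to a
#'   non-DE gene.
#' @param n_duplicates planted probes duplicating an existing sequence.
#' @param n_multimappers planted probes drawn from a segment repeated on
#'   two chromosomes (requires `tile = "genic"`).
#' @param n_unmapped planted probes whose sequence is absent from the
#'   genome.
#' @param n_intergenic_probes planted unique intergenic probes (requires
#'   `tile = "genic"`).
#' @param noise_sd per-array log2-scale noise standard deviation.
#' @param n_replicates replicates per condition.
#' @param baseline_log2 log2 intensity of unexpressed probes.
#' @param expressed_log2 mean log2 intensity of expressed features.
#' @param feature_level_sd between-feature spread of expression levels.
#' @param probe_affinity_sd per-probe affinity spread (constant across
#'   arrays; absorbed by median polish).
#' @param min_feature_gap minimum distance between placed features (nt);
#'   kept above the 120 nt fuse gap so planted regions stay separable.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L,
                            chrom_lengths = c(chrI = 100000L, chrII = 100000L),
                            n_genes = 60L,
                            gene_length_range = c(500L, 2000L),
                            probe_length = 25L,
                            tiling_step = 20L,
                            tile = c("genome", "genic"),
                            n_de_genes = 10L,
                            de_effect_range = c(1, 2),
                            n_intergenic_transcripts = 5L,
                            transcript_length_range = c(300L, 800L),
                            transcript_effect = 1.5,
                            n_antisense_transcripts = 1L,
                            n_duplicates = 0L,
                            n_multimappers = 0L,
                            n_unmapped = 0L,
                            n_intergenic_probes = 0L,
                            noise_sd = 0.15,
                            n_replicates = 2L,
                            baseline_log2 = 7,
                            expressed_log2 = 10,
                            feature_level_sd = 0.5,
                            probe_affinity_sd = 0.3,
                            min_feature_gap = 250L) {
  tile <- match.arg(tile)
  spec <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
               n_genes = as.integer(n_genes),
               gene_length_range = as.integer(gene_length_range),
               probe_length = as.integer(probe_length),
               tiling_step = as.integer(tiling_step), tile = tile,
               n_de_genes = as.integer(n_de_genes),
               de_effect_range = as.numeric(de_effect_range),
               n_intergenic_transcripts = as.integer(n_intergenic_transcripts),
               transcript_length_range = as.integer(transcript_length_range),
               transcript_effect = as.numeric(transcript_effect),
               n_antisense_transcripts = as.integer(n_antisense_transcripts),
               n_duplicates = as.integer(n_duplicates),
               n_multimappers = as.integer(n_multimappers),
               n_unmapped = as.integer(n_unmapped),
               n_intergenic_probes = as.integer(n_intergenic_probes),
               noise_sd = as.numeric(noise_sd),
               n_replicates = as.integer(n_replicates),
               baseline_log2 = as.numeric(baseline_log2),
               expressed_log2 = as.numeric(expressed_log2),
               feature_level_sd = as.numeric(feature_level_sd),
               probe_affinity_sd = as.numeric(probe_affinity_sd),
               min_feature_gap = as.integer(min_feature_gap))
  if (spec$tiling_step >= 60L)
    stop("tiling_step must stay below the 60 nt clustering gap")
  if (spec$probe_length < 10L) stop("probe_length too short")
  if (is.null(names(spec$chrom_lengths)))
    stop("chrom_lengths must be named")
  if (spec$n_de_genes > spec$n_genes)
    stop("more DE genes than genes")
  if ((spec$n_multimappers > 0L || spec$n_intergenic_probes > 0L) &&
      spec$tile != "genic")
    stop("multi-mapper and intergenic-probe planting require tile = 'genic'")
  if (any(!is.finite(c(spec$de_effect_range, spec$transcript_effect))))
    stop("effects must be finite")
  if (max(spec$gene_length_range) + spec$min_feature_gap >
      min(spec$chrom_lengths))
    stop("genes do not fit in the chromosomes")
  structure(spec, class = "simulation_spec")
}

# reserved prefix of each chromosome used (in genic mode) for planted
# multi-mapper repeats and intergenic probe sources
.RESERVE <- 3000L

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# place features (lengths li) sequentially on a chromosome with random
# gaps >= min_gap, starting at `from`; error if they do not fit
.place_features <- function(lens, chrom_len, from, min_gap) {
  pos <- from
  starts <- integer(length(lens))
  for (i in seq_along(lens)) {
    gap <- min_gap + sample.int(400L, 1L)
    starts[i] <- pos + gap
    pos <- starts[i] + lens[i]
    if (pos > chrom_len - 100L)
      stop("simulation spec infeasible: features do not fit on chromosome")
  }
  starts
}

#' Simulate a genome, annotation and probe design with known ground truth
#'
#' Fully reproducible from `spec$seed`: the same spec yields byte-identical
#' outputs. Genes and planted transcripts are placed without overlap and
#' separated by at least `min_feature_gap`; probes tile both strands at
#' the stated step (`tile = "genome"`) or cover gene bodies on the sense
#' strand (`tile = "genic"`); planted duplicates copy existing probe
#' sequences, planted multi-mappers are drawn from a segment repeated on
#' two chromosomes, planted unmapped probes are verified absent from the
#' genome.
#'
#' @param spec a [simulation_spec()] object.
#' @return a list of class `tile_sim` with elements `genome`
#'   ([genome_seq()]), `features` (exon table), `probes` (probe table),
#'   `probe_truth` (true genomic placement of each designed probe) and
#'   `truth` (tables of planted genes, transcripts and anomalies).
#' @export
simulate_genome_and_probes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  chroms <- names(spec$chrom_lengths)
  seqs <- vapply(spec$chrom_lengths, .random_dna, character(1L))
  names(seqs) <- chroms

  # plant the multi-mapper repeat inside the reserved prefix
  repeat_len <- max(150L, spec$probe_length +
                      spec$tiling_step * spec$n_multimappers)
  if (spec$n_multimappers > 0L) {
    if (length(chroms) < 2L)
      stop("multi-mapper planting needs at least two chromosomes")
    seg <- substr(seqs[[1L]], 101L, 100L + repeat_len)
    substr(seqs[[2L]], 101L, 100L + repeat_len) <- seg
  }

  # distribute genes and intergenic transcripts across chromosomes
  glen <- sample(seq(spec$gene_length_range[1L], spec$gene_length_range[2L]),
                 spec$n_genes, replace = TRUE)
  tlen <- if (spec$n_intergenic_transcripts > 0L)
    sample(seq(spec$transcript_length_range[1L],
               spec$transcript_length_range[2L]),
           spec$n_intergenic_transcripts, replace = TRUE) else integer(0)
  items <- data.frame(
    id = c(sprintf("gene%03d", seq_len(spec$n_genes)),
           if (spec$n_intergenic_transcripts > 0L)
             sprintf("tx%02d", seq_len(spec$n_intergenic_transcripts))),
    kind = c(rep("gene", spec$n_genes),
             rep("transcript", spec$n_intergenic_transcripts)),
    len = c(glen, tlen), stringsAsFactors = FALSE)
  items$chrom <- chroms[rep_len(seq_along(chroms), nrow(items))]
  items$strand <- sample(c("+", "-"), nrow(items), replace = TRUE)
  items <- items[sample.int(nrow(items)), , drop = FALSE]
  placed <- lapply(chroms, function(ch) {
    it <- items[items$chrom == ch, , drop = FALSE]
    it$start <- .place_features(it$len, spec$chrom_lengths[[ch]],
                                from = .RESERVE, spec$min_feature_gap)
    it$end <- it$start + it$len
    it
  })
  items <- do.call(rbind, placed)

  genes <- items[items$kind == "gene", , drop = FALSE]
  genes <- genes[order(genes$id), , drop = FALSE]
  features <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                         strand = genes$strand, start = genes$start,
                         end = genes$end, stringsAsFactors = FALSE)

  # planted differential expression
  de_idx <- sort(sample.int(spec$n_genes, spec$n_de_genes))
  effects <- runif(spec$n_de_genes, spec$de_effect_range[1L],
                   spec$de_effect_range[2L]) *
    rep_len(c(1, -1), spec$n_de_genes)
  gene_truth <- data.frame(gene_id = features$gene_id,
                           chrom = features$chrom, strand = features$strand,
                           start = features$start, end = features$end,
                           is_de = seq_len(spec$n_genes) %in% de_idx,
                           effect = 0, stringsAsFactors = FALSE)
  gene_truth$effect[de_idx] <- effects

  # planted transcripts: intergenic ones from the placement, antisense
  # ones carved out of non-DE genes
  tx <- items[items$kind == "transcript", , drop = FALSE]
  tx_truth <- if (nrow(tx) > 0L) {
    data.frame(tx_id = tx$id, chrom = tx$chrom, strand = tx$strand,
               start = tx$start, end = tx$end, type = "intergenic",
               effect = spec$transcript_effect *
                 rep_len(c(1, -1), nrow(tx)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(tx_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               type = character(0), effect = numeric(0),
               stringsAsFactors = FALSE)
  }
  if (spec$n_antisense_transcripts > 0L) {
    host_pool <- which(!gene_truth$is_de &
                         (gene_truth$end - gene_truth$start) >=
                           spec$transcript_length_range[1L])
    if (length(host_pool) < spec$n_antisense_transcripts)
      stop("not enough non-DE genes to host antisense transcripts")
    hosts <- sample(host_pool, spec$n_antisense_transcripts)
    as_tx <- data.frame(
      tx_id = sprintf("astx%02d", seq_len(spec$n_antisense_transcripts)),
      chrom = gene_truth$chrom[hosts],
      strand = ifelse(gene_truth$strand[hosts] == "+", "-", "+"),
      start = gene_truth$start[hosts],
      end = pmin(gene_truth$end[hosts], gene_truth$start[hosts] +
                   pmax(spec$transcript_length_range[1L], 600L)),
      type = "antisense", effect = spec$transcript_effect,
      stringsAsFactors = FALSE)
    tx_truth <- rbind(tx_truth, as_tx)
  }

  # probe design
  pl <- spec$probe_length
  if (spec$tile == "genome") {
    tiles <- lapply(chroms, function(ch) {
      starts <- seq(0L, spec$chrom_lengths[[ch]] - pl, by = spec$tiling_step)
      data.frame(chrom = ch, start = starts, stringsAsFactors = FALSE)
    })
    tiles <- do.call(rbind, tiles)
    tiles <- tiles[rep(seq_len(nrow(tiles)), each = 2L), , drop = FALSE]
    tiles$strand <- rep_len(c("+", "-"), nrow(tiles))
  } else {
    tiles <- lapply(seq_len(nrow(features)), function(i) {
      g <- features[i, ]
      starts <- seq(g$start, g$end - pl, by = spec$tiling_step)
      data.frame(chrom = g$chrom, start = starts, strand = g$strand,
                 stringsAsFactors = FALSE)
    })
    tiles <- do.call(rbind, tiles)
  }
  fwd <- substring(seqs[tiles$chrom], tiles$start + 1L, tiles$start + pl)
  seq_out <- ifelse(tiles$strand == "+", fwd, NA_character_)
  minus <- tiles$strand == "-"
  if (any(minus)) seq_out[minus] <- .revcomp(fwd[minus])
  probes <- data.frame(probe_id = sprintf("P%06d", seq_len(nrow(tiles))),
                       sequence = seq_out, chrom = tiles$chrom,
                       start = tiles$start, end = tiles$start + pl,
                       strand = tiles$strand, role = "tiling",
                       stringsAsFactors = FALSE)

  extra <- list()
  if (spec$n_intergenic_probes > 0L) {
    starts <- 2000L + spec$tiling_step * (seq_len(spec$n_intergenic_probes) - 1L)
    if (max(starts) + pl > .RESERVE)
      stop("too many intergenic probes for the reserved region")
    extra$intergenic <- data.frame(
      probe_id = sprintf("IG%04d", seq_len(spec$n_intergenic_probes)),
      sequence = substring(seqs[[1L]], starts + 1L, starts + pl),
      chrom = chroms[1L], start = starts, end = starts + pl, strand = "+",
      role = "intergenic", stringsAsFactors = FALSE)
  }
  if (spec$n_multimappers > 0L) {
    starts <- 100L + spec$tiling_step * (seq_len(spec$n_multimappers) - 1L)
    extra$multi <- data.frame(
      probe_id = sprintf("MM%04d", seq_len(spec$n_multimappers)),
      sequence = substring(seqs[[1L]], starts + 1L, starts + pl),
      chrom = chroms[1L], start = starts, end = starts + pl, strand = "+",
      role = "multimapper", stringsAsFactors = FALSE)
  }
  if (spec$n_duplicates > 0L) {
    src <- sample.int(nrow(probes), spec$n_duplicates)
    extra$dup <- data.frame(
      probe_id = sprintf("DUP%04d", seq_len(spec$n_duplicates)),
      sequence = probes$sequence[src], chrom = probes$chrom[src],
      start = probes$start[src], end = probes$end[src],
      strand = probes$strand[src], role = "duplicate",
      stringsAsFactors = FALSE)
    attr(extra$dup, "duplicate_of") <- probes$probe_id[src]
  }
  if (spec$n_unmapped > 0L) {
    gset <- Biostrings::DNAStringSet(seqs)
    mk <- function(i) {
      for (try in 1:50) {
        s <- .random_dna(pl)
        n1 <- sum(Biostrings::vcountPattern(s, gset))
        n2 <- sum(Biostrings::vcountPattern(.revcomp(s), gset))
        if (n1 + n2 == 0L) return(s)
      }
      stop("could not generate an unmapped probe sequence")
    }
    extra$unmapped <- data.frame(
      probe_id = sprintf("UM%04d", seq_len(spec$n_unmapped)),
      sequence = vapply(seq_len(spec$n_unmapped), mk, character(1L)),
      chrom = NA_character_, start = NA_integer_, end = NA_integer_,
      strand = NA_character_, role = "unmapped", stringsAsFactors = FALSE)
  }
  dup_of <- if (!is.null(extra$dup)) attr(extra$dup, "duplicate_of")
  probes <- rbind(probes, do.call(rbind, unname(extra)))

  # array coordinates on a square-ish grid
  width <- as.integer(ceiling(sqrt(nrow(probes))))
  probes$x <- (seq_len(nrow(probes)) - 1L) %% width
  probes$y <- (seq_len(nrow(probes)) - 1L) %/% width

  truth <- list(genes = gene_truth, transcripts = tx_truth,
                duplicates = if (!is.null(extra$dup))
                  data.frame(probe_id = extra$dup$probe_id,
                             duplicate_of = dup_of,
                             stringsAsFactors = FALSE),
                multimappers = extra$multi$probe_id,
                unmapped = extra$unmapped$probe_id,
                intergenic_probes = extra$intergenic$probe_id)

  structure(list(genome = genome_seq(seqs),
                 features = features,
                 probes = probes[, c("probe_id", "x", "y", "sequence")],
                 probe_truth = probes[, c("probe_id", "chrom", "start",
                                          "end", "strand", "role")],
                 truth = truth, spec = spec),
            class = "tile_sim")
}

#' Simulate a replicated two-condition intensity matrix
#'
#' Log2 intensities are the sum of a per-probe baseline (expressed
#' features have a feature-specific level, everything else sits at the
#' background level), a per-probe affinity term constant across arrays,
#' half the planted effect subtracted on control arrays and added on
#' treated arrays (so the treated-minus-control difference equals the
#' planted log2 effect), and per-array Gaussian noise on the log2 scale
#' (multiplicative log-normal noise on the raw scale). Only sense-strand
#' probes of a feature carry its signal, so antisense transcription is
#' visible exclusively on its own strand.
#'
#' @param spec the [simulation_spec()] used to build `sim`.
#' @param sim output of [simulate_genome_and_probes()].
#' @return list with `intensities` (probes x arrays matrix, raw scale)
#'   and `design` (`array_id`, `condition`).
#' @export
simulate_intensities <- function(spec, sim) {
  stopifnot(inherits(sim, "tile_sim"))
  set.seed(spec$seed + 777L)
  pt <- sim$probe_truth
  n <- nrow(pt)

  feats <- rbind(
    data.frame(id = sim$truth$genes$gene_id, chrom = sim$truth$genes$chrom,
               strand = sim$truth$genes$strand,
               start = sim$truth$genes$start, end = sim$truth$genes$end,
               effect = sim$truth$genes$effect, stringsAsFactors = FALSE),
    data.frame(id = sim$truth$transcripts$tx_id,
               chrom = sim$truth$transcripts$chrom,
               strand = sim$truth$transcripts$strand,
               start = sim$truth$transcripts$start,
               end = sim$truth$transcripts$end,
               effect = sim$truth$transcripts$effect,
               stringsAsFactors = FALSE))
  level <- setNames(rnorm(nrow(feats), spec$expressed_log2,
                          spec$feature_level_sd), feats$id)

  base <- rep(spec$baseline_log2, n)
  effect <- rep(0, n)
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    hit <- !is.na(pt$chrom) & pt$chrom == f$chrom & pt$strand == f$strand &
      pt$start >= f$start & pt$end <= f$end
    base[hit] <- level[[f$id]]
    effect[hit] <- f$effect
  }
  base <- base + rnorm(n, 0, spec$probe_affinity_sd)

  arrays <- c(sprintf("control_%d", seq_len(spec$n_replicates)),
              sprintf("treated_%d", seq_len(spec$n_replicates)))
  design <- data.frame(array_id = arrays,
                       condition = rep(c("control", "treated"),
                                       each = spec$n_replicates),
                       stringsAsFactors = FALSE)
  m <- matrix(NA_real_, n, length(arrays),
              dimnames = list(pt$probe_id, arrays))
  for (j in seq_along(arrays)) {
    shift <- if (design$condition[j] == "treated") effect / 2 else -effect / 2
    noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
    m[, j] <- 2^(base + shift + noise)
  }
  list(intensities = m, design = design)
}

#' Simulate a complete dataset (genome, annotation, probes, intensities)
#' @param spec a [simulation_spec()] object.
#' @return a `tile_sim` list with the additional elements `intensities`
#'   and `design`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  sim <- simulate_genome_and_probes(spec)
  ints <- simulate_intensities(spec, sim)
  sim$intensities <- ints$intensities
  sim$design <- ints$design
  sim
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `genome.fasta`, `annotation.gff3`, `probes.tsv`,
#' `intensities.tsv`, `design.tsv` and the ground-truth tables
#' (`truth_genes.tsv`, `truth_transcripts.tsv`, `truth_probes.tsv`) so
#' that fixtures are self-describing.
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fasta"))
  write_annotation(sim$features, file.path(dir, "annotation.gff3"))
  write_probe_table(sim$probes, file.path(dir, "probes.tsv"))
  if (!is.null(sim$intensities))
    write_intensities(sim$intensities, file.path(dir, "intensities.tsv"))
  if (!is.null(sim$design))
    write_design(sim$design, file.path(dir, "design.tsv"))
  .write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  .write_tsv(sim$truth$transcripts, file.path(dir, "truth_transcripts.tsv"))
  .write_tsv(sim$probe_truth, file.path(dir, "truth_probes.tsv"))
  invisible(dir)
}
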