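#' Genome sequence container
#'
#' Holds per-chromosome uppercase DNA strings over the alphabet
#' \{A,C,G,T,N\} together with an optional set of masked intervals that are
#' excluded from probe mapping (the mechanism used to take a repeated locus
#' such as an rDNA array out of the uniqueness assessment).
#'
#' @param sequences named character vector of uppercase DNA sequences;
#'   names are the chromosome identifiers and must be unique.
#' @param mask optional `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open) of regions excluded from mapping.
#' @return an object of class `genome_seq`: a list with elements
#'   `sequences` and `mask`.
#' @export
genome_seq <- function(sequences, mask = NULL) {
  if (length(sequences) == 0L) stop("genome contains no sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named by chromosome")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome names")
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences)))
    stop("genome alphabet restricted to A, C, G, T, N")
  if (!is.null(mask)) {
    mask <- as.data.frame(mask)
    req <- c("chrom", "start", "end")
    if (!all(req %in% names(mask))) stop("mask needs columns chrom, start, end")
    bad <- !(mask$chrom %in% names(sequences))
    if (any(bad)) stop("mask interval on undeclared chromosome: ",
                       paste(unique(mask$chrom[bad]), collapse = ", "))
    len <- nchar(sequences)[match(mask$chrom, names(sequences))]
    if (any(mask$start < 0L | mask$end > len | mask$start >= mask$end))
      stop("mask interval out of chromosome bounds")
  }
  structure(list(sequences = sequences, mask = mask), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("genome_seq:", length(x$sequences), "chromosome(s),",
      sum(nchar(x$sequences)), "bp total\n")
  if (!is.null(x$mask)) cat("  masked intervals:", nrow(x$mask), "\n")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased on input. Positions overlapping `N` never
#' produce probe matches downstream, and matches starting inside a masked
#' interval are discarded by [karp_rabin_search()].
#'
#' @param path FASTA file.
#' @param mask optional `data.frame(chrom, start, end)` of 0-based
#'   half-open intervals excluded from mapping.
#' @return a [genome_seq()] object.
#' @export
read_genome <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("malformed FASTA ", path, ": ",
                                          conditionMessage(e)))
  if (length(ss) == 0L) stop("FASTA contains no sequences: ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_seq(seqs, mask = mask)
}

#' Write a genome to a FASTA file
#'
#' @param genome a [genome_seq()] object.
#' @param path output file.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

.resolve_gene <- function(id, parent_of, is_gene, max_depth = 5L) {
  # climb Parent attributes until a feature of type "gene" is reached
  cur <- id
  for (d in seq_len(max_depth)) {
    if (is.na(cur)) return(NA_character_)
    if (isTRUE(is_gene[cur])) return(cur)
    cur <- parent_of[cur]
  }
  NA_character_
}

#' Read gene annotation from a GFF3 file
#'
#' Reads a gene/mRNA/exon (or CDS) hierarchy and returns one row per exon
#' with GFF3 1-based inclusive coordinates converted to internal 0-based
#' half-open intervals. Exons that cannot be traced to a parent gene are
#' skipped with a warning; overlapping exons within one gene are merged
#' with a warning so that containment tests operate on disjoint intervals.
#'
#' @param path GFF3 file.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, sorted by gene then position.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  parents <- if (!is.null(gr$Parent)) {
    vapply(gr$Parent, function(p) if (length(p)) as.character(p[[1L]]) else NA_character_,
           character(1L))
  } else rep(NA_character_, length(gr))

  is_gene <- setNames(type == "gene", ids)
  is_gene <- is_gene[!is.na(names(is_gene))]
  parent_of <- setNames(parents, ids)
  parent_of <- parent_of[!is.na(names(parent_of))]

  part <- type %in% "exon"
  if (!any(part)) part <- type %in% "CDS"
  if (!any(part)) stop("annotation contains no exon or CDS features")

  exon_parent <- parents[part]
  gene_id <- vapply(exon_parent, .resolve_gene, character(1L),
                    parent_of = parent_of, is_gene = is_gene)
  orphan <- is.na(gene_id)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) without a resolvable parent gene skipped")
  }
  sub <- gr[part][!orphan]
  gene_id <- gene_id[!orphan]
  if (length(sub) == 0L) stop("no exons left after orphan filtering")

  strand <- as.character(GenomicRanges::strand(sub))
  if (any(!strand %in% c("+", "-")))
    stop("unknown strand symbol in annotation (expected + or -)")

  ex <- data.frame(gene_id = gene_id,
                   chrom = as.character(GenomicRanges::seqnames(sub)),
                   strand = strand,
                   start = GenomicRanges::start(sub) - 1L,  # to 0-based half-open
                   end = GenomicRanges::end(sub),
                   stringsAsFactors = FALSE)

  # one gene must live on one chromosome/strand
  chk <- unique(ex[, c("gene_id", "chrom", "strand")])
  if (anyDuplicated(chk$gene_id))
    stop("gene annotated on multiple chromosomes or strands: ",
         paste(chk$gene_id[duplicated(chk$gene_id)], collapse = ", "))

  # merge overlapping exons per gene
  merged <- lapply(split(ex, ex$gene_id), function(g) {
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    if (length(ir) < nrow(g))
      warning("overlapping or adjacent exons merged for gene ", g$gene_id[1L])
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               strand = g$strand[1L],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene annotation to a GFF3 file
#'
#' Inverse of [read_annotation()]: internal 0-based half-open exons are
#' written as a gene/exon GFF3 hierarchy with 1-based inclusive
#' coordinates.
#'
#' @param features exon table as returned by [read_annotation()].
#' @param path output GFF3 file.
#' @export
write_annotation <- function(features, path) {
  genes <- split(features, features$gene_id)
  rows <- lapply(genes, function(g) {
    span <- c(min(g$start), max(g$end))
    rbind(
      data.frame(chrom = g$chrom[1L], start = span[1L] + 1L, end = span[2L],
                 strand = g$strand[1L], type = "gene",
                 ID = g$gene_id[1L], Parent = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(chrom = g$chrom, start = g$start + 1L, end = g$end,
                 strand = g$strand, type = "exon",
                 ID = sprintf("%s.exon%d", g$gene_id, seq_len(nrow(g))),
                 Parent = g$gene_id, stringsAsFactors = FALSE)
    )
  })
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$chrom,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$type <- tab$type
  gr$ID <- tab$ID
  gr$Parent <- ifelse(is.na(tab$Parent), "", tab$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a probe definition table
#'
#' Tab-delimited with header `probe_id, x, y, sequence` (the plain-text
#' stand-in for vendor probe-sequence files). Lines starting with `#` are
#' ignored.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `probe_id`, `x`, `y`, `sequence`.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("probe table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("probe_id", "x", "y", "sequence")
  if (!all(req %in% names(tab)))
    stop("probe table needs columns: ", paste(req, collapse = ", "))
  tab <- tab[, req]
  validate_probes(tab)
  tab
}

validate_probes <- function(probes) {
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id in probe table")
  if (anyDuplicated(probes[, c("x", "y")])) stop("duplicate (x,y) in probe table")
  if (any(probes$x < 0L | probes$y < 0L)) stop("negative array coordinates")
  if (any(!nzchar(probes$sequence)) || any(grepl("[^ACGT]", probes$sequence)))
    stop("probe sequences must be non-empty over alphabet A, C, G, T")
  invisible(probes)
}

#' Write a probe definition table
#' @param probes probe `data.frame` (`probe_id`, `x`, `y`, `sequence`).
#' @param path output TSV file.
#' @param header optional character vector of `#`-prefixed header lines.
#' @export
write_probe_table <- function(probes, path, header = NULL) {
  .write_tsv(probes[, c("probe_id", "x", "y", "sequence")], path, header)
}

#' Read a probe-level intensity matrix
#'
#' Tab-delimited with header `probe_id` followed by one column per array
#' (the plain-text stand-in for CEL files). All intensities must be
#' strictly positive.
#'
#' @param path TSV file.
#' @return numeric matrix, probes in rows (rownames = probe ids), arrays
#'   in columns.
#' @export
read_intensities <- function(path) {
  if (!file.exists(path)) stop("intensity matrix not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
  if (names(tab)[1L] != "probe_id" || ncol(tab) < 2L)
    stop("intensity matrix needs a probe_id column plus >=1 array column")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$probe_id
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing values in intensity matrix")
  if (any(m <= 0)) stop("intensities must be strictly positive")
  m
}

#' Write a probe-level intensity matrix
#' @param m numeric matrix, probes in rows, arrays in columns.
#' @param path output TSV file.
#' @param header optional character vector of `#`-prefixed header lines.
#' @export
write_intensities <- function(m, path, header = NULL) {
  tab <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  .write_tsv(tab, path, header)
}

#' Read an experiment design table
#'
#' Tab-delimited with header `array_id, condition`; array ids must match
#' the intensity matrix columns.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `array_id`, `condition`.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("array_id", "condition") %in% names(tab)))
    stop("design table needs columns array_id, condition")
  tab
}

#' Write an experiment design table
#' @param design `data.frame` with columns `array_id`, `condition`.
#' @param path output TSV file.
#' @export
write_design <- function(design, path) {
  .write_tsv(design[, c("array_id", "condition")], path, NULL)
}

#' Write a probe map (flat-CDF) file
#'
#' One row per probe: `probeset_id, probe_id, x, y, chrom, start, end,
#' strand`, tab-delimited, in deterministic order (probeset id, then
#' genomic position). This flat dialect replaces the binary vendor CDF:
#' it is consumed directly by [summarize_probesets()].
#'
#' @param probesets probe-map `data.frame` as produced by [build_cdf()].
#' @param path output TSV file.
#' @param header optional character vector of `#`-prefixed header lines.
#' @export
write_probe_map <- function(probesets, path, header = NULL) {
  req <- c("probeset_id", "probe_id", "x", "y", "chrom", "start", "end", "strand")
  if (!all(req %in% names(probesets)))
    stop("probe map needs columns: ", paste(req, collapse = ", "))
  dup <- duplicated(probesets[, c("probeset_id", "probe_id")])
  if (any(dup)) stop("duplicate probe within a probeset: ",
                     paste(unique(probesets$probe_id[dup]), collapse = ", "))
  out <- probesets[order(probesets$probeset_id, probesets$chrom,
                         probesets$start, probesets$probe_id), req]
  .write_tsv(out, path, header)
}

#' Read a probe map (flat-CDF) file
#' @param path TSV file written by [write_probe_map()].
#' @return probe-map `data.frame`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("probe map not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("probeset_id", "probe_id", "x", "y", "chrom", "start", "end", "strand")
  if (!all(req %in% names(tab)))
    stop("probe map needs columns: ", paste(req, collapse = ", "))
  tab[, req]
}

#' Write the per-step probe counts of a CDF build
#' @param counts named integer vector (`total`, `unique_seq`, `in_genome`,
#'   `unique_in_genome`, `intragenic`, `n_probesets`).
#' @param path output TSV file.
#' @param header optional character vector of `#`-prefixed header lines.
#' @export
write_step_counts <- function(counts, path, header = NULL) {
  tab <- data.frame(step = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  .write_tsv(tab, path, header)
}

.write_tsv <- function(tab, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Resolve overlapping probe intervals into disjoint sorted bedGraph
# intervals: equal starts are averaged, each interval is truncated at the
# start of the next one.
.bedgraph_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    if (anyDuplicated(d$start)) {
      v <- tapply(d$value, d$start, mean)
      e <- tapply(d$end, d$start, max)
      d <- data.frame(chrom = d$chrom[1L], start = as.integer(names(v)),
                      end = as.integer(e), value = as.numeric(v),
                      stringsAsFactors = FALSE)
    }
    if (nrow(d) > 1L) {
      nxt <- c(d$start[-1L], Inf)
      d$end <- pmin(d$end, nxt)
    }
    d[d$end > d$start, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.write_bedgraph <- function(df, path) {
  df <- .bedgraph_intervals(df)
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               score = df$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Export differential-signal browser tracks as bedGraph files
#'
#' Writes one bedGraph per strand with the full probe-level log2
#' differential signal (`signal_plus` / `signal_minus`), and one per
#' (strand, direction) containing only probes whose absolute log2
#' difference reaches the display threshold
#' (`differential_{plus,minus}_{up,down}`). The default threshold of
#' 1.75-fold reproduces the browser display convention: differences below
#' it are not shown.
#'
#' @param track differential-signal track from [build_diff_track()].
#' @param dir output directory (created if needed).
#' @param display_threshold fold-change display cutoff (default 1.75).
#' @return invisibly, the named vector of files written.
#' @export
export_tracks <- function(track, dir, display_threshold = 1.75) {
  .validate_track(track)
  if (display_threshold <= 1) stop("display_threshold must exceed 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cut <- log2(display_threshold)
  files <- character(0)
  for (st in c("+", "-")) {
    code <- if (st == "+") "plus" else "minus"
    sub <- track[track$strand == st, , drop = FALSE]
    base <- data.frame(chrom = sub$chrom, start = sub$start, end = sub$end,
                       value = sub$log2_diff, stringsAsFactors = FALSE)
    f <- file.path(dir, sprintf("signal_%s.bedGraph", code))
    .write_bedgraph(base, f)
    files[sprintf("signal_%s", code)] <- f
    for (dirn in c("up", "down")) {
      keep <- if (dirn == "up") base$value >= cut else base$value <= -cut
      f <- file.path(dir, sprintf("differential_%s_%s.bedGraph", code, dirn))
      .write_bedgraph(base[keep, , drop = FALSE], f)
      files[sprintf("differential_%s_%s", code, dirn)] <- f
    }
  }
  invisible(files)
}

#' Export dTR intervals as a BED file
#' @param dtrs dTR table from [segment_track()] (with ids from
#'   [name_dtrs()]).
#' @param path output BED file.
#' @export
export_dtr_bed <- function(dtrs, path) {
  if (nrow(dtrs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(dtrs$chrom,
                               IRanges::IRanges(dtrs$start + 1L, dtrs$end),
                               strand = dtrs$strand)
  names(gr) <- if (!is.null(dtrs$dtr_id)) dtrs$dtr_id else
    sprintf("region%04d", seq_len(nrow(dtrs)))
  gr$score <- round(1000 * pmin(1, abs(dtrs$mean_diff) / 4))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
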