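#' Exact multi-pattern search of probe sequences against a genome
#'
#' Karp-Rabin rolling-hash search adapted to the four-letter DNA alphabet:
#' patterns are hashed with a base-4 polynomial hash (one hash table per
#' distinct pattern length), the genome is scanned once per length with a
#' rolling window, and every hash hit is verified by direct string
#' comparison so collisions cannot corrupt the result. Both strands are
#' searched: a forward-genome occurrence of the reverse complement of a
#' pattern is reported with strand `-`, i.e. the probe sequence equals the
#' reverse complement of the genomic interval. Windows overlapping an `N`
#' never match, and matches starting inside a masked genome interval are
#' discarded.
#'
#' @param patterns named character vector of DNA patterns (names are probe
#'   ids), or a probe `data.frame` with columns `probe_id` and `sequence`.
#'   Mixed lengths are allowed.
#' @param genome a [genome_seq()] object.
#' @return `data.frame` with columns `probe_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, sorted by chromosome (genome order),
#'   start, strand (`+` before `-`), probe id.
#' @examples
#' g <- genome_seq(c(chr1 = "ACGACG"))
#' karp_rabin_search(c(p1 = "ACG"), g)  # hits at 0 and 3 on "+"
#' @export
karp_rabin_search <- function(patterns, genome) {
  if (is.data.frame(patterns)) {
    patterns <- setNames(patterns$sequence, patterns$probe_id)
  }
  if (length(patterns) == 0L) stop("no patterns supplied")
  if (is.null(names(patterns)))
    names(patterns) <- sprintf("pattern%d", seq_along(patterns))
  if (!inherits(genome, "genome_seq")) stop("genome must be a genome_seq object")
  if (any(grepl("[^ACGT]", patterns)))
    stop("patterns must be over alphabet A, C, G, T")

  n <- length(patterns)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(patterns))))
  hits <- kr_search_cpp(unname(genome$sequences), c(unname(patterns), rc))

  if (nrow(hits) == 0L) {
    return(data.frame(probe_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  pat_idx <- ((hits$pattern - 1L) %% n) + 1L
  strand <- ifelse(hits$pattern <= n, "+", "-")
  out <- data.frame(probe_id = names(patterns)[pat_idx],
                    chrom = names(genome$sequences)[hits$chrom],
                    start = hits$start,
                    end = hits$start + nchar(patterns)[pat_idx],
                    strand = strand,
                    stringsAsFactors = FALSE)

  if (!is.null(genome$mask) && nrow(genome$mask) > 0L) {
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(genome$mask))) {
      m <- genome$mask[i, ]
      drop <- drop | (out$chrom == m$chrom & out$start >= m$start &
                        out$start < m$end)
    }
    out <- out[!drop, , drop = FALSE]
  }

  ord <- order(match(out$chrom, names(genome$sequences)), out$start,
               match(out$strand, c("+", "-")), out$probe_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify probes by genomic match multiplicity
#'
#' Probes with no match are unmapped, probes with exactly one match over
#' both strands combined are unique, probes with two or more are
#' multi-mapping (and are discarded by the CDF pipeline). A palindromic
#' probe hitting one locus on both strands therefore counts as
#' multi-mapping, the conservative choice for strand-specific analysis.
#'
#' @param matches match table from [karp_rabin_search()].
#' @param probes probe `data.frame` the matches were produced from.
#' @return an object of class `match_report`: a list with `status` (per
#'   probe: `probe_id`, `n_matches`, `status`), the counters `n_unmapped`,
#'   `n_unique`, `n_multi`, and the `matches` table.
#' @export
classify_matches <- function(matches, probes) {
  unknown <- setdiff(matches$probe_id, probes$probe_id)
  if (length(unknown))
    stop("match references unknown probe_id: ",
         paste(head(unknown, 5L), collapse = ", "))
  nm <- table(factor(matches$probe_id, levels = probes$probe_id))
  status <- data.frame(probe_id = probes$probe_id,
                       n_matches = as.integer(nm),
                       stringsAsFactors = FALSE)
  status$status <- ifelse(status$n_matches == 0L, "unmapped",
                          ifelse(status$n_matches == 1L, "unique", "multi"))
  rep <- list(status = status,
              n_unmapped = sum(status$status == "unmapped"),
              n_unique = sum(status$status == "unique"),
              n_multi = sum(status$status == "multi"),
              matches = matches)
  stopifnot(rep$n_unmapped + rep$n_unique + rep$n_multi == nrow(probes))
  structure(rep, class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("match_report:", nrow(x$status), "probes —",
      x$n_unique, "unique,", x$n_multi, "multi-mapping,",
      x$n_unmapped, "unmapped\n")
  invisible(x)
}

#' Matches of uniquely mapping probes
#' @param report a `match_report` from [classify_matches()].
#' @return the subset of the match table belonging to unique probes.
#' @export
unique_matches <- function(report) {
  uniq <- report$status$probe_id[report$status$status == "unique"]
  report$matches[report$matches$probe_id %in% uniq, , drop = FALSE]
}
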