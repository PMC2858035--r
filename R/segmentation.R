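#' Parameters of the dTR segmentation algorithm
#'
#' Defaults are the published operating point: probes qualify when their
#' absolute log2 signal difference exceeds 0.8; qualifying probes less
#' than 60 nt apart (about three tiling probes) are clustered; only
#' regions spanning more than 180 nt whose members average above the
#' threshold are kept; surviving regions closer than 120 nt are fused.
#'
#' @param min_probe_diff log2 difference threshold for a probe to qualify
#'   and for the region mean filter (default 0.8).
#' @param cluster_gap maximum gap in nt (exclusive) between consecutive
#'   qualifying probes within one cluster (default 60).
#' @param min_region_len minimum region span in nt (exclusive) (default
#'   180).
#' @param fuse_gap regions closer than this many nt are fused (default
#'   120); must be at least `cluster_gap`.
#' @param mean_over `"selected"` (region mean over the qualifying member
#'   probes, the reading consistent with an algorithm that only ever
#'   includes above-threshold probes) or `"spanned"` (mean over every
#'   track probe inside the region boundaries).
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_probe_diff = 0.8, cluster_gap = 60L,
                                min_region_len = 180L, fuse_gap = 120L,
                                mean_over = c("selected", "spanned")) {
  if (min_probe_diff <= 0 || cluster_gap <= 0 || min_region_len <= 0 ||
      fuse_gap <= 0)
    stop("all segmentation parameters must be positive")
  if (fuse_gap < cluster_gap) stop("fuse_gap must be >= cluster_gap")
  structure(list(min_probe_diff = min_probe_diff,
                 cluster_gap = as.integer(cluster_gap),
                 min_region_len = as.integer(min_region_len),
                 fuse_gap = as.integer(fuse_gap),
                 mean_over = match.arg(mean_over)),
            class = "segmentation_params")
}

.validate_track <- function(track) {
  req <- c("chrom", "strand", "start", "end", "log2_diff")
  if (!all(req %in% names(track)))
    stop("track needs columns: ", paste(req, collapse = ", "))
  for (key in split(seq_len(nrow(track)),
                    paste(track$chrom, track$strand))) {
    if (is.unsorted(track$start[key]))
      stop("track positions must be sorted within each (chrom, strand)")
  }
  invisible(track)
}

#' Build strand-specific differential-signal tracks
#'
#' For every uniquely mapping probe, the log2 differential signal is the
#' mean log2 intensity over treated arrays minus the mean over control
#' arrays, computed on the quantile-normalized matrix. Probes are placed
#' at their genomic match position on their match strand; probes without
#' a genomic match are skipped (count in attribute `n_skipped`).
#'
#' @param normalized quantile-normalized intensity matrix (raw scale).
#' @param matches unique-in-genome match table.
#' @param design `data.frame` with columns `array_id`, `condition`.
#' @param control,treated the two condition labels.
#' @return `data.frame` with columns `probe_id`, `chrom`, `strand`,
#'   `start`, `end`, `log2_diff`, sorted by chromosome, strand, start.
#' @export
build_diff_track <- function(normalized, matches, design,
                             control = "control", treated = "treated") {
  grp <- .split_conditions(design, control, treated)
  if (length(grp$control) < 1L || length(grp$treated) < 1L)
    stop("each condition needs at least one replicate")
  keep <- matches$probe_id %in% rownames(normalized)
  n_skipped <- sum(!rownames(normalized) %in% matches$probe_id)
  m <- matches[keep, , drop = FALSE]
  lg <- log2(normalized[m$probe_id, , drop = FALSE])
  diff <- rowMeans(lg[, grp$treated, drop = FALSE]) -
    rowMeans(lg[, grp$control, drop = FALSE])
  out <- data.frame(probe_id = m$probe_id, chrom = m$chrom,
                    strand = m$strand, start = m$start, end = m$end,
                    log2_diff = unname(diff), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, match(out$strand, c("+", "-")), out$start,
                   out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# cluster/filter/fuse for one (chrom, strand, direction) probe subset;
# sel is sorted by start and contains only qualifying probes.
.segment_one <- function(sel, sub, params, direction) {
  if (nrow(sel) == 0L) return(NULL)
  gap <- sel$start[-1L] - sel$end[-nrow(sel)]
  cl <- cumsum(c(TRUE, gap >= params$cluster_gap))
  regions <- lapply(split(seq_len(nrow(sel)), cl), function(i) {
    list(start = sel$start[i[1L]], end = max(sel$end[i]),
         probes = sel$probe_id[i], diffs = sel$log2_diff[i])
  })
  rmean <- function(r) {
    if (params$mean_over == "selected") return(mean(r$diffs))
    inside <- sub$start >= r$start & sub$end <= r$end
    mean(sub$log2_diff[inside])
  }
  keep <- vapply(regions, function(r) {
    (r$end - r$start) > params$min_region_len &&
      abs(rmean(r)) > params$min_probe_diff
  }, logical(1L))
  regions <- regions[keep]
  if (length(regions) == 0L) return(NULL)
  # fuse to a fixed point; fused regions can only grow, so the length
  # filter is not re-applied
  repeat {
    if (length(regions) < 2L) break
    starts <- vapply(regions, `[[`, numeric(1L), "start")
    regions <- regions[order(starts)]
    fused <- FALSE
    i <- 1L
    out <- list()
    while (i <= length(regions)) {
      r <- regions[[i]]
      while (i < length(regions) &&
             regions[[i + 1L]]$start - r$end < params$fuse_gap) {
        nxt <- regions[[i + 1L]]
        r <- list(start = min(r$start, nxt$start), end = max(r$end, nxt$end),
                  probes = c(r$probes, nxt$probes),
                  diffs = c(r$diffs, nxt$diffs))
        i <- i + 1L
        fused <- TRUE
      }
      out[[length(out) + 1L]] <- r
      i <- i + 1L
    }
    regions <- out
    if (!fused) break
  }
  do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = sel$chrom[1L], strand = sel$strand[1L],
               start = r$start, end = r$end, direction = direction,
               mean_diff = rmean(r), n_probes = length(r$probes),
               probes = I(list(r$probes)), stringsAsFactors = FALSE)
  }))
}

#' Segment a differential-signal track into dTRs
#'
#' Runs separately per (chromosome, strand) and per direction
#' (up: `log2_diff > min_probe_diff`; down: `log2_diff <
#' -min_probe_diff`): qualifying probes are selected; consecutive
#' qualifying probes whose gap (next start minus previous end) is below
#' `cluster_gap` are clustered; region bounds run from the first member's
#' start to the last member's end; regions are kept when their span
#' exceeds `min_region_len` and the absolute mean log2 difference of
#' their members exceeds `min_probe_diff`; surviving regions closer than
#' `fuse_gap` are fused iteratively to a fixed point, with the mean
#' recomputed over the union of members. Gaps use half-open arithmetic
#' and all comparisons are strict, as published.
#'
#' @param track differential-signal track from [build_diff_track()].
#' @param params a [segmentation_params()] object.
#' @return `data.frame` with columns `dtr_id` (`NA` until [name_dtrs()]),
#'   `chrom`, `strand`, `start`, `end`, `direction`, `mean_diff`,
#'   `n_probes` and a list column `probes` of member probe ids; sorted by
#'   chromosome, strand, start. Regions are pairwise disjoint within each
#'   (strand, direction).
#' @export
segment_track <- function(track, params = segmentation_params()) {
  .validate_track(track)
  res <- list()
  for (ch in unique(track$chrom)) {
    for (st in c("+", "-")) {
      sub <- track[track$chrom == ch & track$strand == st, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (dirn in c("up", "down")) {
        sel <- if (dirn == "up") {
          sub[sub$log2_diff > params$min_probe_diff, , drop = FALSE]
        } else {
          sub[sub$log2_diff < -params$min_probe_diff, , drop = FALSE]
        }
        res[[length(res) + 1L]] <- .segment_one(sel, sub, params, dirn)
      }
    }
  }
  res <- res[!vapply(res, is.null, logical(1L))]
  if (length(res) == 0L) {
    return(data.frame(dtr_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      mean_diff = numeric(0), n_probes = integer(0),
                      probes = I(list()), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- cbind(dtr_id = NA_character_, out, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, match(out$strand, c("+", "-")), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign deterministic identifiers to dTRs
#'
#' `dtr_id = "dTR" + chromosome index (1-based, in genome order) + strand
#' code (0 for "+", 1 for "-") + zero-padded 4-digit ordinal per
#' (chromosome, strand)`, e.g. the first region on the forward strand of
#' the first chromosome is `dTR100001`. Renaming is stable across reruns
#' on identical input.
#'
#' @param dtrs dTR table from [segment_track()].
#' @param chrom_names ordered chromosome names of the genome.
#' @return the dTR table with `dtr_id` filled in.
#' @export
name_dtrs <- function(dtrs, chrom_names) {
  if (nrow(dtrs) == 0L) return(dtrs)
  ci <- match(dtrs$chrom, chrom_names)
  if (anyNA(ci)) stop("dTR on a chromosome absent from chrom_names")
  sc <- ifelse(dtrs$strand == "+", 0L, 1L)
  ord <- order(ci, sc, dtrs$start)
  ordinal <- integer(nrow(dtrs))
  key <- paste(ci, sc)
  ordinal[ord] <- stats::ave(seq_along(ord), key[ord], FUN = seq_along)
  dtrs$dtr_id <- sprintf("dTR%d%d%04d", ci, sc, ordinal)
  dtrs
}

#' Build a dTR probeset collection (dTR CDF)
#'
#' For every dTR, the probeset contains every uniquely mapping probe whose
#' interval is fully contained in the dTR on the dTR's strand; regions
#' with fewer than `min_probes_per_set` probes are dropped, mirroring the
#' gene-CDF rule. Expression of the resulting probesets is then
#' quantified with the standard machinery ([rma()],
#' [differential_expression()]).
#'
#' @param dtrs named dTR table ([segment_track()] + [name_dtrs()]).
#' @param matches unique-in-genome match table.
#' @param params a [pipeline_params()] object (only `min_probes_per_set`
#'   is used).
#' @param probes optional probe table supplying array `x`, `y`
#'   coordinates.
#' @return probe-map `data.frame` keyed by `dtr_id`.
#' @export
dtr_cdf <- function(dtrs, matches, params = pipeline_params(),
                    probes = NULL) {
  rows <- lapply(seq_len(nrow(dtrs)), function(i) {
    d <- dtrs[i, ]
    hit <- matches$chrom == d$chrom & matches$strand == d$strand &
      matches$start >= d$start & matches$end <= d$end
    if (sum(hit) < params$min_probes_per_set) return(NULL)
    m <- matches[hit, , drop = FALSE]
    data.frame(probeset_id = d$dtr_id, probe_id = m$probe_id,
               x = NA_integer_, y = NA_integer_, chrom = m$chrom,
               start = m$start, end = m$end, strand = m$strand,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(probeset_id = character(0), probe_id = character(0),
                      x = integer(0), y = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  if (!is.null(probes)) {
    idx <- match(out$probe_id, probes$probe_id)
    out$x <- probes$x[idx]
    out$y <- probes$y[idx]
  }
  out <- out[order(out$probeset_id, out$chrom, out$start, out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify how dTRs overlap annotated ORFs
#'
#' Geometric, strand-agnostic comparison against each gene's ORF span
#' (first to last exon). Classes and their conventional labels: `none`
#' (no overlap), `orf_within_dtr` (`> name <`, the whole ORF inside the
#' dTR), `dtr_within_orf` (`< name >`, the whole dTR inside the ORF),
#' `partial_start` (`<name`, the ORF's right end inside the dTR, its left
#' end beyond the dTR start) and `partial_end` (`name>`, the ORF's left
#' end inside the dTR, its right end beyond the dTR end). A dTR
#' overlapping several genes produces one record per gene.
#'
#' @param dtrs dTR table.
#' @param features exon table from [read_annotation()].
#' @return `data.frame` with one row per (dTR, overlapping gene) — plus
#'   one `none` row for dTRs without overlap — and columns `dtr_id`,
#'   `gene_id`, `overlap_class`, `label`.
#' @export
classify_overlap <- function(dtrs, features) {
  spans <- do.call(rbind, lapply(split(features, features$gene_id),
                                 function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rows <- lapply(seq_len(nrow(dtrs)), function(i) {
    d <- dtrs[i, ]
    id <- if (!is.null(d$dtr_id) && !is.na(d$dtr_id)) d$dtr_id else
      sprintf("region%04d", i)
    ov <- spans[spans$chrom == d$chrom & spans$start < d$end &
                  spans$end > d$start, , drop = FALSE]
    if (nrow(ov) == 0L) {
      return(data.frame(dtr_id = id, gene_id = NA_character_,
                        overlap_class = "none", label = "",
                        stringsAsFactors = FALSE))
    }
    cls <- character(nrow(ov))
    lab <- character(nrow(ov))
    for (j in seq_len(nrow(ov))) {
      g <- ov[j, ]
      if (g$start >= d$start && g$end <= d$end) {
        cls[j] <- "orf_within_dtr"; lab[j] <- sprintf("> %s <", g$gene_id)
      } else if (d$start >= g$start && d$end <= g$end) {
        cls[j] <- "dtr_within_orf"; lab[j] <- sprintf("< %s >", g$gene_id)
      } else if (g$start < d$start) {
        cls[j] <- "partial_start"; lab[j] <- sprintf("<%s", g$gene_id)
      } else {
        cls[j] <- "partial_end"; lab[j] <- sprintf("%s>", g$gene_id)
      }
    }
    data.frame(dtr_id = id, gene_id = ov$gene_id, overlap_class = cls,
               label = lab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse overlap records into one label per dTR
#' @param overlaps table from [classify_overlap()].
#' @return named character vector, one (possibly empty) label per dTR id.
#' @export
overlap_labels <- function(overlaps) {
  vapply(split(overlaps$label, overlaps$dtr_id),
         function(l) paste(l[nzchar(l)], collapse = "; "), character(1L))
}
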