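# Independent oracles and fixture builders used across the suite.

# Both-strand exact search via Biostrings (independent of the package's
# Karp-Rabin path). Returns the same columns and sort order as
# karp_rabin_search().
oracle_search <- function(patterns, genome) {
  rc <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(patterns)))), names(patterns))
  rows <- list()
  # enumerate every genome window of each pattern width and compare the
  # strings directly; duplicate pattern sequences each get their matches
  scan_naive <- function(pats, st) {
    w <- nchar(pats[[1L]])
    grp <- split(names(pats), unname(pats))
    useq <- names(grp)
    for (ci in seq_along(genome$sequences)) {
      s <- genome$sequences[[ci]]
      n <- nchar(s)
      if (n < w) next
      starts <- seq_len(n - w + 1L)
      win <- substring(s, starts, starts + w - 1L)
      pi <- match(win, useq)
      hit <- which(!is.na(pi))
      if (length(hit) == 0L) next
      ids <- grp[pi[hit]]
      nrep <- lengths(ids)
      rows[[length(rows) + 1L]] <<- data.frame(
        probe_id = unlist(ids, use.names = FALSE),
        chrom = names(genome$sequences)[ci],
        start = rep(hit - 1L, nrep), end = rep(hit - 1L + w, nrep),
        strand = st, stringsAsFactors = FALSE)
    }
  }
  widths <- nchar(patterns)
  for (w in unique(widths)) {
    scan_naive(patterns[widths == w], "+")
    scan_naive(rc[widths == w], "-")
  }
  if (length(rows) == 0L) {
    return(data.frame(probe_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
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

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random genome + probe set with a mix of planted (guaranteed-hit) and
# random probes
random_search_instance <- function(max_genome = 50000L, max_probes = 2000L,
                                   probe_len = 25L) {
  nchrom <- sample(1:3, 1L)
  lens <- sample(500:max_genome, nchrom, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1L))
  names(seqs) <- sprintf("chr%d", seq_len(nchrom))
  g <- genome_seq(seqs)
  np <- sample(20:max_probes, 1L)
  n_planted <- floor(np * 0.7)
  ci <- sample(nchrom, n_planted, replace = TRUE)
  smax <- nchar(seqs)[ci] - probe_len
  s <- floor(runif(n_planted) * smax)
  planted <- substring(seqs[ci], s + 1L, s + probe_len)
  flip <- runif(n_planted) < 0.5
  if (any(flip)) {
    planted[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(planted[flip])))
  }
  n_rand <- np - n_planted
  rand <- do.call(paste0, as.data.frame(
    matrix(sample(c("A", "C", "G", "T"), n_rand * probe_len,
                  replace = TRUE), n_rand), stringsAsFactors = FALSE))
  pats <- c(planted, rand)
  names(pats) <- sprintf("p%04d", seq_along(pats))
  list(genome = g, patterns = pats)
}

# Brute-force dTR segmentation written as an explicit enumeration of the
# published rules, structurally independent of segment_track().
oracle_segment <- function(track, params) {
  out <- NULL
  groups <- unique(track[, c("chrom", "strand")])
  for (gi in seq_len(nrow(groups))) {
    sub <- track[track$chrom == groups$chrom[gi] &
                   track$strand == groups$strand[gi], , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    for (dirn in c("up", "down")) {
      qual <- if (dirn == "up") sub$log2_diff > params$min_probe_diff
              else sub$log2_diff < -params$min_probe_diff
      idx <- which(qual)
      if (length(idx) == 0L) next
      # step 2: cluster consecutive qualifying probes
      clusters <- list()
      cur <- idx[1L]
      if (length(idx) > 1L) {
        for (k in 2L:length(idx)) {
          i <- idx[k]
          prev <- cur[length(cur)]
          if (sub$start[i] - sub$end[prev] < params$cluster_gap) {
            cur <- c(cur, i)
          } else {
            clusters[[length(clusters) + 1L]] <- cur
            cur <- i
          }
        }
      }
      clusters[[length(clusters) + 1L]] <- cur
      # step 3: length and mean filters
      regs <- list()
      for (cl in clusters) {
        rs <- sub$start[cl[1L]]
        re <- max(sub$end[cl])
        mn <- mean(sub$log2_diff[cl])
        if ((re - rs) > params$min_region_len &&
            abs(mn) > params$min_probe_diff) {
          regs[[length(regs) + 1L]] <- list(start = rs, end = re, members = cl)
        }
      }
      # step 4: fuse to fixed point
      changed <- TRUE
      while (changed && length(regs) > 1L) {
        changed <- FALSE
        regs <- regs[order(vapply(regs, `[[`, numeric(1L), "start"))]
        for (k in seq_len(length(regs) - 1L)) {
          if (regs[[k + 1L]]$start - regs[[k]]$end < params$fuse_gap) {
            regs[[k]] <- list(start = regs[[k]]$start,
                              end = max(regs[[k]]$end, regs[[k + 1L]]$end),
                              members = c(regs[[k]]$members,
                                          regs[[k + 1L]]$members))
            regs[[k + 1L]] <- NULL
            changed <- TRUE
            break
          }
        }
      }
      for (r in regs) {
        out <- rbind(out, data.frame(
          chrom = groups$chrom[gi], strand = groups$strand[gi],
          start = r$start, end = r$end, direction = dirn,
          mean_diff = mean(sub$log2_diff[r$members]),
          n_probes = length(r$members), stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(chrom = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      direction = character(0), mean_diff = numeric(0),
                      n_probes = integer(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, match(out$strand, c("+", "-")), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# random differential-signal track on one chromosome/strand
random_track <- function(n_probes = 100L, probe_len = 25L,
                         chrom = "chr1", strand = "+") {
  steps <- sample(c(5L, 20L, 40L, 80L, 150L, 400L), n_probes - 1L,
                  replace = TRUE, prob = c(.1, .4, .2, .15, .1, .05))
  starts <- cumsum(c(0L, steps))
  data.frame(probe_id = sprintf("t%04d", seq_len(n_probes)), chrom = chrom,
             strand = strand, start = starts, end = starts + probe_len,
             log2_diff = rnorm(n_probes, 0, 0.8), stringsAsFactors = FALSE)
}

# track with a uniform signal block planted on a null background
planted_track <- function(block_start, block_len, effect, spacing = 20L,
                          probe_len = 25L, n_flank = 40L, noise_sd = 0.2,
                          chrom = "chr1", strand = "+") {
  total_len <- block_start + block_len + n_flank * spacing
  starts <- seq(0L, total_len, by = spacing)
  inside <- starts >= block_start & (starts + probe_len) <= block_start + block_len
  diff <- rnorm(length(starts), ifelse(inside, effect, 0), noise_sd)
  data.frame(probe_id = sprintf("t%04d", seq_along(starts)), chrom = chrom,
             strand = strand, start = starts, end = starts + probe_len,
             log2_diff = diff, stringsAsFactors = FALSE)
}

# independent step-by-step Tukey median-polish sweep (plain loops)
oracle_medpolish <- function(x, eps = 0.01, maxiter = 10L) {
  nr <- nrow(x); nc <- ncol(x)
  t0 <- 0; re <- rep(0, nr); ce <- rep(0, nc); z <- x
  for (iter in seq_len(maxiter)) {
    rd <- numeric(nr)
    for (i in seq_len(nr)) rd[i] <- median(z[i, ])
    for (i in seq_len(nr)) z[i, ] <- z[i, ] - rd[i]
    re <- re + rd
    d <- median(ce); ce <- ce - d; t0 <- t0 + d
    cd <- numeric(nc)
    for (j in seq_len(nc)) cd[j] <- median(z[, j])
    for (j in seq_len(nc)) z[, j] <- z[, j] - cd[j]
    ce <- ce + cd
    d <- median(re); re <- re - d; t0 <- t0 + d
    if (max(abs(c(rd, cd))) < eps) break
  }
  list(overall = t0, row = re, col = ce, residuals = z, summary = t0 + ce)
}

# tiny GFF3 written by hand for reader tests
write_test_gff3 <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

expect_same_matches <- function(a, b) {
  same <- nrow(a) == nrow(b) &&
    all(a$probe_id == b$probe_id) && all(a$chrom == b$chrom) &&
    all(a$start == b$start) && all(a$end == b$end) &&
    all(a$strand == b$strand)
  if (!same) {
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a[, c("probe_id", "chrom", "start", "end", "strand")],
                 b[, c("probe_id", "chrom", "start", "end", "strand")])
  }
  expect_true(same)
}
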