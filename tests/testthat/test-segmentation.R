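uniform_track <- function(starts, diff, probe_len = 25L, chrom = "chr1",
                          strand = "+") {
  data.frame(probe_id = sprintf("p%03d", seq_along(starts)), chrom = chrom,
             strand = strand, start = as.integer(starts),
             end = as.integer(starts) + probe_len,
             log2_diff = rep_len(diff, length(starts)),
             stringsAsFactors = FALSE)
}

test_that("differential track: ratios, strand routing, skipped probes", {
  matches <- data.frame(probe_id = c("pp", "pm"), chrom = "chr1",
                        start = c(100L, 100L), end = c(125L, 125L),
                        strand = c("+", "-"), stringsAsFactors = FALSE)
  design <- data.frame(array_id = c("c1", "c2", "t1", "t2"),
                       condition = rep(c("control", "treated"), each = 2L))
  m <- matrix(c(100, 100, 400, 400,   # pp: 4-fold up
                200, 200, 200, 200),  # pm: unchanged
              nrow = 2, byrow = TRUE,
              dimnames = list(c("pp", "pm"), design$array_id))
  track <- build_diff_track(m, matches, design)
  expect_equal(track$log2_diff[track$probe_id == "pp"], 2)
  expect_equal(track$log2_diff[track$probe_id == "pm"], 0)
  # same locus, different strands -> different track rows by strand
  expect_equal(track$strand[track$probe_id == "pp"], "+")
  expect_equal(track$strand[track$probe_id == "pm"], "-")

  m2 <- rbind(m, orphan = c(50, 50, 50, 50))
  track2 <- build_diff_track(m2, matches, design)
  expect_equal(attr(track2, "n_skipped"), 1L)
  expect_false("orphan" %in% track2$probe_id)
})

test_that("hand-worked segmentation examples behave exactly as specified", {
  params <- segmentation_params()

  # 11 probes every 20 nt, all at +1: one up-region [0,225), mean 1
  t1 <- uniform_track(seq(0L, 200L, by = 20L), 1.0)
  d1 <- segment_track(t1, params)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$start, 0L)
  expect_equal(d1$end, 225L)
  expect_equal(d1$direction, "up")
  expect_equal(d1$mean_diff, 1.0)
  expect_equal(d1$n_probes, 11L)

  # 7 probes spanning 145 nt <= 180: rejected by the length rule
  t2 <- uniform_track(seq(0L, 120L, by = 20L), 1.0)
  expect_equal(nrow(segment_track(t2, params)), 0L)

  # two qualifying clusters separated by a 100-nt gap: fused into one dTR
  starts3 <- c(seq(0L, 200L, by = 20L), seq(325L, 525L, by = 20L))
  t3 <- uniform_track(starts3, 1.0)
  d3 <- segment_track(t3, params)
  expect_equal(nrow(d3), 1L)
  expect_equal(d3$start, 0L)
  expect_equal(d3$end, 550L)
  expect_equal(d3$n_probes, 22L)

  # all probes below threshold: nothing
  t4 <- uniform_track(seq(0L, 400L, by = 20L), 0.5)
  expect_equal(nrow(segment_track(t4, params)), 0L)

  # same layout with negative signal appears as a down-region
  t5 <- uniform_track(seq(0L, 200L, by = 20L), -1.0)
  d5 <- segment_track(t5, params)
  expect_equal(d5$direction, "down")
  expect_equal(d5$mean_diff, -1.0)
})

test_that("a 60-nt probe gap splits clusters; smaller gaps do not", {
  params <- segmentation_params()
  # gap = next.start - prev.end; 59 clusters together, 60 splits
  joined <- uniform_track(c(seq(0L, 200L, by = 20L),
                            seq(225L + 59L, 225L + 59L + 200L, by = 20L)), 1.0)
  expect_equal(nrow(segment_track(joined, params)), 1L)
  split_starts <- c(seq(0L, 200L, by = 20L),
                    seq(225L + 60L, 225L + 60L + 200L, by = 20L))
  split <- uniform_track(split_starts, 1.0)
  d <- segment_track(split, params)
  # the two clusters are then refused (gap 60 < 120): fused back into one
  expect_equal(nrow(d), 1L)
  # with a gap in [120, ...) they stay separate
  far_starts <- c(seq(0L, 200L, by = 20L),
                  seq(225L + 120L, 225L + 120L + 200L, by = 20L))
  far <- segment_track(uniform_track(far_starts, 1.0), params)
  expect_equal(nrow(far), 2L)
})

test_that("segmentation equals the brute-force oracle on random tracks", {
  set.seed(61)
  params <- segmentation_params()
  for (i in 1:30) {
    track <- random_track(n_probes = sample(20:200, 1L),
                          strand = sample(c("+", "-"), 1L))
    mine <- segment_track(track, params)
    orac <- oracle_segment(track, params)
    expect_equal(mine[, colnames(orac)], orac, ignore_attr = TRUE)
  }
})

test_that("up and down regions are segmented independently, never fused", {
  starts <- seq(0L, 420L, by = 20L)
  diffs <- c(rep(1.5, 11L), rep(-1.5, 11L))
  tr <- uniform_track(starts, 0); tr$log2_diff <- diffs
  d <- segment_track(tr, segmentation_params())
  expect_equal(nrow(d), 2L)
  expect_setequal(d$direction, c("up", "down"))
})

test_that("strands are segmented separately", {
  plus <- uniform_track(seq(0L, 200L, by = 20L), 1.0, strand = "+")
  minus <- uniform_track(seq(0L, 200L, by = 20L), 1.0, strand = "-")
  both <- rbind(plus, minus)
  both <- both[order(both$chrom, match(both$strand, c("+", "-")), both$start), ]
  d <- segment_track(both, segmentation_params())
  expect_equal(nrow(d), 2L)
  expect_setequal(d$strand, c("+", "-"))
})

test_that("planted blocks are recovered with tight boundaries, nulls stay empty", {
  set.seed(71)
  params <- segmentation_params()
  hits <- 0L
  for (i in 1:25) {
    blk_len <- sample(250:800, 1L)
    blk_start <- sample(300:1500, 1L)
    tr <- planted_track(blk_start, blk_len, effect = 1.5)
    d <- segment_track(tr, params)
    ov <- d[d$start < blk_start + blk_len & d$end > blk_start, , drop = FALSE]
    expect_equal(nrow(ov), 1L)
    expect_lte(abs(ov$start - blk_start), 20L)
    expect_lte(abs(ov$end - (blk_start + blk_len)), 25L + 20L)
    hits <- hits + nrow(ov)
  }
  expect_equal(hits, 25L)
  # null tracks: false dTRs in fewer than 5% of seeds
  false_pos <- 0L
  for (i in 1:100) {
    tr <- planted_track(600L, 0L, effect = 0)
    if (nrow(segment_track(tr, params)) > 0L) false_pos <- false_pos + 1L
  }
  expect_lt(false_pos, 5L)
})

test_that("dTR ids follow the chrom/strand/ordinal scheme and are stable", {
  dtrs <- data.frame(
    dtr_id = NA_character_,
    chrom = c("chrI", "chrI", "chrI", "chrII"),
    strand = c("+", "-", "-", "+"),
    start = c(100L, 50L, 900L, 10L), end = c(400L, 350L, 1200L, 310L),
    direction = "up", mean_diff = 1, n_probes = 5L,
    stringsAsFactors = FALSE)
  named <- name_dtrs(dtrs, c("chrI", "chrII"))
  expect_equal(named$dtr_id,
               c("dTR100001", "dTR110001", "dTR110002", "dTR200001"))
  # 92nd region on chrI minus formats as dTR110092
  many <- data.frame(dtr_id = NA_character_, chrom = "chrI", strand = "-",
                     start = seq(0L, by = 1000L, length.out = 92L),
                     end = seq(300L, by = 1000L, length.out = 92L),
                     direction = "up", mean_diff = 1, n_probes = 4L,
                     stringsAsFactors = FALSE)
  expect_equal(name_dtrs(many, c("chrI"))$dtr_id[92L], "dTR110092")
  expect_identical(name_dtrs(dtrs, c("chrI", "chrII")), named)
})

test_that("dTR CDF keeps contained same-strand probes and the >=4 rule", {
  matches <- data.frame(
    probe_id = sprintf("m%02d", 1:14),
    chrom = "chr1",
    start = c(seq(0L, 200L, by = 20L), 50L, 1000L, 1040L),
    end = c(seq(0L, 200L, by = 20L), 50L, 1000L, 1040L) + 25L,
    strand = c(rep("+", 11L), "-", "+", "+"),
    stringsAsFactors = FALSE)
  dtrs <- data.frame(dtr_id = c("dTR100001", "dTR100002"), chrom = "chr1",
                     strand = "+", start = c(0L, 990L), end = c(225L, 1100L),
                     direction = "up", mean_diff = 1.2, n_probes = c(11L, 2L),
                     stringsAsFactors = FALSE)
  cdf <- dtr_cdf(dtrs, matches)
  # 11 contained "+" probes; the "-" probe at 50 is excluded;
  # the 2-probe region is dropped by the minimum-probe rule
  expect_equal(unique(cdf$probeset_id), "dTR100001")
  expect_equal(nrow(cdf), 11L)
  expect_false("m12" %in% cdf$probe_id)
  # a probe straddling the boundary is not contained
  edge <- dtrs[1L, ]; edge$end <- 220L
  cdf2 <- dtr_cdf(edge, matches)
  expect_equal(nrow(cdf2), 10L)
})

test_that("overlap classification covers the symbol taxonomy", {
  feats <- data.frame(gene_id = c("inner", "outer", "left", "right"),
                      chrom = "chr1", strand = "+",
                      start = c(1200L, 900L, 800L, 1900L),
                      end = c(1800L, 2100L, 1100L, 2200L),
                      stringsAsFactors = FALSE)
  dtr <- data.frame(dtr_id = "dTR100001", chrom = "chr1", strand = "+",
                    start = 1000L, end = 2000L, direction = "up",
                    mean_diff = 1, n_probes = 10L, stringsAsFactors = FALSE)
  ov <- classify_overlap(dtr, feats)
  expect_equal(nrow(ov), 4L)  # one record per overlapping gene
  get <- function(g) ov$overlap_class[ov$gene_id == g]
  expect_equal(get("inner"), "orf_within_dtr")
  expect_equal(get("outer"), "dtr_within_orf")
  expect_equal(get("left"), "partial_start")
  expect_equal(get("right"), "partial_end")
  expect_equal(ov$label[ov$gene_id == "inner"], "> inner <")
  expect_equal(ov$label[ov$gene_id == "outer"], "< outer >")
  expect_equal(ov$label[ov$gene_id == "left"], "<left")
  expect_equal(ov$label[ov$gene_id == "right"], "right>")

  # no overlap at all
  far <- dtr; far$start <- 5000L; far$end <- 6000L
  ov2 <- classify_overlap(far, feats)
  expect_equal(ov2$overlap_class, "none")
  expect_true(is.na(ov2$gene_id))

  lab <- overlap_labels(ov)
  expect_match(lab[["dTR100001"]], "> inner <")
})

test_that("dTRs per strand/direction are disjoint and separated by >= fuse gap", {
  set.seed(81)
  params <- segmentation_params()
  for (i in 1:10) {
    tr <- random_track(n_probes = 150L)
    tr$log2_diff <- rnorm(150L, 0, 1.5)
    d <- segment_track(tr, params)
    for (dirn in unique(d$direction)) {
      sub <- d[d$direction == dirn, ]
      if (nrow(sub) < 2L) next
      sub <- sub[order(sub$start), ]
      gaps <- sub$start[-1L] - sub$end[-nrow(sub)]
      expect_true(all(gaps >= params$fuse_gap))
    }
  }
})

test_that("spanned-mean mode averages over sub-threshold probes too", {
  starts <- seq(0L, 200L, by = 20L)
  diffs <- rep(1.0, 11L); diffs[c(3L, 6L, 9L)] <- 0.2
  tr <- uniform_track(starts, 0); tr$log2_diff <- diffs
  sel <- segment_track(tr, segmentation_params(mean_over = "selected"))
  expect_equal(sel$mean_diff, 1.0)
  spn <- segment_track(tr, segmentation_params(mean_over = "spanned"))
  if (nrow(spn) > 0L) {
    expect_equal(spn$mean_diff, mean(diffs))
  } else {
    # the diluted mean fell below the threshold and the region is rejected
    expect_lt(mean(diffs), 0.8)
  }
})
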