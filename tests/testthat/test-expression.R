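test_that("background adjustment: validation, constancy, monotonicity", {
  expect_error(background_adjust(matrix(c(1, -2, 3, 4), 2)), "positive")
  # constant array passes through unchanged
  m <- matrix(100, 50, 2)
  expect_equal(background_adjust(m), m)
  # monotone and strictly positive on random arrays
  set.seed(4)
  x <- rexp(5000, 1 / 300) + rnorm(5000, 80, 15)
  x[x <= 0] <- 0.5
  adj <- background_adjust(matrix(x, ncol = 1))[, 1L]
  expect_true(all(adj > 0))
  ord <- order(x)
  expect_true(all(diff(adj[ord]) >= -1e-9))
})

test_that("background adjustment recovers the planted signal mean", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    n <- 50000
    obs <- rexp(n, rate = 1 / 200) + rnorm(n, 100, 20)
    obs[obs <= 0] <- 0.1
    adj <- background_adjust(matrix(obs, ncol = 1))
    expect_lt(abs(mean(adj) - 200) / 200, 0.10)
  }
})

test_that("quantile normalization: hand example, identity, idempotence", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical arrays unchanged; single array unchanged
  m2 <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m2), m2)
  m3 <- matrix(c(5, 1, 9), dimnames = list(NULL, "a"))
  expect_equal(quantile_normalize(m3), m3)
  # idempotence and identical sorted columns on random data
  set.seed(8)
  r <- matrix(rexp(600), 100, 6)
  q1 <- quantile_normalize(r)
  expect_equal(quantile_normalize(q1), q1)
  sorted <- apply(q1, 2L, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1L])
  expect_equal(diff(range(colMeans(q1))), 0)
})

test_that("median polish: additive matrices are recovered exactly", {
  r <- c(0.5, -1, 2)
  cc <- c(10, 11, 12, 13)
  x <- outer(r, cc, "+")
  mp <- median_polish(x)
  expect_equal(max(abs(mp$residuals)), 0)
  # summaries recover column values up to the common overall split
  expect_equal(unname(mp$summary), cc + median(r))
  expect_equal(diff(mp$summary), diff(cc))
  # 1x1 matrix
  expect_equal(unname(median_polish(matrix(7.5))$summary), 7.5)
})

test_that("median polish agrees with an independent sweep oracle", {
  set.seed(12)
  for (rep in 1:20) {
    nr <- sample(2:4, 1L)
    nc <- sample(2:4, 1L)
    x <- matrix(sample(seq(0, 5, by = 0.5), nr * nc, replace = TRUE), nr, nc)
    x[sample(nr * nc, 1L)] <- 20  # planted outlier
    mine <- median_polish(x)
    orac <- oracle_medpolish(x)
    expect_equal(mine$summary, orac$summary, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(mine$residuals, orac$residuals, tolerance = 1e-12)
  }
})

test_that("median polish residual rows/columns have median near zero", {
  set.seed(13)
  x <- matrix(rnorm(40, 8, 1), 8, 5)
  mp <- median_polish(x, eps = 1e-6, maxiter = 50L)
  expect_lt(max(abs(apply(mp$residuals, 1L, median))), 1e-3)
  expect_lt(max(abs(apply(mp$residuals, 2L, median))), 1e-3)
})

simple_probe_map <- function(ids, probes_per_set = 5L) {
  do.call(rbind, lapply(ids, function(ps) {
    data.frame(probeset_id = ps,
               probe_id = sprintf("%s_p%d", ps, seq_len(probes_per_set)),
               x = 0L, y = 0L, chrom = "chr1",
               start = seq_len(probes_per_set), end = seq_len(probes_per_set) + 25L,
               strand = "+", stringsAsFactors = FALSE)
  }))
}

test_that("summarization reproduces exact and planted expression", {
  pm <- simple_probe_map("g1")
  m <- matrix(2^6, 5, 3, dimnames = list(pm$probe_id, c("a1", "a2", "a3")))
  expr <- summarize_probesets(pm, m)
  expect_equal(unname(expr["g1", ]), rep(6, 3))

  # planted 2-fold increase under multiplicative noise sigma = 0.1
  set.seed(19)
  pm2 <- simple_probe_map(c("up2x", "flat"), probes_per_set = 30L)
  arrays <- c("control_1", "control_2", "control_3",
              "treated_1", "treated_2", "treated_3")
  base <- rnorm(60, 9, 0.4)
  m2 <- sapply(arrays, function(a) {
    eff <- ifelse(grepl("treated", a) & grepl("up2x", pm2$probe_id), 1, 0)
    2^(base + eff + rnorm(60, 0, 0.1))
  })
  rownames(m2) <- pm2$probe_id
  expr2 <- summarize_probesets(pm2, m2)
  d <- mean(expr2["up2x", 4:6]) - mean(expr2["up2x", 1:3])
  expect_lt(abs(d - 1), 0.05)
  d0 <- mean(expr2["flat", 4:6]) - mean(expr2["flat", 1:3])
  expect_lt(abs(d0), 0.05)

  # probeset order follows the probe map; missing probes are fatal
  expect_equal(rownames(expr2), c("up2x", "flat"))
  expect_error(summarize_probesets(pm2, m2[-1L, ]), "up2x")
})

test_that("differential expression: ratios, p-values, degenerate designs", {
  pm <- simple_probe_map("g1")
  design <- data.frame(array_id = c("c1", "c2", "t1", "t2"),
                       condition = rep(c("control", "treated"), each = 2L))
  expr <- matrix(c(5, 5.1, 5.05, 4.95), 1,
                 dimnames = list("g1", design$array_id))
  de <- differential_expression(expr, design)
  expect_equal(de$log2_ratio, mean(c(5.05, 4.95)) - mean(c(5, 5.1)))
  expect_true(de$p_value >= 0 && de$p_value <= 1)

  # identical conditions: ratio 0
  expr0 <- matrix(c(4, 4, 4, 4), 1, dimnames = list("g1", design$array_id))
  expect_equal(differential_expression(expr0, design)$log2_ratio, 0)

  # single replicate per condition: p missing, ratio still defined
  d1 <- data.frame(array_id = c("c1", "t1"),
                   condition = c("control", "treated"))
  e1 <- matrix(c(4, 6), 1, dimnames = list("g1", c("c1", "t1")))
  de1 <- differential_expression(e1, d1)
  expect_equal(de1$log2_ratio, 2)
  expect_true(is.na(de1$p_value))

  # more than two conditions is an error
  d3 <- data.frame(array_id = c("a", "b", "c"),
                   condition = c("x", "y", "z"))
  expect_error(differential_expression(expr, d3), "two conditions")
})

test_that("p-values stay in [0,1] on random expression data", {
  set.seed(23)
  design <- data.frame(array_id = sprintf("a%d", 1:6),
                       condition = rep(c("control", "treated"), each = 3L))
  expr <- matrix(rnorm(300, 8), 50, 6,
                 dimnames = list(sprintf("g%02d", 1:50), design$array_id))
  de <- differential_expression(expr, design)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1, na.rm = TRUE))
})

test_that("platform correlation: identity, negation, shared-id handling", {
  a <- data.frame(probeset_id = sprintf("g%d", 1:10), n_probes = 5L,
                  log2_ratio = rnorm(10), p_value = NA_real_)
  expect_equal(platform_correlation(a, a)$r, 1.0)
  b <- a; b$log2_ratio <- -a$log2_ratio
  expect_equal(platform_correlation(a, b)$r, -1.0)
  expect_equal(platform_correlation(a, b[1:5, ])$n_shared, 5L)
  expect_error(platform_correlation(a, a[1L, ]), "fewer than two")
})

test_that("two CDF variants over one simulation correlate strongly", {
  spec <- simulation_spec(seed = 88,
                          chrom_lengths = c(chrI = 60000L, chrII = 60000L),
                          n_genes = 40L, n_de_genes = 12L,
                          n_intergenic_transcripts = 0L,
                          n_antisense_transcripts = 0L, noise_sd = 0.1)
  sim <- simulate_dataset(spec)
  dense <- build_cdf(sim$probes, sim$genome, sim$features)$probesets
  # sparse variant: every third probe of each probeset
  sparse <- do.call(rbind, lapply(split(dense, dense$probeset_id), function(d)
    d[seq(1L, nrow(d), by = 3L), , drop = FALSE]))
  de_dense <- differential_expression(rma(dense, sim$intensities), sim$design)
  de_sparse <- differential_expression(rma(sparse, sim$intensities), sim$design)
  pc <- platform_correlation(de_dense, de_sparse)
  expect_gte(pc$r, 0.9)
  expect_equal(pc$n_shared, 40L)
})

test_that("scaling one condition by 2^d shifts the log2 ratio by about d", {
  set.seed(27)
  pm <- simple_probe_map(c("gA", "gB"), probes_per_set = 12L)
  design <- data.frame(array_id = c("c1", "c2", "t1", "t2"),
                       condition = rep(c("control", "treated"), each = 2L))
  m <- matrix(2^rnorm(96, 9, 0.3), 24, 4,
              dimnames = list(pm$probe_id, design$array_id))
  m_shift <- m
  sel <- grepl("gA", rownames(m))
  m_shift[sel, c("t1", "t2")] <- m_shift[sel, c("t1", "t2")] * 2^1.5
  de0 <- differential_expression(summarize_probesets(pm, m), design)
  de1 <- differential_expression(summarize_probesets(pm, m_shift), design)
  shift <- de1$log2_ratio[de1$probeset_id == "gA"] -
    de0$log2_ratio[de0$probeset_id == "gA"]
  expect_lt(abs(shift - 1.5), 0.05)
})

test_that("replicate arrays at sigma = 0.05 are nearly perfectly correlated", {
  spec <- simulation_spec(seed = 55, chrom_lengths = c(chrI = 40000L),
                          n_genes = 20L, n_de_genes = 5L,
                          n_intergenic_transcripts = 0L,
                          n_antisense_transcripts = 0L, noise_sd = 0.05)
  sim <- simulate_dataset(spec)
  lg <- log2(sim$intensities)
  expect_gt(cor(lg[, "control_1"], lg[, "control_2"]), 0.99)
  expect_gt(cor(lg[, "treated_1"], lg[, "treated_2"]), 0.99)
})
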