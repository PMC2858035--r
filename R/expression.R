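#' RMA convolution background adjustment
#'
#' Per array, observed intensities are modelled as the sum of an
#' exponential signal and normal noise (observed = signal + noise,
#' signal ~ Exp(alpha), noise ~ N(mu, sigma)). The noise mode `mu` is
#' estimated as the maximum of a kernel density estimate, `sigma` from the
#' spread of points below the mode, and `alpha` from the mean exceedance
#' above it; each intensity is then replaced by the posterior expectation
#' of the signal, a strictly positive, monotone transformation.
#'
#' @param raw numeric matrix of strictly positive intensities, probes in
#'   rows, arrays in columns.
#' @return background-adjusted matrix of the same shape.
#' @export
background_adjust <- function(raw) {
  raw <- as.matrix(raw)
  if (anyNA(raw) || any(raw <= 0))
    stop("background adjustment requires strictly positive intensities")
  out <- apply(raw, 2L, .rma_bg_one)
  dimnames(out) <- dimnames(raw)
  out
}

.rma_bg_one <- function(x) {
  if (length(x) < 2L || diff(range(x)) < .Machine$double.eps) return(x)
  p <- .rma_bg_params(x)
  a <- x - p$mu - p$alpha * p$sigma^2
  z <- a / p$sigma
  # posterior mean of the exponential signal; stays > 0 for all inputs
  a + p$sigma * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
}

# log-density of observed = Exp(alpha) signal + N(mu, sigma) noise:
#   f(o) = alpha * exp(alpha*(mu - o) + alpha^2 sigma^2 / 2)
#              * pnorm((o - mu - alpha*sigma^2) / sigma)
.expnorm_loglik <- function(par, x) {
  mu <- par[1L]; sigma <- exp(par[2L]); alpha <- exp(par[3L])
  ll <- log(alpha) + alpha * (mu - x) + alpha^2 * sigma^2 / 2 +
    pnorm((x - mu - alpha * sigma^2) / sigma, log.p = TRUE)
  if (!all(is.finite(ll))) return(-Inf)
  sum(ll)
}

.rma_bg_params <- function(x) {
  # moment-style initial values: density mode for the noise level, lower
  # tail for its spread, mean exceedance for the signal scale
  d <- density(x, kernel = "epanechnikov", n = 2^12)
  mu0 <- d$x[which.max(d$y)]
  lower <- x[x < mu0]
  if (length(lower) < 2L) lower <- x
  sigma0 <- max(sqrt(sum((lower - mu0)^2) / max(length(lower) - 1L, 1L)),
                .Machine$double.eps)
  alpha0 <- 1 / max(mean(x) - mu0 + sigma0, .Machine$double.eps)
  init <- c(mu0, log(sigma0), log(alpha0))
  fit <- tryCatch(
    stats::optim(init, .expnorm_loglik, x = x, method = "Nelder-Mead",
                 control = list(fnscale = -1, maxit = 500L)),
    error = function(e) NULL)
  par <- if (!is.null(fit) && is.finite(fit$value)) fit$par else init
  list(mu = par[1L], sigma = exp(par[2L]), alpha = exp(par[3L]))
}

#' Quantile normalization across arrays
#'
#' Forces every array to share the same empirical distribution: each
#' order statistic is replaced by its across-array mean, with ties
#' averaged. Applying the transformation twice equals applying it once.
#'
#' @param m numeric matrix, probes in rows, arrays in columns; no missing
#'   values.
#' @return quantile-normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("quantile normalization requires complete data")
  if (ncol(m) <= 1L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Tukey median polish of a probes-by-arrays log2 matrix
#'
#' Iterative row/column median sweeps until the largest absolute sweep
#' adjustment falls below `eps` or `maxiter` iterations have run. At
#' convergence the residual rows and columns have median approximately
#' zero. The per-array summary is the overall effect plus the column
#' (array) effects — the RMA expression measure.
#'
#' @param x numeric matrix (>= 1 row, >= 1 column) of log2 intensities.
#' @param eps convergence tolerance on the sweep adjustments (default
#'   0.01).
#' @param maxiter maximum number of sweep iterations (default 10).
#' @return list with `overall`, `row`, `col`, `residuals`, `summary`
#'   (= overall + col) and `iterations`.
#' @export
median_polish <- function(x, eps = 0.01, maxiter = 10L) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stop("median_polish needs a non-empty matrix")
  overall <- 0
  row_eff <- rep(0, nrow(x))
  col_eff <- rep(0, ncol(x))
  z <- x
  it <- 0L
  for (it in seq_len(maxiter)) {
    rd <- apply(z, 1L, median)
    z <- z - rd
    row_eff <- row_eff + rd
    delta <- median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cd <- apply(z, 2L, median)
    z <- sweep(z, 2L, cd)
    col_eff <- col_eff + cd
    delta <- median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    if (max(abs(c(rd, cd))) < eps) break
  }
  list(overall = overall, row = setNames(row_eff, rownames(x)),
       col = setNames(col_eff, colnames(x)), residuals = z,
       summary = setNames(overall + col_eff, colnames(x)), iterations = it)
}

#' Summarize probe intensities into probeset expression values
#'
#' For every probeset in the probe map, the probes-by-arrays submatrix is
#' log2-transformed and median-polished; the expression value of the
#' probeset on each array is the overall plus the array effect. Probeset
#' order in the output follows the probe map.
#'
#' @param probesets probe-map `data.frame` from [build_cdf()] /
#'   [read_probe_map()].
#' @param normalized background-adjusted and/or quantile-normalized
#'   intensity matrix (raw scale; the log2 transform is applied here).
#' @param eps,maxiter passed to [median_polish()].
#' @return expression matrix (probesets x arrays, log2 scale) with an
#'   `n_probes` attribute (named integer vector).
#' @export
summarize_probesets <- function(probesets, normalized, eps = 0.01,
                                maxiter = 10L) {
  ids <- unique(probesets$probeset_id)
  arrays <- colnames(normalized)
  expr <- matrix(NA_real_, length(ids), ncol(normalized),
                 dimnames = list(ids, arrays))
  n_probes <- setNames(integer(length(ids)), ids)
  for (ps in ids) {
    pid <- probesets$probe_id[probesets$probeset_id == ps]
    missing <- setdiff(pid, rownames(normalized))
    if (length(missing))
      stop("probeset ", ps, " references probes absent from the intensity ",
           "matrix: ", paste(head(missing, 5L), collapse = ", "))
    sub <- log2(normalized[pid, , drop = FALSE])
    mp <- median_polish(sub, eps = eps, maxiter = maxiter)
    expr[ps, ] <- mp$summary
    n_probes[ps] <- length(pid)
  }
  attr(expr, "n_probes") <- n_probes
  expr
}

#' Full RMA processing of an intensity matrix against a probe map
#'
#' Background adjustment (optional), quantile normalization, log2
#' transform and median-polish summarization, in that order.
#'
#' @param probesets probe-map `data.frame`.
#' @param intensities raw intensity matrix (probes x arrays, strictly
#'   positive).
#' @param background apply the convolution background adjustment first
#'   (default `TRUE`, the standard choice for gene-level CDFs).
#' @return expression matrix as from [summarize_probesets()].
#' @export
rma <- function(probesets, intensities, background = TRUE) {
  m <- if (background) background_adjust(intensities) else intensities
  m <- quantile_normalize(m)
  summarize_probesets(probesets, m)
}

.split_conditions <- function(design, control, treated) {
  conds <- unique(design$condition)
  if (length(conds) != 2L)
    stop("exactly two conditions are required, got: ",
         paste(conds, collapse = ", "))
  if (!all(c(control, treated) %in% conds))
    stop("design conditions (", paste(conds, collapse = ", "),
         ") do not match control='", control, "', treated='", treated, "'")
  list(control = design$array_id[design$condition == control],
       treated = design$array_id[design$condition == treated])
}

#' Probeset-level differential expression between two conditions
#'
#' The log2 ratio is the mean expression over treated arrays minus the
#' mean over control arrays. The p-value comes from a two-sided Welch
#' two-sample t-test on the per-array expression values; with fewer than
#' two replicates in either condition it is reported as missing.
#'
#' @param expr expression matrix from [summarize_probesets()] / [rma()].
#' @param design `data.frame` with columns `array_id`, `condition`
#'   (exactly two condition labels).
#' @param control,treated the two condition labels.
#' @return `data.frame` with columns `probeset_id`, `n_probes`,
#'   `log2_ratio`, `p_value`.
#' @export
differential_expression <- function(expr, design, control = "control",
                                    treated = "treated") {
  grp <- .split_conditions(design, control, treated)
  missing <- setdiff(c(grp$control, grp$treated), colnames(expr))
  if (length(missing))
    stop("design arrays absent from expression matrix: ",
         paste(missing, collapse = ", "))
  tv <- expr[, grp$treated, drop = FALSE]
  cv <- expr[, grp$control, drop = FALSE]
  lr <- rowMeans(tv) - rowMeans(cv)
  p <- rep(NA_real_, nrow(expr))
  if (length(grp$treated) >= 2L && length(grp$control) >= 2L) {
    for (i in seq_len(nrow(expr))) {
      p[i] <- tryCatch(t.test(tv[i, ], cv[i, ])$p.value,
                       error = function(e) NA_real_)
    }
  }
  np <- attr(expr, "n_probes")
  data.frame(probeset_id = rownames(expr),
             n_probes = if (is.null(np)) NA_integer_ else
               as.integer(np[rownames(expr)]),
             log2_ratio = unname(lr), p_value = p,
             stringsAsFactors = FALSE)
}

#' Pearson correlation of differential expression between two platforms
#'
#' @param a,b differential-expression tables from
#'   [differential_expression()] computed on two CDFs/platforms.
#' @return list with `r` (Pearson coefficient over the shared probesets'
#'   log2 ratios) and `n_shared`.
#' @export
platform_correlation <- function(a, b) {
  shared <- intersect(a$probeset_id, b$probeset_id)
  if (length(shared) < 2L)
    stop("fewer than two shared probesets between the platforms")
  r <- cor(a$log2_ratio[match(shared, a$probeset_id)],
           b$log2_ratio[match(shared, b$probeset_id)])
  list(r = r, n_shared = length(shared))
}
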