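# Drift- and Pool-seq-noise-aware candidate SNP detection.

drift_factor <- function(n_e, t) 1 - (1 - 1 / (2 * n_e))^t

sampling_term <- function(coverage, pool_size = NULL) {
  # variance inflation of a Pool-seq frequency estimate relative to the
  # population frequency, in units of p(1-p): read sampling plus (optional)
  # pool-construction sampling of 2*pool_size chromosomes
  term <- 1 / coverage
  if (!is.null(pool_size) && is.finite(pool_size)) {
    term <- term + 1 / (2 * pool_size) - 1 / (2 * pool_size * coverage)
  }
  term
}

#' Temporal effective population size from two Pool-seq samples
#'
#' Waples-style temporal method under sampling plan I, windowed. Within each
#' window the standardized variance of allele-frequency change is the
#' ratio-of-sums statistic `Fc = sum((p0 - pt)^2) / sum(pbar (1 - pbar))`
#' with `pbar = (p0 + pt)/2`. The sampling-plan-I correction subtracts the
#' read/pool sampling contribution at both time points and adds back the
#' census covariance term: `F' = Fc - samp0 - sampt + 1/census`, with the
#' per-time-point sampling term `1/C (+ 1/(2 S) - 1/(2 S C))` for coverage
#' `C` and pool size `S`. Each window yields
#' `Ne = -t / (2 log(1 - F'))`, and the reported estimate is the median
#' over windows; values are clipped to `[10, 10 * census]` with a warning.
#'
#' @param table0,tablet `sync_table`s for the early and late time point with
#'   matching sites (single sample each, or use `sample0`/`samplet`).
#' @param t Generations between the two samples.
#' @param pool_size Number of pooled individuals per sample, or `NULL` when
#'   the data were sampled directly as reads from population frequencies.
#' @param census Census population size (used for the plan-I term and the
#'   clipping bound); `NULL` drops the census term.
#' @param window Window size in bp (default 10 kb).
#' @param sample0,samplet Sample index within each table (default 1).
#' @param min_snps Minimum usable SNPs per window (default 5).
#' @return An object of class `ne_estimate`: list with `ne` (median over
#'   windows), `per_window`, `window_size`, and `method`.
#' @export
estimate_ne <- function(table0, tablet, t, pool_size = NULL, census = NULL,
                        window = 1e4, sample0 = 1, samplet = 1,
                        min_snps = 5) {
  stopifnot(inherits(table0, "sync_table"), inherits(tablet, "sync_table"))
  if (t < 1) stop("`t` must be >= 1", call. = FALSE)
  if (length(table0$pos) != length(tablet$pos) ||
      any(table0$pos != tablet$pos)) {
    stop("the two sync tables must cover matching sites", call. = FALSE)
  }
  p0 <- sync_freqs(table0)[, sample0]
  pt <- sync_freqs(tablet)[, samplet]
  c0 <- sync_coverage(table0)[, sample0]
  ct <- sync_coverage(tablet)[, samplet]
  pbar <- (p0 + pt) / 2
  usable <- pbar > 0 & pbar < 1 & c0 > 0 & ct > 0
  win <- floor(table0$pos / window)
  ne_w <- vapply(split(which(usable), win[usable]), function(idx) {
    if (length(idx) < min_snps) return(NA_real_)
    fc <- sum((p0[idx] - pt[idx])^2) / sum(pbar[idx] * (1 - pbar[idx]))
    f_corr <- fc -
      sampling_term(1 / mean(1 / c0[idx]), pool_size) -
      sampling_term(1 / mean(1 / ct[idx]), pool_size) +
      (if (is.null(census)) 0 else 1 / census)
    if (f_corr <= 0) return(Inf)           # no drift signal left
    if (f_corr >= 1) return(-t / (2 * log(1e-12)))
    -t / (2 * log(1 - f_corr))
  }, numeric(1))
  ne_w <- ne_w[!is.na(ne_w)]
  if (!length(ne_w)) {
    stop("no window with at least ", min_snps, " usable SNPs", call. = FALSE)
  }
  ne <- stats::median(ne_w)
  lo <- 10
  hi <- if (is.null(census)) Inf else 10 * census
  if (ne < lo || ne > hi) {
    warning("Ne estimate ", signif(ne, 4), " clipped to [", lo, ", ", hi, "]")
    ne <- min(max(ne, lo), hi)
  }
  structure(
    list(ne = ne, per_window = ne_w, window_size = window,
         method = "P.planI"),
    class = "ne_estimate"
  )
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat("Ne estimate (", x$method, ", ", x$window_size / 1e3, " kb windows): ",
      signif(x$ne, 5), " (", length(x$per_window), " windows)\n", sep = "")
  invisible(x)
}

#' Median Ne over a time series of samples
#'
#' Realizes the inclusion of intermediate generations: Ne is estimated for
#' every adjacent pair of time points and the estimates are combined by
#' their median.
#'
#' @param tables List of single-sample `sync_table`s, one per time point.
#' @param generations Generation of each table (same length, increasing).
#' @param ... Passed on to [estimate_ne()].
#' @return An `ne_estimate` whose `per_window` holds the per-pair medians.
#' @export
estimate_ne_series <- function(tables, generations, ...) {
  stopifnot(length(tables) == length(generations), length(tables) >= 2)
  per_pair <- vapply(seq_len(length(tables) - 1), function(i) {
    estimate_ne(tables[[i]], tables[[i + 1]],
                t = generations[i + 1] - generations[i], ...)$ne
  }, numeric(1))
  structure(
    list(ne = stats::median(per_pair), per_window = per_pair,
         window_size = NA, method = "P.planI/adjacent-pairs"),
    class = "ne_estimate"
  )
}

test_variance <- function(p0_hat, pt_hat, cov0, covt, n_e, t,
                          pool_size = NULL) {
  pbar <- (p0_hat + pt_hat) / 2
  v <- pbar * (1 - pbar) * drift_factor(n_e, t) +
    p0_hat * (1 - p0_hat) / cov0 +
    pt_hat * (1 - pt_hat) / covt
  if (!is.null(pool_size) && is.finite(pool_size)) {
    v <- v + 2 * pbar * (1 - pbar) / (2 * pool_size)
  }
  v
}

#' Drift-aware chi-squared test for one replicate
#'
#' Tests, per SNP, whether the allele-frequency change between two time
#' points exceeds the joint expectation under genetic drift and Pool-seq
#' sampling. The statistic is `T = (pt_hat - p0_hat)^2 / V` with
#' `V = pbar(1-pbar) [1 - (1 - 1/(2 Ne))^t] + p0_hat(1-p0_hat)/C0 +
#' pt_hat(1-pt_hat)/Ct` (plus a pool-construction term
#' `2 pbar(1-pbar)/(2 pool_size)` when `pool_size` is given), referred to a
#' chi-squared distribution with 1 df. SNPs monomorphic at both time points
#' return p = 1.
#'
#' @param c0,ct Allele-1 (T) read counts at the two time points.
#' @param cov0,covt Coverages at the two time points (>= 1).
#' @param n_e Effective population size (an `ne_estimate` or a number).
#' @param t Generations between the time points.
#' @param pool_size Pooled individuals per sample, or `NULL` for data
#'   sampled directly as reads.
#' @return Numeric vector of p-values.
#' @export
drift_chi2_test <- function(c0, ct, cov0, covt, n_e, t, pool_size = NULL) {
  if (inherits(n_e, "ne_estimate")) n_e <- n_e$ne
  if (any(cov0 < 1) || any(covt < 1)) {
    stop("coverages must be >= 1", call. = FALSE)
  }
  p0_hat <- c0 / cov0
  pt_hat <- ct / covt
  v <- test_variance(p0_hat, pt_hat, cov0, covt, n_e, t, pool_size)
  stat <- (pt_hat - p0_hat)^2 / v
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[v == 0] <- 1    # monomorphic at both time points
  p
}

#' Drift-aware Cochran-Mantel-Haenszel test across replicates
#'
#' Combines the per-replicate frequency changes into
#' `T = (sum_r (pt_hat_r - p0_hat_r))^2 / sum_r V_r`, with the same
#' per-replicate variance as [drift_chi2_test()], so consistent-direction
#' changes across replicates accumulate while opposing changes cancel.
#'
#' @param c0,ct Matrices of allele-1 counts, SNPs x replicates.
#' @param cov0,covt Coverage matrices (or scalars), SNPs x replicates.
#' @param n_e Effective sizes per replicate (vector, numbers or
#'   `ne_estimate`s in a list).
#' @param t Generations between the time points.
#' @param pool_size Pooled individuals per sample, or `NULL`.
#' @return Numeric vector of p-values, one per SNP.
#' @export
drift_cmh_test <- function(c0, ct, cov0, covt, n_e, t, pool_size = NULL) {
  c0 <- as.matrix(c0); ct <- as.matrix(ct)
  if (ncol(c0) < 2) stop("need at least 2 replicates", call. = FALSE)
  if (is.list(n_e)) {
    n_e <- vapply(n_e, function(x) if (inherits(x, "ne_estimate")) x$ne else x,
                  numeric(1))
  }
  n_e <- rep_len(n_e, ncol(c0))
  if (length(cov0) == 1) cov0 <- matrix(cov0, nrow(c0), ncol(c0))
  if (length(covt) == 1) covt <- matrix(covt, nrow(ct), ncol(ct))
  cov0 <- as.matrix(cov0); covt <- as.matrix(covt)
  num <- 0
  den <- 0
  for (r in seq_len(ncol(c0))) {
    p0_hat <- c0[, r] / cov0[, r]
    pt_hat <- ct[, r] / covt[, r]
    num <- num + (pt_hat - p0_hat)
    den <- den + test_variance(p0_hat, pt_hat, cov0[, r], covt[, r],
                               n_e[r], t, pool_size)
  }
  stat <- num^2 / den
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[den == 0] <- 1
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment (a thin wrapper around
#' `stats::p.adjust(method = "BH")`, kept as the single correction point of
#' the scan).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Combine CMH and per-replicate chi-squared candidates
#'
#' A SNP is a candidate when its BH-adjusted CMH p-value is below `alpha`
#' (consistent response across replicates) or any replicate-specific
#' BH-adjusted chi-squared p-value is below `alpha` (replicate-specific
#' response). The provenance records which test fired.
#'
#' @param cmh_q Adjusted CMH p-values.
#' @param chi2_q Matrix of adjusted chi-squared p-values, SNPs x replicates.
#' @param alpha Significance threshold (default 0.05).
#' @param positions Optional bp positions carried through to the output.
#' @return A data frame of class `candidate_set` with columns `position`,
#'   `cmh_q`, `chi2_q_min`, `candidate`, `source` ("cmh", "chi2", "both" or
#'   "none").
#' @export
call_candidates <- function(cmh_q, chi2_q, alpha = 0.05, positions = NULL) {
  chi2_q <- as.matrix(chi2_q)
  stopifnot(length(cmh_q) == nrow(chi2_q))
  if (is.null(positions)) positions <- seq_along(cmh_q)
  by_cmh <- cmh_q < alpha
  by_chi2 <- apply(chi2_q < alpha, 1, any)
  source <- ifelse(by_cmh & by_chi2, "both",
                   ifelse(by_cmh, "cmh", ifelse(by_chi2, "chi2", "none")))
  out <- data.frame(
    position = positions,
    cmh_q = cmh_q,
    chi2_q_min = apply(chi2_q, 1, min),
    candidate = by_cmh | by_chi2,
    source = source,
    stringsAsFactors = FALSE
  )
  class(out) <- c("candidate_set", class(out))
  out
}
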