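# Selection-coefficient estimation from logit-linear allele-frequency
# trajectories, with a simulation-based neutrality test.

prepare_logit_traj <- function(traj, generations, coverage) {
  p <- clamp_freq(traj, coverage)
  clamped <- p != traj
  eps <- 1 / (2 * coverage)
  at_bound <- p == eps | p == 1 - eps
  # a run of records stuck at the same boundary carries no slope
  # information beyond its first record: drop the repeats
  drop <- c(FALSE, at_bound[-1] & at_bound[-length(p)] &
              diff(p) == 0)
  list(p = p[!drop], gen = generations[!drop], clamped = any(clamped))
}

lls_slope <- function(p, gen) {
  y <- logit(p)
  x <- gen - mean(gen)
  sum(x * (y - mean(y))) / sum(x^2)
}

#' Selection coefficient of one trajectory (log-linear least squares)
#'
#' Estimates the per-generation selection coefficient as the ordinary
#' least-squares slope of `logit(p)` on generation. Frequencies at 0 or 1
#' are clamped to `[1/(2 coverage), 1 - 1/(2 coverage)]` first; repeated
#' records stuck at the same boundary are reduced to their first occurrence.
#' The p-value against neutrality is the two-sided empirical tail
#' probability of `|s|` among `n_null` neutral Wright-Fisher trajectories
#' simulated from the same starting frequency, effective size, coverage and
#' time grid, with the same read noise ([wf_trajectories()] +
#' [pool_noise()]); the add-one estimator `(1 + k)/(n_null + 1)` keeps the
#' p-value positive.
#'
#' @param traj Observed frequencies, one per recorded generation.
#' @param generations Recorded generations (same length as `traj`).
#' @param n_e Effective population size for the neutral null (an
#'   `ne_estimate` or a number).
#' @param coverage Read depth behind the observed frequencies.
#' @param n_null Number of null simulations (default 1000); 0 skips the
#'   test (p-value `NA`).
#' @param seed Optional integer seed for the null simulations.
#' @return List of class `s_estimate`: `s`, `p_value`, `n_used` (time
#'   points entering the fit), `clamped`.
#' @examples
#' p <- 0.05 * exp(0.1 * c(0, 11, 21, 31, 41, 51))
#' p <- p / (1 - 0.05 + p)
#' fit_lls_s(p, c(0, 11, 21, 31, 41, 51), n_e = 1000, coverage = 100,
#'           n_null = 0)$s  # exactly 0.1
#' @export
fit_lls_s <- function(traj, generations, n_e, coverage, n_null = 1000,
                      seed = NULL) {
  if (inherits(n_e, "ne_estimate")) n_e <- n_e$ne
  stopifnot(length(traj) == length(generations))
  pr <- prepare_logit_traj(traj, generations, coverage)
  if (length(pr$p) < 2) {
    stop("fewer than 2 usable time points after boundary handling",
         call. = FALSE)
  }
  if (pr$clamped) {
    warning("frequencies at the boundary were clamped before the logit fit")
  }
  s_hat <- lls_slope(pr$p, pr$gen)
  p_value <- NA_real_
  if (n_null > 0) {
    p0 <- traj[1]
    if (p0 <= 0 || p0 >= 1) p0 <- pr$p[1]
    null_true <- wf_trajectories(p0, n_e, max(generations),
                                 n_snps = n_null, record_at = generations,
                                 seed = seed)
    null_obs <- pool_noise(null_true, coverage,
                           seed = if (is.null(seed)) NULL else
                             derive_seed(seed, 77L))
    s_null <- apply(null_obs, 1, function(row) {
      prn <- prepare_logit_traj(row, generations, coverage)
      if (length(prn$p) < 2) return(0)
      lls_slope(prn$p, prn$gen)
    })
    p_value <- (1 + sum(abs(s_null) >= abs(s_hat))) / (n_null + 1)
  }
  structure(
    list(s = s_hat, p_value = p_value, n_used = length(pr$p),
         clamped = pr$clamped),
    class = "s_estimate"
  )
}

#' @export
print.s_estimate <- function(x, ...) {
  cat("s =", signif(x$s, 4), " p =", signif(x$p_value, 3),
      sprintf("(%d time points%s)\n", x$n_used,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Per-replicate selection coefficients of a selection target
#'
#' Runs [fit_lls_s()] on each replicate column of the target's median
#' marker trajectory.
#'
#' @param target A `selection_target`.
#' @param n_e Effective size, scalar or per-replicate vector.
#' @param coverage Read depth.
#' @param n_null,seed Passed to [fit_lls_s()] (the seed is varied per
#'   replicate).
#' @param alpha Significance threshold for the `included` flag
#'   (default 0.05).
#' @return Data frame with one row per replicate: target, replicate, s,
#'   p_value, included (p < alpha and s > 0), delta_p (last minus first
#'   median marker frequency).
#' @export
estimate_target_s <- function(target, n_e, coverage, n_null = 1000,
                              seed = NULL, alpha = 0.05) {
  stopifnot(inherits(target, "selection_target"))
  n_rep <- ncol(target$trajectory)
  n_e <- rep_len(if (inherits(n_e, "ne_estimate")) n_e$ne else n_e, n_rep)
  rows <- lapply(seq_len(n_rep), function(r) {
    fit <- fit_lls_s(target$trajectory[, r], target$recorded_generations,
                     n_e[r], coverage, n_null = n_null,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, r))
    data.frame(target = target$block_id, replicate = r, s = fit$s,
               p_value = fit$p_value,
               included = !is.na(fit$p_value) && fit$p_value < alpha &&
                 fit$s > 0,
               delta_p = target$trajectory[nrow(target$trajectory), r] -
                 target$trajectory[1, r],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Median selection coefficient over significantly selected replicates
#'
#' Replicates in which the target did not rise significantly (p >= alpha or
#' s <= 0) are excluded; the median is taken over the rest. Targets with no
#' included replicate are flagged.
#'
#' @param estimates Data frame from [estimate_target_s()] (possibly several
#'   targets row-bound).
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame per target: median_s (`NA` when flagged),
#'   n_included, significant.
#' @examples
#' est <- data.frame(target = "1", replicate = 1:5,
#'                   s = c(0.08, 0.09, -0.01, 0.07, 0.10),
#'                   p_value = c(0.01, 0.02, 0.60, 0.03, 0.04))
#' median_target_s(est)  # median of {0.08, 0.09, 0.07, 0.10} = 0.085
#' @export
median_target_s <- function(estimates, alpha = 0.05) {
  stopifnot(all(c("target", "s", "p_value") %in% names(estimates)))
  out <- lapply(split(estimates, estimates$target), function(d) {
    inc <- d$p_value < alpha & d$s > 0
    data.frame(
      target = d$target[1],
      median_s = if (any(inc)) stats::median(d$s[inc]) else NA_real_,
      n_included = sum(inc),
      significant = any(inc),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Regression of selection strength on starting frequency
#'
#' Ordinary least squares of `log10(median_s)` on starting allele frequency
#' (optionally with a quadratic term) and, when supplied, `log10(block
#' size)`. Residual diagnostics report a Shapiro-Wilk normality p-value and
#' a Spearman test of |residual| against fitted values as a variance
#' homogeneity check.
#'
#' @param start_frequency Starting frequencies of the targets.
#' @param median_s Median selection coefficients (> 0).
#' @param block_size Optional block sizes in bp (> 0).
#' @param quadratic Include a quadratic starting-frequency term?
#' @return List of class `freq_s_fit`: `model` (the `lm`), `coefficients`
#'   (matrix with estimates, SE, p-values), `diagnostics` (normality and
#'   homogeneity p-values and flags).
#' @export
freq_s_model <- function(start_frequency, median_s, block_size = NULL,
                         quadratic = FALSE) {
  ok <- stats::complete.cases(start_frequency, median_s)
  start_frequency <- start_frequency[ok]
  median_s <- median_s[ok]
  if (!is.null(block_size)) block_size <- block_size[ok]
  if (length(median_s) < 5) stop("need at least 5 targets", call. = FALSE)
  if (any(median_s <= 0)) {
    stop("all selection coefficients must be > 0 (log scale)", call. = FALSE)
  }
  d <- data.frame(log_s = log10(median_s), p0 = start_frequency)
  form <- log_s ~ p0
  if (quadratic) form <- stats::update(form, . ~ . + I(p0^2))
  if (!is.null(block_size)) {
    if (any(block_size <= 0)) {
      stop("all block sizes must be > 0 (log scale)", call. = FALSE)
    }
    d$log_size <- log10(block_size)
    form <- stats::update(form, . ~ . + log_size)
  }
  fit <- stats::lm(form, data = d)
  res <- stats::residuals(fit)
  norm_p <- if (length(res) >= 3 && length(res) <= 5000 &&
                stats::var(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  hom_p <- if (stats::var(res) > 0) {
    suppressWarnings(stats::cor.test(abs(res), stats::fitted(fit),
                                     method = "spearman")$p.value)
  } else NA_real_
  structure(
    list(
      model = fit,
      coefficients = summary(fit)$coefficients,
      diagnostics = list(
        normality_p = norm_p,
        homogeneity_p = hom_p,
        residuals_ok = isTRUE(norm_p > 0.05) && isTRUE(hom_p > 0.05)
      )
    ),
    class = "freq_s_fit"
  )
}

#' @export
print.freq_s_fit <- function(x, ...) {
  cat("log10(s) regression:\n")
  stats::printCoefmat(x$coefficients)
  invisible(x)
}
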