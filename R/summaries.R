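# Replicate-parallelism and diversity summaries, and the paired
# high-LD / linkage-equilibrium simulation experiment.

#' Binary replicate-by-target response matrix
#'
#' Turns per-replicate selection estimates into presence/absence of a
#' selection response. Rule `"significant_s"`: response iff the selection
#' coefficient is positive and significantly different from neutrality
#' (p < alpha). Rule `"af_change_gt"`: response iff the median marker
#' allele-frequency change exceeds `cutoff` (strict inequality).
#'
#' @param estimates Data frame from [estimate_target_s()] with columns
#'   `target`, `replicate`, `s`, `p_value`, `delta_p`.
#' @param rule `"significant_s"` (default) or `"af_change_gt"`.
#' @param cutoff Frequency-change cutoff for `"af_change_gt"`
#'   (default 0.1).
#' @param alpha Significance threshold for `"significant_s"`
#'   (default 0.05).
#' @return Integer 0/1 matrix, replicates x targets.
#' @export
binarize_targets <- function(estimates, rule = c("significant_s",
                                                 "af_change_gt"),
                             cutoff = 0.1, alpha = 0.05) {
  rule <- match.arg(rule)
  hit <- switch(rule,
    significant_s = estimates$p_value < alpha & estimates$s > 0,
    af_change_gt = estimates$delta_p > cutoff
  )
  tab <- tapply(as.integer(hit), list(estimates$replicate, estimates$target),
                max)
  mat <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
  mat
}

#' Pairwise Jaccard similarity of replicate responses
#'
#' `J(r1, r2) = |intersection| / |union|` of the target sets responding in
#' the two replicates. Pairs whose union is empty are defined as 1
#' (identical emptiness) and flagged in the `empty_union` attribute.
#'
#' @param binary Integer 0/1 matrix, replicates x targets.
#' @return Symmetric matrix with unit diagonal; attributes `empty_union`
#'   (logical matrix) and `median` (median off-diagonal Jaccard index).
#' @examples
#' jaccard_matrix(rbind(c(1, 1, 1, 0), c(0, 1, 1, 1)))[1, 2]  # 0.5
#' @export
jaccard_matrix <- function(binary) {
  binary <- as.matrix(binary)
  if (nrow(binary) < 2) stop("need at least 2 replicates", call. = FALSE)
  if (ncol(binary) < 1) stop("need at least 1 target", call. = FALSE)
  n <- nrow(binary)
  J <- diag(1, n)
  empty <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- sum(binary[i, ] & binary[j, ])
      uni <- sum(binary[i, ] | binary[j, ])
      if (uni == 0) {
        J[i, j] <- J[j, i] <- 1
        empty[i, j] <- empty[j, i] <- TRUE
      } else {
        J[i, j] <- J[j, i] <- inter / uni
      }
    }
  }
  attr(J, "empty_union") <- empty
  attr(J, "median") <- stats::median(J[upper.tri(J)])
  J
}

#' Coefficient of variation of the mean frequency change across replicates
#'
#' Per replicate, the frequency change of every locus between the first and
#' last recorded generation is averaged; the coefficient of variation
#' (sd/mean, reported as an absolute value) of these per-replicate means
#' measures how parallel the replicates responded — 0 for identical
#' responses, large values for heterogeneous ones.
#'
#' @param trajectories A `trajectory_set`.
#' @param loci Optional locus indices (default: all).
#' @return List with `cv` (`NA` and `flagged = TRUE` when the mean change
#'   is within 1e-6 of zero), `per_replicate_mean`, `flagged`.
#' @export
cv_parallelism <- function(trajectories, loci = NULL) {
  f <- trajectories$freqs
  if (!is.null(loci)) f <- f[loci, , , drop = FALSE]
  d <- dim(f)
  if (d[3] < 2) stop("need at least 2 replicates", call. = FALSE)
  change <- f[, d[2], , drop = FALSE] - f[, 1, , drop = FALSE]
  per_rep <- colMeans(matrix(change, d[1], d[3]))
  m <- mean(per_rep)
  flagged <- abs(m) < 1e-6
  list(
    cv = if (flagged) NA_real_ else abs(stats::sd(per_rep) / m),
    per_replicate_mean = per_rep,
    flagged = flagged
  )
}

#' Windowed nucleotide diversity (Tajima's pi) from pooled counts
#'
#' Per site, the heterozygosity `2 p (1 - p) C / (C - 1)` (with `C` the
#' site's coverage; the factor corrects for the finite read sample), summed
#' over the sites of each non-overlapping window and divided by the window
#' length in bp. Monomorphic sites contribute 0; windows without any
#' covered site are reported as `NA`.
#'
#' @param table A `sync_table`.
#' @param window Window size in bp (default 10 kb).
#' @param allele Allele whose frequency defines `p` (default `"T"`; pi is
#'   symmetric in `p`, so any biallelic choice works).
#' @return Data frame with `chr`, `start` (0-based), `end`, `n_sites`, and
#'   one pi column per sample.
#' @export
tajima_pi_windows <- function(table, window = 1e4, allele = "T") {
  stopifnot(inherits(table, "sync_table"))
  cov <- sync_coverage(table)
  p <- sync_freqs(table, allele)
  if (any(cov > 0 & cov < 2)) {
    stop("coverage must be >= 2 at covered sites", call. = FALSE)
  }
  het <- 2 * p * (1 - p) * cov / (cov - 1)
  het[cov == 0] <- NA
  win <- floor(table$pos / window)
  groups <- split(seq_along(table$pos), list(table$chr, win), drop = TRUE)
  rows <- lapply(groups, function(idx) {
    covered <- !is.na(het[idx, 1, drop = TRUE])
    pi_s <- if (any(covered)) {
      colSums(het[idx, , drop = FALSE], na.rm = TRUE) / window
    } else {
      rep(NA_real_, length(table$samples))
    }
    data.frame(
      chr = table$chr[idx[1]],
      start = win[idx[1]] * window,
      end = (win[idx[1]] + 1) * window,
      n_sites = sum(covered),
      t(pi_s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0("pi_", table$samples)
  out <- out[order(out$chr, out$start), ]
  rownames(out) <- NULL
  out
}

#' Paired high-LD / linkage-equilibrium simulation experiment
#'
#' Runs `n_sims` independent forward simulations per founder scenario and
#' summarizes each: founder mean pairwise r-squared, founder mean genotypic
#' and phenotypic value and mean fitness, final mean phenotype, mean
#' contributing-allele frequency change across loci and replicates, and the
#' coefficient of variation of the mean change across replicates. Matched
#' seeds are used across scenarios so the batches are paired.
#'
#' @param arch A [trait_architecture()].
#' @param n_sims Simulations per scenario (default 100).
#' @param scenarios Founder construction modes to run.
#' @param n_hap,n,n_selected,n_sets,p0 Founder and census parameters
#'   (defaults 1000, 1000, 200, 4, 0.05).
#' @param generations,n_replicates Experiment dimensions (defaults 50, 5).
#' @param seed Integer root seed.
#' @return Data frame of class `ld_experiment`, one row per scenario x
#'   simulation, with the summary columns described above.
#' @export
run_ld_experiment <- function(arch, n_sims = 100,
                              scenarios = c("high_ld", "linkage_equilibrium"),
                              n_hap = 1000, n = 1000, n_selected = 200,
                              n_sets = 4, p0 = 0.05, generations = 50,
                              n_replicates = 5, seed = NULL) {
  stopifnot_count(n_sims, "n_sims")
  rows <- list()
  for (sc in scenarios) {
    for (i in seq_len(n_sims)) {
      sim_seed <- derive_seed(if (is.null(seed)) 0L else seed, i)
      pool <- if (sc == "high_ld") {
        build_high_ld_founders(arch, n_hap, n_selected, n_sets, p0,
                               seed = sim_seed)
      } else {
        build_le_founders(arch, n_hap, p0, n_carriers = n_selected,
                          seed = sim_seed)
      }
      ts <- evolve(pool, arch, n = n, generations = generations,
                   n_replicates = n_replicates,
                   record_at = c(0, generations),
                   seed = derive_seed(sim_seed, match(sc, scenarios)))
      cv <- cv_parallelism(ts)
      n_t <- length(ts$recorded_generations)
      rows[[length(rows) + 1]] <- data.frame(
        scenario = sc,
        sim = i,
        founder_r2 = mean_pairwise_r2(pool),
        founder_mean_gv = ts$mean_gv[1, 1],
        founder_mean_phenotype = mean(ts$mean_phenotype[1, ]),
        founder_mean_fitness = mean(ts$mean_fitness[1, ]),
        final_mean_phenotype = mean(ts$mean_phenotype[n_t, ]),
        mean_freq_change = mean(ts$freqs[, n_t, ] - ts$freqs[, 1, ]),
        cv_freq_change = cv$cv,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ld_experiment", class(out))
  out
}

#' Long format of an LD-experiment report
#'
#' One row per scenario x simulation x metric; the shape violin/box plots
#' want.
#'
#' @param report Data frame from [run_ld_experiment()].
#' @return Data frame with columns scenario, sim, metric, value.
#' @export
ld_experiment_long <- function(report) {
  metrics <- setdiff(names(report), c("scenario", "sim"))
  do.call(rbind, lapply(metrics, function(m) {
    data.frame(scenario = report$scenario, sim = report$sim, metric = m,
               value = report[[m]], stringsAsFactors = FALSE)
  }))
}
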