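# Seeded end-to-end pipeline: simulate -> sample -> scan -> blocks ->
# estimate -> summarize, with a YAML-round-trippable configuration and a
# reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the package defaults.
#' The configuration round-trips losslessly through YAML
#' ([write_run_config()] / [read_run_config()]); every stochastic stage
#' derives its RNG stream from the single root `seed`.
#'
#' @param mode Founder construction: `"high_ld"` or `"linkage_equilibrium"`.
#' @param seed Root seed.
#' @param n_hap,n_selected,n_sets,p0 Founder parameters.
#' @param census Census size of the evolving populations.
#' @param generations,record_at Experiment length and recorded generations.
#' @param n_replicates Number of replicate populations.
#' @param coverage Pool-seq depth.
#' @param pool_size Pooled individuals per sample (`NULL`: reads sampled
#'   directly from population frequencies, no pool-construction noise term).
#' @param alpha Candidate/selection significance threshold.
#' @param top_coverage_fraction Coverage-tail fraction removed before
#'   testing.
#' @param mncs Minimum correlated-SNP fraction for block acceptance.
#' @param corr_threshold Trajectory-correlation clustering threshold.
#' @param early_upto Last generation of the early-time-point refinement.
#' @param top_fraction Marker-SNP fraction defining a selection target.
#' @param n_null Null simulations per selection-coefficient test.
#' @param window Window size (bp) for Ne estimation and diversity.
#' @param arch A [trait_architecture()] (stored as its parameter list).
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = "high_ld", seed = 1, n_hap = 1000,
                       n_selected = 200, n_sets = 4, p0 = 0.05,
                       census = 1000, generations = 50,
                       record_at = c(0, 11, 21, 31, 41, 50),
                       n_replicates = 5, coverage = 50, pool_size = NULL,
                       alpha = 0.05, top_coverage_fraction = 0,
                       mncs = 0.01, corr_threshold = 0.6, early_upto = 31,
                       top_fraction = 0.1, n_null = 200, window = 1e4,
                       arch = trait_architecture()) {
  cfg <- list(
    mode = mode, seed = as.integer(seed), n_hap = n_hap,
    n_selected = n_selected, n_sets = n_sets, p0 = p0, census = census,
    generations = generations, record_at = record_at,
    n_replicates = n_replicates, coverage = coverage,
    pool_size = pool_size, alpha = alpha,
    top_coverage_fraction = top_coverage_fraction, mncs = mncs,
    corr_threshold = corr_threshold, early_upto = early_upto,
    top_fraction = top_fraction, n_null = n_null, window = window,
    arch = unclass(arch)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Write a pipeline configuration as YAML
#' @param config A [run_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path File path written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  arch <- do.call(trait_architecture, raw$arch[
    c("n_loci", "region_length", "positions", "effect_a", "heritability",
      "optimum", "fitness_sd", "fitness_max", "fitness_min", "recomb_rate")
  ])
  raw$arch <- NULL
  do.call(run_config, c(raw, list(arch = arch)))
}

config_hash <- function(config) {
  # polynomial rolling hash over the canonical YAML serialization; changes
  # iff a parameter changes
  txt <- yaml::as.yaml(unclass(config))
  h <- 0
  for (b in utf8ToInt(txt)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run the full simulate-to-summarize pipeline
#'
#' Executes the stages in order — founder construction, Wright-Fisher
#' forward simulation, Pool-seq sampling (sync output), drift-aware
#' candidate scan, haplotype-block reconstruction with early-time-point
#' refinement, selection-coefficient estimation, and parallelism/diversity
#' summaries — writing per-stage outputs and a manifest into `out_dir`.
#' Reruns with the same configuration are reproducible.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return The run manifest (list), invisibly; files written: founder
#'   haplotypes, trajectory TSV, one sync file per time point, candidate
#'   table, block table, estimate table, summary YAML, `manifest.yaml`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arch <- do.call(trait_architecture, config$arch[
    c("n_loci", "region_length", "positions", "effect_a", "heritability",
      "optimum", "fitness_sd", "fitness_max", "fitness_min", "recomb_rate")
  ])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed (config ",
           config_hash(config), "): ", conditionMessage(e), call. = FALSE)
    })
  }

  # simulate
  pool <- stage("simulate", {
    if (config$mode == "high_ld") {
      build_high_ld_founders(arch, config$n_hap, config$n_selected,
                             config$n_sets, config$p0,
                             seed = derive_seed(config$seed, 1L))
    } else {
      build_le_founders(arch, config$n_hap, config$p0,
                        n_carriers = config$n_selected,
                        seed = derive_seed(config$seed, 1L))
    }
  })
  write_haplotypes(pool, file.path(out_dir, "founders.tsv"))
  record_at <- config$record_at[config$record_at <= config$generations]
  ts <- stage("simulate", evolve(
    pool, arch, n = config$census, generations = config$generations,
    n_replicates = config$n_replicates, record_at = record_at,
    seed = derive_seed(config$seed, 2L)
  ))
  write_trajectories(ts, file.path(out_dir, "trajectories.tsv"))

  # sample: one sync file per time point, replicates as samples
  gens <- ts$recorded_generations
  sync_paths <- character(0)
  tables <- stage("sample", lapply(seq_along(gens), function(ti) {
    m <- matrix(ts$freqs[, ti, ], dim(ts$freqs)[1], dim(ts$freqs)[3])
    colnames(m) <- sprintf("r%d_F%d", seq_len(dim(ts$freqs)[3]), gens[ti])
    sample_pool(m, coverage = config$coverage,
                seed = derive_seed(config$seed, 3L, ti),
                positions = ts$positions + 1)
  }))
  for (ti in seq_along(gens)) {
    path <- file.path(out_dir, sprintf("F%d.sync", gens[ti]))
    write_sync(tables[[ti]], path)
    sync_paths <- c(sync_paths, path)
  }

  # scan
  scan <- stage("scan", {
    obs <- array(NA_real_, dim = c(dim(ts$freqs)[1], length(gens),
                                   config$n_replicates))
    for (ti in seq_along(gens)) obs[, ti, ] <- sync_freqs(tables[[ti]])
    n_t <- length(gens)
    if (n_t < 2) {
      list(candidates = call_candidates(numeric(0), matrix(numeric(0), 0, 1)),
           ne = rep(NA_real_, config$n_replicates), obs = obs)
    } else {
      ne <- vapply(seq_len(config$n_replicates), function(r) {
        per_tp <- lapply(seq_along(gens), function(ti) {
          new_sync_table(tables[[ti]]$chr, tables[[ti]]$pos,
                         tables[[ti]]$ref,
                         tables[[ti]]$counts[, , r, drop = FALSE],
                         tables[[ti]]$samples[r])
        })
        est <- tryCatch(
          # one window spanning the whole simulated region: the handful of
          # trait loci would never fill genome-scan-sized windows
          estimate_ne_series(per_tp, gens, pool_size = config$pool_size,
                             census = config$census,
                             window = arch$region_length + 1,
                             min_snps = 2),
          error = function(e) NULL
        )
        if (is.null(est)) config$census else est$ne
      }, numeric(1))
      t_total <- gens[n_t] - gens[1]
      cnt0 <- matrix(tables[[1]]$counts[, 2, ], ncol = config$n_replicates)
      cntt <- matrix(tables[[n_t]]$counts[, 2, ], ncol = config$n_replicates)
      cov0 <- sync_coverage(tables[[1]])
      covt <- sync_coverage(tables[[n_t]])
      chi2_p <- vapply(seq_len(config$n_replicates), function(r) {
        drift_chi2_test(cnt0[, r], cntt[, r], cov0[, r], covt[, r],
                        ne[r], t_total, config$pool_size)
      }, numeric(nrow(cnt0)))
      chi2_q <- apply(matrix(chi2_p, ncol = config$n_replicates), 2,
                      bh_adjust)
      cmh_q <- bh_adjust(drift_cmh_test(cnt0, cntt, cov0, covt, ne,
                                        t_total, config$pool_size))
      list(candidates = call_candidates(cmh_q,
                                        matrix(chi2_q,
                                               ncol = config$n_replicates),
                                        alpha = config$alpha,
                                        positions = ts$positions),
           ne = ne, obs = obs)
    }
  })
  utils::write.table(scan$candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # blocks
  cand_idx <- which(scan$candidates$candidate)
  obs_ts <- structure(
    list(freqs = scan$obs, recorded_generations = gens,
         positions = ts$positions, census_n = config$census,
         n_replicates = config$n_replicates, coverage = config$coverage),
    class = "trajectory_set"
  )
  blocks <- stage("blocks", {
    if (length(cand_idx) < 2 || length(gens) < 3) {
      list()
    } else {
      cm <- trajectory_correlation(obs_ts, snps = cand_idx)
      kept <- attr(cm, "snps")
      qv <- pmin(scan$candidates$cmh_q, scan$candidates$chi2_q_min)
      b <- cluster_blocks(cm, positions = ts$positions[kept],
                          qvalues = qv[kept],
                          mncs_fraction = config$mncs,
                          corr_threshold = config$corr_threshold)
      if (config$early_upto < max(gens) &&
          sum(gens <= config$early_upto) >= 3) {
        b <- refine_with_early_timepoints(b, obs_ts, config$early_upto,
                                          config$mncs,
                                          config$corr_threshold,
                                          n_candidates = length(cand_idx))
      }
      b
    }
  })
  utils::write.table(blocks_table(blocks), file.path(out_dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # estimate
  estimates <- stage("estimate", {
    if (!length(blocks)) {
      data.frame(target = character(), replicate = integer(), s = numeric(),
                 p_value = numeric(), included = logical(),
                 delta_p = numeric())
    } else {
      do.call(rbind, lapply(seq_along(blocks), function(i) {
        tg <- define_selection_target(blocks[[i]], obs_ts,
                                      top_fraction = config$top_fraction)
        estimate_target_s(tg, n_e = scan$ne, coverage = config$coverage,
                          n_null = config$n_null,
                          seed = derive_seed(config$seed, 4L, i),
                          alpha = config$alpha)
      }))
    }
  })
  utils::write.table(estimates, file.path(out_dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # summarize
  summary <- stage("summarize", {
    cv <- cv_parallelism(ts)
    pi0 <- tajima_pi_windows(tables[[1]], window = config$window)
    out <- list(
      n_candidates = sum(scan$candidates$candidate),
      n_blocks = length(blocks),
      ne = as.numeric(scan$ne),
      cv_freq_change = cv$cv,
      mean_founder_pi = mean(as.matrix(pi0[, -(1:4)]), na.rm = TRUE)
    )
    if (nrow(estimates) > 0 && any(estimates$included)) {
      med <- median_target_s(estimates, alpha = config$alpha)
      out$median_s <- stats::median(med$median_s, na.rm = TRUE)
      bin <- binarize_targets(estimates, alpha = config$alpha)
      if (ncol(bin) >= 1) {
        out$median_jaccard <- attr(jaccard_matrix(bin), "median")
      }
    }
    out
  })
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))

  manifest <- list(
    package = "erpoly",
    version = as.character(utils::packageVersion("erpoly")),
    seed = config$seed,
    config_hash = config_hash(config),
    config = unclass(config),
    outputs = basename(c("founders.tsv", "trajectories.tsv", sync_paths,
                         "candidates.tsv", "blocks.tsv", "estimates.tsv",
                         "summary.yaml"))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
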