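test_that("binarization rules map estimates to presence/absence", {
  est <- data.frame(target = rep(c("a", "b"), each = 2),
                    replicate = rep(1:2, 2),
                    s = c(0.08, 0.01, 0.05, -0.02),
                    p_value = c(0.01, 0.2, 0.04, 0.01),
                    delta_p = c(0.25, 0.09, 0.11, -0.05))
  bs <- binarize_targets(est, rule = "significant_s")
  expect_equal(as.vector(bs), c(1L, 0L, 1L, 0L))
  ba <- binarize_targets(est, rule = "af_change_gt", cutoff = 0.1)
  # strict inequality: 0.09 and a negative change stay 0
  expect_equal(as.vector(ba), c(1L, 0L, 1L, 0L))
  expect_equal(binarize_targets(est, rule = "af_change_gt",
                                cutoff = 0.05)["1", "b"], 1L)
  expect_error(binarize_targets(est, rule = "nope"))
})

test_that("Jaccard matrices follow set arithmetic", {
  expect_equal(jaccard_matrix(rbind(c(1, 1, 0), c(1, 1, 0)))[1, 2], 1)
  expect_equal(jaccard_matrix(rbind(c(1, 0, 0), c(0, 1, 1)))[1, 2], 0)
  J <- jaccard_matrix(rbind(c(1, 1, 1, 0), c(0, 1, 1, 1)))
  expect_equal(J[1, 2], 0.5)
  # empty union: defined as 1 and flagged
  J0 <- jaccard_matrix(rbind(c(0, 0), c(0, 0), c(1, 0)))
  expect_equal(J0[1, 2], 1)
  expect_true(attr(J0, "empty_union")[1, 2])
  expect_false(attr(J0, "empty_union")[1, 3])
  # symmetry and unit diagonal for random inputs
  set.seed(1)
  for (i in 1:5) {
    B <- matrix(rbinom(20, 1, 0.5), 4, 5)
    J <- jaccard_matrix(B)
    expect_true(isSymmetric(unname(J)))
    expect_equal(unname(diag(J)), rep(1, 4))
    expect_true(all(J >= 0 & J <= 1))
  }
  expect_error(jaccard_matrix(matrix(1, 1, 3)), "2 replicates")
})

test_that("the parallelism CV summarizes replicate heterogeneity", {
  gens <- c(0, 50)
  # identical replicates: CV 0
  f <- array(rep(c(0.1, 0.4), each = 3), dim = c(3, 2, 1))
  f <- array(rep(f, 4), dim = c(3, 2, 4))
  expect_equal(cv_parallelism(make_traj(f, gens))$cv, 0)
  # per-replicate mean changes 0.1..0.5
  f2 <- array(0.2, dim = c(1, 2, 5))
  f2[1, 2, ] <- 0.2 + seq(0.1, 0.5, 0.1)
  cv <- cv_parallelism(make_traj(f2, gens))
  expect_equal(cv$cv, sd(seq(0.1, 0.5, 0.1)) / 0.3)
  # zero net change is flagged rather than divided by
  f3 <- array(0.5, dim = c(2, 2, 3))
  f3[, 2, 1] <- c(0.6, 0.4)
  f3[, 2, 2] <- c(0.4, 0.6)
  f3[, 2, 3] <- 0.5
  cv3 <- cv_parallelism(make_traj(f3, gens))
  expect_true(cv3$flagged)
  expect_true(is.na(cv3$cv))
})

test_that("windowed pi matches the pooled Tajima formula", {
  # one SNP at p = 0.5, coverage 10, 10 kb window
  tab <- sync_from_freqs(0.5, 10, positions = 500)
  pi <- tajima_pi_windows(tab, window = 1e4)
  expect_equal(pi$pi_s1, 2 * 0.25 * (10 / 9) / 1e4)
  expect_equal(pi$n_sites, 1)
  # monomorphic sites contribute zero
  tab0 <- sync_from_freqs(c(0, 1, 0), 10)
  expect_equal(tajima_pi_windows(tab0, window = 1e4)$pi_s1, 0)
  expect_error(tajima_pi_windows(sync_from_freqs(0.5, 1)), "coverage")
})

test_that("pooled pi estimates the true heterozygosity density", {
  arch <- default_arch()
  L <- 1e4
  rel <- vapply(1:20, function(seed) {
    pool <- build_le_founders(arch, seed = seed)
    p <- colMeans(pool$haplotypes)
    truth <- sum(2 * p * (1 - p)) / L
    tab <- sample_pool(matrix(p, ncol = 1), coverage = 100,
                       seed = seed + 40,
                       positions = round(arch$positions / 100) + 1)
    est <- tajima_pi_windows(tab, window = L)$pi_s1
    est / truth
  }, numeric(1))
  expect_equal(mean(rel), 1, tolerance = 0.05)
})

test_that("the LD experiment report is deterministic and complete", {
  arch <- default_arch()
  r1 <- run_ld_experiment(arch, n_sims = 1, generations = 5,
                          n_replicates = 2, seed = 4)
  r2 <- run_ld_experiment(arch, n_sims = 1, generations = 5,
                          n_replicates = 2, seed = 4)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 2)
  expect_setequal(unique(r1$scenario), c("high_ld", "linkage_equilibrium"))
  expect_true(all(c("founder_r2", "founder_mean_gv", "founder_mean_fitness",
                    "final_mean_phenotype", "mean_freq_change",
                    "cv_freq_change") %in% names(r1)))
  expect_equal(r1$founder_mean_gv, c(-0.45, -0.45))
  long <- ld_experiment_long(r1)
  expect_equal(nrow(long), 2 * (ncol(r1) - 2))
})

test_that("the two binarization rules agree on strongly selected targets", {
  set.seed(8)
  gens <- seq(0, 50, 10)
  rows <- list()
  for (i in 1:10) {
    true <- wf_trajectories(0.1, 1000, 50, n_snps = 5, record_at = gens,
                            s = 0.08, seed = 300 + i)
    obs <- pool_noise(true, 100, seed = 400 + i)
    for (r in 1:5) {
      fit <- suppressWarnings(fit_lls_s(obs[r, ], gens, 1000, 100,
                                        n_null = 100, seed = 500 + 10 * i + r))
      rows[[length(rows) + 1]] <- data.frame(
        target = paste0("t", i), replicate = r, s = fit$s,
        p_value = fit$p_value, delta_p = obs[r, 6] - obs[r, 1]
      )
    }
  }
  est <- do.call(rbind, rows)
  b1 <- binarize_targets(est, rule = "significant_s")
  b2 <- binarize_targets(est, rule = "af_change_gt", cutoff = 0.1)
  expect_gte(mean(b1 == b2), 0.8)
})
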