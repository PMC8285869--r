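test_that("chi-squared statistic composes drift and sampling variance", {
  # no drift (huge Ne), coverage 100 at both time points, p 0.5 -> 0.6:
  # T = 0.01 / (0.25/100 + 0.24/100) = 2.0408, p about 0.153
  p <- drift_chi2_test(c0 = 50, ct = 60, cov0 = 100, covt = 100,
                       n_e = 1e12, t = 50)
  expect_equal(p, 0.1531, tolerance = 1e-3)
  # no change -> p = 1; monomorphic in both -> p = 1
  expect_equal(drift_chi2_test(30, 30, 100, 100, 1000, 50), 1)
  expect_equal(drift_chi2_test(0, 0, 100, 100, 1000, 50), 1)
  expect_equal(drift_chi2_test(100, 100, 100, 100, 1000, 50), 1)
  # the pool-size term enlarges the variance, so p grows
  p_pool <- drift_chi2_test(50, 60, 100, 100, 1e12, 50, pool_size = 100)
  expect_gt(p_pool, p)
  expect_error(drift_chi2_test(1, 1, 0, 10, 1000, 50), "coverages")
})

test_that("the CMH combination rewards consistent direction", {
  # all replicates unchanged
  c0 <- matrix(50, 3, 5)
  expect_equal(drift_cmh_test(c0, c0, 100, 100, rep(1000, 5), 50),
               rep(1, 3))
  # two replicates with equal and opposite changes cancel exactly
  c0 <- cbind(c(50), c(50))
  ct <- cbind(c(60), c(40))
  expect_equal(drift_cmh_test(c0, ct, 100, 100, c(1000, 1000), 50), 1)
  # consistent change across 5 replicates beats the same change in one
  c0 <- matrix(50, 1, 5)
  ct <- matrix(60, 1, 5)
  p5 <- drift_cmh_test(c0, ct, 100, 100, rep(1000, 5), 50)
  p1 <- drift_chi2_test(50, 60, 100, 100, 1000, 50)
  expect_lt(p5, p1)
  expect_error(drift_cmh_test(matrix(1, 2, 1), matrix(1, 2, 1), 10, 10,
                              1000, 5), "replicates")
})

test_that("BH adjustment is the standard step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- c(0.001, 0.3, 0.04, 0.9, 0.012)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("candidates combine CMH and replicate-specific chi2 calls", {
  chi2 <- cbind(c(0.5, 0.01, 0.5), c(0.5, 0.9, 0.6))
  cmh <- c(0.04, 0.2, 0.3)
  cand <- call_candidates(cmh, chi2, alpha = 0.05, positions = c(10, 20, 30))
  expect_equal(cand$candidate, c(TRUE, TRUE, FALSE))
  expect_equal(cand$source, c("cmh", "chi2", "none"))
  empty <- call_candidates(c(0.5, 0.6), cbind(c(0.9, 0.8)), alpha = 0.05)
  expect_equal(sum(empty$candidate), 0)
})

test_that("Ne estimation recovers the simulated population size", {
  nes <- vapply(1:5, function(seed) {
    true <- wf_trajectories(runif(5000, 0.2, 0.8), 1000, 50,
                            record_at = c(0, 50), seed = seed)
    t0 <- sync_from_freqs(pool_noise(true[, 1], 100, seed = seed * 2 + 1),
                          100)
    tt <- sync_from_freqs(pool_noise(true[, 2], 100, seed = seed * 2 + 2),
                          100)
    suppressWarnings(estimate_ne(t0, tt, t = 50, census = 1000)$ne)
  }, numeric(1))
  expect_true(median(nes) > 800 && median(nes) < 1250)
})

test_that("Ne without drift signal clips at the upper bound with a warning", {
  p <- runif(200, 0.2, 0.8)
  t0 <- sync_from_freqs(p, 100)
  expect_warning(est <- estimate_ne(t0, t0, t = 10, census = 1000),
                 "clipped")
  expect_equal(est$ne, 10000)
  # mismatched sites are rejected
  t2 <- sync_from_freqs(p[-1], 100)
  expect_error(estimate_ne(t0, t2, t = 10), "matching")
})

test_that("Ne is insensitive to the sampling interval", {
  one <- function(t, seed) {
    true <- wf_trajectories(runif(4000, 0.2, 0.8), 1000, t,
                            record_at = c(0, t), seed = seed)
    t0 <- sync_from_freqs(pool_noise(true[, 1], 100, seed = seed + 500), 100)
    tt <- sync_from_freqs(pool_noise(true[, 2], 100, seed = seed + 900), 100)
    suppressWarnings(estimate_ne(t0, tt, t = t, census = 1000)$ne)
  }
  ne25 <- median(vapply(1:4, function(s) one(25, s), numeric(1)))
  ne50 <- median(vapply(1:4, function(s) one(50, 10 + s), numeric(1)))
  expect_equal(ne25, ne50, tolerance = 0.2 * ne50)
})

test_that("intermediate time points combine by the median of pair estimates", {
  gens <- c(0, 20, 40)
  true <- wf_trajectories(runif(4000, 0.2, 0.8), 1000, 40,
                          record_at = gens, seed = 42)
  tabs <- lapply(1:3, function(i) {
    sync_from_freqs(pool_noise(true[, i], 100, seed = 60 + i), 100)
  })
  est <- suppressWarnings(estimate_ne_series(tabs, gens, census = 1000))
  expect_equal(length(est$per_window), 2)
  expect_equal(est$ne, median(est$per_window))
  expect_gt(est$ne, 500)
  expect_lt(est$ne, 2000)
})

test_that("test power grows with selection strength", {
  pow <- vapply(c(0.05, 0.1), function(s) {
    true <- wf_trajectories(0.1, 1000, 50, n_snps = 300,
                            record_at = c(0, 50), s = s, seed = 7)
    c0 <- rbinom(300, 100, true[, 1])
    ct <- rbinom(300, 100, true[, 2])
    median(drift_chi2_test(c0, ct, 100, 100, 1000, 50))
  }, numeric(1))
  expect_lt(pow[2], pow[1])
})

test_that("the CMH test detects the experiment's own effect sizes", {
  set.seed(11)
  n_sel <- 100
  n_neu <- 10000
  c0s <- cts <- matrix(0L, n_sel + n_neu, 5)
  for (r in 1:5) {
    sel <- wf_trajectories(0.05, 1000, 50, n_snps = n_sel,
                           record_at = c(0, 50), s = 0.08, seed = 100 + r)
    neu <- wf_trajectories(runif(n_neu, 0.05, 0.95), 1000, 50,
                           record_at = c(0, 50), seed = 200 + r)
    tr <- rbind(sel, neu)
    c0s[, r] <- rbinom(nrow(tr), 100, tr[, 1])
    cts[, r] <- rbinom(nrow(tr), 100, tr[, 2])
  }
  p <- drift_cmh_test(c0s, cts, 100, 100, rep(1000, 5), 50)
  q <- bh_adjust(p)
  expect_lt(median(q[1:n_sel]), 0.05)
})
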