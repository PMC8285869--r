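test_that("genotypic values follow the homozygous-effect parameterization", {
  arch <- default_arch()
  all0 <- matrix(0L, 1, 10)
  all2 <- matrix(2L, 1, 10)
  expect_equal(genotypic_value(all0, arch), -0.5)
  expect_equal(genotypic_value(all2, arch), 0.5)
  het <- matrix(1L, 1, 10)
  expect_equal(genotypic_value(het, arch), 0)
  for (seed in 1:5) {
    pool <- build_high_ld_founders(arch, seed = seed)
    expect_equal(mean(genotypic_value(pool, arch)), -0.45)
    le <- build_le_founders(arch, seed = seed)
    expect_equal(mean(genotypic_value(le, arch)), -0.45)
  }
})

test_that("phenotypes add environmental noise scaled by heritability", {
  arch <- default_arch()
  gv <- c(-0.5, 0, 0.5)
  expect_identical(phenotypic_value(gv, 0), gv)
  pool <- build_high_ld_founders(arch, seed = 1)
  gv <- genotypic_value(pool, arch)
  es <- founder_env_sd(pool, arch)
  # h2 = 0.5 means V_E = V_G, so phenotypic variance is about 2 V_G
  z <- phenotypic_value(rep(gv, 10), es, seed = 2)
  expect_equal(var(z), 2 * var(gv), tolerance = 0.05)
  # founder mean phenotype magnitude near 0.45 (noise has mean zero)
  se <- es / sqrt(length(gv))
  expect_lt(abs(abs(mean(phenotypic_value(gv, es, seed = 3))) - 0.45), 3 * se)
  # degenerate founders: monomorphic pool has no genotypic variance
  mono <- build_le_founders(arch, p0 = 0, n_carriers = 200, seed = 1)
  expect_error(founder_env_sd(mono, arch), "undefined")
})

test_that("the Gaussian fitness function is scaled and floored", {
  arch <- default_arch()
  expect_equal(gaussian_fitness(0.5, arch), 4.5)
  expect_equal(gaussian_fitness(c(-1e6, 1e6), arch), c(0.5, 0.5))
  expect_equal(gaussian_fitness(-0.45, arch),
               0.5 + 4 * exp(-0.95^2 / (2 * 1.44)))
  z <- seq(-2, 3, by = 0.1)
  w <- gaussian_fitness(z, arch)
  expect_true(all(w >= 0.5 & w <= 4.5))
  expect_equal(z[which.max(w)], 0.5)
})

test_that("evolve with zero generations returns the founder state", {
  arch <- default_arch()
  pool <- build_high_ld_founders(arch, seed = 1)
  ts <- evolve(pool, arch, generations = 0, record_at = 0,
               n_replicates = 2, seed = 1)
  expect_identical(as.vector(ts$freqs[, 1, ]), rep(0.05, 20))
})

test_that("frequencies stay in [0,1] and fixation is absorbing", {
  arch <- default_arch()
  pool <- build_high_ld_founders(arch, seed = 2)
  ts <- evolve(pool, arch, n = 200, generations = 20,
               record_at = seq(0, 20, 5), n_replicates = 3, seed = 2)
  expect_true(all(ts$freqs >= 0 & ts$freqs <= 1))
  # a pool fixed for the contributing allele stays fixed (no mutation)
  fixed <- build_le_founders(arch, n_hap = 200, p0 = 1, n_carriers = 200,
                             seed = 1)
  arch1 <- trait_architecture(heritability = 1)
  tsf <- evolve(fixed, arch1, n = 200, generations = 10, n_replicates = 2,
                seed = 3)
  expect_true(all(tsf$freqs == 1))
})

test_that("neutral drift matches the Wright-Fisher closed form", {
  # flat fitness via an essentially infinite fitness width
  arch <- trait_architecture(fitness_sd = 1e9)
  n <- 200
  t <- 5
  pool <- build_le_founders(arch, n_hap = n, p0 = 0.5, n_carriers = n,
                            seed = 1)
  dp <- unlist(lapply(1:60, function(seed) {
    ts <- evolve(pool, arch, n = n, generations = t, n_replicates = 1,
                 seed = seed)
    ts$freqs[, 2, 1] - ts$freqs[, 1, 1]
  }))
  expected_sd <- sqrt(0.25 * (1 - (1 - 1 / (2 * n))^t))
  expect_equal(mean(dp), 0, tolerance = 3 * expected_sd / sqrt(length(dp)))
  expect_equal(sd(dp), expected_sd, tolerance = 0.05)
})

test_that("selection raises contributing alleles and moves the phenotype
           toward the optimum", {
  arch <- default_arch()
  final_freq <- final_z <- init_z <- numeric(0)
  for (seed in 1:20) {
    pool <- build_high_ld_founders(arch, seed = seed)
    ts <- evolve(pool, arch, generations = 15, n_replicates = 2,
                 seed = seed + 100)
    final_freq <- c(final_freq, mean(ts$freqs[, 2, ]))
    init_z <- c(init_z, mean(ts$mean_phenotype[1, ]))
    final_z <- c(final_z, mean(ts$mean_phenotype[2, ]))
  }
  expect_gt(mean(final_freq), 0.05)
  expect_lt(mean(abs(final_z - 0.5)), mean(abs(init_z - 0.5)))
})

test_that("trajectories convert to a tidy data frame and TSV", {
  arch <- default_arch()
  pool <- build_high_ld_founders(arch, seed = 1)
  ts <- evolve(pool, arch, generations = 2, record_at = c(0, 2),
               n_replicates = 2, seed = 1)
  df <- as.data.frame(ts)
  expect_equal(nrow(df), 10 * 2 * 2)
  expect_named(df, c("replicate", "generation", "locus", "position",
                     "frequency"))
  path <- tempfile(fileext = ".tsv")
  write_trajectories(ts, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$frequency, df$frequency)
})

test_that("replicates are reproducible and independent given the root seed", {
  arch <- default_arch()
  pool <- build_high_ld_founders(arch, seed = 1)
  a <- evolve(pool, arch, generations = 5, n_replicates = 3, seed = 9)
  b <- evolve(pool, arch, generations = 5, n_replicates = 3, seed = 9)
  expect_identical(a$freqs, b$freqs)
  expect_false(identical(a$freqs[, 2, 1], a$freqs[, 2, 2]))
})
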