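# deterministic toy trajectories: 2 replicates whose deviations from the
# cross-replicate mean are mirror images, so feature correlations are exact
toy_traj <- function(devs, base = 0.5, gens = seq(0, 50, 10)) {
  n <- nrow(devs)
  freqs <- array(NA_real_, dim = c(n, length(gens), 2))
  freqs[, , 1] <- base + devs
  freqs[, , 2] <- base - devs
  make_traj(freqs, gens)
}

test_that("trajectory correlation scores co-movement of deviations", {
  d <- rbind(c(0.01, 0.05, 0.1, 0.15, 0.1, 0.05),
             c(0.01, 0.05, 0.1, 0.15, 0.1, 0.05),   # identical
             -c(0.01, 0.05, 0.1, 0.15, 0.1, 0.05),  # mirror
             rep(0, 6))                             # no deviation at all
  ts <- toy_traj(d)
  cm <- trajectory_correlation(ts)
  expect_equal(attr(cm, "excluded"), 4)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], -1)
  expect_true(isSymmetric(unname(cm[1:3, 1:3])))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_error(trajectory_correlation(ts, snps = 1), "2 candidate")
})

test_that("noise disattenuation restores same-haplotype correlation", {
  cors <- vapply(1:20, function(i) {
    ps <- simulate_planted_blocks(1, n_markers = 2, s = 0.08, p0 = 0.1,
                                  coverage = 100, seed = i)
    trajectory_correlation(ps)[1, 2]
  }, numeric(1))
  expect_gt(median(cors), 0.8)
})

test_that("a fully correlated candidate set is a single block", {
  cm <- matrix(1, 8, 8)
  blocks <- cluster_blocks(cm, positions = (1:8) * 1000)
  expect_equal(length(blocks), 1)
  expect_equal(length(blocks[[1]]$members), 8)
  expect_equal(blocks[[1]]$interval, c(1000, 8000))
})

test_that("the MNCS rule keeps a floor of two SNPs", {
  expect_equal(erpoly:::mncs_min_size(100, 0.01), 2)
  expect_equal(erpoly:::mncs_min_size(1000, 0.01), 10)
  # an uncorrelated singleton never becomes a block
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.9
  expect_equal(length(cluster_blocks(cm, positions = c(1, 2, 3) * 100)), 1)
  # no cluster passing MNCS: empty list, not an error
  expect_equal(cluster_blocks(diag(4), positions = (1:4) * 10), list())
})

test_that("planted two-block structure is recovered with pure membership", {
  hits <- vapply(1:20, function(i) {
    ps <- simulate_planted_blocks(2, n_markers = 50, s = c(0.11, 0.04),
                                  p0 = c(0.06, 0.40), coverage = 100,
                                  seed = 91000 + i)
    cm <- trajectory_correlation(ps)
    bl <- cluster_blocks(cm, positions = ps$positions[attr(cm, "snps")])
    length(bl) == 2 && all(vapply(bl, function(b) {
      max(table(ps$block_id[b$members])) >= 45
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("clustering is invariant under SNP reordering", {
  ps <- simulate_planted_blocks(2, n_markers = 30, s = c(0.1, 0.05),
                                p0 = c(0.1, 0.3), coverage = 100, seed = 5)
  bl1 <- cluster_blocks(trajectory_correlation(ps),
                        positions = ps$positions)
  perm <- sample(seq_along(ps$positions))
  ps2 <- ps
  ps2$freqs <- ps$freqs[perm, , ]
  ps2$positions <- ps$positions[perm]
  bl2 <- cluster_blocks(trajectory_correlation(ps2),
                        positions = ps2$positions)
  # invariant up to boundary-tie assignments of single markers
  expect_equal(length(bl1), length(bl2))
  sets1 <- lapply(bl1, function(b) sort(b$positions))
  sets2 <- lapply(bl2, function(b) sort(b$positions))
  agree <- sum(lengths(lapply(seq_along(sets1), function(i) {
    intersect(sets1[[i]], sets2[[i]])
  })))
  expect_gte(agree / sum(lengths(sets1)), 0.95)
})

test_that("early time points split recombined blocks into sub-blocks", {
  # 12 SNPs: two groups with opposite early deviations that align from
  # generation 40 on (one haplotype overtook the other)
  early <- c(0.05, 0.05, 0.05, 0.05, 0, 0)
  late <- c(0, 0, 0, 0, 0.2, 0.2)
  d <- rbind(matrix(rep(early + late, 6), 6, byrow = TRUE),
             matrix(rep(-early + late, 6), 6, byrow = TRUE))
  d <- d + matrix(rnorm(72, 0, 1e-4), 12)  # break exact ties
  ts <- toy_traj(d)
  cm <- trajectory_correlation(ts)
  parents <- cluster_blocks(cm, positions = (1:12) * 1000,
                            qvalues = rep(0.01, 12))
  expect_equal(length(parents), 1)
  refined <- refine_with_early_timepoints(parents, ts, early_upto = 30)
  expect_equal(length(refined), 2)
  expect_equal(vapply(refined, `[[`, character(1), "id"), c("1a", "1b"))
  expect_true(all(vapply(refined, `[[`, character(1), "parent_id") == "1"))
  # sub-block members partition a subset of the parent's members
  mem <- sort(unlist(lapply(refined, `[[`, "members")))
  expect_true(all(mem %in% parents[[1]]$members))
  expect_equal(anyDuplicated(mem), 0)
  expect_gte(length(refined), length(parents))
})

test_that("homogeneous blocks survive refinement unchanged", {
  d <- matrix(rep(c(0.02, 0.05, 0.1, 0.15, 0.18, 0.2), 8), 8, byrow = TRUE)
  d <- d * seq(0.9, 1.1, length.out = 8)
  ts <- toy_traj(d)
  parents <- cluster_blocks(trajectory_correlation(ts),
                            positions = (1:8) * 500)
  expect_equal(length(parents), 1)
  refined <- refine_with_early_timepoints(parents, ts, early_upto = 30)
  expect_equal(length(refined), 1)
  expect_equal(refined[[1]]$members, parents[[1]]$members)
  expect_error(refine_with_early_timepoints(parents, ts, early_upto = 50),
               "strict prefix")
})

test_that("sub-clusters below MNCS do not trigger a split", {
  # 7 vs 1: the minority early group is below the floor of 2
  early <- c(0.05, 0.05, 0.05, 0.05, 0, 0)
  late <- c(0, 0, 0, 0, 0.2, 0.2)
  d <- rbind(matrix(rep(early + late, 7), 7, byrow = TRUE),
             -early + late)
  d <- d + matrix(rnorm(48, 0, 1e-4), 8)
  ts <- toy_traj(d)
  parents <- cluster_blocks(trajectory_correlation(ts),
                            positions = (1:8) * 1000)
  refined <- refine_with_early_timepoints(parents, ts, early_upto = 30,
                                          mncs_fraction = 0.25)
  expect_equal(length(refined), length(parents))
  expect_true(is.na(refined[[1]]$parent_id))
})

test_that("selection targets take the top decile of markers by q-value", {
  freqs <- array(runif(10 * 6 * 3), dim = c(10, 6, 3))
  ts <- make_traj(freqs, seq(0, 50, 10))
  block <- erpoly:::new_block("1", members = 1:10,
                              positions = (1:10) * 100,
                              qvalues = seq(0.001, 0.05, length.out = 10))
  tg <- define_selection_target(block, ts, top_fraction = 0.1)
  expect_equal(length(tg$marker_snps), 1)
  expect_equal(tg$marker_snps, 1)  # smallest q
  expect_equal(tg$trajectory[, 2], freqs[1, , 2], ignore_attr = TRUE)
  # median arithmetic over three markers
  f2 <- freqs
  f2[1, 1, 1] <- 0.1; f2[2, 1, 1] <- 0.2; f2[3, 1, 1] <- 0.9
  ts2 <- make_traj(f2, seq(0, 50, 10))
  tg3 <- define_selection_target(block, ts2, top_fraction = 0.3)
  expect_equal(tg3$trajectory[1, 1], 0.2, ignore_attr = TRUE)
  # q ties break by position, left to right
  block_t <- erpoly:::new_block("2", members = 1:10,
                                positions = (10:1) * 100,
                                qvalues = rep(0.01, 10))
  tg_t <- define_selection_target(block_t, ts, top_fraction = 0.1)
  expect_equal(tg_t$marker_positions, 100)
  expect_equal(length(blocks_table(list(block, block_t))$id), 2)
})
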