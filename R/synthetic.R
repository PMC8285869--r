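# Single-locus Wright-Fisher trajectory generators. These are the null and
# planted-truth machinery behind the drift-aware tests, the selection
# coefficient null distribution, and the block-recovery checks.

#' Neutral Wright-Fisher allele-frequency trajectories
#'
#' Simulates `n_snps` independent diallelic loci drifting in a diploid
#' population of effective size `n_e` (binomial resampling of 2*n_e
#' chromosomes per generation), recording frequencies at the requested
#' generations.
#'
#' @param p0 Starting frequency, scalar or length-`n_snps` vector.
#' @param n_e Effective population size (diploid individuals).
#' @param generations Number of generations.
#' @param n_snps Number of independent loci.
#' @param record_at Generations to record (default: 0 and the final one).
#' @param s Per-generation selection coefficient (genic selection,
#'   deterministic update `p' = p(1+s)/(1+ps)` before drift); default 0
#'   (neutral).
#' @param seed Optional integer seed.
#' @return Numeric matrix `n_snps` x `length(record_at)` of true
#'   frequencies, columns named by generation.
#' @examples
#' wf_trajectories(0.5, n_e = 100, generations = 10, n_snps = 3, seed = 1)
#' @export
wf_trajectories <- function(p0, n_e, generations, n_snps = length(p0),
                            record_at = c(0, generations), s = 0,
                            seed = NULL) {
  n_e <- round(n_e)
  stopifnot_count(n_e, "n_e")
  record_at <- sort(unique(as.integer(record_at)))
  if (any(record_at < 0 | record_at > generations)) {
    stop("`record_at` must lie in [0, generations]", call. = FALSE)
  }
  p <- rep_len(p0, n_snps)
  s <- rep_len(s, n_snps)
  out <- matrix(NA_real_, n_snps, length(record_at),
                dimnames = list(NULL, record_at))
  with_seed(seed, {
    for (g in 0:generations) {
      ti <- match(g, record_at)
      if (!is.na(ti)) out[, ti] <- p
      if (g == generations) break
      p_sel <- p * (1 + s) / (1 + p * s)
      p <- stats::rbinom(n_snps, 2L * n_e, p_sel) / (2 * n_e)
    }
  })
  out
}

#' Pool-seq read-noise overlay on true frequencies
#'
#' Adds binomial sequencing noise at fixed depth to a matrix of true
#' frequencies, returning observed read frequencies.
#'
#' @param p Numeric matrix (or vector) of true frequencies.
#' @param coverage Read depth.
#' @param seed Optional integer seed.
#' @return Object of the same shape with entries `Binomial(coverage, p) /
#'   coverage`.
#' @export
pool_noise <- function(p, coverage, seed = NULL) {
  with_seed(seed, {
    obs <- stats::rbinom(length(p), coverage, as.vector(p)) / coverage
    if (is.matrix(p)) {
      obs <- matrix(obs, nrow(p), ncol(p), dimnames = dimnames(p))
    }
    obs
  })
}

#' Simulate candidate SNPs organised in planted selected haplotype blocks
#'
#' Generates the observed-trajectory input of the haplotype-block
#' reconstruction: `n_blocks` independent selection targets, each
#' represented by `n_markers` marker SNPs in perfect linkage (all markers of
#' a block share the block's true frequency trajectory within a replicate
#' and differ only by independent Pool-seq read noise), plus optionally
#' `n_neutral` unlinked neutral SNPs. Blocks occupy disjoint genomic
#' intervals.
#'
#' @param n_blocks Number of planted selection targets.
#' @param n_markers Markers per block (default 50).
#' @param s True selection coefficients, recycled to `n_blocks`
#'   (default 0.08).
#' @param p0 Starting frequencies, recycled to `n_blocks` (default 0.1).
#' @param n_neutral Number of neutral background SNPs (default 0), at
#'   starting frequency `p0_neutral`.
#' @param p0_neutral Starting frequency of neutral SNPs (default 0.2).
#' @param n_e Effective population size (default 1000).
#' @param generations Experiment length (default 50).
#' @param record_at Recorded generations (default `seq(0, 50, 10)`).
#' @param n_replicates Number of replicates (default 5).
#' @param coverage Pool-seq depth (default 100).
#' @param block_span bp spanned by each block (default 1e5); blocks are laid
#'   out head to tail with equal-sized gaps.
#' @param seed Integer seed.
#' @return A `trajectory_set` of observed read frequencies whose extra
#'   elements `block_id` (integer, 0 for neutral SNPs) and `true_s` carry
#'   the planted truth.
#' @export
simulate_planted_blocks <- function(n_blocks, n_markers = 50, s = 0.08,
                                    p0 = 0.1, n_neutral = 0,
                                    p0_neutral = 0.2, n_e = 1000,
                                    generations = 50,
                                    record_at = seq(0, 50, 10),
                                    n_replicates = 5, coverage = 100,
                                    block_span = 1e5, seed = NULL) {
  s <- rep_len(s, n_blocks)
  p0 <- rep_len(p0, n_blocks)
  n_t <- length(record_at)
  n_snps <- n_blocks * n_markers + n_neutral
  freqs <- array(NA_real_, dim = c(n_snps, n_t, n_replicates),
                 dimnames = list(NULL, sort(unique(as.integer(record_at))),
                                 paste0("rep_", seq_len(n_replicates))))
  block_id <- c(rep(seq_len(n_blocks), each = n_markers),
                rep(0L, n_neutral))
  # disjoint intervals: block b occupies [(2b-2), (2b-1)] * block_span,
  # neutral SNPs are scattered beyond the last block
  positions <- numeric(n_snps)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_id == b)
    positions[idx] <- round(seq((2 * b - 2) * block_span + 1,
                                (2 * b - 1) * block_span, length.out = n_markers))
  }
  if (n_neutral > 0) {
    positions[block_id == 0] <- round(seq(2 * n_blocks * block_span + 1,
                                          (2 * n_blocks + 2) * block_span,
                                          length.out = n_neutral))
  }
  for (r in seq_len(n_replicates)) {
    rs <- derive_seed(if (is.null(seed)) 0L else seed, r)
    true_b <- wf_trajectories(p0, n_e, generations, n_snps = n_blocks,
                              record_at = record_at, s = s, seed = rs)
    true_all <- true_b[block_id[block_id > 0], , drop = FALSE]
    if (n_neutral > 0) {
      true_n <- wf_trajectories(p0_neutral, n_e, generations,
                                n_snps = n_neutral, record_at = record_at,
                                seed = derive_seed(rs, 999L))
      true_all <- rbind(true_all, true_n)
    }
    freqs[, , r] <- pool_noise(true_all, coverage,
                               seed = derive_seed(rs, 1000L))
  }
  structure(
    list(
      freqs = freqs,
      recorded_generations = sort(unique(as.integer(record_at))),
      positions = positions,
      census_n = as.integer(n_e),
      n_replicates = as.integer(n_replicates),
      block_id = block_id,
      true_s = s,
      coverage = coverage
    ),
    class = "trajectory_set"
  )
}
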