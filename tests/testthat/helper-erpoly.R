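# Shared fixtures, built in code.

default_arch <- function(...) trait_architecture(...)

# single-sample sync table from a vector of T-allele frequencies at fixed
# coverage (exact rounding, no sampling noise beyond the caller's)
sync_from_freqs <- function(p, coverage, positions = seq_along(p) * 200,
                            chr = "2L", label = "s1") {
  t_cnt <- as.integer(round(p * coverage))
  counts <- array(0L, dim = c(length(p), 6, 1))
  counts[, 1, 1] <- as.integer(coverage) - t_cnt
  counts[, 2, 1] <- t_cnt
  erpoly:::new_sync_table(rep(chr, length(p)), positions, rep("A", length(p)),
                          counts, label)
}

# trajectory_set built directly from an array (loci x time x replicates)
make_traj <- function(freqs, generations, positions = NULL, coverage = NULL,
                      census = 1000) {
  if (is.null(positions)) positions <- seq_len(dim(freqs)[1]) * 1000
  structure(
    list(freqs = freqs, recorded_generations = generations,
         positions = positions, census_n = census,
         n_replicates = dim(freqs)[3], coverage = coverage),
    class = "trajectory_set"
  )
}

logistic_traj <- function(p0, s, gens) {
  x <- p0 * exp(s * gens)
  x / (1 - p0 + x)
}
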