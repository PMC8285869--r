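#' Genotypic values of diploid individuals
#'
#' The genotypic value is the sum of per-locus additive effects: a locus
#' homozygous for the contributing allele contributes `+effect_a`, the
#' opposite homozygote `-effect_a`, a heterozygote 0. For a dosage matrix
#' `G` (individuals x loci, entries 0/1/2) this is
#' `effect_a * (rowSums(G) - n_loci)`.
#'
#' @param geno Either a `haplotype_pool` (each haplotype is doubled into a
#'   homozygous founder individual) or an integer dosage matrix with entries
#'   in `{0, 1, 2}`.
#' @param arch A [trait_architecture()].
#' @return Numeric vector of genotypic values, one per individual, in
#'   `[-n_loci * effect_a, +n_loci * effect_a]`.
#' @examples
#' arch <- trait_architecture()
#' pool <- build_high_ld_founders(arch, seed = 1)
#' mean(genotypic_value(pool, arch))  # -0.45 at the defaults
#' @export
genotypic_value <- function(geno, arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  G <- if (inherits(geno, "haplotype_pool")) 2L * geno$haplotypes else geno
  if (ncol(G) != arch$n_loci) {
    stop("genotypes must cover every trait locus", call. = FALSE)
  }
  if (any(G < 0 | G > 2)) stop("dosages must be 0, 1 or 2", call. = FALSE)
  arch$effect_a * (rowSums(G) - arch$n_loci)
}

#' Environmental standard deviation implied by the founder population
#'
#' Heritability is defined relative to the ancestral population:
#' `env_sd = sqrt(V_G * (1 - h2) / h2)` where `V_G` is the genotypic
#' variance of the founders. The value is computed once per simulation and
#' held fixed across generations.
#'
#' @param pool Founder `haplotype_pool`.
#' @param arch A [trait_architecture()].
#' @param n Number of founder individuals used (default: all haplotypes).
#' @return Environmental standard deviation in trait units.
#' @export
founder_env_sd <- function(pool, arch, n = nrow(pool$haplotypes)) {
  gv <- genotypic_value(
    2L * pool$haplotypes[seq_len(n), , drop = FALSE], arch
  )
  vg <- stats::var(gv)
  h2 <- arch$heritability
  if (h2 == 1) return(0)
  if (vg == 0) {
    stop("founder genotypic variance is zero; environmental variance is ",
         "undefined for heritability < 1", call. = FALSE)
  }
  sqrt(vg * (1 - h2) / h2)
}

#' Phenotypic values from genotypic values
#'
#' Adds independent Gaussian environmental noise with standard deviation
#' `env_sd` (see [founder_env_sd()]) to each genotypic value.
#'
#' @param gv Numeric vector of genotypic values.
#' @param env_sd Environmental standard deviation (>= 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of phenotypes.
#' @export
phenotypic_value <- function(gv, env_sd, seed = NULL) {
  if (env_sd < 0) stop("`env_sd` must be >= 0", call. = FALSE)
  if (env_sd == 0) return(gv)
  with_seed(seed, gv + stats::rnorm(length(gv), 0, env_sd))
}

#' Gaussian stabilizing-selection fitness
#'
#' `w(z) = fitness_min + (fitness_max - fitness_min) *
#' exp(-(z - optimum)^2 / (2 fitness_sd^2))`: maximal at the optimum,
#' decaying to the floor `fitness_min` far from it, so no individual ever
#' has fitness 0.
#'
#' @param z Numeric vector of phenotypes.
#' @param arch A [trait_architecture()].
#' @return Fitness values, strictly within `[fitness_min, fitness_max]`.
#' @examples
#' gaussian_fitness(0.5, trait_architecture())  # 4.5 at the optimum
#' @export
gaussian_fitness <- function(z, arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  arch$fitness_min + (arch$fitness_max - arch$fitness_min) *
    exp(-(z - arch$optimum)^2 / (2 * arch$fitness_sd^2))
}

recombine_gametes <- function(H, parents, arch, lambda) {
  # one gamete per entry of `parents`; H rows 2i-1, 2i are the two
  # haplotypes of individual i
  n_gam <- length(parents)
  start <- sample.int(2L, n_gam, replace = TRUE)
  ncx <- stats::rpois(n_gam, lambda)
  rows0 <- 2L * parents - 2L + start
  G <- H[rows0, , drop = FALSE]
  cx <- which(ncx > 0L)
  if (length(cx)) {
    pos <- arch$positions
    for (k in cx) {
      bp <- sort(stats::runif(ncx[k], 0, arch$region_length))
      seg <- findInterval(pos, bp)
      swap <- seg %% 2L == 1L
      if (any(swap)) {
        other <- 2L * parents[k] - 2L + (3L - start[k])
        G[k, swap] <- H[other, swap]
      }
    }
  }
  G
}

#' Wright-Fisher forward simulation of polygenic adaptation
#'
#' Evolves replicate diploid populations founded from the same homozygous
#' individuals (founder `i` carries two copies of haplotype `i`) under
#' Gaussian stabilizing selection on the additive trait, with non-overlapping
#' generations and constant census size. Each offspring draws two distinct
#' parents with probability proportional to fitness; each parent transmits a
#' recombinant gamete whose crossover count is Poisson with mean
#' `recomb_rate * region_length_Mb / 100` (0.0172 at the defaults), with
#' breakpoints uniform on the region and no interference. The environmental
#' variance is fixed from the founder genotypic variance (see
#' [founder_env_sd()]).
#'
#' @param pool Founder `haplotype_pool` (needs at least `n` haplotypes).
#' @param arch A [trait_architecture()].
#' @param n Census size (default 1000).
#' @param generations Number of generations to evolve (>= 0).
#' @param n_replicates Number of replicate populations (default 5), all
#'   started from the same founders but evolved with independent RNG streams
#'   derived from `seed`.
#' @param record_at Generations at which allele frequencies are recorded
#'   (default: generation 0 and the final generation). Values must lie in
#'   `[0, generations]`.
#' @param seed Integer root seed.
#' @return A `trajectory_set`: list with `freqs` (array loci x time x
#'   replicate), `recorded_generations`, `positions`, `census_n`, and
#'   per-replicate means of genotypic value, phenotype and fitness at each
#'   recorded generation (`mean_gv`, `mean_phenotype`, `mean_fitness`,
#'   time x replicate matrices).
#' @examples
#' arch <- trait_architecture()
#' pool <- build_high_ld_founders(arch, seed = 1)
#' ts <- evolve(pool, arch, generations = 5, n_replicates = 2, seed = 1)
#' ts$freqs[, "0", 1]  # founder frequencies, all 0.05
#' @export
evolve <- function(pool, arch, n = 1000, generations = 50, n_replicates = 5,
                   record_at = c(0, generations), seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(arch, "trait_architecture"))
  stopifnot_count(n, "n")
  if (generations < 0) stop("`generations` must be >= 0", call. = FALSE)
  if (n > nrow(pool$haplotypes)) {
    stop("pool has fewer haplotypes than founder individuals requested",
         call. = FALSE)
  }
  record_at <- sort(unique(as.integer(record_at)))
  if (any(record_at < 0 | record_at > generations)) {
    stop("`record_at` generations must lie in [0, generations]", call. = FALSE)
  }
  L <- arch$n_loci
  env_sd <- if (arch$heritability == 1) 0 else founder_env_sd(pool, arch, n)
  lambda <- arch$recomb_rate * (arch$region_length / 1e6) / 100
  founders <- pool$haplotypes[rep(seq_len(n), each = 2L), , drop = FALSE]

  n_t <- length(record_at)
  freqs <- array(NA_real_, dim = c(L, n_t, n_replicates),
                 dimnames = list(paste0("locus_", seq_len(L)), record_at,
                                 paste0("rep_", seq_len(n_replicates))))
  mean_gv <- mean_z <- mean_w <- matrix(
    NA_real_, n_t, n_replicates, dimnames = list(record_at, NULL)
  )
  odd <- seq(1L, 2L * n, by = 2L)

  for (r in seq_len(n_replicates)) {
    set.seed(derive_seed(if (is.null(seed)) 0L else seed, r))
    H <- founders
    for (g in 0:generations) {
      rs <- rowSums(H)
      gv <- arch$effect_a * (rs[odd] + rs[odd + 1L] - L)
      z <- gv + if (env_sd > 0) stats::rnorm(n, 0, env_sd) else 0
      w <- gaussian_fitness(z, arch)
      ti <- match(g, record_at)
      if (!is.na(ti)) {
        freqs[, ti, r] <- colMeans(H)
        mean_gv[ti, r] <- mean(gv)
        mean_z[ti, r] <- mean(z)
        mean_w[ti, r] <- mean(w)
      }
      if (g == generations) break
      # fitness-proportional parent sampling via inverse CDF; the two
      # parents of an offspring are forced distinct (no selfing)
      cw <- cumsum(w)
      p1 <- findInterval(stats::runif(n) * cw[n], cw) + 1L
      p2 <- findInterval(stats::runif(n) * cw[n], cw) + 1L
      while (any(bad <- p1 == p2)) {
        p2[bad] <- findInterval(stats::runif(sum(bad)) * cw[n], cw) + 1L
      }
      parents <- integer(2L * n)
      parents[odd] <- p1
      parents[odd + 1L] <- p2
      H <- recombine_gametes(H, parents, arch, lambda)
    }
  }
  structure(
    list(
      freqs = freqs,
      recorded_generations = record_at,
      positions = arch$positions,
      census_n = as.integer(n),
      n_replicates = as.integer(n_replicates),
      env_sd = env_sd,
      mean_gv = mean_gv,
      mean_phenotype = mean_z,
      mean_fitness = mean_w
    ),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Trajectory set:", dim(x$freqs)[1], "loci x", dim(x$freqs)[2],
      "time points x", dim(x$freqs)[3], "replicates\n")
  cat("  recorded generations:", paste(x$recorded_generations, collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy data frame of a trajectory set
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return Data frame with columns replicate, generation, locus, position,
#'   frequency.
#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  d <- dim(x$freqs)
  data.frame(
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    generation = rep(rep(x$recorded_generations, each = d[1]), times = d[3]),
    locus = rep(seq_len(d[1]), times = d[2] * d[3]),
    position = rep(x$positions, times = d[2] * d[3]),
    frequency = as.vector(x$freqs)
  )
}

#' Write trajectories as tidy TSV
#'
#' @param ts A `trajectory_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path) {
  utils::write.table(as.data.frame(ts), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
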