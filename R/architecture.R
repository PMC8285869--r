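#' Define the simulated quantitative trait architecture
#'
#' Bundles the parameters of the simulated trait: the positions and effect
#' size of the diallelic contributing loci, the heritability, the Gaussian
#' fitness function after the optimum shift, and the recombination rate.
#'
#' The trait is strictly additive with a homozygous-effect parameterization:
#' a locus homozygous for the contributing allele (coded 1) adds `+effect_a`
#' to the genotypic value, the opposite homozygote adds `-effect_a`, and a
#' heterozygote adds 0. Fitness is a floor-and-ceiling scaled Gaussian of the
#' phenotype, `w(z) = fitness_min + (fitness_max - fitness_min) *
#' exp(-(z - optimum)^2 / (2 * fitness_sd^2))`, so fitness never reaches 0.
#'
#' @param n_loci Number of contributing loci (default 10).
#' @param region_length Length of the simulated region in bp (default 1 Mb).
#' @param positions Strictly increasing bp offsets of the loci inside
#'   `[0, region_length)`. Default: evenly spaced across the region.
#' @param effect_a Additive effect size per locus in trait units
#'   (default 0.05); homozygote effect is `+/- effect_a`.
#' @param heritability Narrow-sense heritability in (0, 1] (default 0.5).
#' @param optimum New trait optimum in trait units (default 0.5).
#' @param fitness_sd Width of the Gaussian fitness function (default 1.2).
#' @param fitness_max Fitness at the optimum (default 4.5).
#' @param fitness_min Fitness floor far from the optimum (default 0.5).
#' @param recomb_rate Recombination rate in cM/Mb (default 1.72).
#' @return An object of class `trait_architecture`.
#' @examples
#' arch <- trait_architecture()
#' arch$positions
#' @export
trait_architecture <- function(n_loci = 10,
                               region_length = 1e6,
                               positions = NULL,
                               effect_a = 0.05,
                               heritability = 0.5,
                               optimum = 0.5,
                               fitness_sd = 1.2,
                               fitness_max = 4.5,
                               fitness_min = 0.5,
                               recomb_rate = 1.72) {
  stopifnot_count(n_loci, "n_loci")
  if (is.null(positions)) {
    # even spacing, mid-point offsets so no locus sits on a region boundary
    positions <- round(region_length * (seq_len(n_loci) - 0.5) / n_loci)
  }
  if (length(positions) != n_loci) {
    stop("`positions` must have length `n_loci`", call. = FALSE)
  }
  if (any(duplicated(positions)) || is.unsorted(positions, strictly = TRUE)) {
    stop("`positions` must be strictly increasing and unique", call. = FALSE)
  }
  if (any(positions < 0 | positions >= region_length)) {
    stop("`positions` must lie inside [0, region_length)", call. = FALSE)
  }
  if (effect_a <= 0) stop("`effect_a` must be > 0", call. = FALSE)
  if (heritability <= 0 || heritability > 1) {
    stop("`heritability` must be in (0, 1]", call. = FALSE)
  }
  if (fitness_sd <= 0) stop("`fitness_sd` must be > 0", call. = FALSE)
  if (fitness_min >= fitness_max) {
    stop("`fitness_min` must be < `fitness_max`", call. = FALSE)
  }
  structure(
    list(
      n_loci = as.integer(n_loci),
      region_length = region_length,
      positions = as.numeric(positions),
      effect_a = effect_a,
      heritability = heritability,
      optimum = optimum,
      fitness_sd = fitness_sd,
      fitness_max = fitness_max,
      fitness_min = fitness_min,
      recomb_rate = recomb_rate
    ),
    class = "trait_architecture"
  )
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat("Trait architecture:", x$n_loci, "diallelic loci in",
      x$region_length / 1e6, "Mb\n")
  cat("  effect +/-", x$effect_a, " h2 =", x$heritability,
      " optimum =", x$optimum, "\n")
  cat("  fitness: N(", x$optimum, ";", x$fitness_sd, ") scaled to [",
      x$fitness_min, ",", x$fitness_max, "]\n", sep = "")
  cat("  recombination:", x$recomb_rate, "cM/Mb\n")
  invisible(x)
}

new_haplotype_pool <- function(haplotypes, mode, seed, arch) {
  structure(
    list(
      haplotypes = haplotypes,
      mode = mode,
      seed = seed,
      positions = arch$positions
    ),
    class = "haplotype_pool"
  )
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("Haplotype pool (", x$mode, "): ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " loci\n", sep = "")
  cat("  per-locus contributing-allele frequencies:",
      paste(format(colMeans(x$haplotypes), digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Construct founder haplotypes with strong linkage disequilibrium
#'
#' Builds a founder pool in which the contributing loci are partitioned at
#' random among `n_sets` disjoint, non-empty haplotype patterns. Each pattern
#' is carried by `n_selected / n_sets` identical haplotypes (50 at the
#' defaults), the remaining `n_hap - n_selected` haplotypes carry no
#' contributing allele, and every locus ends at contributing-allele frequency
#' exactly `p0`. Because whole sets of haplotypes share the same contributing
#' loci, LD within the region is strong.
#'
#' @param arch A [trait_architecture()].
#' @param n_hap Number of founder haplotypes (default 1000).
#' @param n_selected Number of haplotypes carrying contributing alleles
#'   (default 200).
#' @param n_sets Number of distinct selected haplotype patterns (default 4).
#' @param p0 Target per-locus contributing-allele frequency (default 0.05);
#'   must satisfy `p0 * n_hap == n_selected / n_sets`.
#' @param seed Integer seed; the random element is the assignment of loci
#'   to sets.
#' @param require_nonempty Force every set to carry at least one locus?
#'   The default (`FALSE`) assigns each locus to a set uniformly at random,
#'   so a set can end up empty (its haplotypes then carry no contributing
#'   allele); this stochastic assignment is what occasionally concentrates
#'   most loci on one haplotype set and produces the rare near-sweep
#'   simulations. `TRUE` restricts to surjective assignments.
#' @return A `haplotype_pool` with mode `"high_ld"`.
#' @examples
#' pool <- build_high_ld_founders(trait_architecture(), seed = 1)
#' colMeans(pool$haplotypes)  # all exactly 0.05
#' @export
build_high_ld_founders <- function(arch, n_hap = 1000, n_selected = 200,
                                   n_sets = 4, p0 = 0.05, seed = NULL,
                                   require_nonempty = FALSE) {
  stopifnot(inherits(arch, "trait_architecture"))
  stopifnot_count(n_hap, "n_hap")
  stopifnot_count(n_selected, "n_selected")
  stopifnot_count(n_sets, "n_sets")
  if (n_selected %% n_sets != 0) {
    stop("`n_selected` must be divisible by `n_sets`", call. = FALSE)
  }
  if (n_sets > arch$n_loci) {
    stop("cannot partition ", arch$n_loci, " loci into ", n_sets,
         " non-empty sets", call. = FALSE)
  }
  per_set <- n_selected / n_sets
  n_copies <- p0 * n_hap
  if (abs(n_copies - round(n_copies)) > 1e-9) {
    stop("`p0 * n_hap` must be an integer", call. = FALSE)
  }
  if (round(n_copies) != per_set) {
    stop("`p0 * n_hap` must equal `n_selected / n_sets` so that every locus ",
         "ends at frequency exactly `p0`", call. = FALSE)
  }
  assignment <- with_seed(seed, {
    if (require_nonempty) {
      # random surjection of loci onto sets (rejection sampling; the
      # success probability at the defaults, 10 loci onto 4 sets, is 0.78)
      repeat {
        a <- sample.int(n_sets, arch$n_loci, replace = TRUE)
        if (length(unique(a)) == n_sets) break
      }
      a
    } else {
      sample.int(n_sets, arch$n_loci, replace = TRUE)
    }
  })
  H <- matrix(0L, nrow = n_hap, ncol = arch$n_loci)
  for (s in seq_len(n_sets)) {
    rows <- ((s - 1) * per_set + 1):(s * per_set)
    H[rows, assignment == s] <- 1L
  }
  new_haplotype_pool(H, "high_ld", seed, arch)
}

#' Construct founder haplotypes near linkage equilibrium
#'
#' Distributes the contributing alleles of each locus independently across a
#' designated set of `n_carriers` carrier haplotypes: for every locus,
#' exactly `p0 * n_hap` carriers are drawn uniformly without replacement
#' (a fresh draw per locus), so each locus ends at frequency exactly `p0`
#' while loci are assigned independently of one another. The remaining
#' haplotypes carry no contributing allele.
#'
#' @param arch A [trait_architecture()].
#' @param n_hap Number of founder haplotypes (default 1000).
#' @param p0 Target per-locus contributing-allele frequency (default 0.05).
#' @param n_carriers Number of haplotypes over which the contributing
#'   alleles are spread (default 200). Set `n_carriers = n_hap` for fully
#'   unconstrained placement across the whole pool.
#' @param seed Integer seed.
#' @return A `haplotype_pool` with mode `"linkage_equilibrium"`.
#' @examples
#' pool <- build_le_founders(trait_architecture(), seed = 1)
#' colMeans(pool$haplotypes)  # all exactly 0.05
#' @export
build_le_founders <- function(arch, n_hap = 1000, p0 = 0.05,
                              n_carriers = 200, seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"))
  stopifnot_count(n_hap, "n_hap")
  stopifnot_count(n_carriers, "n_carriers")
  if (n_carriers > n_hap) stop("`n_carriers` must be <= `n_hap`", call. = FALSE)
  n_copies <- p0 * n_hap
  if (abs(n_copies - round(n_copies)) > 1e-9) {
    stop("`p0 * n_hap` must be an integer", call. = FALSE)
  }
  n_copies <- as.integer(round(n_copies))
  if (n_copies > n_carriers) {
    stop("`p0 * n_hap` carriers per locus exceed `n_carriers`", call. = FALSE)
  }
  H <- with_seed(seed, {
    H <- matrix(0L, nrow = n_hap, ncol = arch$n_loci)
    for (j in seq_len(arch$n_loci)) {
      H[sample.int(n_carriers, n_copies), j] <- 1L
    }
    H
  })
  new_haplotype_pool(H, "linkage_equilibrium", seed, arch)
}

#' Mean pairwise r-squared of a haplotype pool
#'
#' Computes, for every pair of polymorphic loci, the squared correlation
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB` taken from
#' haplotype co-occurrence, and returns the arithmetic mean over pairs.
#' Monomorphic loci are excluded; an error is raised when fewer than two
#' polymorphic loci remain.
#'
#' @param pool A `haplotype_pool` (or a plain 0/1 haplotype matrix).
#' @param min_minor_count Optional minor-allele-count filter: loci whose
#'   minor allele is carried by fewer haplotypes are excluded (default 0,
#'   no filter).
#' @return Mean pairwise r^2, a number in `[0, 1]`.
#' @examples
#' pool <- build_high_ld_founders(trait_architecture(), seed = 1)
#' mean_pairwise_r2(pool)
#' @export
mean_pairwise_r2 <- function(pool, min_minor_count = 0) {
  H <- if (inherits(pool, "haplotype_pool")) pool$haplotypes else pool
  n <- nrow(H)
  p <- colMeans(H)
  mac <- pmin(p, 1 - p) * n
  keep <- p > 0 & p < 1 & mac >= min_minor_count
  H <- H[, keep, drop = FALSE]
  p <- p[keep]
  if (ncol(H) < 2) {
    stop("need at least two polymorphic loci to compute r^2", call. = FALSE)
  }
  pab <- crossprod(H) / n
  D <- pab - outer(p, p)
  den <- outer(p * (1 - p), p * (1 - p))
  r2 <- D^2 / den
  mean(r2[upper.tri(r2)])
}

#' Write founder haplotypes to a plain-text table
#'
#' One row per haplotype, one column per locus; the header row carries the
#' bp positions. [read_haplotypes()] is its inverse.
#'
#' @param pool A `haplotype_pool`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(pool, path) {
  stopifnot(inherits(pool, "haplotype_pool"))
  H <- pool$haplotypes
  colnames(H) <- paste0("pos_", pool$positions)
  utils::write.table(H, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read founder haplotypes written by [write_haplotypes()]
#'
#' @param path File path.
#' @param mode Mode label to attach (`"high_ld"` or `"linkage_equilibrium"`).
#' @return A `haplotype_pool`.
#' @export
read_haplotypes <- function(path, mode = "unknown") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  H <- as.matrix(tab)
  if (!all(H %in% c(0L, 1L))) stop("haplotype table must be 0/1", call. = FALSE)
  storage.mode(H) <- "integer"
  positions <- as.numeric(sub("^pos_", "", colnames(tab)))
  pool <- structure(
    list(haplotypes = unname(H), mode = mode, seed = NA_integer_,
         positions = positions),
    class = "haplotype_pool"
  )
  pool
}
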