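# Reconstruction of selected haplotype blocks from correlated
# allele-frequency trajectories of candidate SNPs.

traj_features <- function(trajectories, snps = NULL, max_generation = Inf,
                          type = c("cumulative", "increment")) {
  # Replicate-centered trajectory features. The deterministic selection
  # response is shared by every selected SNP in the genome and carries no
  # linkage information; the replicate-specific deviations (the drift of
  # the carrying haplotype) are exactly what co-segregating SNPs share.
  # "cumulative": per-time-point deviation of the replicate trajectory from
  # the SNP's cross-replicate mean — a random walk, high signal-to-noise
  # per feature but few effectively independent features. "increment":
  # adjacent-time-point changes of those deviations — independent across
  # intervals, many effective features but noisier individually.
  type <- match.arg(type)
  keep_t <- trajectories$recorded_generations <= max_generation
  if (sum(keep_t) < 2) {
    stop("need at least 2 recorded time points", call. = FALSE)
  }
  f <- trajectories$freqs[, keep_t, , drop = FALSE]
  if (!is.null(snps)) f <- f[snps, , , drop = FALSE]
  d <- dim(f)
  if (type == "increment") {
    f <- f[, -1, , drop = FALSE] - f[, -d[2], , drop = FALSE]
    d <- dim(f)
  }
  feat <- matrix(NA_real_, d[1], d[2] * d[3])
  for (r in seq_len(d[3])) {
    feat[, (r - 1) * d[2] + seq_len(d[2])] <- f[, , r]
  }
  if (d[3] >= 2) {
    for (k in seq_len(d[2])) {
      idx <- k + d[2] * (seq_len(d[3]) - 1)
      feat[, idx] <- feat[, idx, drop = FALSE] -
        rowMeans(feat[, idx, drop = FALSE])
    }
  }
  feat
}

noise_var_features <- function(trajectories, snps, max_generation, coverage,
                               type = c("cumulative", "increment")) {
  # binomial read-noise variance per feature, estimated from the observed
  # frequencies themselves; replicate-centering removes 1/R of the
  # independent noise variance, increment features sum the noise of two
  # adjacent records
  type <- match.arg(type)
  keep_t <- trajectories$recorded_generations <= max_generation
  f <- trajectories$freqs[snps, keep_t, , drop = FALSE]
  d <- dim(f)
  pv <- f * (1 - f) / coverage
  scale <- if (d[3] >= 2) 1 - 1 / d[3] else 1
  if (type == "increment") {
    pv <- pv[, -1, , drop = FALSE] + pv[, -d[2], , drop = FALSE]
  }
  scale * rowMeans(matrix(pv, d[1]))
}

#' Pairwise trajectory correlation of candidate SNPs
#'
#' Each SNP is summarized by the deviations of its per-replicate frequency
#' trajectory from its own cross-replicate mean trajectory, concatenated
#' across replicates: the deterministic selection response is shared by
#' every selected SNP in the genome and carries no linkage information,
#' while the replicate-specific cumulative deviations — the drift of the
#' haplotype carrying the SNP — are exactly what co-segregating SNPs share.
#' (With a single replicate the features fall back to adjacent-time-point
#' frequency changes.) SNP pairs are scored by the correlation of these
#' feature vectors. Because Pool-seq read noise is
#' independent between SNPs, it attenuates the observed Pearson correlation
#' of truly co-segregating SNPs well below 1; when the read depth is known
#' the correlation is therefore disattenuated: the expected binomial noise
#' variance is subtracted from each SNP's feature variance before
#' standardizing, and the result is clipped to `[-1, 1]`. SNPs with
#' zero feature variance cannot be correlated and are excluded (indices in
#' the `excluded` attribute).
#'
#' @param trajectories A `trajectory_set` (typically of observed Pool-seq
#'   frequencies restricted to candidate SNPs).
#' @param snps Optional indices of the SNPs to use (default: all).
#' @param max_generation Use only time points up to this generation
#'   (default: all).
#' @param coverage Read depth behind the observed frequencies, used for the
#'   noise correction; defaults to the `coverage` element of
#'   `trajectories` when present. `NULL` disables the correction (plain
#'   Pearson correlation, appropriate for noise-free trajectories). The
#'   signal variance is floored at 5% of the observed variance, capping the
#'   disattenuation factor, so SNPs whose variance is dominated by noise are
#'   not blown up arbitrarily.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `snps` holds the (original) indices of the rows, `excluded` the
#'   drop-outs.
#' @export
trajectory_correlation <- function(trajectories, snps = NULL,
                                   max_generation = Inf,
                                   coverage = trajectories$coverage) {
  if (is.null(snps)) snps <- seq_len(dim(trajectories$freqs)[1])
  if (length(snps) < 2) stop("need at least 2 candidate SNPs", call. = FALSE)
  single_rep <- dim(trajectories$freqs)[3] < 2
  type <- if (single_rep) "increment" else "cumulative"
  feat <- traj_features(trajectories, snps, max_generation, type = type)
  v <- apply(feat, 1, stats::var)
  if (is.null(coverage)) {
    ok <- v > 0
    nv <- rep(0, length(v))
    v_true <- v
    cm <- stats::cor(t(feat[ok, , drop = FALSE]))
  } else {
    nv <- noise_var_features(trajectories, snps, max_generation, coverage,
                             type = type)
    v_true <- pmax(v - nv, 0.05 * v)
    ok <- v > 0
    cv <- stats::cov(t(feat[ok, , drop = FALSE]))
    cm <- cv / sqrt(outer(v_true[ok], v_true[ok]))
    cm <- pmin(pmax(cm, -1), 1)
    diag(cm) <- 1
  }
  feat_inc <- traj_features(trajectories, snps, max_generation,
                            type = "increment")
  nv_inc <- if (is.null(coverage)) rep(0, length(v)) else {
    noise_var_features(trajectories, snps, max_generation, coverage,
                       type = "increment")
  }
  attr(cm, "snps") <- snps[ok]
  attr(cm, "excluded") <- snps[!ok]
  attr(cm, "features") <- feat[ok, , drop = FALSE]
  attr(cm, "v_true") <- v_true[ok]
  attr(cm, "noise_var") <- nv[ok]
  attr(cm, "features_inc") <- feat_inc[ok, , drop = FALSE]
  attr(cm, "noise_var_inc") <- nv_inc[ok]
  v_inc <- apply(feat_inc, 1, stats::var)
  attr(cm, "v_true_inc") <- pmax(v_inc - nv_inc, 0.05 * v_inc)[ok]
  cm
}

new_block <- function(id, members, positions, qvalues, parent_id = NA_character_) {
  o <- order(positions)
  structure(
    list(id = as.character(id), members = members[o],
         positions = positions[o], qvalues = qvalues[o],
         interval = range(positions), parent_id = parent_id),
    class = "haplotype_block"
  )
}

#' @export
print.haplotype_block <- function(x, ...) {
  cat("Haplotype block ", x$id, ": ", length(x$members), " SNPs in [",
      x$interval[1], ", ", x$interval[2], "]",
      if (!is.na(x$parent_id)) paste0(" (sub-block of ", x$parent_id, ")"),
      "\n", sep = "")
  invisible(x)
}

mncs_min_size <- function(n_candidates, mncs_fraction) {
  max(2L, as.integer(ceiling(mncs_fraction * n_candidates)))
}

cluster_members <- function(corr, corr_threshold) {
  if (nrow(corr) == 2) {
    # hclust needs >= 2 leaves to cut; handle the pair directly
    return(if (corr[1, 2] >= corr_threshold) c(1L, 1L) else c(1L, 2L))
  }
  hc <- stats::hclust(stats::as.dist(1 - corr), method = "average")
  stats::cutree(hc, h = 1 - corr_threshold)
}

consensus_corr <- function(feat, v_true, nv, labels, anchors) {
  # disattenuated correlation of every SNP's feature vector with the
  # consensus (member-averaged, hence noise-reduced) vector of each anchor;
  # values are left unclipped so that competing anchors can be ranked even
  # when the noise correction pushes several scores above 1
  r_mat <- vapply(anchors, function(cl) {
    m <- which(labels == cl)
    cons <- colMeans(feat[m, , drop = FALSE])
    v_c <- stats::var(cons)
    vt_c <- max(v_c - mean(nv[m]) / length(m), 0.05 * v_c)
    if (vt_c <= 0) return(rep(-Inf, nrow(feat)))
    cv <- apply(feat, 1, function(x) stats::cov(x, cons))
    cv / sqrt(v_true * vt_c)
  }, numeric(nrow(feat)))
  matrix(r_mat, nrow = nrow(feat))
}

merge_anchors <- function(labels, corr, corr_threshold, anchors) {
  # block-level merge decision in increment-feature space: consensus
  # averaging removes most read noise and increments are independent
  # across time intervals, so the correlation between two anchor consensus
  # trajectories is estimated with many effective degrees of freedom and
  # spurious merges are rare
  if (length(anchors) < 2) return(labels)
  feat <- attr(corr, "features_inc")
  nv <- attr(corr, "noise_var_inc")
  cons <- t(vapply(anchors, function(cl) {
    colMeans(feat[labels == cl, , drop = FALSE])
  }, numeric(ncol(feat))))
  vt <- vapply(seq_along(anchors), function(i) {
    m <- sum(labels == anchors[i])
    max(stats::var(cons[i, ]) - mean(nv[labels == anchors[i]]) / m,
        0.05 * stats::var(cons[i, ]))
  }, numeric(1))
  cv <- stats::cov(t(cons))
  cc <- pmin(pmax(cv / sqrt(outer(vt, vt)), -1), 1)
  diag(cc) <- 1
  # fragments of one block have consensus correlations near 1 after noise
  # averaging, so the merge bar sits halfway between the user threshold
  # and 1: chance alignment of distinct blocks rarely reaches it
  grp <- cluster_members(cc, (1 + corr_threshold) / 2)
  for (i in seq_along(anchors)) {
    labels[labels == anchors[i]] <- anchors[which(grp == grp[i])[1]]
  }
  labels
}

consensus_reassign <- function(labels, corr, corr_threshold, min_size) {
  # re-attach SNPs to block anchors via their consensus feature vectors.
  # Anchors claim members greedily from the largest initial cluster down:
  # a small accidental agglomeration that borrowed markers from a real
  # block loses them to the (earlier-processed) real anchor and dissolves.
  feat <- attr(corr, "features")
  v_true <- attr(corr, "v_true")
  nv <- attr(corr, "noise_var")
  if (is.null(feat)) return(labels)
  sizes <- table(labels[labels > 0])
  if (!length(sizes)) return(labels)
  # a consensus is only stable for reasonably sized clusters: splinter
  # groups below the anchor floor are dissolved and their members
  # re-attached (or left unassigned)
  anchor_floor <- max(min_size, min(5L, max(sizes)))
  order_cl <- as.integer(names(sort(sizes, decreasing = TRUE)))
  claimed <- rep(FALSE, nrow(feat))
  out <- rep(0L, nrow(feat))
  for (cl in order_cl) {
    m <- which(labels == cl & !claimed)
    if (length(m) < anchor_floor) next
    tmp <- out
    tmp[m] <- cl
    r <- consensus_corr(feat, v_true, nv, tmp, cl)[, 1]
    take <- !claimed & r >= corr_threshold
    out[take] <- cl
    claimed <- claimed | take
  }
  anchors <- setdiff(unique(out), 0L)
  if (length(anchors) < 1) return(labels)
  # block-level merge of anchors, then iterated polish: reassigning by
  # consensus score and recomputing the consensus purifies anchors that
  # picked up markers of another block during the greedy phase
  out <- merge_anchors(out, corr, corr_threshold, anchors)
  for (pass in 1:3) {
    anchors <- setdiff(unique(out), 0L)
    if (length(anchors) < 1) return(labels)
    r_mat <- consensus_corr(feat, v_true, nv, out, anchors)
    best <- max.col(r_mat, ties.method = "first")
    best_r <- r_mat[cbind(seq_len(nrow(feat)), best)]
    new_out <- ifelse(best_r >= corr_threshold, anchors[best], 0L)
    if (all(new_out == out)) return(new_out)
    out <- new_out
  }
  out
}

#' Cluster candidate SNPs into haplotype blocks
#'
#' Average-linkage hierarchical clustering on the distance `1 - correlation`,
#' cut at height `1 - corr_threshold`. When the correlation matrix carries
#' the underlying feature vectors (as matrices from
#' [trajectory_correlation()] do), the initial cut is followed by a
#' consensus-reassignment pass: each SNP is re-attached to the cluster whose
#' member-averaged (hence noise-reduced) feature vector it correlates with
#' best, provided that correlation reaches `corr_threshold`; small splinter
#' groups of markers that drifted off their block's cluster re-join it
#' here. Clusters smaller than the minimum number of correlated SNPs —
#' `ceiling(mncs_fraction * n_candidates)` with an absolute floor of 2 —
#' are discarded. Each surviving cluster becomes a
#' block whose interval is the span of its member positions; blocks are
#' ordered and numbered by position. When no cluster passes, an empty list
#' is returned (the situation of a chromosome with too few outlier SNPs for
#' reconstruction).
#'
#' @param corr Correlation matrix from [trajectory_correlation()].
#' @param positions bp positions of the SNPs behind the rows of `corr`.
#' @param qvalues Per-SNP adjusted p-values carried into the blocks
#'   (default: `NA`).
#' @param mncs_fraction Minimum cluster size as a fraction of the candidate
#'   count (default 0.01).
#' @param corr_threshold Correlation level at which SNPs are considered
#'   co-selected (default 0.6).
#' @return List of `haplotype_block` objects, ordered by position.
#' @export
cluster_blocks <- function(corr, positions, qvalues = NULL,
                           mncs_fraction = 0.01, corr_threshold = 0.6) {
  n <- nrow(corr)
  stopifnot(length(positions) == n)
  if (is.null(qvalues)) qvalues <- rep(NA_real_, n)
  min_size <- mncs_min_size(n, mncs_fraction)
  if (is.null(attr(corr, "features"))) {
    labels <- cluster_members(corr, corr_threshold)
  } else {
    # strict initial cut: premature merges cannot be undone, whereas
    # fragments are re-joined by the consensus merge step below
    labels <- cluster_members(corr, max(corr_threshold, 0.8))
    labels <- consensus_reassign(labels, corr, corr_threshold, min_size)
  }
  labels_pos <- labels[labels > 0]
  keep <- as.integer(names(which(table(labels_pos) >= min_size)))
  if (!length(keep)) return(list())
  member_idx <- attr(corr, "snps")
  if (is.null(member_idx)) member_idx <- seq_len(n)
  blocks <- lapply(keep, function(cl) {
    sel <- which(labels == cl)
    new_block(NA, member_idx[sel], positions[sel], qvalues[sel])
  })
  blocks <- blocks[order(vapply(blocks, function(b) b$interval[1], numeric(1)))]
  for (i in seq_along(blocks)) blocks[[i]]$id <- as.character(i)
  blocks
}

#' Refine blocks with early time points
#'
#' A reconstructed block may hide several selection targets that recombined
#' onto one winning haplotype late in the experiment. The clustering is
#' repeated on a strict prefix of the recorded generations; when the members
#' of a full-data block fall into two or more early-data clusters that each
#' pass the minimum-size rule, the parent block is replaced by those
#' sub-blocks (labelled `a`, `b`, `c`, ...). Otherwise the parent is kept
#' unchanged.
#'
#' @param blocks List of `haplotype_block`s from [cluster_blocks()].
#' @param trajectories The `trajectory_set` the blocks were built from.
#' @param early_upto Last generation of the early subset; must be smaller
#'   than the final recorded generation and leave at least 2 time points.
#' @param mncs_fraction,corr_threshold As in [cluster_blocks()]; the
#'   minimum size is computed from the same candidate universe.
#' @param n_candidates Size of the candidate universe used for the MNCS
#'   rule (default: total SNPs in `trajectories`).
#' @return List of `haplotype_block`s, refined; sub-blocks carry
#'   `parent_id`.
#' @export
refine_with_early_timepoints <- function(blocks, trajectories, early_upto,
                                         mncs_fraction = 0.01,
                                         corr_threshold = 0.6,
                                         n_candidates = NULL) {
  gens <- trajectories$recorded_generations
  if (early_upto >= max(gens)) {
    stop("`early_upto` must be a strict prefix of the recorded generations",
         call. = FALSE)
  }
  if (!length(blocks)) return(blocks)
  if (is.null(n_candidates)) n_candidates <- dim(trajectories$freqs)[1]
  min_size <- mncs_min_size(n_candidates, mncs_fraction)
  out <- list()
  for (b in blocks) {
    sub <- b
    if (length(b$members) >= 2 * min_size) {
      cm <- tryCatch(
        trajectory_correlation(trajectories, snps = b$members,
                               max_generation = early_upto),
        error = function(e) NULL
      )
      if (!is.null(cm) && nrow(cm) >= 2 * min_size) {
        labels <- cluster_members(cm, corr_threshold)
        sizes <- table(labels)
        passing <- as.integer(names(which(sizes >= min_size)))
        if (length(passing) >= 2) {
          kept_idx <- attr(cm, "snps")
          pos_map <- b$positions[match(kept_idx, b$members)]
          q_map <- b$qvalues[match(kept_idx, b$members)]
          sub <- lapply(seq_along(passing), function(i) {
            sel <- which(labels == passing[i])
            new_block(paste0(b$id, letters[i]), kept_idx[sel],
                      pos_map[sel], q_map[sel], parent_id = b$id)
          })
          sub <- sub[order(vapply(sub, function(x) x$interval[1], numeric(1)))]
          for (i in seq_along(sub)) {
            sub[[i]]$id <- paste0(b$id, letters[i])
          }
        }
      }
    }
    out <- c(out, if (inherits(sub, "haplotype_block")) list(sub) else sub)
  }
  out
}

#' Define the selection target of a haplotype block
#'
#' The selection target is represented by the block's most significant
#' marker SNPs: the `ceiling(top_fraction * n_members)` members with the
#' smallest adjusted p-values (ties broken by position, left to right). Its
#' trajectory is the per-time-point, per-replicate median frequency over
#' those markers, and its starting frequency the median at the first
#' recorded generation across markers and replicates.
#'
#' @param block A `haplotype_block` with q-values.
#' @param trajectories The `trajectory_set` holding the observed
#'   frequencies of the candidate SNPs (indexed by `block$members`).
#' @param top_fraction Fraction of most significant members used as markers
#'   (default 0.1).
#' @param qvalues Optional q-value override (same order as
#'   `block$members`); default: the q-values stored in the block.
#' @return An object of class `selection_target`: list with `block_id`,
#'   `marker_snps`, `marker_positions`, `trajectory` (time x replicate
#'   matrix of median marker frequencies), `recorded_generations` and
#'   `start_frequency`.
#' @export
define_selection_target <- function(block, trajectories, top_fraction = 0.1,
                                    qvalues = NULL) {
  stopifnot(inherits(block, "haplotype_block"))
  n <- length(block$members)
  if (n == 0) stop("block has no members", call. = FALSE)
  if (is.null(qvalues)) qvalues <- block$qvalues
  n_mark <- max(1L, as.integer(ceiling(top_fraction * n)))
  o <- order(qvalues, block$positions)
  sel <- o[seq_len(n_mark)]
  snps <- block$members[sel]
  f <- trajectories$freqs[snps, , , drop = FALSE]
  traj <- apply(f, c(2, 3), stats::median)
  traj <- matrix(traj, dim(f)[2], dim(f)[3],
                 dimnames = list(trajectories$recorded_generations, NULL))
  structure(
    list(
      block_id = block$id,
      marker_snps = snps,
      marker_positions = block$positions[sel],
      trajectory = traj,
      recorded_generations = trajectories$recorded_generations,
      start_frequency = stats::median(f[, 1, ]),
      block_size = diff(block$interval)
    ),
    class = "selection_target"
  )
}

#' @export
print.selection_target <- function(x, ...) {
  cat("Selection target of block ", x$block_id, ": ",
      length(x$marker_snps), " marker SNPs, start frequency ",
      signif(x$start_frequency, 3), "\n", sep = "")
  invisible(x)
}

#' Summary table of a block list
#'
#' @param blocks List of `haplotype_block`s.
#' @return Data frame with id, interval, member count and parent id.
#' @export
blocks_table <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(id = character(), start = numeric(), end = numeric(),
                      n_members = integer(), parent_id = character()))
  }
  data.frame(
    id = vapply(blocks, `[[`, character(1), "id"),
    start = vapply(blocks, function(b) b$interval[1], numeric(1)),
    end = vapply(blocks, function(b) b$interval[2], numeric(1)),
    n_members = vapply(blocks, function(b) length(b$members), integer(1)),
    parent_id = vapply(blocks, `[[`, character(1), "parent_id"),
    stringsAsFactors = FALSE
  )
}
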