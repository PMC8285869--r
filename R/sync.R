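SYNC_ALLELES <- c("A", "T", "C", "G", "N", "del")

new_sync_table <- function(chr, pos, ref, counts, samples) {
  stopifnot(length(dim(counts)) == 3, dim(counts)[2] == 6)
  dimnames(counts) <- list(NULL, SYNC_ALLELES, samples)
  structure(
    list(chr = as.character(chr), pos = as.integer(pos),
         ref = as.character(ref), counts = counts,
         samples = as.character(samples)),
    class = "sync_table"
  )
}

#' @export
print.sync_table <- function(x, ...) {
  cat("Sync table:", length(x$pos), "sites x", length(x$samples), "samples\n")
  if (length(x$samples)) {
    cat("  samples:", paste(utils::head(x$samples, 8), collapse = ", "),
        if (length(x$samples) > 8) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
dim.sync_table <- function(x) c(length(x$pos), length(x$samples))

#' Per-site, per-sample coverage of a sync table
#'
#' @param table A `sync_table`.
#' @return Integer matrix sites x samples of count sums over the six
#'   allele slots.
#' @export
sync_coverage <- function(table) {
  stopifnot(inherits(table, "sync_table"))
  apply(table$counts, c(1, 3), sum)
}

#' Allele frequencies from a sync table
#'
#' Frequency of one allele (by default T, the contributing allele under the
#' biallelic simulation convention) relative to total per-sample coverage.
#'
#' @param table A `sync_table`.
#' @param allele One of `"A"`, `"T"`, `"C"`, `"G"`, `"N"`, `"del"`.
#' @return Numeric matrix sites x samples; `NaN` where coverage is 0.
#' @export
sync_freqs <- function(table, allele = "T") {
  stopifnot(inherits(table, "sync_table"))
  allele <- match.arg(allele, SYNC_ALLELES)
  cnt <- table$counts[, allele, , drop = FALSE]
  dim(cnt) <- dim(cnt)[c(1, 3)]
  cov <- sync_coverage(table)
  out <- cnt / cov
  dimnames(out) <- list(NULL, table$samples)
  out
}

#' Sample Pool-seq read counts from true allele frequencies
#'
#' Emulates pooled sequencing of the simulated populations: at every site and
#' sample the contributing-allele read count is drawn as
#' `Binomial(coverage, p)` and the remaining reads are assigned to the other
#' allele. The biallelic encoding uses the A slot for allele 0 and the T slot
#' for allele 1. Coverage is fixed per site by default; set
#' `poisson_coverage = TRUE` to draw per-site-and-sample depths as
#' `Poisson(coverage)` instead.
#'
#' @param freqs A `trajectory_set` (every replicate x recorded generation
#'   becomes one sample, labelled `r<rep>_F<gen>`) or a numeric matrix of
#'   frequencies, sites x samples.
#' @param coverage Mean read depth (default 50).
#' @param seed Optional integer seed.
#' @param chr Chromosome label for the output records.
#' @param positions 1-based bp positions (default: trajectory positions, or
#'   `1:n_sites` for a plain matrix).
#' @param poisson_coverage Draw depths from a Poisson distribution?
#' @return A `sync_table`.
#' @examples
#' arch <- trait_architecture()
#' pool <- build_high_ld_founders(arch, seed = 1)
#' ts <- evolve(pool, arch, generations = 2, n_replicates = 2, seed = 1)
#' sample_pool(ts, coverage = 50, seed = 1)
#' @export
sample_pool <- function(freqs, coverage = 50, seed = NULL, chr = "sim",
                        positions = NULL, poisson_coverage = FALSE) {
  if (coverage < 1) stop("`coverage` must be >= 1", call. = FALSE)
  if (inherits(freqs, "trajectory_set")) {
    d <- dim(freqs$freqs)
    mat <- matrix(freqs$freqs, nrow = d[1])
    colnames(mat) <- as.vector(outer(
      freqs$recorded_generations, seq_len(d[3]),
      function(g, r) sprintf("r%d_F%d", r, g)
    ))
    if (is.null(positions)) positions <- freqs$positions + 1
  } else {
    mat <- as.matrix(freqs)
    if (is.null(colnames(mat))) {
      colnames(mat) <- paste0("s", seq_len(ncol(mat)))
    }
    if (is.null(positions)) positions <- seq_len(nrow(mat))
  }
  if (any(mat < -1e-9 | mat > 1 + 1e-9)) {
    warning("frequencies outside [0, 1] were clipped before sampling")
  }
  mat <- pmin(pmax(mat, 0), 1)
  n_site <- nrow(mat)
  n_samp <- ncol(mat)
  with_seed(seed, {
    depth <- if (poisson_coverage) {
      matrix(stats::rpois(n_site * n_samp, coverage), n_site, n_samp)
    } else {
      matrix(as.integer(round(coverage)), n_site, n_samp)
    }
    t_cnt <- matrix(stats::rbinom(n_site * n_samp, as.vector(depth),
                                  as.vector(mat)), n_site, n_samp)
    counts <- array(0L, dim = c(n_site, 6, n_samp))
    counts[, 1, ] <- depth - t_cnt
    counts[, 2, ] <- t_cnt
    new_sync_table(rep(chr, n_site), positions, rep("A", n_site), counts,
                   colnames(mat))
  })
}

#' Read a popoolation2 sync file
#'
#' Whitespace-delimited lines: chromosome, 1-based position, reference base,
#' then one `A:T:C:G:N:del` count sextuple per sample. Malformed lines are
#' reported with their line numbers. An empty file yields an empty table.
#'
#' @param path File path.
#' @return A `sync_table`.
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(new_sync_table(character(), integer(), character(),
                          array(0L, c(0, 6, 0)), character()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_field <- lengths(fields)
  if (length(unique(n_field)) != 1 || n_field[1] < 4) {
    bad <- which(n_field != max(c(n_field[n_field >= 4], 4)))
    stop("malformed sync line(s) at line ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": wrong field count", call. = FALSE)
  }
  n_samp <- n_field[1] - 3L
  n_site <- length(fields)
  m <- matrix(unlist(fields), nrow = n_field[1])
  pos <- suppressWarnings(as.integer(m[2, ]))
  if (anyNA(pos)) {
    stop("malformed sync line(s) at line ",
         paste(utils::head(which(is.na(pos)), 5), collapse = ", "),
         ": non-integer position", call. = FALSE)
  }
  counts <- array(0L, dim = c(n_site, 6, n_samp))
  for (s in seq_len(n_samp)) {
    parts <- strsplit(m[3 + s, ], ":", fixed = TRUE)
    if (any(lengths(parts) != 6)) {
      stop("malformed sync line(s) at line ",
           paste(utils::head(which(lengths(parts) != 6), 5), collapse = ", "),
           ": count field is not a sextuple", call. = FALSE)
    }
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v)) {
      bad <- unique(ceiling(which(is.na(v)) / 6))
      stop("malformed sync line(s) at line ",
           paste(utils::head(bad, 5), collapse = ", "),
           ": non-integer count", call. = FALSE)
    }
    counts[, , s] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  new_sync_table(m[1, ], pos, m[3, ], counts,
                 paste0("s", seq_len(n_samp)))
}

#' Write a sync table in popoolation2 format
#'
#' Canonical tab-separated formatting; [read_sync()] followed by
#' `write_sync()` is byte-stable.
#'
#' @param table A `sync_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(table, path) {
  stopifnot(inherits(table, "sync_table"))
  n_samp <- length(table$samples)
  cols <- vapply(seq_len(n_samp), function(s) {
    apply(table$counts[, , s, drop = FALSE], 1, paste, collapse = ":")
  }, character(length(table$pos)))
  if (length(table$pos) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  cols <- matrix(cols, nrow = length(table$pos))
  lines <- apply(cbind(table$chr, table$pos, table$ref, cols), 1, paste,
                 collapse = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Remove sites in the top coverage tail
#'
#' Sites whose total coverage (summed over samples) lies at or above the
#' `1 - top_fraction` quantile are removed; in the field this guards against
#' copy-number variants masquerading as strongly selected SNPs. With ties at
#' the quantile, all tied sites are removed (deterministic rule), so a table
#' with all-equal coverages and `top_fraction > 0` loses all its sites.
#'
#' @param table A `sync_table`.
#' @param top_fraction Fraction of highest-coverage sites to drop
#'   (default 0.01); 0 leaves the table unchanged.
#' @return A filtered `sync_table`.
#' @export
coverage_filter <- function(table, top_fraction = 0.01) {
  stopifnot(inherits(table, "sync_table"))
  if (top_fraction < 0 || top_fraction >= 1) {
    stop("`top_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (top_fraction == 0 || length(table$pos) == 0) return(table)
  tot <- rowSums(sync_coverage(table))
  thr <- stats::quantile(tot, 1 - top_fraction, names = FALSE)
  keep <- tot < thr
  new_sync_table(table$chr[keep], table$pos[keep], table$ref[keep],
                 table$counts[keep, , , drop = FALSE], table$samples)
}
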