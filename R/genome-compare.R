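#' MinHash sketch of a genome
#'
#' Bottom-k sketch: the `sketch_size` smallest 64-bit hash values over the
#' distinct canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement, 2-bit encoded) of all input sequences. K-mers
#' containing non-ACGT symbols are skipped. The hash is a fixed SplitMix64
#' finalizer, so sketches are stable across runs and platforms.
#'
#' @param sequences Character vector (or DNAStringSet) of contig sequences.
#' @param k K-mer length (default 15).
#' @param sketch_size Number of retained hashes (default 100000).
#' @return Object of class `minhash_sketch`: list with `k`, `sketch_size`,
#'   and `hashes` (strictly increasing numeric vector).
#' @export
sketch_genome <- function(sequences, k = 15, sketch_size = 100000) {
  sequences <- as.character(sequences)
  if (length(sequences) == 0 || all(nchar(sequences) == 0))
    stop("'sequences' must be nonempty")
  if (k < 1) stop("k must be >= 1")
  h <- unlist(lapply(toupper(sequences), .kmer_hashes_cpp, k = as.integer(k)))
  if (length(h) == 0)
    stop("empty sketch: all sequences are shorter than k")
  h <- sort(unique(h))
  if (length(h) > sketch_size) h <- h[seq_len(sketch_size)]
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 hashes = h),
            class = "minhash_sketch")
}

#' Mash distance between two sketches
#'
#' The Jaccard index j is estimated from the merged bottom sketch: among the
#' `sketch_size` smallest hashes of the union of both sketches, the fraction
#' present in both. The distance is `-(1/k) * log(2j / (1 + j))`, capped at
#' 1; disjoint sketches (j = 0) return the cap value 1.
#'
#' @param a,b `minhash_sketch` objects with equal k.
#' @return Distance in [0, 1].
#' @export
mash_distance <- function(a, b) {
  if (a$k != b$k) stop("sketches have mismatched k")
  s <- min(a$sketch_size, b$sketch_size)
  u <- sort(unique(c(a$hashes, b$hashes)))
  if (length(u) > s) u <- u[seq_len(s)]
  shared <- sum(u %in% a$hashes & u %in% b$hashes)
  j <- shared / length(u)
  if (j <= 0) return(1)
  if (j >= 1) return(0)
  d <- -(1 / a$k) * log(2 * j / (1 + j))
  min(d, 1)
}

#' Pairwise Mash distance matrix
#'
#' @param sketches Named list of `minhash_sketch` objects.
#' @return Symmetric matrix with zero diagonal, labelled by genome id.
#' @export
mash_distance_matrix <- function(sketches) {
  n <- length(sketches)
  ids <- names(sketches)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
    }
  }
  D
}

#' Single-linkage genome clusters at a distance cutoff
#'
#' Clusters are the connected components of the graph with an edge wherever
#' `d < cutoff` (strictly: ties at exactly the cutoff do not merge), which
#' is identical to cutting a single-linkage dendrogram at the cutoff.
#' Implemented as union-find on the threshold graph so the strict-< tie
#' rule is exact. Cluster ids are the smallest member id of each cluster.
#'
#' @param D Symmetric distance matrix with labels.
#' @param cutoff Merge threshold in (0, 1].
#' @return Data frame with `cluster_id`, `genome_id`, ordered by cluster
#'   then member id.
#' @export
single_linkage_clusters <- function(D, cutoff = 0.1) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("g", seq_len(nrow(D)))
  if (max(abs(D - t(D))) > 1e-12 || any(diag(D) != 0) || any(D < 0))
    stop("D must be symmetric and nonnegative with zero diagonal")
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (D[i, j] < cutoff) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- rownames(D)
  cluster_id <- vapply(split(ids, roots), function(m) min(m), "")
  out <- data.frame(
    cluster_id = unname(cluster_id[as.character(roots)]),
    genome_id = ids, stringsAsFactors = FALSE)
  out[order(out$cluster_id, out$genome_id), , drop = FALSE]
}

#' Length-weighted identity summary over alignment blocks
#'
#' Weighted mean and (population) weighted standard deviation of per-block
#' percent identity, weighted by block length on the query side.
#'
#' @param blocks Data frame with `q_start`, `q_end`, `pct_identity`.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
block_identity_summary <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0)
    stop("identity summary undefined: no alignment blocks")
  w <- blocks$q_end - blocks$q_start
  if (any(w <= 0)) stop("blocks must have positive length")
  m <- sum(w * blocks$pct_identity) / sum(w)
  v <- sum(w * (blocks$pct_identity - m)^2) / sum(w)
  c(mean = m, sd = sqrt(v))
}

#' Aligned fraction of a genome from alignment blocks
#'
#' Percentage of the genome covered by the union of the chosen side's
#' intervals; overlapping blocks are counted once.
#'
#' @param blocks Data frame with `q_start`/`q_end` and `t_start`/`t_end`
#'   columns, 0-based half-open.
#' @param genome_length Total genome length in bases.
#' @param side `"query"` or `"target"`.
#' @return Percentage in [0, 100].
#' @export
aligned_fraction <- function(blocks, genome_length, side = c("query", "target")) {
  side <- match.arg(side)
  if (is.null(blocks) || nrow(blocks) == 0) return(0)
  s <- if (side == "query") blocks$q_start else blocks$t_start
  e <- if (side == "query") blocks$q_end else blocks$t_end
  if (any(s < 0) || any(e > genome_length) || any(e <= s))
    stop("alignment block interval out of [0, genome_length) bounds")
  iv <- IRanges::reduce(IRanges::IRanges(start = s + 1, end = e))
  100 * sum(IRanges::width(iv)) / genome_length
}
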