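#' COG-category percentages per genome
#'
#' @param table Count matrix (rows = genomes, columns = functional
#'   categories). Rows with zero sum are excluded with a warning.
#' @return Matrix of row percentages (each row sums to 100).
#' @export
cog_fractions <- function(table) {
  table <- as.matrix(table)
  rs <- rowSums(table)
  if (any(rs == 0)) {
    warning("genome(s) with zero total counts excluded: ",
            paste(rownames(table)[rs == 0], collapse = ", "))
    table <- table[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  100 * table / rs
}

#' Poisson dissimilarity between genome count profiles
#'
#' The Poisson log-likelihood-ratio dissimilarity for sequencing-type count
#' data. For a pair of genomes i, j with counts X_ig, X_jg, size factors
#' are the pairwise total-count ratios s_i = N_i / mean(N_i, N_j) (or
#' N_i / mean of all row sums in `"global"` mode), the shared per-feature
#' rate is `Nhat_g = (X_ig + X_jg) / (s_i + s_j)`, and
#' `d(i,j) = sum_g [ s_i Nhat_g - X_ig + X_ig log(X_ig / (s_i Nhat_g))
#'                 + s_j Nhat_g - X_jg + X_jg log(X_jg / (s_j Nhat_g)) ]`
#' with `0 log 0 = 0`.
#'
#' @param table Nonnegative integer count matrix (rows = genomes).
#' @param size_factor `"pairwise"` (default) or `"global"`.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
poisson_dissimilarity <- function(table, size_factor = c("pairwise", "global")) {
  size_factor <- match.arg(size_factor)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (nrow(table) < 2) stop("need at least 2 genomes")
  n <- nrow(table)
  N <- rowSums(table)
  global_mean <- mean(N)
  D <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  xlogx <- function(x, r) {
    # x * log(x / r) with 0 log 0 = 0
    out <- numeric(length(x))
    nz <- x > 0
    out[nz] <- x[nz] * log(x[nz] / r[nz])
    out
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      xi <- table[i, ]
      xj <- table[j, ]
      denom <- if (size_factor == "pairwise") mean(c(N[i], N[j])) else global_mean
      si <- N[i] / denom
      sj <- N[j] / denom
      nhat <- (xi + xj) / (si + sj)
      d <- sum(si * nhat - xi + xlogx(xi, si * nhat) +
                 sj * nhat - xj + xlogx(xj, sj * nhat))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Analysis of similarities (ANOSIM) by permutation
#'
#' Rank-based test of group separation on a distance matrix. All
#' off-diagonal distances are ranked (average ranks on ties);
#' `R = (mean rank between groups - mean rank within groups) / (M / 2)`
#' with `M = n(n-1)/2`. The p-value uses the add-one convention
#' `p = (1 + #permuted R >= observed) / (1 + n_permutations)`, with group
#' labels permuted uniformly under the given seed, so p is never 0 and is
#' reproducible bit-for-bit.
#'
#' @param D Symmetric distance matrix.
#' @param groups Group labels, one per row of `D`; at least 2 groups, each
#'   with at least 2 members.
#' @param n_permutations Number of label permutations (default 99999).
#' @param seed Seed for the permutation stream.
#' @return List of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `seed`, `groups`.
#' @export
anosim <- function(D, groups, n_permutations = 99999, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per matrix row required")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) of size 1 not allowed: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  pair <- which(upper.tri(D), arr.ind = TRUE)
  r <- rank(D[upper.tri(D)])
  M <- length(r)
  stat <- function(g) {
    within <- g[pair[, 1]] == g[pair[, 2]]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- stat(groups)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    if (stat(sample(groups)) >= R_obs) count <- count + 1L
  }
  structure(list(R = R_obs,
                 p = (1 + count) / (1 + n_permutations),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 groups = groups),
            class = "anosim_result")
}
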