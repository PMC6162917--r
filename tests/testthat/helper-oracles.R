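# Independent brute-force oracles. These reimplement the checked quantities
# by the most direct route possible (per-position bitmaps, string sets,
# exhaustive enumeration) and deliberately share no code with the package
# internals they verify.

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# set of distinct canonical k-mers of a sequence (character set)
oracle_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  unique(pmin(kmers, oracle_revcomp(kmers)))
}

# Mash distance from the exact Jaccard of full canonical k-mer sets
oracle_exact_mash <- function(seq_a, seq_b, k) {
  A <- oracle_kmer_set(seq_a, k)
  B <- oracle_kmer_set(seq_b, k)
  j <- length(intersect(A, B)) / length(union(A, B))
  if (j <= 0) return(1)
  if (j >= 1) return(0)
  min(-(1 / k) * log(2 * j / (1 + j)), 1)
}

# connected components of the strict-< threshold graph, by BFS
oracle_components <- function(D, cutoff) {
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(D[v, ] < cutoff & is.na(comp))
      nb <- setdiff(nb, v)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# canonical form of a partition for comparison: sorted list of sorted members
partition_canonical <- function(labels, members) {
  unname(lapply(sort(vapply(split(members, labels),
                            function(m) paste(sort(m), collapse = ","), "")),
                identity))
}

# mean silhouette width from a distance matrix and labels, directly
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(unique(labels[labels != labels[i]]), function(g) {
      mean(D[i, labels == g])
    }, 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# covered bases by per-position boolean accumulation
oracle_covered_bases <- function(pos, width, target, contig_subset = NULL) {
  keep <- if (is.null(contig_subset)) rep(TRUE, length(pos))
          else target %in% contig_subset
  total <- 0
  for (tg in unique(target[keep])) {
    sel <- which(keep & target == tg)
    maxp <- max(pos[sel] + width[sel])
    hit <- logical(maxp)
    for (i in sel) hit[pos[i]:(pos[i] + width[i] - 1)] <- TRUE
    total <- total + sum(hit)
  }
  total
}

# sliding tetranucleotide tally, position by position
oracle_tetra_counts <- function(seq) {
  n <- nchar(seq)
  counts <- integer(0)
  for (i in seq_len(n - 3)) {
    w <- substr(seq, i, i + 3)
    if (grepl("[^ACGT]", w)) next
    cw <- min(w, oracle_revcomp(w))
    counts[cw] <- (if (is.na(counts[cw])) 0L else counts[cw]) + 1L
  }
  counts
}

# Poisson dissimilarity of one pair, term by term with explicit loops
oracle_poisson_pair <- function(xi, xj, si, sj) {
  d <- 0
  for (g in seq_along(xi)) {
    nhat <- (xi[g] + xj[g]) / (si + sj)
    for (x_s in list(c(xi[g], si), c(xj[g], sj))) {
      x <- x_s[1]; s <- x_s[2]
      mu <- s * nhat
      d <- d + mu - x + (if (x > 0) x * log(x / mu) else 0)
    }
  }
  d
}

oracle_poisson_matrix <- function(tab) {
  n <- nrow(tab)
  N <- rowSums(tab)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- (N[i] + N[j]) / 2
      D[i, j] <- D[j, i] <- oracle_poisson_pair(tab[i, ], tab[j, ],
                                                N[i] / denom, N[j] / denom)
    }
  }
  dimnames(D) <- list(rownames(tab), rownames(tab))
  D
}

# ANOSIM R for given labels, written independently (no shared helpers)
oracle_anosim_R <- function(D, labels) {
  n <- nrow(D)
  d <- c()
  within <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, D[i, j])
      within <- c(within, labels[i] == labels[j])
    }
  }
  r <- rank(d)
  (mean(r[!within]) - mean(r[within])) / (length(r) / 2)
}

# exhaustive permutation p over all distinct assignments of two groups of 3
oracle_anosim_exhaustive_p <- function(D, labels) {
  R_obs <- oracle_anosim_R(D, labels)
  n <- nrow(D)
  stopifnot(n == 6)
  picks <- utils::combn(6, 3)
  Rs <- apply(picks, 2, function(ix) {
    lab <- rep("b", 6)
    lab[ix] <- "a"
    oracle_anosim_R(D, lab)
  })
  mean(Rs >= R_obs - 1e-12)
}

# maximal exact repeats by quadratic diagonal scan over raw bytes
oracle_exact_repeats <- function(contigs, min_element, min_contig) {
  ids <- names(contigs)
  keep <- which(nchar(contigs) >= min_contig)
  rows <- list()
  for (pi in seq_along(keep)) {
    for (pj in seq_along(keep)) {
      if (pj <= pi) next
      ai <- keep[pi]; bi <- keep[pj]
      A <- charToRaw(contigs[[ai]])
      B <- charToRaw(contigs[[bi]])
      na <- length(A); nb <- length(B)
      for (off in (-(nb - 1)):(na - 1)) {
        # positions a = b + off overlapping both
        b_lo <- max(1, 1 - off)
        b_hi <- min(nb, na - off)
        if (b_hi - b_lo + 1 < min_element) next
        eq <- A[(b_lo + off):(b_hi + off)] == B[b_lo:b_hi]
        rl <- rle(eq)
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1
        good <- which(rl$values & rl$lengths >= min_element)
        for (g in good) {
          bs <- b_lo + starts[g] - 1
          be <- b_lo + ends[g] - 1
          rows[[length(rows) + 1]] <- data.frame(
            contig_a = ids[ai], a_start = bs + off - 1, a_end = be + off,
            contig_b = ids[bi], b_start = bs - 1, b_end = be,
            length = be - bs + 1, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(contig_a = character(0), a_start = integer(0),
                      a_end = integer(0), contig_b = character(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0)))
  df <- do.call(rbind, rows)
  df[order(df$contig_a, df$contig_b, df$a_start, df$b_start), , drop = FALSE]
}

# Truth-side recount of read categories and coverage, from the manifest
# only (same majority/longer-arm rules as the generator contract, but
# rebuilt from scratch against the truth tables, not the emitted records).
oracle_read_truth <- function(read_info, contig_map, bins, focal_bin,
                              binning_threshold = 1000) {
  cat <- character(nrow(read_info))
  target <- rep(NA_character_, nrow(read_info))
  a_start <- rep(NA_real_, nrow(read_info))
  a_end <- rep(NA_real_, nrow(read_info))
  for (i in seq_len(nrow(read_info))) {
    ri <- read_info[i, ]
    if (ri$chimeric) {
      l1 <- ri$arm_split
      l2 <- ri$read_length - ri$arm_split
      if (l2 > l1) { s <- ri$a2_start; e <- ri$a2_end }
      else { s <- ri$a1_start; e <- ri$a1_start + l1 }
    } else {
      s <- ri$a1_start; e <- ri$a1_end
    }
    cm <- contig_map[contig_map$genome == ri$genome, , drop = FALSE]
    ov <- pmin(e, cm$end) - pmax(s, cm$start)
    if (nrow(cm) == 0 || all(ov <= 0)) {
      cat[i] <- "UNMAPPED"
      next
    }
    k <- which.max(ov)
    target[i] <- cm$contig_id[k]
    a_start[i] <- max(s, cm$start[k])
    a_end[i] <- min(e, cm$end[k])
    bin <- bins$bin_id[match(cm$contig_id[k], bins$contig_id)]
    len <- bins$length[match(cm$contig_id[k], bins$contig_id)]
    cat[i] <- if (!is.na(bin) && bin == focal_bin) "IN_MAG"
      else if (len >= binning_threshold) "LONG_NON_MAG"
      else "SHORT"
  }
  data.frame(read_id = read_info$read_id, category = cat, target = target,
             a_start = a_start, a_end = a_end, stringsAsFactors = FALSE)
}

# truth-side FN binning base ratio via per-position bitmaps
oracle_fn_rate_truth <- function(truth_reads, contig_map, bins, focal_bin,
                                 binning_threshold = 1000) {
  mapped <- truth_reads[!is.na(truth_reads$target), , drop = FALSE]
  binned <- bins$contig_id[!is.na(bins$bin_id) &
                             bins$length >= binning_threshold]
  non_mag <- bins$contig_id[!is.na(bins$bin_id) & bins$bin_id != focal_bin &
                              bins$length >= binning_threshold]
  cov_on <- function(ids) {
    total <- 0
    for (tg in intersect(unique(mapped$target), ids)) {
      sel <- mapped$target == tg
      cs <- contig_map$start[match(tg, contig_map$contig_id)]
      len <- contig_map$end[match(tg, contig_map$contig_id)] - cs
      hit <- logical(len)
      ss <- mapped$a_start[sel] - cs + 1
      ee <- mapped$a_end[sel] - cs
      for (r in seq_along(ss)) hit[ss[r]:ee[r]] <- TRUE
      total <- total + sum(hit)
    }
    total
  }
  num <- cov_on(non_mag)
  den <- cov_on(binned)
  list(fn_rate = if (den == 0) 0 else num / den,
       covered_non_mag = num, covered_binned = den)
}
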