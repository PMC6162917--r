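# Map from the 256 tetranucleotides to their 136 canonical classes
# (each 4-mer identified with its reverse complement).
tetra_classes <- function() {
  bases <- c("A", "C", "G", "T")
  all4 <- apply(expand.grid(bases, bases, bases, bases)[, 4:1], 1, paste,
                collapse = "")
  canon <- pmin(all4, revcomp(all4))
  list(kmers = all4, canonical = canon, classes = sort(unique(canon)))
}

#' Canonical tetranucleotide frequency profiles
#'
#' Sliding-window counts of all 4-mers (windows containing non-ACGT symbols
#' are skipped), with each 4-mer added to its canonical class (the
#' lexicographic minimum of the 4-mer and its reverse complement; 136
#' classes), normalized to sum 1. A sequence and its reverse complement
#' have identical profiles.
#'
#' @param sequences Character vector (or DNAStringSet) of contig sequences;
#'   each must contain at least one clean 4-mer.
#' @return List with `frequencies` (matrix, one row per sequence, 136
#'   columns) and `n_windows` (counted 4-mers per sequence).
#' @export
tetra_profile <- function(sequences) {
  x <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  counts <- Biostrings::oligonucleotideFrequency(x, width = 4)
  tc <- tetra_classes()
  # collapse the 256 columns onto canonical classes
  collapsed <- t(rowsum(t(counts), group = tc$canonical[match(colnames(counts),
                                                              tc$kmers)]))
  collapsed <- collapsed[, tc$classes, drop = FALSE]
  n_windows <- rowSums(collapsed)
  if (any(n_windows == 0))
    stop("sequence(s) too short for a tetranucleotide profile: ",
         paste(which(n_windows == 0), collapse = ", "))
  freq <- collapsed / n_windows
  if (!is.null(names(sequences))) rownames(freq) <- names(sequences)
  list(frequencies = freq, n_windows = n_windows)
}

#' Project composition profiles onto the top two principal components
#'
#' Column-centers the profile matrix and projects onto the two leading
#' principal axes (descending eigenvalue order). Each axis sign is fixed so
#' that its largest-magnitude loading is positive, making coordinates
#' reproducible.
#'
#' @param profiles Numeric matrix (rows = contigs); at least 3 rows.
#' @return List with `scores` (n x 2), `loadings`, `sdev` (all component
#'   standard deviations).
#' @export
pca_project <- function(profiles) {
  if (nrow(profiles) < 3) stop("PCA needs at least 3 profiles")
  pc <- prcomp(profiles, center = TRUE, scale. = FALSE)
  ncomp <- ncol(pc$rotation)
  if (ncomp < 2) {
    warning("profile matrix has rank < 2; second coordinate reported as 0")
    scores <- cbind(pc$x[, 1], 0)
    loadings <- cbind(pc$rotation[, 1], 0)
  } else {
    scores <- pc$x[, 1:2, drop = FALSE]
    loadings <- pc$rotation[, 1:2, drop = FALSE]
  }
  for (j in 1:2) {
    if (all(loadings[, j] == 0)) next
    top <- which.max(abs(loadings[, j]))
    if (loadings[top, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- colnames(loadings) <- c("PC1", "PC2")
  rownames(scores) <- rownames(profiles)
  list(scores = scores, loadings = loadings, sdev = pc$sdev)
}

#' Split SAG contigs by aligned fraction to the matched MAG(s)
#'
#' Per contig, the aligned fraction is the union of its aligned intervals
#' (query side of the blocks) divided by its length; when a SAG matches
#' several MAGs the blocks should already be pooled, so the union spans all
#' of them. Contigs aligning with less than `threshold` of their length go
#' to the non-aligning set; the rest (>= threshold, non-strict) align.
#'
#' @param contig_lengths Named vector of SAG contig lengths.
#' @param blocks Alignment blocks with `query_id`, `q_start`, `q_end`
#'   (0-based half-open on the SAG contig).
#' @param threshold Aligned-fraction cutoff (default 0.05).
#' @return Data frame: `contig_id`, `aligned_fraction` (in percent),
#'   `aligning` (logical).
#' @export
split_by_alignment <- function(contig_lengths, blocks, threshold = 0.05) {
  ids <- names(contig_lengths)
  af <- vapply(ids, function(cid) {
    b <- blocks[blocks$query_id == cid, , drop = FALSE]
    aligned_fraction(b, contig_lengths[[cid]], side = "query")
  }, 0)
  data.frame(contig_id = ids,
             aligned_fraction = unname(af),
             aligning = unname(af) >= 100 * threshold,
             stringsAsFactors = FALSE)
}

#' Metagenome coverage estimate per contig
#'
#' Fold coverage assuming a fixed read length (default 100 bases per
#' metagenome read), and a capped version where no value exceeds
#' `cap_multiplier` times the median coverage over the SAG's contigs.
#'
#' @param read_counts Mapped metagenome reads per contig.
#' @param contig_lengths Contig lengths (same order).
#' @param read_length Assumed metagenome read length.
#' @param cap_multiplier Cap at this multiple of the median.
#' @return Data frame with `coverage` and `capped_coverage`.
#' @export
coverage_estimate <- function(read_counts, contig_lengths,
                              read_length = 100, cap_multiplier = 3) {
  if (any(read_counts < 0) || any(contig_lengths <= 0))
    stop("read counts must be >= 0 and lengths > 0")
  cov <- read_length * read_counts / contig_lengths
  cap <- cap_multiplier * median(cov)
  data.frame(coverage = cov, capped_coverage = pmin(cov, cap))
}

#' Flag contaminant SAG contigs
#'
#' Formalizes the composition/coverage contamination screen: a contig is
#' flagged iff it falls in the non-aligning set (less than
#' `align_threshold` of its length aligned to the matched MAG) AND is
#' either a composition outlier or has anomalously low metagenome
#' coverage. The composition test measures the robust squared distance
#' (per-axis median/MAD standardization) of the contig's PC coordinates
#' from the aligning set's center against the chi-square(2 df)
#' `outlier_quantile` quantile. The coverage test flags coverage below
#' `low_coverage_frac` of the median coverage over the SAG's contigs.
#' With fewer than 3 aligning contigs the composition test is skipped with
#' a warning and the coverage rule alone applies.
#'
#' @param sequences Named character vector of SAG contig sequences.
#' @param blocks SAG-vs-MAG alignment blocks (see [split_by_alignment()]).
#' @param read_counts Named vector of metagenome read counts per contig.
#' @param align_threshold Aligned-fraction split (default 0.05).
#' @param outlier_quantile Chi-square quantile for the PC outlier test.
#' @param low_coverage_frac Low-coverage cutoff as a fraction of the median.
#' @param read_length,cap_multiplier Passed to [coverage_estimate()].
#' @return A contamination report data frame: one row per contig with
#'   aligned fraction, set membership, PC coordinates, coverage, capped
#'   coverage, the two evidence columns and the final `flagged` call.
#' @export
flag_contaminants <- function(sequences, blocks, read_counts,
                              align_threshold = 0.05,
                              outlier_quantile = 0.975,
                              low_coverage_frac = 0.1,
                              read_length = 100, cap_multiplier = 3) {
  lens <- nchar(sequences)
  names(lens) <- names(sequences)
  split <- split_by_alignment(lens, blocks, align_threshold)
  prof <- tetra_profile(sequences)
  pca <- pca_project(prof$frequencies)
  cov <- coverage_estimate(unname(read_counts[names(sequences)]), unname(lens),
                           read_length = read_length,
                           cap_multiplier = cap_multiplier)
  med_cov <- median(cov$coverage)
  low_cov <- cov$coverage < low_coverage_frac * med_cov

  aligning <- split$aligning
  pc_outlier <- rep(FALSE, length(sequences))
  if (sum(aligning) < 3) {
    warning("fewer than 3 aligning contigs: composition outlier test ",
            "skipped, coverage rule alone applies")
  } else {
    center <- apply(pca$scores[aligning, , drop = FALSE], 2, median)
    scale <- apply(pca$scores[aligning, , drop = FALSE], 2, mad)
    scale[scale == 0] <- apply(pca$scores[aligning, , drop = FALSE], 2,
                               sd)[scale == 0]
    scale[scale == 0] <- 1
    d2 <- ((pca$scores[, 1] - center[1]) / scale[1])^2 +
      ((pca$scores[, 2] - center[2]) / scale[2])^2
    pc_outlier <- d2 > qchisq(outlier_quantile, df = 2)
  }
  data.frame(contig_id = names(sequences),
             length = unname(lens),
             aligned_fraction = split$aligned_fraction,
             aligning = aligning,
             pc1 = unname(pca$scores[, 1]),
             pc2 = unname(pca$scores[, 2]),
             coverage = cov$coverage,
             capped_coverage = cov$capped_coverage,
             pc_outlier = unname(pc_outlier),
             low_coverage = low_cov,
             flagged = !aligning & (pc_outlier | low_cov),
             stringsAsFactors = FALSE)
}
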