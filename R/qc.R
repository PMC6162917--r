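#' Completeness and redundancy from single-copy-gene counts
#'
#' Completeness is the percentage of the marker set present at least once;
#' redundancy is the percentage present more than once. Designed for the
#' 139-marker bacterial SCG set, but works for any declared set size.
#'
#' @param counts Nonnegative integer copy counts, one per marker.
#' @param marker_set_size Declared set size (default `length(counts)`).
#' @return Named vector `c(completeness, redundancy)` in percent.
#' @export
completeness_redundancy <- function(counts, marker_set_size = length(counts)) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("marker counts must be nonnegative integers")
  c(completeness = 100 * sum(counts >= 1) / marker_set_size,
    redundancy = 100 * sum(counts >= 2) / marker_set_size)
}

#' Bin approval rule on the 36-marker SCG set
#'
#' A bin is approved when it contains at least `min_unique` distinct
#' markers and, under the default reading, at most `max_multi` markers in
#' more than a single copy. The alternative reading (`rule = "max_copies"`)
#' instead bounds the maximum copy count per marker by `max_multi`.
#'
#' @param counts Copy counts over the 36-marker set.
#' @param min_unique Minimum distinct markers present (default 30).
#' @param max_multi Bound used by the chosen rule (default 2).
#' @param rule `"multi_markers"` (default) or `"max_copies"`.
#' @return Logical flag.
#' @export
approve_bin <- function(counts, min_unique = 30, max_multi = 2,
                        rule = c("multi_markers", "max_copies")) {
  rule <- match.arg(rule)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("marker counts must be nonnegative integers")
  unique_ok <- sum(counts >= 1) >= min_unique
  multi_ok <- if (rule == "multi_markers") sum(counts >= 2) <= max_multi
              else max(counts) <= max_multi
  unique_ok && multi_ok
}

#' Erroneously duplicated elements between contigs
#'
#' All maximal exact repeats of at least `min_element` bases (default 100)
#' occurring on two distinct contigs each of at least `min_contig` bases
#' (default 1000), found by anchoring on shared `min_element`-mers and
#' extending each anchored match to its maximal mismatch-free run on the
#' forward strand. Repeats within a single contig are excluded; each
#' maximal repeat is reported once per contig pair and diagonal.
#' Coordinates are 0-based half-open.
#'
#' @param contigs Named character vector of contig sequences.
#' @param min_element Minimum repeat length (bases).
#' @param min_contig Minimum contig length considered (bases).
#' @return Data frame: `contig_a`, `a_start`, `a_end`, `contig_b`,
#'   `b_start`, `b_end`, `length`, sorted by contig pair and position.
#' @export
find_duplicated_elements <- function(contigs, min_element = 100,
                                     min_contig = 1000) {
  if (is.null(names(contigs))) names(contigs) <- paste0("ctg", seq_along(contigs))
  df <- .exact_repeats_cpp(toupper(as.character(contigs)), names(contigs),
                           as.integer(min_element), as.integer(min_contig))
  df <- df[df$length >= min_element, , drop = FALSE]
  df[order(df$contig_a, df$contig_b, df$a_start, df$b_start), , drop = FALSE]
}
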