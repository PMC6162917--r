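# Keep one primary, non-duplicate record per read (Picard-style
# deduplication + primary-only counting).
primary_records <- function(records) {
  records[records$primary & !records$duplicate, , drop = FALSE]
}

#' Categorize SAG reads against a binned metagenome
#'
#' Each primary, non-duplicate record is placed in exactly one category:
#' `UNMAPPED`; `IN_MAG` if its contig belongs to the focal bin;
#' `LONG_NON_MAG` if the contig was long enough to be binned (default
#' >= 1 kb) but sits in another bin; `SHORT` if the contig was below the
#' binning length threshold.
#'
#' @param records Alignment record data frame (see [emit_alignments()]).
#' @param bins Bin table: `contig_id`, `length`, `bin_id` (`NA` = unbinned).
#' @param focal_bin Bin id of the MAG matched to this SAG.
#' @param binning_threshold Minimum contig length subject to binning;
#'   contigs of exactly this length count as binned.
#' @return Factor of categories, one per record row.
#' @export
categorize_reads <- function(records, bins, focal_bin,
                             binning_threshold = 1000) {
  records <- primary_records(records)
  idx <- match(records$target_id, bins$contig_id)
  missing <- records$mapped & is.na(idx)
  if (any(missing))
    stop("contig(s) absent from bin table: ",
         paste(unique(records$target_id[missing]), collapse = ", "))
  len <- bins$length[idx]
  bin <- bins$bin_id[idx]
  cat <- ifelse(!records$mapped, "UNMAPPED",
         ifelse(!is.na(bin) & bin == focal_bin, "IN_MAG",
         ifelse(len >= binning_threshold, "LONG_NON_MAG", "SHORT")))
  factor(cat, levels = READ_CATEGORIES)
}

#' Bases covered by reads on a set of contigs
#'
#' Number of reference positions covered by at least one aligned (M or D)
#' operation of any primary, non-duplicate record, computed by interval
#' union per contig.
#'
#' @param records Alignment record data frame.
#' @param contig_subset Optional character vector restricting to contigs.
#' @return Total covered bases (numeric).
#' @export
covered_bases <- function(records, contig_subset = NULL) {
  r <- primary_records(records)
  r <- r[r$mapped, , drop = FALSE]
  if (!is.null(contig_subset))
    r <- r[r$target_id %in% contig_subset, , drop = FALSE]
  if (nrow(r) == 0) return(0)
  rw <- cigar_summary(r$cigar)$ref_width
  total <- 0
  for (tg in unique(r$target_id)) {
    sel <- r$target_id == tg
    iv <- IRanges::reduce(IRanges::IRanges(start = r$pos[sel],
                                           width = rw[sel]))
    total <- total + sum(IRanges::width(iv))
  }
  total
}

#' False-negative binning rate from SAG read coverage
#'
#' Bases covered by SAG reads on long contigs binned outside the focal MAG,
#' divided by bases covered on contigs subject to binning. The default
#' denominator is all binned contigs (focal plus non-focal); the
#' `"in_mag"` variant divides by covered bases within the focal MAG's
#' contigs only.
#'
#' @inheritParams categorize_reads
#' @param denominator `"binned"` (default) or `"in_mag"`.
#' @return List with `fn_rate`, `covered_non_mag`, `covered_in_mag`,
#'   `covered_binned`.
#' @export
fn_binning_rate <- function(records, bins, focal_bin,
                            binning_threshold = 1000,
                            denominator = c("binned", "in_mag")) {
  denominator <- match.arg(denominator)
  binned <- !is.na(bins$bin_id) & bins$length >= binning_threshold
  in_mag <- binned & bins$bin_id == focal_bin
  non_mag <- binned & bins$bin_id != focal_bin
  cov_non <- covered_bases(records, bins$contig_id[non_mag])
  cov_in <- covered_bases(records, bins$contig_id[in_mag])
  denom <- if (denominator == "binned") cov_non + cov_in else cov_in
  if (denom == 0) {
    warning("no covered bases in the denominator; fn_rate reported as 0")
    rate <- 0
  } else {
    rate <- cov_non / denom
  }
  list(fn_rate = rate, covered_non_mag = cov_non, covered_in_mag = cov_in,
       covered_binned = cov_non + cov_in)
}

#' Per-pair read-attribution summaries and across-pair aggregates
#'
#' @param record_sets Named list (by SAG id) of alignment record data
#'   frames, each the SAG's reads mapped against the metagenome.
#' @param bins Bin table.
#' @param pairs Data frame with `sag_id`, `focal_bin`; SAGs without a
#'   matched MAG should be absent (a SAG id in `record_sets` missing from
#'   `pairs` is skipped with a warning).
#' @param binning_threshold Binning length threshold.
#' @return List with `per_pair` (one row per SAG-MAG pair: counts,
#'   percentages and covered bases per category, `fn_rate`) and `aggregate`
#'   (median and mean of each category percentage and of `fn_rate`).
#' @export
summarize_pairs <- function(record_sets, bins, pairs,
                            binning_threshold = 1000) {
  unmatched <- setdiff(names(record_sets), pairs$sag_id)
  if (length(unmatched) > 0)
    warning("SAG(s) without a matched MAG skipped: ",
            paste(unmatched, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sag <- pairs$sag_id[i]
    focal <- pairs$focal_bin[i]
    rec <- record_sets[[sag]]
    cat <- categorize_reads(rec, bins, focal, binning_threshold)
    counts <- table(cat)
    pct <- 100 * counts / sum(counts)
    fn <- fn_binning_rate(rec, bins, focal, binning_threshold)
    cov <- vapply(READ_CATEGORIES[1:3], function(cc) {
      ids <- switch(cc,
        IN_MAG = bins$contig_id[!is.na(bins$bin_id) & bins$bin_id == focal &
                                  bins$length >= binning_threshold],
        LONG_NON_MAG = bins$contig_id[!is.na(bins$bin_id) &
                                        bins$bin_id != focal &
                                        bins$length >= binning_threshold],
        SHORT = bins$contig_id[bins$length < binning_threshold])
      covered_bases(rec, ids)
    }, 0)
    data.frame(sag_id = sag, focal_bin = focal,
               n_reads = sum(counts),
               n_in_mag = as.integer(counts["IN_MAG"]),
               n_long_non_mag = as.integer(counts["LONG_NON_MAG"]),
               n_short = as.integer(counts["SHORT"]),
               n_unmapped = as.integer(counts["UNMAPPED"]),
               pct_in_mag = as.numeric(pct["IN_MAG"]),
               pct_long_non_mag = as.numeric(pct["LONG_NON_MAG"]),
               pct_short = as.numeric(pct["SHORT"]),
               pct_unmapped = as.numeric(pct["UNMAPPED"]),
               covered_in_mag = cov[["IN_MAG"]],
               covered_long_non_mag = cov[["LONG_NON_MAG"]],
               covered_short = cov[["SHORT"]],
               fn_rate = fn$fn_rate,
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, rows)
  metrics <- c("pct_in_mag", "pct_long_non_mag", "pct_short",
               "pct_unmapped", "fn_rate")
  aggregate <- data.frame(
    metric = metrics,
    median = vapply(metrics, function(m) median(per_pair[[m]]), 0),
    mean = vapply(metrics, function(m) mean(per_pair[[m]]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_pair = per_pair, aggregate = aggregate)
}
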