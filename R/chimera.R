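#' Flag alignments that look like one arm of an inversion chimera
#'
#' A mapped primary alignment is a chimera candidate when it carries at
#' least `min_clip` soft-clipped bases (summed over both ends by default,
#' the largest single clip in `"max"` mode; hard clips count as clipped
#' query bases), its aligned (M) region covers at least half the read
#' length, and it has at most `max_mismatch` substitutions. Records without
#' a mismatch count are skipped with a warning and are never candidates.
#'
#' @param records Alignment record data frame.
#' @param min_clip Minimum clipped bases (default 20).
#' @param max_mismatch Maximum mismatches on the aligned region (default 2).
#' @param min_aligned_frac Minimum aligned fraction of the read (default 0.5).
#' @param clip_mode `"total"` (left+right, default) or `"max"`.
#' @return Logical vector, one per record row.
#' @export
is_chimera_candidate <- function(records, min_clip = 20, max_mismatch = 2,
                                 min_aligned_frac = 0.5,
                                 clip_mode = c("total", "max")) {
  clip_mode <- match.arg(clip_mode)
  cs <- cigar_summary(records$cigar)
  clip <- if (clip_mode == "total") cs$soft_clip + cs$hard_clip
          else pmax(cs$left_clip, cs$right_clip)
  no_nm <- records$mapped & is.na(records$nm)
  if (any(no_nm))
    warning(sum(no_nm), " mapped record(s) without a mismatch count skipped")
  out <- records$mapped & records$primary &
    !is.na(clip) & clip >= min_clip &
    cs$aligned >= min_aligned_frac * records$read_length &
    !is.na(records$nm) & records$nm <= max_mismatch
  out[is.na(out)] <- FALSE
  out
}

#' Flag alignments that are non-chimeric full-length mappings
#'
#' True when the aligned (M) region covers at least `min_aligned_frac`
#' (default 0.95) of the read length with fewer than `max_mismatch`
#' (default 5, strict) substitutions. Used to rescue chimera candidates
#' that map cleanly somewhere.
#'
#' @inheritParams is_chimera_candidate
#' @return Logical vector, one per record row.
#' @export
is_nonchimeric_mapping <- function(records, min_aligned_frac = 0.95,
                                   max_mismatch = 5) {
  cs <- cigar_summary(records$cigar)
  no_nm <- records$mapped & is.na(records$nm)
  if (any(no_nm))
    warning(sum(no_nm), " mapped record(s) without a mismatch count skipped")
  out <- records$mapped &
    cs$aligned >= min_aligned_frac * records$read_length &
    !is.na(records$nm) & records$nm < max_mismatch
  out[is.na(out)] <- FALSE
  out
}

#' Call chimeric reads across samples
#'
#' Candidates are reads with at least one candidate alignment in any
#' sample; the union is deduplicated, and any read that also maps in a
#' non-chimeric fashion in any sample is rescued (removed). The chimeric
#' set is candidates minus rescued.
#'
#' @param sample_records Named list of alignment record data frames, one
#'   per sample (the SAG-vs-self record set may be included as a sample for
#'   the rescue pass).
#' @param ... Passed to [is_chimera_candidate()] and
#'   [is_nonchimeric_mapping()] threshold arguments by name
#'   (`min_clip`, `max_mismatch_candidate`, `min_aligned_frac_candidate`,
#'   `clip_mode`, `min_aligned_frac_rescue`, `max_mismatch_rescue`).
#' @return List of class `chimera_calls`: `candidates`, `rescued`,
#'   `chimeric` (character vectors of read ids) and `provenance` (data
#'   frame read_id/sample/candidate/nonchimeric).
#' @export
call_chimeras <- function(sample_records,
                          min_clip = 20,
                          max_mismatch_candidate = 2,
                          min_aligned_frac_candidate = 0.5,
                          clip_mode = c("total", "max"),
                          min_aligned_frac_rescue = 0.95,
                          max_mismatch_rescue = 5) {
  clip_mode <- match.arg(clip_mode)
  if (is.null(names(sample_records)))
    names(sample_records) <- paste0("sample", seq_along(sample_records))
  prov <- lapply(names(sample_records), function(s) {
    r <- primary_records(sample_records[[s]])
    data.frame(read_id = r$read_id, sample = s,
               candidate = is_chimera_candidate(
                 r, min_clip = min_clip,
                 max_mismatch = max_mismatch_candidate,
                 min_aligned_frac = min_aligned_frac_candidate,
                 clip_mode = clip_mode),
               nonchimeric = is_nonchimeric_mapping(
                 r, min_aligned_frac = min_aligned_frac_rescue,
                 max_mismatch = max_mismatch_rescue),
               stringsAsFactors = FALSE)
  })
  prov <- do.call(rbind, prov)
  candidates <- sort(unique(prov$read_id[prov$candidate]))
  rescued <- intersect(candidates,
                       unique(prov$read_id[prov$nonchimeric]))
  structure(list(candidates = candidates,
                 rescued = sort(rescued),
                 chimeric = sort(setdiff(candidates, rescued)),
                 provenance = prov),
            class = "chimera_calls")
}

#' Downstream statistics for called chimeric reads
#'
#' Computes the chimeric read fraction; the fraction of chimeric (and of
#' other) reads whose alignment against the SAG's own contigs carries more
#' than `clip_threshold` soft-clipped bases; the fraction of chimeric reads
#' aligned over a contig edge (a soft-clipped alignment whose clipped side
#' is flush with position 1 or with the contig's final position); and the
#' distribution of chimeric reads over the read-attribution categories.
#'
#' @param calls A `chimera_calls` object.
#' @param sag_records Alignment records of the reads vs the SAG's contigs.
#' @param metagenome_records Alignment records vs the metagenome (for the
#'   category distribution); may be `NULL` to skip.
#' @param bins,focal_bin,binning_threshold As in [categorize_reads()].
#' @param contig_lengths Named vector of SAG contig lengths.
#' @param total_reads Total read count for the chimeric fraction.
#' @param clip_threshold Soft-clip threshold for the "soft-clipped vs SAG"
#'   statistic (strictly more than this many bases; default 20).
#' @return List of class `chimera_stats`.
#' @export
chimera_stats <- function(calls, sag_records, contig_lengths, total_reads,
                          metagenome_records = NULL, bins = NULL,
                          focal_bin = NULL, binning_threshold = 1000,
                          clip_threshold = 20) {
  chim <- calls$chimeric
  r <- primary_records(sag_records)
  cs <- cigar_summary(r$cigar)
  is_chim <- r$read_id %in% chim
  clipped <- r$mapped & !is.na(cs$soft_clip) & cs$soft_clip > clip_threshold
  frac <- function(x) if (length(x) == 0) 0 else mean(x)
  softclip_chimeric <- frac(clipped[is_chim])
  softclip_other <- frac(clipped[!is_chim])

  # edge rule: the clipped side abuts the contig boundary
  clen <- unname(contig_lengths[r$target_id])
  at_end <- !is.na(r$pos) & !is.na(cs$ref_width) &
    (r$pos + cs$ref_width - 1) == clen
  edge <- r$mapped &
    ((cs$left_clip > 0 & r$pos == 1) | (cs$right_clip > 0 & at_end))
  edge[is.na(edge)] <- FALSE
  edge_fraction <- frac(edge[is_chim])

  category_distribution <- NULL
  if (!is.null(metagenome_records) && length(chim) > 0) {
    mr <- primary_records(metagenome_records)
    mr <- mr[mr$read_id %in% chim, , drop = FALSE]
    cat <- categorize_reads(mr, bins, focal_bin, binning_threshold)
    category_distribution <- 100 * table(cat) / max(sum(table(cat)), 1)
  }
  structure(list(
    chimeric_fraction = length(chim) / total_reads,
    softclip_vs_sag_chimeric = softclip_chimeric,
    softclip_vs_sag_other = softclip_other,
    edge_fraction = edge_fraction,
    category_distribution = category_distribution),
    class = "chimera_stats")
}
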