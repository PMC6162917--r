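#' Pipeline configuration
#'
#' One place for every numeric constant of the comparison pipeline, each
#' with its standard default: the Mash sketch (15-mers, 100,000 hashes) and
#' the 0.1 clustering cutoff; the 1-kb binning length threshold; the
#' chimera criteria (>= 20 clipped bases, aligned >= half the read, <= 2
#' mismatches; rescue at >= 95% aligned with < 5 mismatches); the 5%
#' aligned-fraction contamination split with the 100-base coverage read
#' length and 3x-median cap; the marker-set choice; and the ANOSIM
#' permutation count (99,999). Unknown keys are rejected because the
#' constructor takes named arguments only.
#'
#' @param sim A [sim_config()] describing the synthetic community.
#' @param sketch_k,sketch_size MinHash sketch parameters.
#' @param cluster_cutoff Single-linkage merge cutoff (strict <).
#' @param binning_threshold Contig length subject to binning.
#' @param min_clip,max_mismatch_candidate,min_aligned_frac_candidate
#'   Chimera-candidate criteria.
#' @param min_aligned_frac_rescue,max_mismatch_rescue Non-chimeric rescue
#'   criteria.
#' @param align_split Contamination aligned-fraction split.
#' @param coverage_read_length Assumed metagenome read length.
#' @param cap_multiplier Coverage cap multiplier.
#' @param outlier_quantile,low_coverage_frac Contamination flag thresholds.
#' @param min_element,min_contig Duplicated-element thresholds.
#' @param marker_set `"139"` or `"36"` for the QC table of record.
#' @param n_permutations,anosim_seed ANOSIM settings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            sketch_k = 15,
                            sketch_size = 100000,
                            cluster_cutoff = 0.1,
                            binning_threshold = 1000,
                            min_clip = 20,
                            max_mismatch_candidate = 2,
                            min_aligned_frac_candidate = 0.5,
                            min_aligned_frac_rescue = 0.95,
                            max_mismatch_rescue = 5,
                            align_split = 0.05,
                            coverage_read_length = 100,
                            cap_multiplier = 3,
                            outlier_quantile = 0.975,
                            low_coverage_frac = 0.1,
                            min_element = 100,
                            min_contig = 1000,
                            marker_set = c("139", "36"),
                            n_permutations = 99999,
                            anosim_seed = 42L) {
  marker_set <- match.arg(marker_set)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full SAG/MAG comparison pipeline on a synthetic community
#'
#' Simulates the community, then runs every stage in order — genome
#' sketching and clustering, SAG-vs-MAG identity/aligned-fraction
#' summaries, read attribution with the false-negative binning rate,
#' chimera calling and statistics, the contamination screen, single-copy
#' gene QC with the bin approval rule and duplicated-element detection,
#' and Poisson-dissimilarity ANOSIM on the COG profiles — writing every
#' stage's tables plus a JSON summary under `outdir`. Deterministic for a
#' fixed config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return The summary list, invisibly; all tables are written to `outdir`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  community <- simulate_community(config$sim)
  mg <- community$metagenome
  sags <- community$sags

  # --- simulation outputs -------------------------------------------------
  write_fasta(community$genomes, file.path(outdir, "genomes.fasta"))
  write_fasta(mg$contigs, file.path(outdir, "metagenome_contigs.fasta"))
  write_bins(mg$bins, file.path(outdir, "bins.tsv"))
  mg_lengths <- structure(mg$bins$length, names = mg$bins$contig_id)
  for (sid in names(sags)) {
    s <- sags[[sid]]
    write_fasta(s$contigs, file.path(outdir, paste0(sid, "_contigs.fasta")))
    write_fasta(s$reads, file.path(outdir, paste0(sid, "_reads.fasta")))
    write_sam(s$records_metagenome, mg_lengths,
              file.path(outdir, paste0(sid, "_vs_metagenome.sam")))
    sag_lengths <- structure(s$contig_map$length,
                             names = s$contig_map$contig_id)
    write_sam(s$records_sag, sag_lengths,
              file.path(outdir, paste0(sid, "_vs_self.sam")))
    write_blocks(s$blocks, file.path(outdir, paste0(sid, "_blocks.tsv")))
  }

  # --- genome clustering --------------------------------------------------
  assemblies <- list()
  for (gid in names(community$genomes)) {
    bin <- paste0("bin_", gid)
    ctg <- mg$bins$contig_id[!is.na(mg$bins$bin_id) & mg$bins$bin_id == bin]
    assemblies[[paste0("MAG_", gid)]] <- mg$contigs[ctg]
  }
  for (sid in names(sags)) assemblies[[sid]] <- sags[[sid]]$contigs
  sketches <- lapply(assemblies, sketch_genome, k = config$sketch_k,
                     sketch_size = config$sketch_size)
  D <- mash_distance_matrix(sketches)
  write.table(data.frame(genome_id = rownames(D), D, check.names = FALSE),
              file.path(outdir, "mash_distances.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  clusters <- single_linkage_clusters(D, config$cluster_cutoff)
  clusters$role <- ifelse(startsWith(clusters$genome_id, "SAG"),
                          "SAG", "MAG")
  write.table(clusters, file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  matched <- vapply(split(clusters$role, clusters$cluster_id),
                    function(r) any(r == "SAG") && any(r == "MAG"), TRUE)

  # --- SAG-vs-MAG identity and aligned fractions --------------------------
  pair_rows <- list()
  for (sid in names(sags)) {
    s <- sags[[sid]]
    if (nrow(s$blocks) == 0) next
    ids <- block_identity_summary(s$blocks)
    sag_len <- sum(s$contig_map$length)
    mag_ctg <- mg$bins[!is.na(mg$bins$bin_id) &
                         mg$bins$bin_id == s$focal_bin, , drop = FALSE]
    mag_len <- sum(mag_ctg$length)
    # per-side aligned bases via per-contig interval unions
    q_aligned <- sum(vapply(unique(s$blocks$query_id), function(cid) {
      b <- s$blocks[s$blocks$query_id == cid, ]
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(b$q_start + 1, b$q_end))))
    }, 0))
    t_aligned <- sum(vapply(unique(s$blocks$target_id), function(cid) {
      b <- s$blocks[s$blocks$target_id == cid, ]
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(b$t_start + 1, b$t_end))))
    }, 0))
    pair_rows[[sid]] <- data.frame(
      sag_id = sid, mag_id = paste0("MAG_", s$truth$genome_id),
      identity_mean = ids[["mean"]], identity_sd = ids[["sd"]],
      pct_sag_aligned = 100 * q_aligned / sag_len,
      pct_mag_aligned = 100 * t_aligned / mag_len,
      stringsAsFactors = FALSE)
  }
  pair_summary <- do.call(rbind, pair_rows)
  write.table(pair_summary, file.path(outdir, "pair_identity.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- read attribution ---------------------------------------------------
  record_sets <- lapply(sags, function(s) s$records_metagenome)
  pairs <- data.frame(sag_id = names(sags),
                      focal_bin = vapply(sags, function(s) s$focal_bin, ""),
                      stringsAsFactors = FALSE)
  attribution <- summarize_pairs(record_sets, mg$bins, pairs,
                                 config$binning_threshold)
  write.table(attribution$per_pair,
              file.path(outdir, "attribution_per_pair.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(attribution$aggregate,
              file.path(outdir, "attribution_aggregate.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- chimera screen -----------------------------------------------------
  chim_rows <- list()
  chim_calls <- list()
  for (sid in names(sags)) {
    s <- sags[[sid]]
    calls <- call_chimeras(
      list(metagenome = s$records_metagenome, sag_self = s$records_sag),
      min_clip = config$min_clip,
      max_mismatch_candidate = config$max_mismatch_candidate,
      min_aligned_frac_candidate = config$min_aligned_frac_candidate,
      min_aligned_frac_rescue = config$min_aligned_frac_rescue,
      max_mismatch_rescue = config$max_mismatch_rescue)
    sag_lengths <- structure(s$contig_map$length,
                             names = s$contig_map$contig_id)
    st <- chimera_stats(calls, s$records_sag, sag_lengths,
                        total_reads = nrow(s$read_info),
                        metagenome_records = s$records_metagenome,
                        bins = mg$bins, focal_bin = s$focal_bin,
                        binning_threshold = config$binning_threshold,
                        clip_threshold = config$min_clip)
    chim_calls[[sid]] <- calls
    chim_rows[[sid]] <- data.frame(
      sag_id = sid,
      n_candidates = length(calls$candidates),
      n_rescued = length(calls$rescued),
      n_chimeric = length(calls$chimeric),
      chimeric_fraction = st$chimeric_fraction,
      softclip_vs_sag_chimeric = st$softclip_vs_sag_chimeric,
      softclip_vs_sag_other = st$softclip_vs_sag_other,
      edge_fraction = st$edge_fraction,
      stringsAsFactors = FALSE)
    status <- data.frame(
      read_id = calls$candidates,
      status = ifelse(calls$candidates %in% calls$rescued,
                      "rescued", "chimeric"), stringsAsFactors = FALSE)
    write.table(status, file.path(outdir, paste0(sid, "_chimera_calls.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  chimera_summary <- do.call(rbind, chim_rows)
  write.table(chimera_summary, file.path(outdir, "chimera_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- contamination screen -----------------------------------------------
  contam_rows <- list()
  for (sid in names(sags)) {
    s <- sags[[sid]]
    counts <- structure(s$metagenome_read_counts$read_count,
                        names = s$metagenome_read_counts$contig_id)
    report <- flag_contaminants(
      s$contigs, s$blocks, counts,
      align_threshold = config$align_split,
      outlier_quantile = config$outlier_quantile,
      low_coverage_frac = config$low_coverage_frac,
      read_length = config$coverage_read_length,
      cap_multiplier = config$cap_multiplier)
    write.table(report, file.path(outdir, paste0(sid, "_contamination.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    truth_contam <- s$truth$contaminant_contigs
    contam_rows[[sid]] <- data.frame(
      sag_id = sid, n_flagged = sum(report$flagged),
      n_planted = length(truth_contam),
      n_true_positive = sum(report$contig_id[report$flagged] %in%
                              truth_contam),
      stringsAsFactors = FALSE)
  }
  contam_summary <- do.call(rbind, contam_rows)
  write.table(contam_summary, file.path(outdir, "contamination_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- single-copy-gene QC ------------------------------------------------
  markers <- if (config$marker_set == "139") community$markers139
             else community$markers36
  qc <- data.frame(genome_id = rownames(markers), t(apply(
    markers, 1, completeness_redundancy)), stringsAsFactors = FALSE)
  qc$approved <- apply(community$markers36, 1, approve_bin)
  write.table(qc, file.path(outdir, "qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  dup_rows <- list()
  for (sid in names(sags)) {
    d <- find_duplicated_elements(sags[[sid]]$contigs,
                                  min_element = config$min_element,
                                  min_contig = config$min_contig)
    if (nrow(d) > 0) dup_rows[[sid]] <- cbind(sag_id = sid, d)
  }
  dup <- if (length(dup_rows) > 0) do.call(rbind, dup_rows) else
    data.frame(sag_id = character(0))
  write.table(dup, file.path(outdir, "duplicated_elements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- functional profiles ------------------------------------------------
  Dp <- poisson_dissimilarity(community$cog_counts)
  write.table(data.frame(genome_id = rownames(Dp), Dp, check.names = FALSE),
              file.path(outdir, "poisson_dissimilarity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # groups: cluster for genomes in matched clusters; genome type overall
  cl_of <- structure(clusters$cluster_id, names = clusters$genome_id)
  in_matched <- names(cl_of)[matched[cl_of]]
  an_cluster <- anosim(Dp[in_matched, in_matched], cl_of[in_matched],
                       n_permutations = config$n_permutations,
                       seed = config$anosim_seed)
  type <- ifelse(startsWith(in_matched, "SAG"), "SAG", "MAG")
  an_type <- anosim(Dp[in_matched, in_matched], type,
                    n_permutations = config$n_permutations,
                    seed = config$anosim_seed)
  anosim_report <- data.frame(
    grouping = c("cluster", "genome_type"),
    R = c(an_cluster$R, an_type$R),
    p = c(an_cluster$p, an_type$p),
    n_permutations = config$n_permutations,
    seed = config$anosim_seed, stringsAsFactors = FALSE)
  write.table(anosim_report, file.path(outdir, "anosim.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # --- summary ------------------------------------------------------------
  agg <- attribution$aggregate
  aggv <- function(metric, col) agg[[col]][agg$metric == metric]
  summary <- list(
    n_genomes = length(community$genomes),
    n_sags = length(sags),
    n_clusters = length(unique(clusters$cluster_id)),
    n_matched_clusters = sum(matched),
    mean_identity_pct = mean(pair_summary$identity_mean),
    mean_pct_sag_aligned = mean(pair_summary$pct_sag_aligned),
    mean_pct_mag_aligned = mean(pair_summary$pct_mag_aligned),
    median_pct_reads_in_mag = aggv("pct_in_mag", "median"),
    median_pct_reads_long_non_mag = aggv("pct_long_non_mag", "median"),
    median_pct_reads_short = aggv("pct_short", "median"),
    median_pct_reads_unmapped = aggv("pct_unmapped", "median"),
    mean_fn_binning_rate = aggv("fn_rate", "mean"),
    mean_chimeric_fraction = mean(chimera_summary$chimeric_fraction),
    mean_softclip_vs_sag_chimeric =
      mean(chimera_summary$softclip_vs_sag_chimeric),
    mean_softclip_vs_sag_other =
      mean(chimera_summary$softclip_vs_sag_other),
    mean_edge_fraction = mean(chimera_summary$edge_fraction),
    n_contaminants_planted = sum(contam_summary$n_planted),
    n_contaminants_flagged = sum(contam_summary$n_flagged),
    n_contaminants_recovered = sum(contam_summary$n_true_positive),
    mean_sag_completeness = mean(qc$completeness[startsWith(qc$genome_id,
                                                            "SAG")]),
    mean_mag_completeness = mean(qc$completeness[startsWith(qc$genome_id,
                                                            "MAG")]),
    n_bins_approved = sum(qc$approved),
    anosim_R_cluster = an_cluster$R,
    anosim_p_cluster = an_cluster$p,
    anosim_R_type = an_type$R,
    anosim_p_type = an_type$p)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
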