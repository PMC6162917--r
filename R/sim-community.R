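#' Simulate the full labelled SAG/MAG community
#'
#' Orchestrates the generator: community genomes plus foreign
#' (contamination-source) genomes, a binned metagenome with planted
#' misbinned and short contigs, one SAG per focal genome (the first
#' `n_sags`) with dropout, chimeras and contamination, truth-consistent
#' alignment records of every SAG's reads against the metagenome and
#' against its own contigs, SAG-vs-MAG alignment blocks, and planted
#' single-copy-marker and COG-category count tables for the QC and
#' functional modules.
#'
#' @param config A [sim_config()].
#' @return List with `genomes`, `foreign_genomes`, `metagenome`
#'   (`contigs`, `bins`, `truth`), `sags` (per SAG: generator output plus
#'   `records_metagenome`, `records_sag`, `blocks`, `focal_bin`),
#'   `markers139`, `markers36`, `cog_counts` (matrices over SAG and MAG
#'   ids), and `manifest` (the combined truth manifest).
#' @export
simulate_community <- function(config) {
  validate_sim_config(config)
  genomes <- simulate_genomes(config, seed = config$seed)
  foreign <- character(0)
  if (config$n_foreign > 0) {
    fcfg <- config
    fcfg$n_genomes <- config$n_foreign
    fcfg$n_sags <- 0L
    foreign <- simulate_genomes(fcfg, ids = sprintf("F%02d",
                                                    seq_len(config$n_foreign)),
                                seed = config$seed + 500L)
  }
  mg <- simulate_metagenome(genomes, config, seed = config$seed + 1L)

  sags <- list()
  for (i in seq_len(config$n_sags)) {
    gid <- names(genomes)[i]
    sid <- sprintf("SAG%02d", i)
    sag <- simulate_sag(genomes[[gid]], foreign, config, genome_id = gid,
                        sag_id = sid, seed = config$seed + 10L + i)
    sag$focal_bin <- paste0("bin_", gid)
    sag$records_metagenome <- emit_alignments(
      sag$read_info, mg$truth$contig_map,
      variant_pos = sag$truth$snp_pos, variant_genome = gid)
    sag$records_sag <- emit_alignments(sag$read_info, sag$contig_map)
    sag$blocks <- sag_mag_blocks(sag, mg, gid)
    sags[[sid]] <- sag
  }

  set.seed(config$seed + 900L)
  markers139 <- plant_marker_table(genomes, mg, sags, config, n_markers = 139L,
                                   prefix = "SCG")
  markers36 <- plant_marker_table(genomes, mg, sags, config, n_markers = 36L,
                                  prefix = "B36_SCG")
  cog_counts <- plant_cog_table(genomes, sags, config)

  manifest <- list(
    contig_source = mg$truth$contig_map,
    contig_bin_truth = mg$truth$contig_bin_truth,
    misbinned = mg$truth$misbinned,
    sags = lapply(sags, function(s)
      c(s$truth, list(read_info = s$read_info[setdiff(names(s$read_info),
                                                      "errors")])))
  )
  list(genomes = genomes, foreign_genomes = foreign, metagenome = mg,
       sags = sags, markers139 = markers139, markers36 = markers36,
       cog_counts = cog_counts, manifest = manifest)
}

# Alignment blocks between a SAG's genuine contigs and the contigs of its
# matched MAG (the focal bin as assigned, so misbinned contigs are absent
# from the union, exactly as a whole-genome aligner against the MAG would
# see it). Identity per block reflects the planted cell-vs-population SNPs.
sag_mag_blocks <- function(sag, mg, genome_id) {
  cm <- mg$truth$contig_map
  bins <- mg$bins
  focal <- paste0("bin_", genome_id)
  mag_ctg <- cm[cm$genome == genome_id &
                  bins$bin_id[match(cm$contig_id, bins$contig_id)] %in% focal, ,
                drop = FALSE]
  snp <- sag$truth$snp_pos
  rows <- list()
  sc <- sag$contig_map[!sag$contig_map$contaminant, , drop = FALSE]
  for (i in seq_len(nrow(sc))) {
    ov <- mag_ctg[mag_ctg$end > sc$start[i] & mag_ctg$start < sc$end[i], ,
                  drop = FALSE]
    if (nrow(ov) == 0) next
    os <- pmax(ov$start, sc$start[i])
    oe <- pmin(ov$end, sc$end[i])
    n_snp <- findInterval(oe, snp + 1) - findInterval(os, snp + 1)
    rows[[length(rows) + 1]] <- data.frame(
      query_id = sc$contig_id[i], target_id = ov$contig_id,
      q_start = os - sc$start[i], q_end = oe - sc$start[i],
      t_start = os - ov$start, t_end = oe - ov$start,
      pct_identity = 100 * (1 - n_snp / (oe - os)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(query_id = character(0), target_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      t_start = integer(0), t_end = integer(0),
                      pct_identity = numeric(0)))
  do.call(rbind, rows)
}

# Plant single-copy markers at uniform genome positions. The MAG of each
# genome carries a marker iff its host contig is assigned to the genome's
# own bin (misbinned contigs lose their markers); the SAG carries it iff
# the position escaped amplification dropout. A small fraction of markers
# is duplicated to exercise the redundancy statistic.
plant_marker_table <- function(genomes, mg, sags, config, n_markers,
                               prefix, dup_rate = 0.02) {
  cm <- mg$truth$contig_map
  bins <- mg$bins
  marker_ids <- sprintf("%s%03d", prefix, seq_len(n_markers))
  rows <- list()
  for (gid in names(genomes)) {
    pos <- sort(sample.int(nchar(genomes[[gid]]), n_markers)) - 1L
    cmg <- cm[cm$genome == gid, , drop = FALSE]
    host <- cmg$contig_id[findInterval(pos, cmg$start)]
    assigned <- bins$bin_id[match(host, bins$contig_id)]
    in_own <- !is.na(assigned) & assigned == paste0("bin_", gid)
    mag_counts <- ifelse(in_own, 1L + rbinom(n_markers, 1, dup_rate), 0L)
    rows[[paste0("MAG_", gid)]] <- mag_counts
    sid <- names(sags)[vapply(sags, function(s) s$truth$genome_id == gid,
                              TRUE)]
    if (length(sid) == 1) {
      di <- sags[[sid]]$truth$dropout_intervals
      dropped <- rep(FALSE, n_markers)
      for (k in seq_len(nrow(di)))
        dropped <- dropped | (pos >= di$start[k] & pos < di$end[k])
      sag_counts <- as.integer(!dropped) *
        (1L + rbinom(n_markers, 1, dup_rate))
      rows[[sid]] <- sag_counts
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- marker_ids
  m
}

# COG-category counts: each genome cluster has its own Dirichlet category
# profile; the MAG and SAG of a cluster draw multinomially from the same
# profile (the SAG with fewer genes, reflecting its lower completeness).
plant_cog_table <- function(genomes, sags, config, n_genes = 2000L) {
  categories <- strsplit("JAKLBDYVTMNZWUOCGEFHIPQRS", "")[[1]]
  rows <- list()
  for (gid in names(genomes)) {
    alpha <- rgamma(length(categories), shape = 2)
    prof <- alpha / sum(alpha)
    rows[[paste0("MAG_", gid)]] <-
      as.integer(stats::rmultinom(1, n_genes, prof))
    sid <- names(sags)[vapply(sags, function(s) s$truth$genome_id == gid,
                              TRUE)]
    if (length(sid) == 1) {
      n_sag <- round(n_genes * (1 - config$sag_dropout))
      rows[[sid]] <- as.integer(stats::rmultinom(1, n_sag, prof))
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- categories
  m
}
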