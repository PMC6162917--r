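#!/usr/bin/env Rscript
# Stage 4 — detect MDA inversion-chimera reads from soft-clipped
# alignments, score the calls against the planted truth, and compute the
# downstream soft-clip / contig-edge statistics.

suppressPackageStartupMessages(library(sagmag))

data_dir <- "results/data"
bins <- read_bins(file.path(data_dir, "bins.tsv"))
clusters <- read.delim("results/clusters.tsv", stringsAsFactors = FALSE)
sag_ids <- clusters$genome_id[clusters$role == "SAG"]

rows <- list()
for (sid in sag_ids) {
  mg_rec <- read_sam(file.path(data_dir,
                               paste0(sid, "_vs_metagenome.sam")))$records
  self <- read_sam(file.path(data_dir, paste0(sid, "_vs_self.sam")))
  calls <- call_chimeras(list(metagenome = mg_rec, sag_self = self$records))
  mag <- clusters$genome_id[clusters$cluster_id ==
                              clusters$cluster_id[clusters$genome_id == sid] &
                              clusters$role == "MAG"][1]
  st <- chimera_stats(calls, self$records, self$contig_lengths,
                      total_reads = length(unique(mg_rec$read_id)),
                      metagenome_records = mg_rec, bins = bins,
                      focal_bin = sub("^MAG_", "bin_", mag))
  truth <- read.delim(file.path(data_dir, paste0(sid, "_truth_chimeric.tsv")),
                      stringsAsFactors = FALSE)$read_id
  tp <- length(intersect(calls$chimeric, truth))
  rows[[sid]] <- data.frame(
    sag_id = sid, n_chimeric = length(calls$chimeric),
    chimeric_pct = 100 * st$chimeric_fraction,
    recall = tp / length(truth),
    precision = tp / max(length(calls$chimeric), 1),
    pct_chimeric_softclipped = 100 * st$softclip_vs_sag_chimeric,
    pct_other_softclipped = 100 * st$softclip_vs_sag_other,
    pct_over_edge = 100 * st$edge_fraction)
  write.table(data.frame(read_id = calls$candidates,
                         status = ifelse(calls$candidates %in% calls$rescued,
                                         "rescued", "chimeric")),
              file.path("results", paste0(sid, "_chimera_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
tab <- do.call(rbind, rows)
write.table(tab, "results/chimera_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf(
  "Chimeric reads: %.2f%% of reads on average (recall %.2f, precision %.2f
vs the planted truth). %.1f%% of chimeric reads align to SAG contigs with
>20 soft-clipped bases, vs %.2f%% of other reads; %.1f%% sit over a contig
edge.\n",
  mean(tab$chimeric_pct), mean(tab$recall), mean(tab$precision),
  mean(tab$pct_chimeric_softclipped), mean(tab$pct_other_softclipped),
  mean(tab$pct_over_edge)))
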