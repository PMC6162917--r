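#!/usr/bin/env Rscript
# Stage 1 — generate the fully labelled synthetic community.
#
# Simulates compositionally distinct genomes, a binned metagenome with
# planted misbinned and sub-1-kb contigs, and one SAG per focal genome with
# MDA dropout, inversion chimeras, foreign contamination and
# truth-consistent alignments. Everything downstream works from the plain
# text files written here; the truth tables are kept separate so later
# stages can score themselves against the plants.

suppressPackageStartupMessages(library(sagmag))

data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

config <- sim_config(seed = 42)
community <- simulate_community(config)
mg <- community$metagenome

write_fasta(community$genomes, file.path(data_dir, "genomes.fasta"))
write_fasta(mg$contigs, file.path(data_dir, "metagenome_contigs.fasta"))
write_bins(mg$bins, file.path(data_dir, "bins.tsv"))
mg_lengths <- structure(mg$bins$length, names = mg$bins$contig_id)

for (sid in names(community$sags)) {
  s <- community$sags[[sid]]
  write_fasta(s$contigs, file.path(data_dir, paste0(sid, "_contigs.fasta")))
  write_fasta(s$reads, file.path(data_dir, paste0(sid, "_reads.fasta")))
  write_sam(s$records_metagenome, mg_lengths,
            file.path(data_dir, paste0(sid, "_vs_metagenome.sam")),
            sequences = s$reads)
  write_sam(s$records_sag,
            structure(s$contig_map$length, names = s$contig_map$contig_id),
            file.path(data_dir, paste0(sid, "_vs_self.sam")),
            sequences = s$reads)
  write_blocks(s$blocks, file.path(data_dir, paste0(sid, "_blocks.tsv")))
  write.table(s$metagenome_read_counts,
              file.path(data_dir, paste0(sid, "_mg_read_counts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # truth tables for later scoring
  write.table(data.frame(read_id = s$truth$chimeric_reads),
              file.path(data_dir, paste0(sid, "_truth_chimeric.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(contig_id = s$truth$contaminant_contigs),
              file.path(data_dir, paste0(sid, "_truth_contaminants.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(data.frame(contig_id = mg$truth$misbinned),
            file.path(data_dir, "truth_misbinned.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_count_table(community$markers139, file.path(data_dir, "markers139.tsv"))
write_count_table(community$markers36, file.path(data_dir, "markers36.tsv"))
write_count_table(community$cog_counts, file.path(data_dir, "cog_counts.tsv"))

cat(sprintf(
  "Simulated %d genomes (%d foreign), %d metagenome contigs (%d misbinned,
%d short), %d SAGs with %s reads each.\n",
  length(community$genomes), length(community$foreign_genomes),
  length(mg$contigs), length(mg$truth$misbinned),
  sum(mg$bins$length < 1000), length(community$sags),
  format(length(community$sags$SAG01$reads), big.mark = ",")))
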