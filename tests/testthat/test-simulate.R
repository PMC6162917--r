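test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(misbin_rate = 1.2), "misbin_rate")
  expect_error(sim_config(sag_dropout = 1), "sag_dropout")
  expect_error(sim_config(sag_read_length = 50), "sag_read_length")
  expect_error(sim_config(genome_length = 20000,
                          contig_len_range = c(1000, 5000)), "genome_length")
  expect_error(sim_config(n_sags = 9), "n_sags")
})

test_that("the generator is deterministic: same config, same outputs", {
  g1 <- simulate_genomes(small_config())
  g2 <- simulate_genomes(small_config())
  expect_identical(g1, g2)
  com2 <- simulate_community(small_config())
  expect_identical(test_community$genomes, com2$genomes)
  expect_identical(test_community$metagenome$bins, com2$metagenome$bins)
  expect_identical(test_community$sags$SAG01$reads, com2$sags$SAG01$reads)
  expect_identical(test_community$sags$SAG01$records_metagenome,
                   com2$sags$SAG01$records_metagenome)
})

test_that("order-0 uniform chains give near-uniform tetranucleotide usage", {
  cfg <- sim_config(n_genomes = 1, genome_length = 500000, markov_order = 0,
                    seed = 3)
  g <- simulate_genomes(cfg, transition = list(matrix(0.25, 1, 4)))
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(g[[1]]), width = 4)
  n <- sum(counts)
  p <- 1 / 256
  # binomial SE per word, inflated for clumping of self-overlapping words
  # (a word with period d co-occurs with itself at lag d with prob 4^-d),
  # judged at the Bonferroni level for 256 simultaneous cells (z = 3.9)
  clump <- vapply(names(counts), function(w) {
    periods <- Filter(function(d) substr(w, 1, 4 - d) == substr(w, d + 1, 4),
                      1:3)
    sqrt(1 + 2 * sum(0.25^unlist(periods)))
  }, 0)
  se <- sqrt(n * p * (1 - p)) * clump
  expect_true(all(abs(counts - n * p) <= 3.9 * se))
})

test_that("genomes carry distinct composition signatures", {
  cfg <- sim_config(n_genomes = 2, genome_length = 100000, seed = 5)
  g <- simulate_genomes(cfg)
  win <- function(s) substring(s, seq(1, 95001, 5000), seq(5000, 100000, 5000))
  w1 <- win(g[[1]]); w2 <- win(g[[2]])
  prof <- tetra_profile(c(w1, w2))$frequencies
  D <- as.matrix(dist(prof))
  labels <- rep(1:2, each = length(w1))
  expect_gt(oracle_silhouette(D, labels), 0)
  # inter-genome profile distance exceeds intra-genome windowed distance
  inter <- mean(D[labels == 1, labels == 2])
  intra <- mean(D[labels == 1, labels == 1][upper.tri(diag(length(w1)))])
  expect_gt(inter, intra)
})

test_that("metagenome respects misbinning and short-contig controls", {
  cfg0 <- small_config(misbin_rate = 0)
  g <- simulate_genomes(cfg0)
  mg0 <- simulate_metagenome(g, cfg0)
  expect_length(mg0$truth$misbinned, 0)

  cfg_ns <- small_config(short_contig_fraction = 0)
  mg_ns <- simulate_metagenome(simulate_genomes(cfg_ns), cfg_ns)
  expect_true(all(mg_ns$bins$length >= 1000))

  # planted misbinned counts sit inside the 99% binomial band of the rate
  mg <- test_community$metagenome
  n_long <- sum(mg$bins$length >= 1000)
  n_mis <- length(mg$truth$misbinned)
  band <- qbinom(c(0.005, 0.995), n_long, small_config()$misbin_rate)
  expect_gte(n_mis, band[1])
  expect_lte(n_mis, band[2])
  # misbinned contigs are all long and carry a wrong bin assignment
  idx <- match(mg$truth$misbinned, mg$bins$contig_id)
  expect_true(all(mg$bins$length[idx] >= 1000))
  expect_true(all(mg$bins$bin_id[idx] !=
                    mg$truth$contig_bin_truth[mg$truth$misbinned]))
  expect_error(simulate_metagenome(g[1], small_config()), "wrong bin")
})

test_that("contigs reassemble the genomes and the bin table matches lengths", {
  mg <- test_community$metagenome
  cm <- mg$truth$contig_map
  for (gid in names(test_community$genomes)) {
    sel <- cm$genome == gid
    expect_equal(paste(mg$contigs[cm$contig_id[sel]], collapse = ""),
                 unname(test_community$genomes[gid]))
  }
  expect_identical(unname(nchar(mg$contigs[mg$bins$contig_id])),
                   mg$bins$length)
})

test_that("SAG dropout, chimera planting and contamination follow the config", {
  cfg <- small_config()
  sag <- test_community$sags$SAG01
  di <- sag$truth$dropout_intervals
  target <- round(cfg$sag_dropout * cfg$genome_length)
  expect_lte(abs(sum(di$end - di$start) - target), 10000)  # one segment
  band <- qbinom(c(0.005, 0.995), length(sag$reads), cfg$chimera_rate)
  expect_gte(length(sag$truth$chimeric_reads), band[1])
  expect_lte(length(sag$truth$chimeric_reads), band[2])
  expect_length(sag$truth$contaminant_contigs, cfg$contam_contig_count)

  cfg0 <- small_config(chimera_rate = 0, contam_contig_count = 0)
  sag0 <- simulate_sag(test_community$genomes[[1]], character(0), cfg0)
  expect_length(sag0$truth$chimeric_reads, 0)
  expect_length(sag0$truth$contaminant_contigs, 0)
  # no reads fall inside dropout regions
  gi <- sag$read_info[sag$read_info$genome == sag$truth$genome_id &
                        !sag$read_info$chimeric, ]
  for (k in seq_len(nrow(di)))
    expect_false(any(gi$a1_start < di$end[k] & gi$a1_end > di$start[k]))
})

test_that("emitted alignments follow the majority/clip contract", {
  cm <- data.frame(contig_id = c("c1", "c2"), genome = "G",
                   start = c(0, 1000), end = c(1000, 2000),
                   stringsAsFactors = FALSE)
  ri <- data.frame(read_id = c("inside", "chim", "straddle"), genome = "G",
                   a1_start = c(100, 200, 900), a1_end = c(250, 290, 1050),
                   chimeric = c(FALSE, TRUE, FALSE),
                   arm_split = c(NA, 90L, NA),
                   a2_start = c(NA, 500, NA), a2_end = c(NA, 560, NA),
                   read_length = 150L, stringsAsFactors = FALSE)
  ri$errors <- list(integer(0), integer(0), integer(0))
  rec <- emit_alignments(ri, cm)
  expect_equal(rec$cigar[rec$read_id == "inside"], "150M")
  expect_equal(rec$pos[rec$read_id == "inside"], 101)
  # chimera arms 90 / 60: longer arm aligned, 60 soft-clipped at the end
  expect_equal(rec$cigar[rec$read_id == "chim"], "90M60S")
  # straddling read: 100 bases on c1, 50 on c2 -> majority on c1
  expect_equal(rec$target_id[rec$read_id == "straddle"], "c1")
  expect_equal(rec$cigar[rec$read_id == "straddle"], "100M50S")
  expect_equal(rec$pos[rec$read_id == "straddle"], 901)

  # a read from a genome absent from the tiling is unmapped
  ri2 <- ri[1, ]
  ri2$genome <- "other"
  ri2$errors <- list(integer(0))
  rec2 <- emit_alignments(ri2, cm)
  expect_false(rec2$mapped)
})

test_that("every read yields exactly one record and rates are conserved", {
  sag <- test_community$sags$SAG01
  rec <- sag$records_metagenome
  expect_setequal(rec$read_id, sag$read_info$read_id)
  expect_equal(nrow(rec), nrow(sag$read_info))
  # contaminant-derived reads are unmapped against the metagenome
  contam_reads <- sag$read_info$read_id[sag$read_info$genome !=
                                          sag$truth$genome_id]
  expect_true(all(!rec$mapped[rec$read_id %in% contam_reads]))
  # non-chimeric focal reads are never unmapped (the tiling is complete)
  own <- sag$read_info$read_id[sag$read_info$genome == sag$truth$genome_id]
  expect_true(all(rec$mapped[rec$read_id %in% own]))
})
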