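#' Simulate a single-amplified genome (SAG) with MDA artifacts
#'
#' The sequenced cell's genome is the community genome with substitutions at
#' rate `sag_divergence`. It is partitioned into 2-10 kb segments; segments
#' are dropped at random until `sag_dropout` of the genome has zero coverage
#' (amplification dropout), and each surviving segment receives an
#' independent Gamma(shape 0.3) amplification weight, reproducing the highly
#' uneven coverage typical of MDA. Reads are placed multinomially across
#' segments; a `chimera_rate` fraction are built as inversion chimeras (a
#' forward arm of 20 to read_length-20 bases joined to the reverse
#' complement of a segment starting within 5 kb). `contam_contig_count`
#' contigs sampled from `foreign_genomes` are appended to the assembly, and
#' also seed reads. SAG contigs are the surviving genome segments; assembly
#' is not simulated beyond this segmentation.
#'
#' @param genome Single community genome sequence (character).
#' @param foreign_genomes Named character vector of genomes outside the
#'   community, sourcing contamination. May be empty if
#'   `contam_contig_count` is 0.
#' @param config A [sim_config()].
#' @param genome_id Id of the focal genome (used in truth records).
#' @param sag_id Id prefix for SAG contigs and reads.
#' @param seed Seed (default `config$seed + 2`); `NULL` continues the stream.
#'
#' @return List with `contigs` (named character vector, contaminants
#'   included), `contig_map` (contig source coordinates, 0-based half-open,
#'   with a `contaminant` flag), `reads` (named character vector),
#'   `read_info` (per-read truth: source genome and interval, chimera arm
#'   geometry, sequencing-error query offsets as a list column),
#'   `metagenome_read_counts` (per-contig metagenome read counts for the
#'   coverage screen), and `truth` (dropout intervals, chimeric read ids,
#'   contaminant contig ids, SNP positions of the cell vs the population
#'   genome, 0-based).
#' @export
simulate_sag <- function(genome, foreign_genomes, config,
                         genome_id = "G01", sag_id = "SAG01",
                         seed = config$seed + 2L) {
  validate_sim_config(config)
  if (config$sag_dropout >= 1)
    stop("sag_dropout must be < 1: the whole genome cannot be dropped")
  if (config$contam_contig_count > 0 && length(foreign_genomes) == 0)
    stop("contam_contig_count > 0 requires foreign genomes")
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome)
  read_len <- config$sag_read_length

  # the cell's genome diverges from the population genome by point mutations
  n_snp <- rbinom(1L, L, config$sag_divergence)
  snp_pos <- sort(sample.int(L, n_snp))          # 1-based
  cell_genome <- mutate_positions(genome, snp_pos)

  # segmentation and dropout
  seg_len <- tile_lengths(L, c(2000L, 10000L))
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len
  nseg <- length(seg_len)
  dropped <- rep(FALSE, nseg)
  target <- round(config$sag_dropout * L)
  if (target > 0) {
    ord <- sample.int(nseg)
    cum <- cumsum(seg_len[ord])
    k <- which(cum >= target)[1]
    if (is.na(k)) k <- nseg
    dropped[ord[seq_len(k)]] <- TRUE
  }
  keep <- which(!dropped)
  if (length(keep) == 0) stop("dropout removed every segment")

  # SAG contigs = surviving segments of the cell genome, plus contaminants
  src <- data.frame(genome = genome_id, start = seg_start[keep],
                    end = seg_end[keep], contaminant = FALSE,
                    stringsAsFactors = FALSE)
  if (config$contam_contig_count > 0) {
    for (j in seq_len(config$contam_contig_count)) {
      fg <- sample(names(foreign_genomes), 1L)
      cl <- sample(2000:6000, 1L)
      cs <- sample.int(nchar(foreign_genomes[[fg]]) - cl + 1L, 1L) - 1L
      src <- rbind(src, data.frame(genome = fg, start = cs, end = cs + cl,
                                   contaminant = TRUE,
                                   stringsAsFactors = FALSE))
    }
  }
  src$contig_id <- sprintf("%s_c%03d", sag_id, seq_len(nrow(src)))
  src$length <- src$end - src$start
  seqs <- character(nrow(src))
  for (i in seq_len(nrow(src))) {
    gseq <- if (src$contaminant[i]) foreign_genomes[[src$genome[i]]]
            else cell_genome
    seqs[i] <- substring(gseq, src$start[i] + 1L, src$end[i])
  }
  names(seqs) <- src$contig_id

  # per-segment amplification weights, then multinomial read placement
  w <- rgamma(nrow(src), shape = 0.3) + 1e-9
  n_reads <- round(config$sag_depth * L / read_len)
  seg_of <- sample.int(nrow(src), n_reads, replace = TRUE,
                       prob = w * src$length)
  p <- src$start[seg_of] +
    floor(runif(n_reads) * (src$length[seg_of] - read_len + 1L))
  read_genome <- src$genome[seg_of]

  chim <- runif(n_reads) < config$chimera_rate
  a <- rep(NA_integer_, n_reads)            # forward-arm length
  a2s <- rep(NA_real_, n_reads)             # inverted-arm start
  genome_lengths <- c(structure(L, names = genome_id),
                      vapply(foreign_genomes, nchar, 0L))
  glen <- unname(genome_lengths[read_genome])
  if (any(chim)) {
    idx <- which(chim)
    a[idx] <- sample(20:(read_len - 20L), length(idx), replace = TRUE)
    b <- read_len - a[idx]
    lo <- pmax(0, p[idx] - 5000)
    hi <- pmin(glen[idx] - b, p[idx] + 5000)
    a2s[idx] <- lo + floor(runif(length(idx)) * (hi - lo + 1))
  }
  a1_end <- ifelse(chim, p + a, p + read_len)
  a2_end <- ifelse(chim, a2s + (read_len - a), NA_real_)

  # read sequences, extracted per source genome to avoid copying genomes
  reads <- character(n_reads)
  for (g in unique(read_genome)) {
    gseq <- if (g == genome_id) cell_genome else foreign_genomes[[g]]
    sel <- which(read_genome == g)
    reads[sel] <- substring(gseq, p[sel] + 1L, a1_end[sel])
    csel <- sel[chim[sel]]
    if (length(csel) > 0)
      reads[csel] <- paste0(reads[csel],
                            revcomp(substring(gseq, a2s[csel] + 1L,
                                              a2_end[csel])))
  }

  # substitution sequencing errors (0-based query offsets)
  n_err <- rbinom(n_reads, read_len, config$read_error_rate)
  errors <- vector("list", n_reads)
  for (i in which(n_err > 0)) {
    offs <- sort(sample.int(read_len, n_err[i])) - 1L
    errors[[i]] <- offs
    reads[i] <- mutate_positions(reads[i], offs + 1L)
  }
  read_ids <- sprintf("%s_r%06d", sag_id, seq_len(n_reads))
  names(reads) <- read_ids

  read_info <- data.frame(
    read_id = read_ids, genome = read_genome,
    a1_start = p, a1_end = a1_end, chimeric = chim,
    arm_split = a, a2_start = a2s, a2_end = a2_end,
    read_length = read_len, stringsAsFactors = FALSE)
  read_info$errors <- errors

  # metagenome read counts per SAG contig (reads assumed 100 bases long):
  # genuine contigs at metagenome_depth, contaminants at contam_coverage
  depth <- ifelse(src$contaminant, config$contam_coverage,
                  config$metagenome_depth)
  mg_counts <- rpois(nrow(src), depth * src$length / 100)
  counts <- data.frame(contig_id = src$contig_id, length = src$length,
                       read_count = mg_counts, stringsAsFactors = FALSE)

  drop_iv <- data.frame(genome = genome_id, start = seg_start[dropped],
                        end = seg_end[dropped], stringsAsFactors = FALSE)
  list(contigs = seqs,
       contig_map = src[c("contig_id", "genome", "start", "end", "length",
                          "contaminant")],
       reads = reads,
       read_info = read_info,
       metagenome_read_counts = counts,
       truth = list(sag_id = sag_id, genome_id = genome_id,
                    dropout_intervals = drop_iv,
                    chimeric_reads = read_ids[chim],
                    contaminant_contigs = src$contig_id[src$contaminant],
                    snp_pos = snp_pos - 1L))
}
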