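#' Configuration for the synthetic SAG/MAG community
#'
#' Bundles every knob of the synthetic community generator. The defaults
#' describe the study conditions used throughout the package: a small
#' community of compositionally distinct genomes, a metagenome tiled into
#' contigs with a planted misbinning rate and a planted fraction of short
#' (sub-1-kb, unbinned) contigs, and MDA-style SAGs with amplification
#' dropout, inversion-chimera reads and foreign-genome contamination.
#'
#' @param n_genomes Number of community genomes (each becomes one bin/MAG).
#' @param genome_length Bases per genome. Must be at least 10x the longest
#'   metagenome contig.
#' @param markov_order Order of the per-genome Markov composition model.
#'   Order 3 gives each genome a distinct tetranucleotide signature.
#' @param contig_len_range Length-2 vector, (min, max) bases for long
#'   metagenome contigs.
#' @param short_contig_fraction Fraction of metagenome contigs drawn short
#'   (200-999 bases); short contigs are never binned.
#' @param misbin_rate Fraction of each genome's long (>= 1 kb) contigs
#'   assigned to a uniformly chosen wrong bin; planted count per genome is
#'   `round(misbin_rate * n_long)`.
#' @param sag_dropout Fraction of the focal genome with zero SAG coverage
#'   (amplification dropout). Must be < 1.
#' @param sag_read_length SAG read length in bases (>= 100).
#' @param sag_depth Mean fold-coverage of SAG reads over the whole genome.
#' @param chimera_rate Fraction of SAG reads built as inversion chimeras
#'   (forward arm joined to the reverse complement of a nearby segment).
#' @param contam_contig_count Number of foreign-composition contigs injected
#'   into each SAG assembly.
#' @param n_foreign Number of extra genomes simulated outside the community;
#'   contaminant contigs are sampled from these, so they are absent from the
#'   metagenome and recruit (almost) no metagenome reads.
#' @param n_sags Number of community genomes that receive a SAG (the first
#'   `n_sags` genomes), emulating partial SAG/MAG overlap; default
#'   `min(3, n_genomes)`.
#' @param sag_divergence Per-base substitution rate between the sequenced
#'   cell and the population genome in the metagenome; produces realistic
#'   (~99.5%) SAG-vs-MAG nucleotide identity.
#' @param read_error_rate Per-base substitution sequencing-error rate on SAG
#'   reads (no indels are simulated).
#' @param metagenome_depth Fold-coverage used to draw per-contig metagenome
#'   read counts for genuine SAG contigs (reads assumed 100 bases).
#' @param contam_coverage Fold-coverage for contaminant contigs in the
#'   metagenome (well below `metagenome_depth`, as free DNA would be).
#' @param seed Integer seed; fully determines all generator outputs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 5,
                       genome_length = 200000,
                       markov_order = 3,
                       contig_len_range = c(1000, 5000),
                       short_contig_fraction = 0.1,
                       misbin_rate = 0.05,
                       sag_dropout = 0.2,
                       sag_read_length = 150,
                       sag_depth = 15,
                       chimera_rate = 0.02,
                       contam_contig_count = 5,
                       n_foreign = 2,
                       n_sags = NULL,
                       sag_divergence = 0.005,
                       read_error_rate = 0.001,
                       metagenome_depth = 10,
                       contam_coverage = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genome_length = as.integer(genome_length),
    markov_order = as.integer(markov_order),
    contig_len_range = as.integer(contig_len_range),
    short_contig_fraction = short_contig_fraction,
    misbin_rate = misbin_rate,
    sag_dropout = sag_dropout,
    sag_read_length = as.integer(sag_read_length),
    sag_depth = sag_depth,
    chimera_rate = chimera_rate,
    contam_contig_count = as.integer(contam_contig_count),
    n_foreign = as.integer(n_foreign),
    n_sags = as.integer(if (is.null(n_sags)) min(3L, n_genomes) else n_sags),
    sag_divergence = sag_divergence,
    read_error_rate = read_error_rate,
    metagenome_depth = metagenome_depth,
    contam_coverage = contam_coverage,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(sprintf("sim_config field '%s' must be a fraction in [0, 1]",
                   field), call. = FALSE)
  }
  for (f in c("short_contig_fraction", "misbin_rate", "sag_dropout",
              "chimera_rate", "sag_divergence", "read_error_rate"))
    chk_frac(f)
  chk_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop(sprintf("sim_config field '%s' must be positive", field),
           call. = FALSE)
  }
  for (f in c("n_genomes", "genome_length", "sag_read_length", "sag_depth",
              "metagenome_depth"))
    chk_pos(f)
  if (length(cfg$contig_len_range) != 2 ||
      any(cfg$contig_len_range < 200) || diff(cfg$contig_len_range) < 0)
    stop("sim_config field 'contig_len_range' must be (min, max) with min >= 200",
         call. = FALSE)
  if (cfg$genome_length < 10 * max(cfg$contig_len_range))
    stop("sim_config field 'genome_length' must be >= 10x max contig length",
         call. = FALSE)
  if (cfg$sag_read_length < 100)
    stop("sim_config field 'sag_read_length' must be >= 100", call. = FALSE)
  if (cfg$sag_dropout >= 1)
    stop("sim_config field 'sag_dropout' must be < 1", call. = FALSE)
  if (cfg$markov_order < 0 || cfg$markov_order > 6)
    stop("sim_config field 'markov_order' must be in 0..6", call. = FALSE)
  if (cfg$contam_contig_count < 0)
    stop("sim_config field 'contam_contig_count' must be >= 0", call. = FALSE)
  if (cfg$n_sags < 0 || cfg$n_sags > cfg$n_genomes)
    stop("sim_config field 'n_sags' must be in 0..n_genomes", call. = FALSE)
  if (is.na(cfg$seed))
    stop("sim_config field 'seed' must be an integer", call. = FALSE)
  invisible(cfg)
}
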