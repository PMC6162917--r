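# Tile a genome of length L into contiguous segment lengths drawn uniformly
# from len_range, with a short_frac chance of a short (200-999 base) segment.
# The remainder is absorbed so no segment falls below len_range[1] except
# deliberate short draws; an over-long remainder is split in two.
tile_lengths <- function(L, len_range, short_frac = 0) {
  lens <- integer(0)
  pos <- 0L
  while (pos < L) {
    remaining <- L - pos
    l <- if (short_frac > 0 && runif(1) < short_frac)
      sample(200:999, 1L)
    else
      sample(len_range[1]:len_range[2], 1L)
    if (remaining - l < len_range[1]) {
      if (remaining > len_range[2]) {
        lens <- c(lens, remaining - len_range[1], len_range[1])
      } else {
        lens <- c(lens, remaining)
      }
      break
    }
    lens <- c(lens, l)
    pos <- pos + l
  }
  lens
}

#' Simulate a binned metagenome from community genomes
#'
#' Tiles each genome into contigs, assigns every contig of at least 1 kb to
#' its source bin except a planted `misbin_rate` fraction sent to a uniformly
#' chosen wrong bin, and leaves sub-1-kb contigs unbinned. The planted
#' misbinned count per genome is `round(misbin_rate * n_long)`.
#'
#' @param genomes Named character vector from [simulate_genomes()].
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed + 1`); `NULL` continues the stream.
#'
#' @return List with `contigs` (named character vector), `bins` (a bin table:
#'   `contig_id`, `length`, `bin_id`, with `NA` bin for short contigs), and
#'   `truth` (list: `contig_map` data frame of contig source coordinates,
#'   0-based half-open; `contig_bin_truth`; `misbinned` contig ids).
#' @export
simulate_metagenome <- function(genomes, config, seed = config$seed + 1L) {
  validate_sim_config(config)
  if (length(genomes) == 0) stop("'genomes' must be nonempty")
  if (config$misbin_rate > 0 && length(genomes) < 2)
    stop("misbin_rate > 0 requires at least two genomes (no wrong bin exists)")
  if (!is.null(seed)) set.seed(seed)

  maps <- vector("list", length(genomes))
  for (gi in seq_along(genomes)) {
    gid <- names(genomes)[gi]
    lens <- tile_lengths(nchar(genomes[[gi]]), config$contig_len_range,
                         config$short_contig_fraction)
    ends <- cumsum(lens)
    starts <- ends - lens
    maps[[gi]] <- data.frame(
      contig_id = sprintf("%s_c%04d", gid, seq_along(lens)),
      genome = gid, start = starts, end = ends, length = lens,
      stringsAsFactors = FALSE)
  }
  contig_map <- do.call(rbind, maps)
  contigs <- substring(genomes[contig_map$genome],
                       contig_map$start + 1L, contig_map$end)
  names(contigs) <- contig_map$contig_id

  bin_of <- function(g) paste0("bin_", g)
  true_bin <- ifelse(contig_map$length >= 1000L,
                     bin_of(contig_map$genome), NA_character_)
  assigned <- true_bin
  misbinned <- character(0)
  all_bins <- bin_of(names(genomes))
  if (config$misbin_rate > 0) {
    for (gid in names(genomes)) {
      long_ids <- contig_map$contig_id[contig_map$genome == gid &
                                         contig_map$length >= 1000L]
      n_mis <- round(config$misbin_rate * length(long_ids))
      if (n_mis == 0) next
      picked <- sample(long_ids, n_mis)
      wrong <- sample(setdiff(all_bins, bin_of(gid)), n_mis, replace = TRUE)
      assigned[match(picked, contig_map$contig_id)] <- wrong
      misbinned <- c(misbinned, picked)
    }
  }
  bins <- data.frame(contig_id = contig_map$contig_id,
                     length = contig_map$length,
                     bin_id = assigned, stringsAsFactors = FALSE)
  list(contigs = contigs, bins = bins,
       truth = list(contig_map = contig_map[c("contig_id", "genome",
                                              "start", "end", "length")],
                    contig_bin_truth = structure(true_bin,
                                                 names = contig_map$contig_id),
                    misbinned = misbinned))
}
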