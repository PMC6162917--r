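#' Simulate compositionally distinct genomes
#'
#' Each genome is drawn from its own Markov chain of the configured order,
#' with transition rows sampled from a flat Dirichlet. Independent transition
#' matrices give every genome a distinct tetranucleotide signature, the
#' feature the contamination screen exploits.
#'
#' @param config A [sim_config()].
#' @param transition Optional list of transition matrices (one per genome,
#'   `4^markov_order` rows by 4 columns), overriding the random draw. Used
#'   e.g. to force uniform base composition at order 0.
#' @param ids Optional character vector of genome ids (default `G01`, ...).
#' @param seed Seed applied before generation (default `config$seed`); pass
#'   `NULL` to continue the current RNG stream.
#'
#' @return Named character vector of genome sequences over A/C/G/T.
#' @export
simulate_genomes <- function(config, transition = NULL, ids = NULL,
                             seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_genomes
  if (is.null(ids)) ids <- sprintf("G%02d", seq_len(n))
  ncontext <- 4L^config$markov_order
  genomes <- character(n)
  for (i in seq_len(n)) {
    if (is.null(transition)) {
      g <- matrix(rgamma(ncontext * 4L, shape = 1), nrow = ncontext)
      tm <- g / rowSums(g)
    } else {
      tm <- transition[[i]]
      if (nrow(tm) != ncontext || ncol(tm) != 4)
        stop("transition matrix must be 4^markov_order x 4")
    }
    genomes[i] <- .markov_sequence_cpp(tm, config$markov_order,
                                       config$genome_length)
  }
  names(genomes) <- ids
  genomes
}

#' Reverse complement of DNA strings
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute bases at `pos` (1-based) of `seq` with a uniformly chosen
# different base; returns the mutated string.
mutate_positions <- function(seq, pos) {
  if (length(pos) == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  old <- chars[pos]
  pick <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "")
  chars[pos] <- pick
  paste(chars, collapse = "")
}
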