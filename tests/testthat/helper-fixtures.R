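# Shared small synthetic community, built once per test run. Sizes are kept
# modest (3 genomes of 60 kb, two SAGs of ~3,200 reads each) so the whole
# suite stays fast while every planted artifact class is present.
small_config <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(n_genomes = 3, genome_length = 60000, n_sags = 2, sag_depth = 8,
         contam_contig_count = 3, seed = seed),
    list(...))
  do.call(sim_config, args)
}

test_community <- simulate_community(small_config())

# a tiny hand-built record set for constructed-case tests
make_records <- function(read_id, mapped = TRUE, target_id = NA, pos = NA,
                         cigar = NA, nm = NA, read_length = 150,
                         primary = TRUE, duplicate = FALSE, reverse = FALSE) {
  n <- length(read_id)
  rep_n <- function(x) rep_len(x, n)
  data.frame(read_id = read_id, mapped = rep_n(mapped),
             primary = rep_n(primary), duplicate = rep_n(duplicate),
             target_id = rep_n(target_id), pos = rep_n(pos),
             cigar = rep_n(cigar), nm = rep_n(nm),
             read_length = rep_n(read_length), reverse = rep_n(reverse),
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
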