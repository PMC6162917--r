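test_that("chimera-candidate criteria follow clip, span and mismatch rules", {
  rec <- make_records(c("a", "b", "c"),
                      target_id = "m1", pos = 1,
                      cigar = c("30S120M", "25S50M75S", "10S140M"),
                      nm = c(1, 0, 0))
  expect_equal(is_chimera_candidate(rec), c(TRUE, FALSE, FALSE))
  # mismatch bound is inclusive at 2, fails at 3
  rec$nm <- c(2, 0, 0)
  expect_true(is_chimera_candidate(rec)[1])
  rec$nm <- c(3, 0, 0)
  expect_false(is_chimera_candidate(rec)[1])
  # per-clip mode: two 15-base clips pass summed, fail as single clips
  rec2 <- make_records("d", target_id = "m1", pos = 1, cigar = "15S120M15S",
                       nm = 0)
  expect_true(is_chimera_candidate(rec2))
  expect_false(is_chimera_candidate(rec2, clip_mode = "max"))
  expect_warning(
    got <- is_chimera_candidate(make_records("e", target_id = "m1", pos = 1,
                                             cigar = "30S120M", nm = NA)),
    "mismatch count")
  expect_false(got)
})

test_that("non-chimeric mappings need 95% aligned and under 5 mismatches", {
  rec <- make_records(c("a", "b", "c"),
                      target_id = "m1", pos = 1,
                      cigar = c("150M", "8S142M", "190M10S"),
                      nm = c(0, 4, 5), read_length = c(150, 150, 200))
  expect_equal(is_nonchimeric_mapping(rec), c(TRUE, FALSE, FALSE))
})

test_that("calls combine samples, deduplicate, and rescue dominates", {
  cand <- make_records("r1", target_id = "m1", pos = 1, cigar = "40S110M",
                       nm = 0)
  clean <- make_records("r1", target_id = "m9", pos = 5, cigar = "150M",
                        nm = 0)
  calls <- call_chimeras(list(s1 = cand, s2 = clean))
  expect_equal(calls$candidates, "r1")
  expect_equal(calls$rescued, "r1")
  expect_length(calls$chimeric, 0)
  # candidate in two samples appears once
  calls2 <- call_chimeras(list(s1 = cand, s2 = cand))
  expect_equal(calls2$candidates, "r1")
  expect_equal(calls2$chimeric, "r1")
})

test_that("relaxing the mismatch bound never shrinks the candidate set", {
  sag <- test_community$sags$SAG01
  strict <- is_chimera_candidate(sag$records_metagenome, max_mismatch = 2)
  loose <- is_chimera_candidate(sag$records_metagenome, max_mismatch = 3)
  expect_true(all(loose[strict]))
})

test_that("planted inversion chimeras are recovered with high precision", {
  for (sid in names(test_community$sags)) {
    sag <- test_community$sags[[sid]]
    calls <- call_chimeras(list(metagenome = sag$records_metagenome,
                                sag_self = sag$records_sag))
    # chimeras formed in contaminant DNA have no mappable origin, so
    # recall is assessed on chimeras with a focal-genome source
    src <- sag$read_info$genome[match(sag$truth$chimeric_reads,
                                      sag$read_info$read_id)]
    truth <- sag$truth$chimeric_reads[src == sag$truth$genome_id]
    tp <- length(intersect(calls$chimeric, truth))
    expect_gt(tp / length(truth), 0.9)
    expect_gt(length(intersect(calls$chimeric, sag$truth$chimeric_reads)) /
                length(calls$chimeric), 0.95)
    expect_length(intersect(calls$chimeric, calls$rescued), 0)
  }
})

test_that("chimera-free substitution-only data yields zero calls", {
  cfg <- small_config(chimera_rate = 0)
  com <- simulate_community(cfg)
  sag <- com$sags$SAG01
  calls <- call_chimeras(list(metagenome = sag$records_metagenome,
                              sag_self = sag$records_sag))
  expect_length(calls$chimeric, 0)
})

test_that("chimera statistics count clips, edges and categories", {
  empty <- call_chimeras(list(s = make_records("r", target_id = "m",
                                               pos = 1, cigar = "150M",
                                               nm = 0)))
  st0 <- chimera_stats(empty, make_records("r", target_id = "c1", pos = 1,
                                           cigar = "150M", nm = 0),
                       c(c1 = 5000), total_reads = 1)
  expect_equal(st0$chimeric_fraction, 0)
  expect_equal(st0$edge_fraction, 0)
  expect_null(st0$category_distribution)

  # flush-left soft clip at position 1 counts as an edge alignment
  calls <- list(candidates = "r1", rescued = character(0), chimeric = "r1")
  class(calls) <- "chimera_calls"
  sagrec <- make_records("r1", target_id = "c1", pos = 1, cigar = "40S110M",
                         nm = 0)
  st1 <- chimera_stats(calls, sagrec, c(c1 = 5000), total_reads = 10)
  expect_equal(st1$edge_fraction, 1)
  expect_equal(st1$softclip_vs_sag_chimeric, 1)
  expect_equal(st1$chimeric_fraction, 0.1)
  # interior soft clip is not an edge; flush-right is
  sagrec2 <- make_records("r1", target_id = "c1", pos = 100,
                          cigar = "40S110M", nm = 0)
  expect_equal(chimera_stats(calls, sagrec2, c(c1 = 5000),
                             total_reads = 10)$edge_fraction, 0)
  sagrec3 <- make_records("r1", target_id = "c1", pos = 4891,
                          cigar = "110M40S", nm = 0)
  expect_equal(chimera_stats(calls, sagrec3, c(c1 = 5000),
                             total_reads = 10)$edge_fraction, 1)
})

test_that("soft-clip statistics match direct recounts on synthetic data", {
  sag <- test_community$sags$SAG01
  mg <- test_community$metagenome
  calls <- call_chimeras(list(metagenome = sag$records_metagenome,
                              sag_self = sag$records_sag))
  lens <- structure(sag$contig_map$length, names = sag$contig_map$contig_id)
  st <- chimera_stats(calls, sag$records_sag, lens,
                      total_reads = nrow(sag$read_info),
                      metagenome_records = sag$records_metagenome,
                      bins = mg$bins, focal_bin = sag$focal_bin)
  # direct recount of the >20-clip fraction among chimeric reads vs SAG
  r <- sag$records_sag
  cs <- cigar_summary(r$cigar)
  is_chim <- r$read_id %in% calls$chimeric
  clip20 <- r$mapped & !is.na(cs$soft_clip) & cs$soft_clip > 20
  expect_equal(st$softclip_vs_sag_chimeric, mean(clip20[is_chim]))
  expect_equal(st$softclip_vs_sag_other, mean(clip20[!is_chim]))
  expect_equal(st$chimeric_fraction,
               length(calls$chimeric) / nrow(sag$read_info))
  expect_equal(sum(st$category_distribution), 100)
})
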