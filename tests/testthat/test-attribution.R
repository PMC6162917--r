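toy_bins <- data.frame(
  contig_id = c("m1", "m2", "s1"),
  length = c(2000L, 1500L, 800L),
  bin_id = c("binA", "binB", NA),
  stringsAsFactors = FALSE)

test_that("reads are categorized by bin membership and contig length", {
  rec <- make_records(c("r1", "r2", "r3", "r4"),
                      mapped = c(TRUE, TRUE, TRUE, FALSE),
                      target_id = c("m1", "m2", "s1", NA),
                      pos = c(1, 1, 1, NA),
                      cigar = c("150M", "150M", "150M", NA), nm = 0)
  got <- categorize_reads(rec, toy_bins, "binA")
  expect_equal(as.character(got),
               c("IN_MAG", "LONG_NON_MAG", "SHORT", "UNMAPPED"))
  # a contig of exactly the threshold length counts as binned
  bins2 <- toy_bins
  bins2$length[2] <- 1000L
  expect_equal(as.character(categorize_reads(rec, bins2, "binA"))[2],
               "LONG_NON_MAG")
  bad <- make_records("rx", target_id = "nope", pos = 1, cigar = "150M")
  expect_error(categorize_reads(bad, toy_bins, "binA"), "nope")
})

test_that("covered bases equal the per-position union", {
  expect_equal(covered_bases(make_records(character(0))[0, ]), 0)
  rec <- make_records(c("r1", "r2"), target_id = "m1", pos = c(1, 51),
                      cigar = c("100M", "100M"), nm = 0)
  expect_equal(covered_bases(rec), 150)
  set.seed(31)
  for (rep in 1:10) {
    nr <- sample(3:20, 1)
    tg <- sample(c("m1", "m2"), nr, replace = TRUE)
    pos <- sample(1:500, nr, replace = TRUE)
    w <- sample(20:200, nr, replace = TRUE)
    rec <- make_records(paste0("r", 1:nr), target_id = tg, pos = pos,
                        cigar = paste0(w, "M"), nm = 0)
    expect_equal(covered_bases(rec),
                 oracle_covered_bases(pos, w, tg))
    expect_equal(covered_bases(rec, "m2"),
                 oracle_covered_bases(pos, w, tg, "m2"))
  }
  # deletions consume reference, insertions and clips do not
  rec <- make_records("r1", target_id = "m1", pos = 11,
                      cigar = "10S50M5D20M", nm = 0)
  expect_equal(covered_bases(rec), 75)
})

test_that("the FN binning rate is the covered-base ratio", {
  rec_in <- make_records("r1", target_id = "m1", pos = 1, cigar = "150M",
                         nm = 0)
  rec_out <- make_records("r2", target_id = "m2", pos = 1, cigar = "150M",
                          nm = 0)
  expect_equal(fn_binning_rate(rec_in, toy_bins, "binA")$fn_rate, 0)
  expect_equal(fn_binning_rate(rec_out, toy_bins, "binA")$fn_rate, 1)
  both <- rbind(rec_in, rec_out)
  expect_equal(fn_binning_rate(both, toy_bins, "binA")$fn_rate, 0.5)
  # the alternative denominator divides by in-MAG coverage only
  expect_equal(fn_binning_rate(both, toy_bins, "binA",
                               denominator = "in_mag")$fn_rate, 1)
  expect_warning(
    z <- fn_binning_rate(make_records("r", target_id = "s1", pos = 1,
                                      cigar = "100M", nm = 0),
                         toy_bins, "binA"),
    "denominator")
  expect_equal(z$fn_rate, 0)
})

test_that("attribution matches the truth recount on the synthetic community", {
  mg <- test_community$metagenome
  for (sid in names(test_community$sags)) {
    sag <- test_community$sags[[sid]]
    got <- categorize_reads(sag$records_metagenome, mg$bins, sag$focal_bin)
    truth <- oracle_read_truth(sag$read_info, mg$truth$contig_map, mg$bins,
                               sag$focal_bin)
    expect_identical(as.character(got), truth$category)
    # partition: every read in exactly one category
    expect_equal(sum(table(got)), nrow(sag$read_info))
    fn <- fn_binning_rate(sag$records_metagenome, mg$bins, sag$focal_bin)
    want <- oracle_fn_rate_truth(truth, mg$truth$contig_map, mg$bins,
                                 sag$focal_bin)
    expect_equal(fn$fn_rate, want$fn_rate, tolerance = 1e-12)
    expect_equal(fn$covered_non_mag, want$covered_non_mag)
  }
})

test_that("fn_rate ignores read order and duplicate records", {
  sag <- test_community$sags$SAG01
  bins <- test_community$metagenome$bins
  base <- fn_binning_rate(sag$records_metagenome, bins, sag$focal_bin)
  shuf <- sag$records_metagenome[sample(nrow(sag$records_metagenome)), ]
  expect_equal(fn_binning_rate(shuf, bins, sag$focal_bin)$fn_rate,
               base$fn_rate)
  dup <- sag$records_metagenome[1:50, ]
  dup$duplicate <- TRUE
  with_dup <- rbind(sag$records_metagenome, dup)
  expect_equal(fn_binning_rate(with_dup, bins, sag$focal_bin)$fn_rate,
               base$fn_rate)
})

test_that("pair summaries aggregate with medians over pairs", {
  rec <- make_records(c("r1", "r2"), target_id = "m1", pos = 1,
                      cigar = "150M", nm = 0)
  one <- summarize_pairs(list(S1 = rec),
                         toy_bins,
                         data.frame(sag_id = "S1", focal_bin = "binA"))
  expect_equal(one$per_pair$pct_in_mag, 100)
  expect_equal(one$aggregate$median[one$aggregate$metric == "pct_in_mag"],
               100)
  expect_equal(one$aggregate$median[one$aggregate$metric == "pct_unmapped"],
               0)

  mg <- test_community$metagenome
  sets <- lapply(test_community$sags, function(s) s$records_metagenome)
  pairs <- data.frame(
    sag_id = names(test_community$sags),
    focal_bin = vapply(test_community$sags, function(s) s$focal_bin, ""),
    stringsAsFactors = FALSE)
  both <- summarize_pairs(sets, mg$bins, pairs)
  # n = 2 medians are componentwise midpoints of the per-pair table
  expect_equal(both$aggregate$median[both$aggregate$metric == "pct_in_mag"],
               mean(both$per_pair$pct_in_mag))
  expect_equal(both$aggregate$mean[both$aggregate$metric == "fn_rate"],
               mean(both$per_pair$fn_rate))
  expect_equal(rowSums(both$per_pair[, c("pct_in_mag", "pct_long_non_mag",
                                         "pct_short", "pct_unmapped")]),
               c(100, 100), ignore_attr = TRUE)
  expect_warning(
    summarize_pairs(c(sets, list(ORPHAN = sets[[1]])), mg$bins, pairs),
    "ORPHAN")
})
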