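test_that("tetranucleotide profiles are canonical and match a direct tally", {
  p <- tetra_profile("AAAAAA")
  expect_equal(sum(p$frequencies > 0), 1)
  expect_equal(unname(p$frequencies[1, "AAAA"]), 1)
  expect_equal(p$n_windows, 3)
  expect_equal(ncol(p$frequencies), 136)

  set.seed(41)
  s <- random_dna(10000)
  p1 <- tetra_profile(s)$frequencies
  p2 <- tetra_profile(oracle_revcomp(s))$frequencies
  expect_equal(p1, p2, ignore_attr = TRUE)
  expect_equal(sum(p1), 1, tolerance = 1e-9)
  want <- oracle_tetra_counts(s)
  got <- tetra_profile(s)
  counts <- got$frequencies[1, ] * got$n_windows
  expect_equal(counts[names(want)], want / 1, ignore_attr = TRUE)
  expect_error(tetra_profile("ACN"), "too short")
})

test_that("PCA projection is deterministic and variance-faithful", {
  set.seed(42)
  prof <- tetra_profile(vapply(1:8, function(i) random_dna(3000), ""))
  pr <- pca_project(prof$frequencies)
  # duplicated profiles get identical coordinates
  prof2 <- rbind(prof$frequencies, prof$frequencies[1, , drop = FALSE])
  pr2 <- pca_project(prof2)
  expect_equal(unname(pr2$scores[9, ]), unname(pr2$scores[1, ]))
  # sign convention: the largest-magnitude loading of each axis is positive
  for (j in 1:2)
    expect_gt(pr$loadings[which.max(abs(pr$loadings[, j])), j], 0)
  # residual sum of squares from 2 components = trailing eigenvalue mass
  X <- scale(prof$frequencies, center = TRUE, scale = FALSE)
  full <- prcomp(prof$frequencies)
  resid <- sum((X - pr$scores %*% t(pr$loadings))^2)
  expect_equal(resid, (nrow(X) - 1) * sum(full$sdev[-(1:2)]^2),
               tolerance = 1e-9)
})

test_that("contigs split on the 5% aligned-fraction rule, strict below", {
  lens <- c(a = 10000, b = 10000, c = 2000)
  blocks <- data.frame(
    query_id = c("a", "a", "c"), target_id = "m",
    q_start = c(0, 200, 0), q_end = c(300, 400, 2000),
    t_start = 0, t_end = 1, pct_identity = 100)
  got <- split_by_alignment(lens, blocks)
  # a: union [0,400) of 10 kb = 4% -> non-aligning; b: no blocks; c: 100%
  expect_equal(got$aligning, c(FALSE, FALSE, TRUE))
  expect_equal(got$aligned_fraction, c(4, 0, 100))
  # exactly 5% aligns (the split is strict-<)
  blocks5 <- data.frame(query_id = "a", target_id = "m", q_start = 0,
                        q_end = 500, t_start = 0, t_end = 1,
                        pct_identity = 100)
  expect_true(split_by_alignment(lens["a"], blocks5)$aligning)
})

test_that("coverage estimates cap at three times the median", {
  got <- coverage_estimate(c(50, 0), c(1000, 500))
  expect_equal(got$coverage, c(5, 0))
  got2 <- coverage_estimate(c(10, 20, 100), c(1000, 1000, 1000))
  expect_equal(got2$coverage, c(1, 2, 10))
  expect_equal(got2$capped_coverage, c(1, 2, 6))
  # capping never changes values at or below the cap, nor the median when
  # fewer than half the contigs are capped
  expect_equal(median(got2$capped_coverage), median(got2$coverage))
  expect_error(coverage_estimate(-1, 100), "counts")
})

test_that("planted contaminants are flagged with high recall and precision", {
  for (sid in names(test_community$sags)) {
    sag <- test_community$sags[[sid]]
    counts <- structure(sag$metagenome_read_counts$read_count,
                        names = sag$metagenome_read_counts$contig_id)
    rep <- flag_contaminants(sag$contigs, sag$blocks, counts)
    truth <- sag$truth$contaminant_contigs
    tp <- sum(rep$contig_id[rep$flagged] %in% truth)
    expect_gte(tp / length(truth), 0.8)
    expect_gte(tp / max(sum(rep$flagged), 1), 0.8)
    # flagged contigs are always from the non-aligning set
    expect_true(all(!rep$aligning[rep$flagged]))
    # separation: contaminants sit far from genuine contigs in PC space
    pc <- rep[, c("pc1", "pc2")]
    is_con <- rep$contig_id %in% truth
    cen <- colMeans(pc[!is_con, ])
    d_gen <- sqrt(rowSums(sweep(pc[!is_con, ], 2, cen)^2))
    d_con <- sqrt(rowSums(sweep(pc[is_con, ], 2, cen)^2))
    expect_gt(mean(d_con), mean(d_gen))
  }
})

test_that("the screen is exactly strand-invariant", {
  sag <- test_community$sags$SAG01
  counts <- structure(sag$metagenome_read_counts$read_count,
                      names = sag$metagenome_read_counts$contig_id)
  rep1 <- flag_contaminants(sag$contigs, sag$blocks, counts)
  flipped <- sag$contigs
  flip <- seq(1, length(flipped), by = 2)
  flipped[flip] <- oracle_revcomp(flipped[flip])
  rep2 <- flag_contaminants(flipped, sag$blocks, counts)
  expect_identical(rep1$flagged, rep2$flagged)
  expect_equal(rep1$pc1, rep2$pc1)
  expect_equal(rep1$pc2, rep2$pc2)
  expect_identical(rep1$coverage, rep2$coverage)
})

test_that("well-covered, typical-composition contigs are never flagged", {
  sag <- test_community$sags$SAG01
  # plant a pseudo-contaminant with focal composition and normal coverage:
  # a genuine segment, no alignment blocks, high read count
  fake_id <- "fake_contaminant"
  contigs <- c(sag$contigs, structure(substr(
    test_community$genomes[[sag$truth$genome_id]], 1, 4000), names = fake_id))
  counts <- structure(c(sag$metagenome_read_counts$read_count, 400),
                      names = c(sag$metagenome_read_counts$contig_id,
                                fake_id))
  rep <- flag_contaminants(contigs, sag$blocks, counts)
  expect_false(rep$flagged[rep$contig_id == fake_id])
  expect_false(rep$aligning[rep$contig_id == fake_id])
})

test_that("too few aligning contigs fall back to the coverage rule", {
  set.seed(43)
  contigs <- c(a = random_dna(3000), b = random_dna(3000),
               c = random_dna(3000), d = random_dna(3000))
  blocks <- data.frame(query_id = "a", target_id = "m", q_start = 0,
                       q_end = 3000, t_start = 0, t_end = 1,
                       pct_identity = 100)
  counts <- c(a = 300, b = 310, c = 290, d = 1)
  expect_warning(rep <- flag_contaminants(contigs, blocks, counts),
                 "fewer than 3 aligning")
  expect_equal(rep$contig_id[rep$flagged], "d")
})
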