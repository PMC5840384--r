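test_that("true map has the requested shape and is reproducible", {
  tm <- simulate_true_map(24, 130, 180, seed = 1)
  expect_equal(length(unique(tm$chrom)), 24)
  expect_equal(nrow(tm), 3120)
  expect_false(anyDuplicated(tm$marker) > 0)
  for (ch in unique(tm$chrom)[1:3]) {
    d <- tm[tm$chrom == ch, ]
    expect_true(all(diff(d$cM) > 0))
    expect_true(all(diff(d$bp) > 0))
  }
  tm2 <- simulate_true_map(24, 130, 180, seed = 1)
  expect_identical(tm, tm2)
  small <- simulate_true_map(1, 2, 50, seed = 2)
  expect_equal(nrow(small), 2)
  expect_lt(small$cM[1], small$cM[2])
  expect_error(simulate_true_map(0, 10), "positive")
  expect_error(simulate_true_map(2, 1), "positive")
})

test_that("family simulation is deterministic and respects the map", {
  tm <- simulate_true_map(2, 10, 80, seed = 3)
  cs <- cross_spec(n_offspring = 40, seed = 4)
  gm1 <- simulate_family(tm, cs)
  gm2 <- simulate_family(tm, cs)
  expect_identical(gm1$geno, gm2$geno)
  expect_equal(dim(gm1$geno), c(20, 40))
  # markers 0 cM apart are transmitted without recombination
  tm0 <- tiny_true_map(0)
  gm0 <- simulate_family(tm0, cross_spec(n_offspring = 200, missing_rate = 0,
                                         error_rate = 0, seed = 5))
  truth <- attr(gm0, "truth")
  expect_equal(truth$hap_p1[1, ], truth$hap_p1[2, ])
  expect_equal(truth$hap_p2[1, ], truth$hap_p2[2, ])
})

test_that("unlinked markers recombine in half the meioses", {
  tm <- structure(data.frame(chrom = c("chr01", "chr02"),
                             marker = c("M1", "M2"), cM = c(0, 0),
                             bp = c(1e5, 1e5), stringsAsFactors = FALSE),
                  class = c("true_map", "data.frame"))
  gm <- simulate_family(tm, cross_spec(n_offspring = 2000, missing_rate = 0,
                                       error_rate = 0, seed = 6))
  truth <- attr(gm, "truth")
  # haplotype switches between independent chromosomes: fraction ~ 1/2 of
  # 2 x 2000 meioses, binomial s.e. ~ 0.008
  rec <- mean(c(truth$hap_p1[1, ] != truth$hap_p1[2, ],
                truth$hap_p2[1, ] != truth$hap_p2[2, ]))
  expect_lt(abs(rec - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("undistorted markers segregate Mendelian at nominal rate", {
  # near-independent markers (two per 200 cM chromosome) so the binomial
  # standard error applies
  tm <- simulate_true_map(150, 2, 200, seed = 7)
  gm <- simulate_family(tm, cross_spec(n_offspring = 94,
                                       distorted_fraction = 0, seed = 8))
  qc <- filter_markers(gm)
  distorted_drop <- mean(qc$report$reason == "distortion")
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(distorted_drop - 0.05), 2.5 * se)
})

test_that("distorted markers are detectably skewed", {
  tm <- simulate_true_map(1, 120, 500, seed = 9)
  gm <- simulate_family(tm, cross_spec(n_offspring = 94,
                                       distorted_fraction = 0.5,
                                       distortion_strength = 0.7, seed = 10))
  truth <- attr(gm, "truth")
  qc <- filter_markers(gm)
  flagged <- qc$report$reason == "distortion"
  is_dist <- qc$report$marker %in% truth$distorted$marker
  expect_gt(mean(flagged[is_dist]), 0.6)
  expect_lt(mean(flagged[!is_dist]), 0.15)
})

test_that("derived genomes honour the rearrangement operations", {
  tm <- simulate_true_map(3, 30, 100, seed = 11)
  clean <- rearrangement_spec(no_hit = 0, repetitive = 0, wrong_chrom = 0,
                              bp_jitter = 0)
  gen <- derive_reference_genome(tm, clean, "sp0", seed = 12)
  # identity: same order per chromosome
  expect_equal(gen$positions$chrom, tm$chrom)
  expect_equal(order(gen$positions$bp), order(tm$bp))
  expect_equal(nrow(gen$hits), nrow(tm))
  # inversion reverses exactly the covered run
  inv <- rearrangement_spec(ops = list(list(type = "inversion", chrom = "chr01",
                                            lo = tm$bp[5], hi = tm$bp[15])),
                            no_hit = 0, repetitive = 0, wrong_chrom = 0,
                            bp_jitter = 0)
  gi <- derive_reference_genome(tm, inv, "spI", seed = 13)
  r1 <- gi$positions[gi$positions$chrom == "chr01", ]
  expect_equal(r1$marker[order(r1$bp)][5:15],
               tm$marker[15:5])
  # fusion unions the marker sets on one chromosome
  fus <- rearrangement_spec(ops = list(list(type = "fusion", a = "chr02",
                                            b = "chr03")),
                            no_hit = 0, repetitive = 0, wrong_chrom = 0,
                            bp_jitter = 0)
  gf <- derive_reference_genome(tm, fus, "spF", seed = 14)
  expect_equal(sort(unique(gf$positions$chrom)), c("chr01", "chr02"))
  expect_setequal(gf$positions$marker[gf$positions$chrom == "chr02"],
                  tm$marker[tm$chrom %in% c("chr02", "chr03")])
  expect_error(rearrangement_spec(ops = list(list(type = "fusion",
                                                  a = "chr01", b = "chr01"))),
               "itself")
  # repetitive markers emit more than 10 surviving hits
  noisy <- rearrangement_spec(no_hit = 0.2, repetitive = 0.2, wrong_chrom = 0,
                              bp_jitter = 0)
  gn <- derive_reference_genome(tm, noisy, "spN", seed = 15)
  nh <- table(gn$hits$qseqid)
  expect_true(all(nh %in% c(1, 11)))
  expect_equal(sum(gn$truth$kind == "none"),
               nrow(tm) - length(unique(gn$hits$qseqid)))
})

test_that("simulated transcripts sit between their flanking markers", {
  tm <- simulate_true_map(2, 20, 100, seed = 16)
  clean <- rearrangement_spec(no_hit = 0, repetitive = 0, wrong_chrom = 0,
                              bp_jitter = 0)
  gen <- list(spA = derive_reference_genome(tm, clean, "spA", seed = 17))
  tx <- simulate_unplaced_transcripts(tm, gen, 100, single_hit_fraction = 1,
                                      seed = 18)
  expect_equal(nrow(tx$truth), 100)
  expect_equal(nrow(tx$hits$spA), 100)
  expect_true(all(table(tx$hits$spA$qseqid) == 1))
  for (k in c(1, 50, 100)) {
    tr <- tx$truth[k, ]
    lcm <- tm$cM[tm$marker == tr$left]; rcm <- tm$cM[tm$marker == tr$right]
    expect_true(tr$cM >= lcm && tr$cM <= rcm)
  }
  tx2 <- simulate_unplaced_transcripts(tm, gen, 100, single_hit_fraction = 1,
                                       seed = 18)
  expect_identical(tx$hits, tx2$hits)
  mixed <- simulate_unplaced_transcripts(tm, gen, 200,
                                         single_hit_fraction = 0.5, seed = 19)
  nh <- table(mixed$hits$spA$qseqid)
  expect_true(any(nh == 2) && any(nh == 1))
  expect_error(simulate_unplaced_transcripts(tm, gen, 0), ">= 1")
})
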