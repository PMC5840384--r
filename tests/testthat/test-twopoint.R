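test_that("pair likelihood equals brute-force gamete enumeration", {
  set.seed(7)
  # random small families across cross-type combinations
  combos <- list(
    list(p1 = c("a/b", "a/b"), p2 = c("a/b", "a/b")),
    list(p1 = c("a/b", "a/b"), p2 = c("a/b", "a/c")),
    list(p1 = c("a/b", "a/b"), p2 = c("a/c", "c/d")),
    list(p1 = c("a/b", "a/b"), p2 = c("c/d", "c/d")))
  par_alleles <- function(g) strsplit(g, "/")[[1]]
  n_checked <- 0
  for (cb in combos) {
    # offspring drawn allele-by-allele from the parents (valid by construction)
    draw <- function(pg1, pg2, n) {
      a <- sample(par_alleles(pg1), n, replace = TRUE)
      b <- sample(par_alleles(pg2), n, replace = TRUE)
      out <- paste(a, b, sep = "/")
      out[sample(n, 1)] <- "-"  # one missing call
      out
    }
    for (r in c(0.05, 0.2, 0.45)) for (ph in 1:4) {
      g1 <- draw(cb$p1[1], cb$p2[1], 9)
      g2 <- draw(cb$p1[2], cb$p2[2], 9)
      gm2 <- make_gm(c(cb$p1[1], cb$p1[2]), c(cb$p2[1], cb$p2[2]),
                     rbind(g1, g2))
      ph1 <- (ph - 1) %/% 2; ph2 <- (ph - 1) %% 2
      n_checked <- n_checked + 1
      ll_pkg <- pair_likelihood(gm2$geno[1, ], gm2$geno[2, ],
                                gm2$markers$cross_type[1],
                                gm2$markers$cross_type[2], ph, r)
      ll_bf <- bf_pair_loglik(g1, g2,
                              par_alleles(cb$p1[1]), par_alleles(cb$p1[2]),
                              par_alleles(cb$p2[1]), par_alleles(cb$p2[2]),
                              ph1, ph2, r)
      expect_equal(ll_pkg, ll_bf, tolerance = 1e-10)
    }
  }
  expect_equal(n_checked, 48)
})

test_that("likelihood at rf = 0.5 is phase independent", {
  gm <- cd_pair_family(20, 3, 4)
  lls <- vapply(1:4, function(ph)
    pair_likelihood(gm$geno[1, ], gm$geno[2, ], "AB_x_CD", "AB_x_CD", ph, 0.5),
    0)
  expect_true(all(abs(lls - lls[1]) < 1e-12))
})

test_that("rf estimate equals the count-ratio MLE on fully informative pairs", {
  # 94 offspring, 19 recombinant of 188 scorable meioses
  gm <- cd_pair_family(94, 10, 9)
  est <- estimate_rf(gm, 1, 2)
  expect_equal(est$rf, 19 / 188, tolerance = 1e-3)
  expect_equal(est$n, 94)
  # scan agrees with the single-pair R path
  tp <- twopoint_scan(gm)
  expect_equal(tp$rf[1], est$rf, tolerance = 1e-5)
  expect_equal(tp$lod[1], est$lod, tolerance = 1e-5)
  expect_equal(tp$phase[1], est$phase)
})

test_that("identical genotype vectors give rf near 0 with maximal LOD", {
  gm <- cd_pair_family(94, 0, 0)
  est <- estimate_rf(gm, 1, 2)
  expect_lt(est$rf, 1e-3)
  # LOD for a fully informative pair with zero recombinants: 2n log10(2)
  expect_equal(est$lod, 188 * log10(2), tolerance = 0.01)
})

test_that("LOD is invariant to allele relabelling and parent swapping", {
  set.seed(11)
  tm <- tiny_true_map(15)
  gm <- simulate_family(tm, cross_spec(n_offspring = 60, missing_rate = 0,
                                       error_rate = 0, seed = 13))
  est <- estimate_rf(gm, 1, 2)
  g1 <- radmap:::.format_geno(gm$geno[1, ])
  g2 <- radmap:::.format_geno(gm$geno[2, ])
  # swap the parents (and therefore the genotype labels stay the same)
  gm_sw <- make_gm(gm$markers$p2, gm$markers$p1, rbind(g1, g2))
  est_sw <- estimate_rf(gm_sw, 1, 2)
  expect_equal(est_sw$rf, est$rf, tolerance = 1e-6)
  expect_equal(est_sw$lod, est$lod, tolerance = 1e-6)
  # relabel alleles a<->b at marker 1 (parents and offspring consistently)
  flip <- chartr("ab", "ba", g1)
  gm_rl <- make_gm(c(chartr("ab", "ba", gm$markers$p1[1]), gm$markers$p1[2]),
                   c(chartr("ab", "ba", gm$markers$p2[1]), gm$markers$p2[2]),
                   rbind(flip, g2))
  est_rl <- estimate_rf(gm_rl, 1, 2)
  expect_equal(est_rl$rf, est$rf, tolerance = 1e-6)
  expect_equal(est_rl$lod, est$lod, tolerance = 1e-6)
})

test_that("independent markers are estimated unlinked", {
  # markers on different chromosomes: r = 0.5
  tm <- structure(data.frame(chrom = c("chr01", "chr02"),
                             marker = c("M1", "M2"), cM = c(0, 0),
                             bp = c(1e5, 1e5), stringsAsFactors = FALSE),
                  class = c("true_map", "data.frame"))
  rfs <- lods <- numeric(20)
  for (k in 1:20) {
    gm <- simulate_family(tm, cross_spec(n_offspring = 100, missing_rate = 0,
                                         error_rate = 0, seed = 500 + k))
    tp <- twopoint_scan(gm)
    rfs[k] <- tp$rf[1]; lods[k] <- tp$lod[1]
  }
  expect_gt(median(rfs), 0.42)
  expect_gte(mean(lods < 1), 0.90)
})

test_that("degenerate pairs are rejected", {
  gm <- cd_pair_family(4, 1, 1)
  gm$geno[1, 1:3] <- NA
  gm$geno[2, 4] <- NA
  expect_error(estimate_rf(gm, 1, 2), "fewer than 2")
})
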