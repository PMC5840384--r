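# a reference setup shared by the placement tests: one LG whose anchors are
# collinear with chromosome "c1" in two species, plus a second LG elsewhere
place_fixture <- function() {
  map <- data.frame(group = rep(c("LG1", "LG2"), each = 6),
                    marker = paste0("m", 1:12),
                    position_cM = c(seq(0, 20, by = 4), seq(0, 10, by = 2)))
  mk_blocks <- function(sp, shift = 0) {
    an <- data.frame(marker = paste0("m", 1:6),
                     cM = seq(0, 20, by = 4),
                     bp = seq(1e5, 6e5, by = 1e5) + shift)
    aset <- anchor_set(an, lg_length_cM = 20, chrom_length_bp = 1e6,
                       lg = "LG1", species = sp, chrom = "c1")
    species_blocks(list(aset))
  }
  list(map = map, blocks = list(spA = mk_blocks("spA"),
                                spB = mk_blocks("spB", shift = 0)))
}

test_that("direct hits inherit the marker's exact position", {
  map <- data.frame(group = "LG1", marker = c("mk1", "mk2"),
                    position_cM = c(63.67, 10))
  hits <- filter_hits(rbind(hit("tx1", "mk1", evalue = 1e-40),
                            hit("tx2", "mkZ", evalue = 1e-40)), e_max = 1e-20)
  pl <- direct_assign(hits, map)
  expect_equal(pl$status, c("placed", "unplaced"))
  expect_equal(pl$lo_cM[1], 63.67)
  expect_equal(pl$hi_cM[1], 63.67)
  expect_match(pl$note[2], "unmapped")
})

test_that("a hit between two anchors is flanked by their map positions", {
  fx <- place_fixture()
  # midpoint 2.5e5 sits between m2 (4 cM, 2e5) and m3 (8 cM, 3e5)
  tx_hits <- list(spA = hit("t1", "c1", sstart = 249953, send = 250047))
  pl <- collinearity_place(tx_hits, fx$blocks["spA"])
  expect_equal(pl$status, "placed")
  expect_equal(pl$lg, "LG1")
  expect_equal(pl$lo_cM, 4)
  expect_equal(pl$hi_cM, 8)
  expect_equal(pl$n_species, 1L)
  ev <- attr(pl, "evidence")
  expect_equal(ev$left, "m2"); expect_equal(ev$right, "m3")
})

test_that("overlapping species intervals intersect; evidence order is irrelevant", {
  fx <- place_fixture()
  # spA places t1 in [4, 8]; spB between m3 and m4 -> [8, 12]? shift spB hit
  tx_hits <- list(spA = hit("t1", "c1", sstart = 249953, send = 250047),
                  spB = hit("t1", "c1", sstart = 289953, send = 290047))
  pl <- collinearity_place(tx_hits, fx$blocks)
  expect_equal(pl$status, "placed")
  expect_equal(pl$n_species, 2L)
  expect_equal(c(pl$lo_cM, pl$hi_cM), c(4, 8))  # both give [4, 8] here
  # disjoint-interval case: smallest interval kept and flagged partial
  tx2 <- list(spA = hit("t1", "c1", sstart = 149953, send = 150047),
              spB = hit("t1", "c1", sstart = 449953, send = 450047))
  pl2 <- collinearity_place(tx2, fx$blocks)
  expect_match(pl2$note, "partial")
  expect_equal(pl2$hi_cM - pl2$lo_cM, 4)
  # processing order must not matter
  pl_rev <- collinearity_place(rev(tx_hits), fx$blocks)
  expect_equal(pl_rev, pl, ignore_attr = TRUE)
})

test_that("single-species consensus equals that species' interval", {
  fx <- place_fixture()
  tx_hits <- list(spA = hit("t1", "c1", sstart = 249953, send = 250047))
  both <- collinearity_place(c(tx_hits,
                               list(spB = hit("t1", "c1", sstart = 249953,
                                              send = 250047))),
                             fx$blocks)
  solo <- collinearity_place(tx_hits, fx$blocks["spA"])
  expect_equal(solo$lo_cM, both$lo_cM)
  expect_equal(solo$hi_cM, both$hi_cM)
  # consensus never wider than any contributing species interval
  expect_lte(both$hi_cM - both$lo_cM, solo$hi_cM - solo$lo_cM)
})

test_that("multi-hit transcripts, outside hits and LG ties are classified", {
  fx <- place_fixture()
  # two hits in spA: single-hit rule drops the transcript there
  multi <- list(spA = rbind(hit("t1", "c1", sstart = 249953, send = 250047),
                            hit("t1", "c1", sstart = 549953, send = 550047)))
  pl <- collinearity_place(multi, fx$blocks["spA"])
  expect_equal(nrow(pl), 0)
  # hit beyond every block's bp span
  outside <- list(spA = hit("t2", "c1", sstart = 899953, send = 900047))
  plo <- collinearity_place(outside, fx$blocks["spA"])
  expect_equal(plo$status, "ambiguous")
  # tie between two LGs across species -> conflict
  blB <- fx$blocks$spB
  blB$lg <- "LG2"
  tie <- collinearity_place(
    list(spA = hit("t3", "c1", sstart = 249953, send = 250047),
         spB = hit("t3", "c1", sstart = 249953, send = 250047)),
    list(spA = fx$blocks$spA, spB = blB))
  expect_equal(tie$status, "conflict")
  expect_match(tie$note, "tied")
})

test_that("simulated transcripts are recovered inside their consensus intervals", {
  tm <- simulate_true_map(3, 40, 120, seed = 61)
  map <- data.frame(group = paste0("LG", as.integer(factor(tm$chrom))),
                    marker = tm$marker,
                    position_cM = tm$cM -
                      ave(tm$cM, tm$chrom, FUN = min)[seq_len(nrow(tm))])
  specs <- list(
    spA = rearrangement_spec(no_hit = 0, repetitive = 0, wrong_chrom = 0,
                             bp_jitter = 0),
    spB = rearrangement_spec(ops = list(list(type = "fusion", a = "chr01",
                                             b = "chr02")),
                             no_hit = 0, repetitive = 0, wrong_chrom = 0,
                             bp_jitter = 0))
  genomes <- list(); assignments <- list(); chrlens <- list()
  for (sp in names(specs)) {
    gen <- derive_reference_genome(tm, specs[[sp]], sp,
                                   seed = 62 + match(sp, names(specs)))
    genomes[[sp]] <- gen
    asg <- hit_assignments(filter_hits(gen$hits)); asg$species <- sp
    assignments[[sp]] <- asg
    cl <- gen$chrom_lengths; cl$species <- sp; chrlens[[sp]] <- cl
  }
  assignments <- do.call(rbind, assignments)
  chrlens <- do.call(rbind, chrlens)
  asets <- anchor_sets_from_map(map, assignments, chrlens)
  bls <- lapply(names(specs), function(sp)
    species_blocks(asets[vapply(asets, function(a) a$species == sp, TRUE)]))
  names(bls) <- names(specs)
  tx <- simulate_unplaced_transcripts(tm, genomes, 120,
                                      single_hit_fraction = 1, seed = 65)
  pl <- collinearity_place(tx$hits, bls)
  tr <- tx$truth[match(pl$transcript, tx$truth$transcript), ]
  truelg <- paste0("LG", as.integer(factor(tr$chrom, levels = unique(tm$chrom))))
  truecm <- tr$cM - vapply(tr$chrom, function(ch) min(tm$cM[tm$chrom == ch]), 0)
  good <- pl$status == "placed" & pl$lg == truelg &
    pl$lo_cM - 1e-9 <= truecm & truecm <= pl$hi_cM + 1e-9
  expect_gte(mean(good, na.rm = TRUE), 0.95)
})
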