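# Ground-truthed simulation of the study design: one F1 full-sib family from
# two outbred parents, bi-allelic markers heterozygous in both parents,
# rearranged reference genomes and transcript hit tables.

#' Simulate a true genetic/physical map
#'
#' Marker cM positions are drawn uniformly along each chromosome and sorted;
#' physical positions are monotone in cM, spaced about 100 kb apart with
#' uniform jitter (downstream code only uses relative order).
#'
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param markers_per_chromosome markers per chromosome (>= 2).
#' @param mean_length_cM mean chromosome length; individual lengths vary
#'   uniformly within +/- 30%.
#' @param seed RNG seed.
#' @return a `true_map`: data.frame with `chrom`, `marker`, `cM`, `bp`.
#' @export
simulate_true_map <- function(n_chromosomes, markers_per_chromosome,
                              mean_length_cM = 180, seed = 1L) {
  if (n_chromosomes < 1 || markers_per_chromosome < 2 || mean_length_cM <= 0)
    stop("sizes must be positive (>= 2 markers per chromosome)")
  set.seed(seed)
  rows <- lapply(seq_len(n_chromosomes), function(ch) {
    L <- mean_length_cM * runif(1, 0.7, 1.3)
    cm <- sort(runif(markers_per_chromosome, 0, L))
    # enforce strict increase
    cm <- cm + seq_along(cm) * 1e-9
    bp <- cumsum(round(runif(markers_per_chromosome, 8e4, 1.2e5)))
    data.frame(chrom = sprintf("chr%02d", ch),
               marker = sprintf("C%02dM%04d", ch, seq_len(markers_per_chromosome)),
               cM = cm, bp = bp, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("true_map", "data.frame"))
}

#' Specification of the simulated cross
#'
#' Defaults emulate the mapping family of the study design this generator
#' mirrors: 94 F1 offspring of one female x one male, cross-type proportions
#' matching the observed pattern counts 1896 : 1114 : 136 for
#' ab x ab : ab x ac : ab x cd, 5% missing calls and 0.5% allele-call errors.
#'
#' @param n_offspring number of F1 offspring.
#' @param cross_type_proportions fractions of ab x ab, ab x ac, ab x cd
#'   markers (must sum to 1).
#' @param missing_rate probability a genotype call is missing.
#' @param error_rate probability one allele of a call is replaced by another
#'   allele segregating at the marker.
#' @param distorted_fraction fraction of markers under viability selection.
#' @param distortion_strength selection coefficient in \[0, 1) against one
#'   parental allele at distorted markers.
#' @param seed RNG seed.
#' @return a `cross_spec` list.
#' @export
cross_spec <- function(n_offspring = 94L,
                       cross_type_proportions = c(1896, 1114, 136) / 3146,
                       missing_rate = 0.05, error_rate = 0.005,
                       distorted_fraction = 0, distortion_strength = 0.5,
                       seed = 1L) {
  p <- cross_type_proportions
  if (length(p) != 3 || abs(sum(p) - 1) > 1e-8)
    stop("cross_type_proportions must be 3 fractions summing to 1")
  rates <- c(missing_rate, error_rate, distorted_fraction)
  if (any(rates < 0 | rates >= 1) || distortion_strength < 0 ||
      distortion_strength >= 1)
    stop("rates must lie in [0, 1)")
  if (n_offspring < 1) stop("need at least one offspring")
  structure(list(n_offspring = as.integer(n_offspring),
                 cross_type_proportions = p, missing_rate = missing_rate,
                 error_rate = error_rate,
                 distorted_fraction = distorted_fraction,
                 distortion_strength = distortion_strength,
                 seed = as.integer(seed)),
            class = "cross_spec")
}

# alleles segregating at a marker of given cross type (canonical frame)
.segregating <- function(ct_idx) {
  switch(ct_idx, c(1L, 2L), c(1L, 2L, 3L), c(1L, 2L, 3L, 4L))
}

#' Simulate genotypes of an F1 full-sib family along a true map
#'
#' Each marker is assigned a cross type (both parents heterozygous). Each
#' parent transmits gametes by a no-interference crossover process: the
#' transmitted haplotype switches between adjacent markers with probability
#' equal to the inverse Kosambi of their cM separation, independently across
#' intervals. Genotyping errors (one allele replaced by another segregating
#' allele, constrained to keep the call producible from the parents),
#' missingness, and viability selection at distorted markers are applied
#' after transmission.
#'
#' @param true_map a [simulate_true_map()] result.
#' @param cross a [cross_spec()].
#' @return a [genotype_matrix()] with attribute `truth`: parental phases,
#'   per-offspring transmitted haplotypes and crossover counts, distorted
#'   markers, and the marker-to-chromosome assignment.
#' @export
simulate_family <- function(true_map, cross = cross_spec()) {
  stopifnot(inherits(true_map, "true_map"))
  if (nrow(true_map) == 0) stop("empty true map")
  set.seed(cross$seed)
  n_off <- cross$n_offspring
  n_m <- nrow(true_map)
  ct_idx <- sample.int(3L, n_m, replace = TRUE,
                       prob = cross$cross_type_proportions)
  p1a <- rbind(c(1L, 2L), c(1L, 2L), c(1L, 2L))      # parent 1 alleles by ct
  p2a <- rbind(c(1L, 2L), c(1L, 3L), c(3L, 4L))      # parent 2 alleles by ct
  # phase: which allele sits on haplotype 1, per parent per marker
  ph1 <- sample.int(2L, n_m, replace = TRUE)
  ph2 <- sample.int(2L, n_m, replace = TRUE)
  # transmitted haplotype (1/2) per parent: Markov chain along each chromosome
  hap <- function() {
    h <- matrix(0L, n_m, n_off)
    for (ch in unique(true_map$chrom)) {
      rows <- which(true_map$chrom == ch)
      r <- kosambi_inv(diff(true_map$cM[rows]))
      h[rows[1], ] <- sample.int(2L, n_off, replace = TRUE)
      for (k in seq_along(r)) {
        flip <- runif(n_off) < r[k]
        h[rows[k + 1], ] <- ifelse(flip, 3L - h[rows[k], ], h[rows[k], ])
      }
    }
    h
  }
  h1 <- hap(); h2 <- hap()
  # transmitted allele index (1/2 within parent) given hap and phase:
  # hap 1 carries allele ph, hap 2 the other
  idx1 <- ifelse(h1 == 1L, ph1[row(h1)], 3L - ph1[row(h1)])
  idx2 <- ifelse(h2 == 1L, ph2[row(h2)], 3L - ph2[row(h2)])
  # viability selection at distorted markers: allele 1 of a random parent
  distorted <- which(runif(n_m) < cross$distorted_fraction)
  dist_parent <- sample.int(2L, length(distorted), replace = TRUE)
  dist_allele <- sample.int(2L, length(distorted), replace = TRUE)
  s <- cross$distortion_strength
  for (k in seq_along(distorted)) {
    m <- distorted[k]
    tgt <- if (dist_parent[k] == 1L) idx1 else idx2
    hit <- tgt[m, ] == dist_allele[k] & runif(n_off) < s
    if (dist_parent[k] == 1L) idx1[m, hit] <- 3L - dist_allele[k]
    else idx2[m, hit] <- 3L - dist_allele[k]
  }
  al1 <- matrix(p1a[cbind(rep(ct_idx, n_off), as.vector(idx1))], n_m, n_off)
  al2 <- matrix(p2a[cbind(rep(ct_idx, n_off), as.vector(idx2))], n_m, n_off)
  geno <- matrix(.pair_code(al1, al2), n_m, n_off)
  # genotyping error: replace one allele, keeping the call producible
  err <- which(matrix(runif(n_m * n_off) < cross$error_rate, n_m, n_off))
  for (e in err) {
    m <- (e - 1L) %% n_m + 1L
    valid <- .cross_classes(c("AB_x_AB", "AB_x_AC", "AB_x_CD")[ct_idx[m]])$codes
    al <- .code_alleles(geno[e])
    seg <- .segregating(ct_idx[m])
    cand <- list()
    for (slot in 1:2) for (rep_al in setdiff(seg, al[slot])) {
      nw <- al; nw[slot] <- rep_al
      cd <- .pair_code(nw[1], nw[2])
      if (cd %in% valid && cd != geno[e]) cand <- c(cand, cd)
    }
    if (length(cand)) geno[e] <- cand[[sample.int(length(cand), 1L)]]
  }
  geno[matrix(runif(n_m * n_off) < cross$missing_rate, n_m, n_off)] <- NA_integer_
  ct_names <- c("AB_x_AB", "AB_x_AC", "AB_x_CD")[ct_idx]
  p1 <- c("a/b", "a/b", "a/b")[ct_idx]
  p2 <- c("a/b", "a/c", "c/d")[ct_idx]
  gm <- genotype_matrix(
    data.frame(id = true_map$marker, p1 = p1, p2 = p2,
               stringsAsFactors = FALSE),
    matrix(.format_geno(as.vector(geno)), n_m, n_off),
    offspring = sprintf("off%03d", seq_len(n_off)))
  xo <- function(h) {
    sw <- 0L
    for (ch in unique(true_map$chrom)) {
      rows <- which(true_map$chrom == ch)
      if (length(rows) > 1)
        sw <- sw + colSums(h[rows[-1], , drop = FALSE] !=
                             h[rows[-length(rows)], , drop = FALSE])
    }
    sw
  }
  attr(gm, "truth") <- list(
    chrom = true_map$chrom, cM = true_map$cM, cross_type = ct_names,
    phase_p1 = ph1, phase_p2 = ph2, hap_p1 = h1, hap_p2 = h2,
    crossovers_p1 = xo(h1), crossovers_p2 = xo(h2),
    distorted = data.frame(marker = true_map$marker[distorted],
                           parent = dist_parent, allele = dist_allele,
                           strength = rep(s, length(distorted))))
  gm
}

#' Specification of a rearranged reference genome and its hit noise
#'
#' @param ops list of rearrangement operations; each a list with `type`
#'   (`"inversion"`, `"translocation"` or `"fusion"`) and fields: inversion
#'   needs `chrom`, `lo`, `hi` (bp interval); translocation needs `src`,
#'   `lo`, `hi`, `dst`, `at`; fusion needs `a`, `b`.
#' @param no_hit fraction of markers with no homology hit.
#' @param repetitive fraction of markers with more than 10 hits.
#' @param wrong_chrom fraction of markers whose best hit lands on the wrong
#'   chromosome.
#' @param bp_jitter s.d. of positional noise added to hit coordinates (bp).
#' @return a `rearrangement_spec` list.
#' @export
rearrangement_spec <- function(ops = list(), no_hit = 0.05, repetitive = 0.02,
                               wrong_chrom = 0.02, bp_jitter = 5e3) {
  rates <- c(no_hit, repetitive, wrong_chrom)
  if (any(rates < 0) || sum(rates) >= 1) stop("hit-noise fractions invalid")
  if (bp_jitter < 0) stop("bp_jitter must be >= 0")
  for (op in ops) {
    if (!op$type %in% c("inversion", "translocation", "fusion"))
      stop("unknown operation type: ", op$type)
    if (op$type == "fusion" && op$a == op$b)
      stop("cannot fuse a chromosome with itself")
  }
  structure(list(ops = ops, no_hit = no_hit, repetitive = repetitive,
                 wrong_chrom = wrong_chrom, bp_jitter = bp_jitter),
            class = "rearrangement_spec")
}

#' Derive a rearranged reference genome and marker hit table
#'
#' Applies the spec's inversions, translocations and fusions to the true
#' map's physical layout, then emits a 12-column tabular hit file: one best
#' hit per marker, except that a `no_hit` fraction is dropped, a `repetitive`
#' fraction receives 11 decoy hits (so downstream filtering excludes them),
#' and a `wrong_chrom` fraction hits a random other chromosome.
#'
#' @param true_map a [simulate_true_map()] result.
#' @param spec a [rearrangement_spec()].
#' @param species_id label used in the truth record.
#' @param seed RNG seed.
#' @return list with `positions` (marker, chrom, bp on the derived genome),
#'   `hits` (12-column hit table), `chrom_lengths` (chrom, length_bp) and
#'   `truth` (species id and applied operations).
#' @export
derive_reference_genome <- function(true_map, spec = rearrangement_spec(),
                                    species_id = "sp", seed = 1L) {
  stopifnot(inherits(true_map, "true_map"), inherits(spec, "rearrangement_spec"))
  set.seed(seed)
  pos <- data.frame(marker = true_map$marker, chrom = true_map$chrom,
                    bp = as.numeric(true_map$bp), stringsAsFactors = FALSE)
  for (op in spec$ops) {
    if (op$type == "inversion") {
      sel <- pos$chrom == op$chrom & pos$bp >= op$lo & pos$bp <= op$hi
      pos$bp[sel] <- op$lo + op$hi - pos$bp[sel]
    } else if (op$type == "translocation") {
      if (!any(pos$chrom == op$src)) stop("unknown chromosome: ", op$src)
      w <- op$hi - op$lo
      sel <- pos$chrom == op$src & pos$bp >= op$lo & pos$bp <= op$hi
      shift_dst <- pos$chrom == op$dst & pos$bp >= op$at
      shift_src <- pos$chrom == op$src & pos$bp > op$hi
      pos$bp[shift_dst] <- pos$bp[shift_dst] + w
      pos$chrom[sel] <- op$dst
      pos$bp[sel] <- op$at + (pos$bp[sel] - op$lo)
      pos$bp[shift_src] <- pos$bp[shift_src] - w
    } else if (op$type == "fusion") {
      if (!any(pos$chrom == op$a) || !any(pos$chrom == op$b))
        stop("fusion of unknown chromosome")
      off <- max(pos$bp[pos$chrom == op$a]) + 1e6
      sel <- pos$chrom == op$b
      pos$bp[sel] <- pos$bp[sel] + off
      pos$chrom[sel] <- op$a
    }
  }
  n_m <- nrow(pos)
  u <- runif(n_m)
  chroms <- unique(pos$chrom)
  kind <- rep("ok", n_m)
  kind[u < spec$no_hit] <- "none"
  kind[u >= spec$no_hit & u < spec$no_hit + spec$repetitive] <- "repeat"
  kind[u >= spec$no_hit + spec$repetitive &
         u < spec$no_hit + spec$repetitive + spec$wrong_chrom] <- "wrong"
  hit_row <- function(q, chrom, bp, evalue, bits) {
    mid <- max(48, round(bp + rnorm(1, 0, spec$bp_jitter)))
    minus <- runif(1) < 0.5
    st <- mid - 47; en <- mid + 47
    data.frame(qseqid = q, sseqid = chrom, pident = round(runif(1, 92, 100), 2),
               length = 95L, mismatch = sample.int(5L, 1L) - 1L, gapopen = 0L,
               qstart = 1L, qend = 95L,
               sstart = if (minus) en else st, send = if (minus) st else en,
               evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
  }
  rows <- vector("list", n_m)
  for (m in seq_len(n_m)) {
    if (kind[m] == "none") next
    if (kind[m] == "repeat") {
      rows[[m]] <- do.call(rbind, lapply(1:11, function(k)
        hit_row(pos$marker[m], sample(chroms, 1L),
                runif(1, 1e5, max(pos$bp)), 1e-15, round(runif(1, 80, 120), 1))))
    } else {
      chrom <- pos$chrom[m]; bp <- pos$bp[m]
      if (kind[m] == "wrong" && length(chroms) > 1) {
        chrom <- sample(setdiff(chroms, chrom), 1L)
        bp <- runif(1, 1e5, max(pos$bp[pos$chrom == chrom]))
      }
      rows[[m]] <- hit_row(pos$marker[m], chrom, bp,
                           10^-runif(1, 20, 60), round(runif(1, 150, 190), 1))
    }
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(hits) <- NULL
  lens <- vapply(split(pos$bp, pos$chrom), max, 0) + 1e5
  list(positions = pos, hits = hits,
       chrom_lengths = data.frame(chrom = names(lens), length_bp = unname(lens),
                                  stringsAsFactors = FALSE),
       truth = list(species = species_id, ops = spec$ops, kind = kind))
}

#' Simulate unplaced transcripts and their genome hits
#'
#' Each transcript gets a true location between two adjacent markers of the
#' true map (so its true cM lies between theirs). For every reference genome
#' it receives a hit at the interpolated position between the flanking
#' markers' derived positions, provided both flanks still sit on the same
#' derived chromosome. A `single_hit_fraction` of transcripts get exactly one
#' hit per species; the rest get zero or two (and are then excluded by the
#' single-hit rule downstream).
#'
#' @param true_map a [simulate_true_map()] result.
#' @param genomes named list of [derive_reference_genome()] results.
#' @param n number of transcripts (>= 1).
#' @param single_hit_fraction fraction with exactly one hit per species.
#' @param bp_jitter s.d. of positional noise on hit coordinates.
#' @param seed RNG seed.
#' @return list with `hits` (named list of 12-column hit tables, one per
#'   species) and `truth` (transcript, chrom, cM, bp).
#' @export
simulate_unplaced_transcripts <- function(true_map, genomes, n,
                                          single_hit_fraction = 1,
                                          bp_jitter = 0, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  stopifnot(inherits(true_map, "true_map"))
  set.seed(seed)
  chroms <- unique(true_map$chrom)
  tx <- sprintf("TX%04d", seq_len(n))
  tchrom <- sample(chroms, n, replace = TRUE)
  truth <- data.frame(transcript = tx, chrom = tchrom, cM = NA_real_,
                      bp = NA_real_, left = NA_character_,
                      right = NA_character_, stringsAsFactors = FALSE)
  frac <- runif(n, 0.1, 0.9)
  left <- right <- character(n)
  for (k in seq_len(n)) {
    rows <- which(true_map$chrom == tchrom[k])
    iv <- sample.int(length(rows) - 1L, 1L)
    left[k] <- true_map$marker[rows[iv]]
    right[k] <- true_map$marker[rows[iv + 1L]]
    truth$cM[k] <- true_map$cM[rows[iv]] +
      frac[k] * (true_map$cM[rows[iv + 1L]] - true_map$cM[rows[iv]])
    truth$bp[k] <- true_map$bp[rows[iv]] +
      frac[k] * (true_map$bp[rows[iv + 1L]] - true_map$bp[rows[iv]])
  }
  truth$left <- left; truth$right <- right
  single <- runif(n) < single_hit_fraction
  hits <- lapply(genomes, function(gen) {
    p <- gen$positions
    out <- vector("list", n)
    for (k in seq_len(n)) {
      pl <- p[p$marker == left[k], ]; pr <- p[p$marker == right[k], ]
      if (nrow(pl) == 0 || nrow(pr) == 0 || pl$chrom != pr$chrom) next
      bp <- pl$bp + frac[k] * (pr$bp - pl$bp) + rnorm(1, 0, bp_jitter)
      row1 <- data.frame(qseqid = tx[k], sseqid = pl$chrom,
                         pident = round(runif(1, 92, 100), 2), length = 400L,
                         mismatch = sample.int(8L, 1L) - 1L, gapopen = 0L,
                         qstart = 1L, qend = 400L,
                         sstart = round(bp - 199), send = round(bp + 200),
                         evalue = 10^-runif(1, 25, 80),
                         bitscore = round(runif(1, 300, 600), 1),
                         stringsAsFactors = FALSE)
      if (single[k]) {
        out[[k]] <- row1
      } else if (runif(1) < 0.5) {
        row2 <- row1
        row2$sseqid <- sample(unique(p$chrom), 1L)
        row2$sstart <- round(runif(1, 1e5, max(p$bp)))
        row2$send <- row2$sstart + 399
        row2$evalue <- 10^-runif(1, 25, 40)
        row2$bitscore <- round(runif(1, 300, 400), 1)
        out[[k]] <- rbind(row1, row2)
      }  # else: no hit in this species
    }
    got <- !vapply(out, is.null, TRUE)
    if (!any(got)) return(NULL)
    res <- do.call(rbind, out[got])
    rownames(res) <- NULL
    res
  })
  list(hits = hits, truth = truth)
}
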