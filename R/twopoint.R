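# Two-point recombination-fraction machinery for outcross (CP) families.
#
# For a pair of markers the joint offspring genotype probabilities are sums
# over the 2 x 2 parental gamete combinations: under a given parental phase
# each gamete is one of the two parental haplotypes with probability
# (1 - r) / 2 each, or one of the two recombinants with probability r / 2.
# Every observable joint genotype class therefore has probability
#   P(class) = (c0 (1-r)^2 + c1 r (1-r) + c2 r^2) / 4
# with integer coefficients c counting gamete combinations by number of
# recombinant gametes. The coefficients depend only on the two cross types
# (in the canonical allele frame) and the phase pair, so they are enumerated
# once and cached.

.ct_index <- function(cross_type) {
  match(cross_type, c("AB_x_AB", "AB_x_AC", "AB_x_CD"))
}

# parent 2's canonical alleles for each cross type (parent 1 is always a/b)
.p2_alleles <- function(ct_idx) {
  switch(ct_idx, c(1L, 2L), c(1L, 3L), c(3L, 4L))
}

.tp_cache <- new.env(parent = emptyenv())

# flattened coefficient table, index ((tt*4 + phase)*256 + jclass)*3 + deg + 1
# with tt = (t1-1)*3 + (t2-1), phase = 2*p1 + p2, jclass 0..255.
.tp_coef_tables <- function() {
  if (!is.null(.tp_cache$tabs)) return(.tp_cache$tabs)
  tabs <- numeric(9L * 4L * 256L * 3L)
  for (t1 in 1:3) for (t2 in 1:3) {
    tt <- (t1 - 1L) * 3L + (t2 - 1L)
    a1m1 <- c(1L, 2L); a1m2 <- c(1L, 2L)           # parent 1
    a2m1 <- .p2_alleles(t1); a2m2 <- .p2_alleles(t2)  # parent 2
    for (p1 in 0:1) for (p2 in 0:1) {
      phase <- 2L * p1 + p2
      for (i1 in 1:2) for (j1 in 1:2) for (i2 in 1:2) for (j2 in 1:2) {
        # a gamete is parental when the m2 allele index matches the phase
        # pairing of the m1 allele index
        pair1 <- if (p1 == 0L) i1 else 3L - i1
        pair2 <- if (p2 == 0L) i2 else 3L - i2
        deg <- (j1 != pair1) + (j2 != pair2)
        code1 <- .pair_code(a1m1[i1], a2m1[i2])
        code2 <- .pair_code(a1m2[j1], a2m2[j2])
        jc <- (code1 - 1L) * 16L + (code2 - 1L)
        idx <- ((tt * 4L + phase) * 256L + jc) * 3L + deg + 1L
        tabs[idx] <- tabs[idx] + 1
      }
    }
  }
  .tp_cache$tabs <- tabs
  tabs
}

# coefficient matrix (256 x 3) for one cross-type pair and phase
.tp_coef <- function(t1, t2, phase) {
  tabs <- .tp_coef_tables()
  tt <- (t1 - 1L) * 3L + (t2 - 1L)
  off <- (tt * 4L + phase) * 256L * 3L
  matrix(tabs[(off + 1L):(off + 768L)], ncol = 3L, byrow = TRUE)
}

#' Joint log-likelihood of a marker pair at a given phase and rf
#'
#' Sums, over offspring with both genotypes observed, the log probability of
#' the joint genotype under the outcross two-point model: each parent
#' transmits a parental haplotype with probability (1 - rf)/2 or a
#' recombinant with probability rf/2, with the haplotypes fixed by the phase
#' configuration. Missing genotypes contribute nothing.
#'
#' @param g1,g2 canonical genotype codes for the two markers (rows of a
#'   [genotype_matrix()]'s `geno`).
#' @param ct1,ct2 cross types of the two markers.
#' @param phase phase configuration 1..4 (parent-1 phase x parent-2 phase).
#' @param rf recombination fraction in \[0, 0.5\].
#' @return log-likelihood (natural log).
#' @export
pair_likelihood <- function(g1, g2, ct1, ct2, phase, rf) {
  if (rf < 0 || rf > 0.5) stop("rf must be in [0, 0.5]")
  t1 <- .ct_index(ct1); t2 <- .ct_index(ct2)
  if (is.na(t1) || is.na(t2)) stop("both markers must be informative")
  stopifnot(phase %in% 1:4)
  co <- .tp_coef(t1, t2, phase - 1L)
  ok <- !is.na(g1) & !is.na(g2)
  jc <- (g1[ok] - 1L) * 16L + (g2[ok] - 1L) + 1L
  cnt <- tabulate(jc, nbins = 256L)
  use <- cnt > 0L
  p <- (co[use, 1L] * (1 - rf)^2 + co[use, 2L] * rf * (1 - rf) +
          co[use, 3L] * rf^2) / 4
  if (any(p == 0))
    return(-Inf)
  sum(cnt[use] * log(p))
}

#' Estimate the recombination fraction of one marker pair
#'
#' Maximises [pair_likelihood()] over rf separately under each of the four
#' parental phase configurations and returns the phase with the highest
#' maximised likelihood. The LOD score is the decimal log-likelihood ratio of
#' the estimate against rf = 0.5 (no linkage), at which the likelihood does
#' not depend on phase.
#'
#' @param gm a [genotype_matrix()] of informative markers.
#' @param i,j marker indices or ids.
#' @param tol convergence tolerance of the rf optimisation.
#' @return list with `rf`, `lod`, `phase`, `n` (jointly scored offspring).
#' @export
estimate_rf <- function(gm, i, j, tol = 1e-6) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.character(i)) i <- match(i, gm$markers$id)
  if (is.character(j)) j <- match(j, gm$markers$id)
  g1 <- gm$geno[i, ]; g2 <- gm$geno[j, ]
  ct1 <- gm$markers$cross_type[i]; ct2 <- gm$markers$cross_type[j]
  n <- sum(!is.na(g1) & !is.na(g2))
  if (n < 2) stop("fewer than 2 jointly non-missing offspring")
  best <- list(ll = -Inf, rf = NA_real_, phase = NA_integer_)
  for (ph in 1:4) {
    opt <- optimize(function(r) pair_likelihood(g1, g2, ct1, ct2, ph, r),
                    interval = c(1e-6, 0.4999), maximum = TRUE, tol = tol)
    if (opt$objective > best$ll + 1e-9 ||
        (abs(opt$objective - best$ll) <= 1e-9 && !is.na(best$rf) &&
           opt$maximum < best$rf)) {
      best <- list(ll = opt$objective, rf = opt$maximum, phase = ph)
    }
  }
  ll0 <- pair_likelihood(g1, g2, ct1, ct2, 1L, 0.5)
  list(rf = best$rf, lod = max(0, (best$ll - ll0) / log(10)),
       phase = best$phase, n = n)
}

#' Two-point scan over all marker pairs
#'
#' Computes the maximum-likelihood recombination fraction, LOD score and best
#' phase for every pair of informative markers, using a compiled
#' golden-section optimiser. This is the input to linkage grouping and
#' ordering.
#'
#' @param gm a [genotype_matrix()]; uninformative markers are not allowed
#'   (filter first with [filter_markers()]).
#' @param tol optimisation tolerance.
#' @return data.frame with columns `i`, `j` (marker indices, i < j), `rf`,
#'   `lod`, `phase`, `n`. Pairs with fewer than 2 jointly scored offspring get
#'   `rf = NA`, `lod = 0`.
#' @export
twopoint_scan <- function(gm, tol = 1e-6) {
  stopifnot(inherits(gm, "geno_matrix"))
  ct <- .ct_index(gm$markers$cross_type)
  if (anyNA(ct)) stop("all markers must be informative; run filter_markers first")
  if (nrow(gm$geno) < 2) stop("need at least two markers")
  res <- tp_scan_cpp(gm$geno, as.integer(ct), .tp_coef_tables(), tol)
  data.frame(i = res$i, j = res$j, rf = res$rf, lod = res$lod,
             phase = res$phase, n = res$n)
}
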