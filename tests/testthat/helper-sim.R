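# Shared fixtures and an independent brute-force oracle for the two-point
# likelihood, written over genotype strings so it shares no machinery with
# the package's coefficient-table implementation.

make_gm <- function(p1, p2, geno) {
  genotype_matrix(data.frame(id = paste0("M", seq_along(p1)), p1 = p1, p2 = p2,
                             stringsAsFactors = FALSE),
                  geno)
}

# P(joint offspring genotype) for two markers by explicit enumeration of the
# 2 x 2 parental gamete combinations. Parents are given as per-marker allele
# pairs; phase p in {0, 1} pairs parent allele i at marker 1 with allele i
# (p = 0) or allele 3 - i (p = 1) at marker 2.
bf_pair_loglik <- function(g1, g2, par1_m1, par1_m2, par2_m1, par2_m2,
                           ph1, ph2, r) {
  gam <- function(alle_m1, alle_m2, p) {
    out <- list()
    for (i in 1:2) for (j in 1:2) {
      parental <- if (p == 0) j == i else j == (3 - i)
      out[[length(out) + 1]] <- list(a1 = alle_m1[i], a2 = alle_m2[j],
                                     pr = if (parental) (1 - r) / 2 else r / 2)
    }
    out
  }
  G1 <- gam(par1_m1, par1_m2, ph1)
  G2 <- gam(par2_m1, par2_m2, ph2)
  sameg <- function(x, y) paste(sort(x), collapse = "/") ==
    paste(sort(y), collapse = "/")
  ll <- 0
  for (k in seq_along(g1)) {
    if (is.na(g1[k]) || g1[k] == "-" || is.na(g2[k]) || g2[k] == "-") next
    o1 <- strsplit(g1[k], "/")[[1]]; o2 <- strsplit(g2[k], "/")[[1]]
    p <- 0
    for (u in G1) for (v in G2) {
      if (sameg(c(u$a1, v$a1), o1) && sameg(c(u$a2, v$a2), o2))
        p <- p + u$pr * v$pr
    }
    ll <- ll + log(p)
  }
  ll
}

# a fully informative (ab x cd at both markers) family with a prescribed
# number of recombinant meioses, coupling phase in both parents
cd_pair_family <- function(n_off, rec_pat, rec_mat) {
  stopifnot(rec_pat <= n_off, rec_mat <= n_off)
  # parent 1 haps: a-a / b-b over (m1, m2); parent 2: c-c / d-d
  pat_h <- rep(c(1, 2), length.out = n_off)
  mat_h <- rep(c(1, 2), length.out = n_off)
  pat_rec <- seq_len(n_off) <= rec_pat
  mat_rec <- n_off - seq_len(n_off) < rec_mat
  p1al <- c("a", "b"); p2al <- c("c", "d")
  m1 <- paste(p1al[pat_h], p2al[mat_h], sep = "/")
  m2 <- paste(p1al[ifelse(pat_rec, 3 - pat_h, pat_h)],
              p2al[ifelse(mat_rec, 3 - mat_h, mat_h)], sep = "/")
  make_gm(c("a/b", "a/b"), c("c/d", "c/d"), rbind(m1, m2))
}

# two-marker true map at a given Kosambi distance
tiny_true_map <- function(d_cM) {
  structure(data.frame(chrom = "chr01", marker = c("M1", "M2"),
                       cM = c(0, max(d_cM, 1e-9)), bp = c(1e5, 2e5),
                       stringsAsFactors = FALSE),
            class = c("true_map", "data.frame"))
}

# 12-column hit row builder
hit <- function(q, s, evalue = 1e-30, bits = 180, sstart = 1000, send = 1094) {
  data.frame(qseqid = q, sseqid = s, pident = 99, length = 95, mismatch = 0,
             gapopen = 0, qstart = 1, qend = 95, sstart = sstart, send = send,
             evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
}
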