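# Homology-hit filtering and chromosome-level synteny tabulation.

.hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

.check_hits <- function(hits) {
  if (!all(.hit_cols %in% names(hits)))
    stop("hit table must have the 12 standard tabular columns")
  if (any(hits$evalue < 0) || any(hits$sstart <= 0) || any(hits$send <= 0))
    stop("malformed hit rows: negative e-value or non-positive coordinates")
  hits
}

#' Filter homology hits to one best hit per query
#'
#' Drops hits above the e-value cutoff, excludes queries with more than
#' `max_hits` surviving hits (repetitive sequences), and keeps the highest
#' bit score per remaining query (ties broken by lowest e-value, then
#' lexicographic subject id, then smallest subject start). Subject
#' coordinates follow the tabular-hit convention (1-based inclusive, start >
#' end on the minus strand); the result adds 0-based half-open `s_lo`/`s_hi`,
#' a `strand` flag and the hit `midpoint`.
#'
#' @param hits data.frame with the 12 standard tabular columns.
#' @param e_max e-value cutoff (1e-9 is typical against genomes, 1e-20
#'   against a transcriptome).
#' @param max_hits queries with more surviving hits than this are excluded.
#' @return filtered data.frame, at most one row per query.
#' @export
filter_hits <- function(hits, e_max = 1e-9, max_hits = 10) {
  stopifnot(e_max > 0)
  hits <- .check_hits(hits)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(hits) == 0) return(.with_hit_coords(hits))
  nh <- table(hits$qseqid)
  keep_q <- names(nh)[nh <= max_hits]
  hits <- hits[hits$qseqid %in% keep_q, , drop = FALSE]
  if (nrow(hits) == 0) return(.with_hit_coords(hits))
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid,
               pmin(hits$sstart, hits$send))
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(hits) <- NULL
  .with_hit_coords(hits)
}

.with_hit_coords <- function(hits) {
  hits$s_lo <- pmin(hits$sstart, hits$send) - 1
  hits$s_hi <- pmax(hits$sstart, hits$send)
  hits$strand <- ifelse(hits$sstart <= hits$send, "+", "-")
  hits$midpoint <- (hits$s_lo + hits$s_hi) / 2
  hits
}

#' Turn filtered hits into marker-to-genome assignments
#'
#' @param filtered output of [filter_hits()].
#' @param source provenance label (`"direct"` or `"transcriptome-anchored"`).
#' @return data.frame with `marker`, `chrom`, `bp` (hit midpoint), `source`.
#' @export
hit_assignments <- function(filtered, source = "direct") {
  if (nrow(filtered) == 0)
    return(data.frame(marker = character(), chrom = character(),
                      bp = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  data.frame(marker = filtered$qseqid, chrom = filtered$sseqid,
             bp = filtered$midpoint, source = source, stringsAsFactors = FALSE)
}

#' Anchor unmatched markers to a genome via the transcriptome
#'
#' A marker with no direct genome hit inherits the genome position of its
#' single best transcriptome contig, provided that contig itself has a
#' (filtered) genome hit. Both input tables must already be filtered with
#' [filter_hits()].
#'
#' @param marker_tx filtered marker-to-transcriptome hits.
#' @param tx_genome filtered transcriptome-contig-to-genome hits.
#' @return assignments data.frame (`marker`, `chrom`, `bp`,
#'   `source = "transcriptome-anchored"`).
#' @export
anchor_via_transcriptome <- function(marker_tx, tx_genome) {
  m <- match(marker_tx$sseqid, tx_genome$qseqid)
  ok <- !is.na(m)
  data.frame(marker = marker_tx$qseqid[ok],
             chrom = tx_genome$sseqid[m[ok]],
             bp = tx_genome$midpoint[m[ok]],
             source = "transcriptome-anchored", stringsAsFactors = FALSE)
}

#' Tabulate chromosome-level conserved synteny
#'
#' For each linkage group and reference species, counts the homologous loci
#' per subject chromosome and assigns the homologous chromosome(s): every
#' chromosome holding more than `majority_min` of the group's hits, or —
#' when no single chromosome reaches the majority — the top two chromosomes
#' when each holds at least `count_min` hits and together they exceed the
#' majority (the split pattern left by a chromosome fission/fusion).
#'
#' @param map data.frame with `group` and `marker` columns (e.g. the `map`
#'   component of a [linkage_map()] fit).
#' @param assignments data.frame with `marker`, `species`, `chrom`, `bp`
#'   (rbind of per-species [hit_assignments()] with a `species` column).
#' @param majority_min majority fraction threshold.
#' @param count_min minimum hits per chromosome in the two-chromosome case.
#' @return a `synteny_table`: list with `assigned` (group, species, chrom,
#'   n_hits, fraction), `counts` (all group x species x chrom counts) and
#'   `lg_totals` (homologous-locus totals per group and species).
#' @export
build_synteny_table <- function(map, assignments, majority_min = 0.5,
                                count_min = 5) {
  lg <- map$group[match(assignments$marker, map$marker)]
  keep <- !is.na(lg)
  a <- assignments[keep, , drop = FALSE]
  a$group <- lg[keep]
  cnt <- as.data.frame(table(group = a$group, species = a$species,
                             chrom = a$chrom), stringsAsFactors = FALSE)
  cnt <- cnt[cnt$Freq > 0, , drop = FALSE]
  names(cnt)[4] <- "n_hits"
  tot <- stats::aggregate(n_hits ~ group + species, cnt, sum)
  names(tot)[3] <- "total"
  assigned <- list()
  for (r in seq_len(nrow(tot))) {
    d <- cnt[cnt$group == tot$group[r] & cnt$species == tot$species[r], ]
    d <- d[order(-d$n_hits, d$chrom), ]
    frac <- d$n_hits / tot$total[r]
    if (frac[1] > majority_min) {
      sel <- d[1, , drop = FALSE]
    } else if (nrow(d) >= 2 && all(d$n_hits[1:2] >= count_min) &&
               sum(frac[1:2]) > majority_min) {
      sel <- d[1:2, , drop = FALSE]
    } else {
      next
    }
    sel$fraction <- sel$n_hits / tot$total[r]
    assigned[[length(assigned) + 1L]] <- sel
  }
  assigned <- if (length(assigned)) do.call(rbind, assigned) else
    data.frame(group = character(), species = character(), chrom = character(),
               n_hits = integer(), fraction = numeric())
  rownames(assigned) <- NULL
  structure(list(assigned = assigned, counts = cnt, lg_totals = tot),
            class = "synteny_table")
}

#' @export
print.synteny_table <- function(x, ...) {
  cat("Chromosome-level synteny table\n")
  cat(sprintf("  %d linkage-group x species assignments over %d species\n",
              nrow(x$assigned), length(unique(x$assigned$species))))
  invisible(x)
}
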