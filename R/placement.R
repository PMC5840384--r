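# Placement of unplaced transcripts on the linkage map: directly through a
# hit to a mapped marker, or through collinear blocks via the nearest left
# and right flanking loci, combining evidence across reference species for
# the smallest possible interval.

.placement_row <- function(transcript, status, lg = NA_character_,
                           lo = NA_real_, hi = NA_real_, n_species = 0L,
                           species = "", note = "") {
  n <- length(transcript)
  data.frame(transcript = transcript, status = rep_len(status, n),
             lg = rep_len(lg, n), lo_cM = rep_len(lo, n),
             hi_cM = rep_len(hi, n), n_species = rep_len(n_species, n),
             species = rep_len(species, n), note = rep_len(note, n),
             stringsAsFactors = FALSE)
}

#' Place transcripts that hit a mapped marker directly
#'
#' A transcript whose best (filtered) hit is a mapped RAD marker inherits
#' that marker's exact map position as a zero-width interval. Hits to
#' markers absent from the map yield `unplaced` with a reason.
#'
#' @param tx_marker_hits output of [filter_hits()] for transcript-to-marker
#'   searches (queries are transcripts, subjects are markers).
#' @param map data.frame with `group`, `marker`, `position_cM`.
#' @return placement data.frame: `transcript`, `status`, `lg`, `lo_cM`,
#'   `hi_cM`, `n_species`, `species`, `note`.
#' @export
direct_assign <- function(tx_marker_hits, map) {
  rows <- lapply(seq_len(nrow(tx_marker_hits)), function(r) {
    tx <- tx_marker_hits$qseqid[r]
    mk <- tx_marker_hits$sseqid[r]
    m <- match(mk, map$marker)
    if (is.na(m))
      return(.placement_row(tx, "unplaced", note = paste0("hit to unmapped marker ", mk)))
    .placement_row(tx, "placed", map$group[m], map$position_cM[m],
                   map$position_cM[m], 0L, note = paste0("direct:", mk))
  })
  if (!length(rows)) return(.placement_row(character(0), character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# queries with exactly one hit passing the e-value cutoff
.single_hit <- function(hits, e_max) {
  hits <- .check_hits(hits)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  nh <- table(hits$qseqid)
  hits <- hits[hits$qseqid %in% names(nh)[nh == 1], , drop = FALSE]
  .with_hit_coords(hits)
}

# evidence for one transcript in one species: containing block and flanks
.species_evidence <- function(bp, blocks, members, anchors) {
  if (nrow(blocks) == 0) return(NULL)
  inside <- which(blocks$bp_lo <= bp & bp <= blocks$bp_hi)
  if (!length(inside)) return(list(status = "outside"))
  b <- inside[1]
  mk <- members[[b]]
  an <- anchors[match(mk, anchors$marker), ]
  li <- findInterval(bp, an$bp)
  left <- an[max(li, 1L), ]
  right <- an[min(li + 1L, nrow(an)), ]
  list(status = "in_block", lg = blocks$lg[b], block = blocks$block[b],
       left = left$marker, right = right$marker,
       lo = min(left$cM, right$cM), hi = max(left$cM, right$cM),
       edge = li == 0L || li == nrow(an))
}

#' Place transcripts by collinearity with reference genomes
#'
#' Per species, a transcript is used only when it has a single genome hit
#' below `e_max`. The hit midpoint is located inside a collinear block on
#' its chromosome; the nearest anchors left and right of it (by bp) give a
#' species interval spanning their map positions. Evidence is combined
#' across species: species voting for the modal linkage group are retained;
#' if their intervals pairwise overlap the consensus is their intersection,
#' otherwise the single smallest species interval (noted `partial`). Status
#' is `conflict` when the linkage-group vote is tied between different
#' groups, `ambiguous` when every species' hit falls outside all blocks, and
#' `unplaced` when no species has usable evidence.
#'
#' @param tx_hits named list (one element per species) of *raw* transcript
#'   to genome hit tables.
#' @param blocks_by_species named list of [detect_blocks()] results per
#'   species (rbind of all anchor sets' blocks, with `members` and `anchors`
#'   attributes preserved per element as returned by [species_blocks()]).
#' @param e_max e-value cutoff for the single-hit rule.
#' @return placement data.frame plus an `evidence` attribute with one row
#'   per (transcript, species) giving chromosome, hit bp, block and flanks.
#' @export
collinearity_place <- function(tx_hits, blocks_by_species, e_max = 1e-9) {
  species <- sort(names(tx_hits))
  singles <- lapply(tx_hits[species], function(h)
    if (is.null(h)) NULL else .single_hit(h, e_max))
  tx_all <- sort(unique(unlist(lapply(singles, function(h) h$qseqid))))
  ev_rows <- list()
  out_rows <- list()
  for (tx in tx_all) {
    per_sp <- list()
    any_outside <- FALSE
    for (sp in species) {
      h <- singles[[sp]]
      if (is.null(h)) next
      r <- which(h$qseqid == tx)
      if (!length(r)) next
      bl <- blocks_by_species[[sp]]
      if (is.null(bl)) next
      chrom_bl <- bl[bl$chrom == h$sseqid[r], , drop = FALSE]
      memb <- attr(bl, "members")[chrom_bl$block]
      anch <- attr(bl, "anchors")
      anch <- anch[anch$chrom == h$sseqid[r], , drop = FALSE]
      ev <- .species_evidence(h$midpoint[r], chrom_bl, memb, anch)
      if (is.null(ev)) next
      if (ev$status == "outside") { any_outside <- TRUE; next }
      per_sp[[sp]] <- ev
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        transcript = tx, species = sp, chrom = h$sseqid[r],
        bp = h$midpoint[r], block = ev$block, lg = ev$lg,
        left = ev$left, right = ev$right, lo_cM = ev$lo, hi_cM = ev$hi,
        stringsAsFactors = FALSE)
    }
    if (!length(per_sp)) {
      out_rows[[length(out_rows) + 1L]] <- .placement_row(
        tx, if (any_outside) "ambiguous" else "unplaced",
        note = if (any_outside) "hit outside every block" else "no species evidence")
      next
    }
    lgs <- vapply(per_sp, `[[`, "", "lg")
    vt <- table(lgs)
    top <- names(vt)[vt == max(vt)]
    if (length(top) > 1) {
      out_rows[[length(out_rows) + 1L]] <- .placement_row(
        tx, "conflict", n_species = length(per_sp),
        species = paste(names(per_sp), collapse = ","),
        note = paste0("tied linkage-group vote: ", paste(top, collapse = " vs ")))
      next
    }
    sel <- per_sp[lgs == top]
    lo <- vapply(sel, `[[`, 0, "lo"); hi <- vapply(sel, `[[`, 0, "hi")
    note <- ""
    if (max(lo) <= min(hi)) {
      clo <- max(lo); chi <- min(hi)
    } else {
      w <- hi - lo
      k <- which.min(w)
      clo <- lo[k]; chi <- hi[k]
      note <- "partial: disjoint species intervals, smallest kept"
    }
    status <- if (all(vapply(sel, `[[`, TRUE, "edge"))) "edge" else "placed"
    out_rows[[length(out_rows) + 1L]] <- .placement_row(
      tx, status, top, clo, chi, length(sel),
      paste(names(sel), collapse = ","), note)
  }
  out <- if (length(out_rows)) do.call(rbind, out_rows) else
    .placement_row(character(0), character(0))
  rownames(out) <- NULL
  attr(out, "evidence") <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL
  out
}

#' Detect blocks for all anchor sets of one species and pool them
#'
#' Runs [detect_blocks()] over every anchor set of a species and binds the
#' results, renumbering blocks and pooling the member lists and anchors so
#' [collinearity_place()] can search them per chromosome.
#'
#' @param asets list of [anchor_set()] objects (one species).
#' @param tolerance passed to [detect_blocks()].
#' @return blocks data.frame with `members` and `anchors` attributes.
#' @export
species_blocks <- function(asets, tolerance = 0.05) {
  all_blocks <- list(); all_members <- list(); all_anchors <- list()
  for (as_ in asets) {
    if (nrow(as_$anchors) < 2) next
    bl <- detect_blocks(as_, tolerance)
    if (nrow(bl) == 0) next
    memb <- attr(bl, "members")
    an <- as_$anchors
    an$chrom <- as_$chrom
    bl$block <- bl$block + length(all_members)
    all_blocks[[length(all_blocks) + 1L]] <- bl
    all_members <- c(all_members, memb)
    all_anchors[[length(all_anchors) + 1L]] <- an
  }
  out <- if (length(all_blocks)) do.call(rbind, all_blocks) else
    detect_blocks_empty()
  rownames(out) <- NULL
  attr(out, "members") <- all_members
  attr(out, "anchors") <- if (length(all_anchors))
    do.call(rbind, all_anchors) else
      data.frame(marker = character(), cM = numeric(), bp = numeric(),
                 chrom = character(), stringsAsFactors = FALSE)
  out
}

detect_blocks_empty <- function() {
  data.frame(block = integer(), lg = character(), species = character(),
             chrom = character(), n = integer(), orientation = character(),
             mismatches = integer(), cM_lo = numeric(), cM_hi = numeric(),
             bp_lo = numeric(), bp_hi = numeric(), stringsAsFactors = FALSE)
}
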