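# Collinear-block detection between a linkage group and a reference
# chromosome, with the 5%-of-total-length tolerance for local order
# mismatches.

#' Bundle the anchors shared by one linkage group and one chromosome
#'
#' @param anchors data.frame with `marker`, `cM` (map position) and `bp`
#'   (position on the reference chromosome).
#' @param lg_length_cM total length of the linkage group.
#' @param chrom_length_bp total length of the chromosome.
#' @param lg,species,chrom identifiers.
#' @param interrupters bp positions, on this chromosome, of mapped loci
#'   belonging to *other* linkage groups; a block may not span one.
#' @return an `anchor_set`.
#' @export
anchor_set <- function(anchors, lg_length_cM, chrom_length_bp,
                       lg = "LG", species = "sp", chrom = "chr",
                       interrupters = numeric()) {
  stopifnot(all(c("marker", "cM", "bp") %in% names(anchors)),
            lg_length_cM > 0, chrom_length_bp > 0)
  anchors <- anchors[order(anchors$bp), , drop = FALSE]
  rownames(anchors) <- NULL
  structure(list(anchors = anchors, lg_length_cM = lg_length_cM,
                 chrom_length_bp = chrom_length_bp, lg = lg,
                 species = species, chrom = chrom,
                 interrupters = sort(interrupters)),
            class = "anchor_set")
}

# Kendall tau sign of (bp order, cM) for a candidate run
.run_orientation <- function(cm) {
  n <- length(cm)
  if (n < 2) return(1L)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + sum(sign(cm[(i + 1):n] - cm[i]))
  if (s >= 0) 1L else -1L
}

#' Detect collinear blocks within an anchor set
#'
#' A block is a run of at least two anchors, consecutive along the
#' chromosome, whose map order agrees with their chromosome order in one
#' orientation. An order violation between two anchors is tolerated when
#' their separation is below `tolerance` of the linkage group's total cM
#' length on the map side, or below `tolerance` of the chromosome's total bp
#' length on the genome side (either suffices). A run is interrupted by any
#' intervening mapped locus from a different linkage group. Candidate runs
#' are grown greedily from every start in both orientations; maximal runs
#' are selected longest-first (ties by smaller bp start), so blocks are
#' disjoint.
#'
#' @param aset an [anchor_set()].
#' @param tolerance mismatch tolerance as a fraction of total length
#'   (default 0.05).
#' @return data.frame of blocks: `block`, `lg`, `species`, `chrom`, `n`,
#'   `orientation`, `mismatches`, `cM_lo`, `cM_hi`, `bp_lo`, `bp_hi`, plus a
#'   `members` attribute (list of marker-id vectors in bp order).
#' @export
detect_blocks <- function(aset, tolerance = 0.05) {
  stopifnot(inherits(aset, "anchor_set"))
  an <- aset$anchors
  if (nrow(an) < 2) stop("need at least 2 anchors")
  tol_cm <- tolerance * aset$lg_length_cM
  tol_bp <- tolerance * aset$chrom_length_bp
  used <- rep(FALSE, nrow(an))
  ints <- aset$interrupters
  interrupted <- function(b1, b2) {
    (length(ints) && any(ints > b1 & ints < b2)) ||
      any(used & an$bp > b1 & an$bp < b2)
  }
  extend <- function(avail, s, o) {
    run <- avail[s]
    mism <- 0L
    # the anchor holding the run's running extreme map position: order
    # violations are judged, and the tolerance measured, against it
    extreme <- avail[s]
    last <- avail[s]
    inorder_seen <- FALSE
    prev_mismatch <- FALSE
    if (s < length(avail)) for (t in (s + 1):length(avail)) {
      nxt <- avail[t]
      if (interrupted(an$bp[last], an$bp[nxt])) break
      d <- o * (an$cM[nxt] - an$cM[extreme])
      if (d >= 0) {
        extreme <- nxt
        inorder_seen <- TRUE
        prev_mismatch <- FALSE
      } else {
        # a mismatch is only tolerated inside an established run and never
        # twice in a row, so a reversed or drifting segment forms its own
        # block instead of being nibbled from the ends of a neighbour
        ok <- inorder_seen && !prev_mismatch &&
          (abs(an$cM[nxt] - an$cM[extreme]) < tol_cm ||
             (an$bp[nxt] - an$bp[extreme]) < tol_bp)
        if (!ok) break
        mism <- mism + 1L
        prev_mismatch <- TRUE
      }
      run <- c(run, nxt)
      last <- nxt
    }
    list(run = run, mism = mism)
  }
  blocks <- list(); members <- list()
  repeat {
    avail <- which(!used)
    if (length(avail) < 2) break
    best <- NULL
    better <- function(cand, best) {
      if (is.null(best)) return(TRUE)
      if (length(cand$run) != length(best$run))
        return(length(cand$run) > length(best$run))
      if (cand$mism != best$mism) return(cand$mism < best$mism)
      an$bp[cand$run[1]] < an$bp[best$run[1]]
    }
    for (s in seq_along(avail)) for (o in c(1L, -1L)) {
      cand <- extend(avail, s, o)
      if (better(cand, best)) best <- cand
    }
    if (length(best$run) < 2) break
    used[best$run] <- TRUE
    idx <- best$run
    ori <- .run_orientation(an$cM[idx])
    blocks[[length(blocks) + 1L]] <- data.frame(
      block = length(blocks) + 1L, lg = aset$lg, species = aset$species,
      chrom = aset$chrom, n = length(idx),
      orientation = if (ori > 0) "+" else "-", mismatches = best$mism,
      cM_lo = min(an$cM[idx]), cM_hi = max(an$cM[idx]),
      bp_lo = min(an$bp[idx]), bp_hi = max(an$bp[idx]),
      stringsAsFactors = FALSE)
    members[[length(members) + 1L]] <- an$marker[idx]
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block = integer(), lg = character(), species = character(),
               chrom = character(), n = integer(), orientation = character(),
               mismatches = integer(), cM_lo = numeric(), cM_hi = numeric(),
               bp_lo = numeric(), bp_hi = numeric(), stringsAsFactors = FALSE)
  attr(out, "members") <- members
  attr(out, "anchors") <- an
  out
}

#' Build anchor sets for every (linkage group, species chromosome) pair
#'
#' Joins a genetic map with per-species marker assignments and produces one
#' [anchor_set()] per (group, chromosome) pair with at least `min_anchors`
#' shared markers, wiring in the interrupter positions of other groups'
#' anchors on the same chromosome.
#'
#' @param map data.frame with `group`, `marker`, `position_cM`.
#' @param assignments data.frame with `marker`, `species`, `chrom`, `bp`.
#' @param chrom_lengths data.frame with `species`, `chrom`, `length_bp`.
#' @param min_anchors minimum shared markers (default 2).
#' @return list of `anchor_set` objects.
#' @export
anchor_sets_from_map <- function(map, assignments, chrom_lengths,
                                 min_anchors = 2) {
  a <- assignments
  m <- match(a$marker, map$marker)
  a$group <- map$group[m]
  a$cM <- map$position_cM[m]
  a <- a[!is.na(a$group), , drop = FALSE]
  lg_len <- tapply(map$position_cM, map$group, max)
  out <- list()
  for (sp in unique(a$species)) {
    asp <- a[a$species == sp, , drop = FALSE]
    for (ch in unique(asp$chrom)) {
      d <- asp[asp$chrom == ch, , drop = FALSE]
      clen <- chrom_lengths$length_bp[chrom_lengths$species == sp &
                                        chrom_lengths$chrom == ch]
      if (!length(clen)) clen <- max(d$bp) + 1
      for (g in unique(d$group)) {
        dg <- d[d$group == g, , drop = FALSE]
        if (nrow(dg) < min_anchors) next
        out[[length(out) + 1L]] <- anchor_set(
          dg[, c("marker", "cM", "bp")],
          lg_length_cM = max(lg_len[g], 1e-9), chrom_length_bp = clen,
          lg = g, species = sp, chrom = ch,
          interrupters = d$bp[d$group != g])
      }
    }
  }
  out
}

#' Oxford-grid scatter data for map-versus-genome comparison
#'
#' One row per anchored marker per species: map position against physical
#' position, ready for dot plotting.
#'
#' @param map data.frame with `group`, `marker`, `position_cM`.
#' @param assignments data.frame with `marker`, `species`, `chrom`, `bp`.
#' @return data.frame with `marker`, `lg`, `cM`, `species`, `chrom`, `bp`.
#' @export
oxford_grid_data <- function(map, assignments) {
  m <- match(assignments$marker, map$marker)
  ok <- !is.na(m)
  data.frame(marker = assignments$marker[ok], lg = map$group[m[ok]],
             cM = map$position_cM[m[ok]], species = assignments$species[ok],
             chrom = assignments$chrom[ok], bp = assignments$bp[ok],
             stringsAsFactors = FALSE)
}
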