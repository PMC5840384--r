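#' Configuration for linkage-map construction
#'
#' Defaults follow common practice for dense outcross RAD maps: a permissive
#' two-point screen (LOD 4, rf <= 0.4), stringent grouping (LOD 14, chosen in
#' the original analysis so the group count matches the karyotype), a seed of
#' the 6 most informative markers ordered exhaustively, and a ripple window
#' of 4.
#'
#' @param twopoint_lod_min minimum LOD for a pair to be considered linked in
#'   the two-point screen.
#' @param twopoint_rf_max maximum rf in the two-point screen.
#' @param grouping_lod LOD threshold for linkage-group assignment.
#' @param grouping_rf_max maximum rf for linkage-group assignment.
#' @param ordering_seed_size number of most-informative markers ordered
#'   exhaustively to seed each group's order.
#' @param ordering_lod LOD threshold retained for interface compatibility
#'   with likelihood-based placement of added markers; the SARF criterion
#'   used here is deterministic and does not consult it.
#' @param ripple_window window size of the final ripple pass.
#' @return a `map_config` list.
#' @export
map_config <- function(twopoint_lod_min = 4, twopoint_rf_max = 0.4,
                       grouping_lod = 14, grouping_rf_max = 0.4,
                       ordering_seed_size = 6, ordering_lod = 3,
                       ripple_window = 4) {
  cfg <- list(twopoint_lod_min = twopoint_lod_min,
              twopoint_rf_max = twopoint_rf_max,
              grouping_lod = grouping_lod, grouping_rf_max = grouping_rf_max,
              ordering_seed_size = as.integer(ordering_seed_size),
              ordering_lod = ordering_lod,
              ripple_window = as.integer(ripple_window))
  if (any(vapply(cfg, function(x) x <= 0, TRUE)))
    stop("all map_config values must be positive")
  if (cfg$twopoint_rf_max > 0.5 || cfg$grouping_rf_max > 0.5)
    stop("rf bounds must be <= 0.5")
  structure(cfg, class = "map_config")
}

#' Assign markers to linkage groups
#'
#' Two markers are linked when their two-point LOD is at least
#' `grouping_lod` and their rf at most `grouping_rf_max`; linkage groups are
#' the transitive closure (connected components) of that relation. Markers in
#' singleton components are reported as unassigned.
#'
#' @param tp two-point table from [twopoint_scan()].
#' @param n_markers total number of markers indexed by `tp`.
#' @param config a [map_config()].
#' @return list with `groups` (list of integer marker-index vectors, largest
#'   first) and `unassigned` (integer vector).
#' @export
group_markers <- function(tp, n_markers, config = map_config()) {
  linked <- !is.na(tp$rf) & tp$lod >= config$grouping_lod &
    tp$rf <= config$grouping_rf_max
  g <- igraph::make_empty_graph(n = n_markers, directed = FALSE)
  if (any(linked))
    g <- igraph::add_edges(g, rbind(tp$i[linked], tp$j[linked]))
  comp <- igraph::components(g)
  idx <- split(seq_len(n_markers), comp$membership)
  sizes <- lengths(idx)
  groups <- idx[sizes >= 2]
  # largest first; ties by smallest member index for determinism
  ord <- order(-lengths(groups), vapply(groups, min, 0L))
  groups <- unname(groups[ord])
  unassigned <- sort(unlist(idx[sizes == 1], use.names = FALSE))
  list(groups = groups, unassigned = as.integer(unassigned))
}

#' Group-count profile over a range of grouping LOD thresholds
#'
#' Utility for choosing the grouping LOD the way dense-map studies do: scan
#' thresholds and pick one whose group count matches the karyotype while
#' leaving few markers unassigned.
#'
#' @param tp two-point table from [twopoint_scan()].
#' @param n_markers total number of markers.
#' @param lods LOD thresholds to scan.
#' @param config base [map_config()]; its rf bound is kept.
#' @return data.frame with `lod`, `n_groups`, `n_unassigned`.
#' @export
scan_grouping_lod <- function(tp, n_markers, lods = 3:30,
                              config = map_config()) {
  rows <- lapply(lods, function(l) {
    cfg <- config; cfg$grouping_lod <- l
    gr <- group_markers(tp, n_markers, cfg)
    data.frame(lod = l, n_groups = length(gr$groups),
               n_unassigned = length(gr$unassigned))
  })
  do.call(rbind, rows)
}

# all permutations of 1..n (n small), deterministic order
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

.sarf <- function(ord, rfm) {
  if (length(ord) < 2) return(0)
  sum(rfm[cbind(ord[-length(ord)], ord[-1])])
}

#' Order the markers of one linkage group
#'
#' Seriation by the sum of adjacent recombination fractions (SARF): the
#' `ordering_seed_size` most informative markers (cross-type priority
#' ab x cd > ab x ac > ab x ab, then most scored offspring, then marker id)
#' are ordered exhaustively; the remaining markers are inserted greedily, one
#' at a time in informativeness order, each at the position that increases
#' SARF least; a final ripple pass permutes every sliding window of
#' `ripple_window` markers and accepts strict improvements until none remain.
#' Orientation of the result is not identifiable (reversal preserves SARF).
#'
#' @param members integer indices of the group's markers.
#' @param tp two-point table from [twopoint_scan()].
#' @param gm the [genotype_matrix()] the scan was run on.
#' @param config a [map_config()].
#' @return integer vector: `members` in estimated order.
#' @export
order_markers <- function(members, tp, gm, config = map_config()) {
  m <- length(members)
  if (m < 2) stop("group must have at least 2 markers")
  if (m == 2) return(members)
  # local rf matrix; missing estimates treated as unlinked
  rfm <- matrix(0.5, m, m)
  pos <- match(tp$i, members); qos <- match(tp$j, members)
  sel <- !is.na(pos) & !is.na(qos)
  rf <- ifelse(is.na(tp$rf[sel]), 0.5, tp$rf[sel])
  rfm[cbind(pos[sel], qos[sel])] <- rf
  rfm[cbind(qos[sel], pos[sel])] <- rf
  prio <- match(gm$markers$cross_type[members],
                c("AB_x_AB", "AB_x_AC", "AB_x_CD"))
  scored <- rowSums(!is.na(gm$geno[members, , drop = FALSE]))
  info_ord <- order(-prio, -scored, gm$markers$id[members])
  k <- min(config$ordering_seed_size, m)
  seed <- info_ord[seq_len(k)]
  rest <- info_ord[-seq_len(k)]
  pm <- .perms(k)
  costs <- apply(pm, 1, function(p) .sarf(seed[p], rfm))
  cur <- seed[pm[which.min(costs), ]]
  for (x in rest) {
    ncur <- length(cur)
    # cost of inserting x at each of ncur+1 positions
    delta <- numeric(ncur + 1)
    delta[1] <- rfm[x, cur[1]]
    delta[ncur + 1] <- rfm[cur[ncur], x]
    if (ncur > 1) {
      a <- cur[-ncur]; b <- cur[-1]
      delta[2:ncur] <- rfm[cbind(a, x)] + rfm[cbind(x, b)] - rfm[cbind(a, b)]
    }
    at <- which.min(delta)
    cur <- append(cur, x, after = at - 1L)
  }
  # ripple
  w <- min(config$ripple_window, m)
  wperms <- .perms(w)
  improved <- TRUE
  guard <- 0L
  while (improved && guard < 50L) {
    improved <- FALSE
    guard <- guard + 1L
    for (s in seq_len(m - w + 1L)) {
      idx <- s:(s + w - 1L)
      best_cost <- .sarf(cur, rfm)
      best <- NULL
      for (r in seq_len(nrow(wperms))) {
        cand <- cur
        cand[idx] <- cur[idx][wperms[r, ]]
        cc <- .sarf(cand, rfm)
        if (cc < best_cost - 1e-12) { best_cost <- cc; best <- cand }
      }
      if (!is.null(best)) { cur <- best; improved <- TRUE }
    }
  }
  # canonical orientation: smaller first-marker id than last-marker id
  if (gm$markers$id[members[cur[1]]] > gm$markers$id[members[cur[m]]])
    cur <- rev(cur)
  members[cur]
}

#' Assemble a genetic map from grouped, ordered markers
#'
#' Positions are cumulative Kosambi distances of the adjacent two-point
#' recombination fractions along each group's order, starting at 0.
#'
#' @param orders list of ordered integer marker-index vectors (one per group).
#' @param tp two-point table from [twopoint_scan()].
#' @param marker_ids character vector of marker ids indexed by `tp`.
#' @return data.frame with `group`, `rank`, `marker`, `position_cM`.
#' @export
build_map <- function(orders, tp, marker_ids) {
  key <- paste(tp$i, tp$j)
  rows <- lapply(seq_along(orders), function(g) {
    ord <- orders[[g]]
    n <- length(ord)
    pos <- numeric(n)
    if (n > 1) {
      a <- pmin(ord[-n], ord[-1]); b <- pmax(ord[-n], ord[-1])
      rf <- tp$rf[match(paste(a, b), key)]
      rf[is.na(rf)] <- 0.4999
      pos <- c(0, cumsum(kosambi_cM(pmin(rf, 0.49989))))
    }
    data.frame(group = paste0("LG", g), rank = seq_len(n),
               marker = marker_ids[ord], position_cM = pos,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-group summary of a genetic map
#'
#' @param map data.frame as returned by [build_map()].
#' @return data.frame with `group`, `size_cM` (last position), `n_loci`,
#'   `mean_distance_cM` (size / (n - 1)) and `largest_gap_cM`.
#' @export
map_summary <- function(map) {
  rows <- lapply(split(map, map$group), function(d) {
    d <- d[order(d$rank), ]
    n <- nrow(d)
    size <- d$position_cM[n]
    gaps <- diff(d$position_cM)
    data.frame(group = d$group[1], size_cM = size, n_loci = n,
               mean_distance_cM = if (n > 1) size / (n - 1) else NA_real_,
               largest_gap_cM = if (n > 1) max(gaps) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(as.integer(sub("^LG", "", out$group))), ]
  rownames(out) <- NULL
  out
}

#' Fit a genetic linkage map to a full-sib outcross family
#'
#' The central fitting function: runs the two-point scan over all marker
#' pairs, assigns markers to linkage groups at the grouping LOD, orders each
#' group by SARF seriation, and converts adjacent recombination fractions to
#' cumulative Kosambi centiMorgan positions.
#'
#' @param gm a [genotype_matrix()] of informative, QC-retained markers (see
#'   [filter_markers()]).
#' @param config a [map_config()].
#' @return an object of class `linkage_map` with components `map` (group,
#'   rank, marker, position_cM), `summary` (per-group size, locus count, mean
#'   spacing, largest gap), `unassigned` (marker ids), `twopoint` (the scan
#'   table), `config` and `call`.
#' @seealso [map_summary()], [scan_grouping_lod()]
#' @export
linkage_map <- function(gm, config = map_config()) {
  stopifnot(inherits(gm, "geno_matrix"))
  tp <- twopoint_scan(gm)
  grp <- group_markers(tp, nrow(gm$geno), config)
  orders <- lapply(grp$groups, order_markers, tp = tp, gm = gm, config = config)
  map <- build_map(orders, tp, gm$markers$id)
  structure(list(map = map, summary = map_summary(map),
                 unassigned = gm$markers$id[grp$unassigned],
                 twopoint = tp, config = config, call = match.call()),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Genetic linkage map: %d groups, %d loci, %.2f cM (Kosambi)\n",
              nrow(s), sum(s$n_loci), sum(s$size_cM)))
  cat(sprintf("  mean inter-marker distance: %.2f cM; largest gap: %.2f cM\n",
              sum(s$size_cM) / (sum(s$n_loci) - nrow(s)),
              max(s$largest_gap_cM, na.rm = TRUE)))
  if (length(x$unassigned))
    cat(sprintf("  unassigned markers: %d\n", length(x$unassigned)))
  invisible(x)
}

#' @export
summary.linkage_map <- function(object, ...) object$summary

#' @export
plot.linkage_map <- function(x, ...) {
  s <- x$summary
  n <- nrow(s)
  plot(NA, xlim = c(0.5, n + 0.5), ylim = c(max(s$size_cM), 0),
       xlab = "linkage group", ylab = "position (cM)", xaxt = "n", ...)
  axis(1, at = seq_len(n), labels = sub("^LG", "", s$group))
  for (g in seq_len(n)) {
    d <- x$map[x$map$group == s$group[g], ]
    segments(g - 0.3, 0, g - 0.3, s$size_cM[g])
    segments(g - 0.38, d$position_cM, g - 0.22, d$position_cM)
  }
  invisible(x)
}

#' Rand index between two partitions
#'
#' Agreement between two clusterings of the same items: the fraction of item
#' pairs on which the partitions agree (together in both or separate in
#' both). Used to compare recovered linkage groups with the true chromosomes
#' of a simulation.
#'
#' @param a,b cluster labels of the same length.
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  ta <- table(a); tb <- table(b); tab <- table(a, b)
  ss <- sum(choose(tab, 2))
  sa <- sum(choose(ta, 2)); sb <- sum(choose(tb, 2))
  tot <- choose(n, 2)
  (tot + 2 * ss - sa - sb) / tot
}
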