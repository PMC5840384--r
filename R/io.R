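# File formats: genotype TSV dialect, 12-column tabular hits, map TSV,
# summary CSV, Circos karyotype/links, PhenoGram and Oxford-grid tables.
# cM values are serialized with 6 decimals, bp as integers; row order is
# deterministic so diffs are meaningful.

#' Write a genotype matrix to the package's TSV dialect
#'
#' Header `marker_id`, `P1`, `P2`, then offspring ids; genotype cells are
#' `"x/y"` with alleles a-d, `"-"` for missing. Original allele symbols are
#' restored, so write then read is the identity.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_m <- nrow(gm$geno)
  cells <- matrix("-", n_m, ncol(gm$geno))
  for (m in seq_len(n_m)) {
    syms <- rep(NA_character_, 4)
    ok <- !is.na(gm$allele_map[m, ])
    syms[ok] <- ALLELES[gm$allele_map[m, ok]]
    cells[m, ] <- .format_geno(gm$geno[m, ], symbols = syms)
  }
  out <- data.frame(marker_id = gm$markers$id, P1 = gm$markers$p1,
                    P2 = gm$markers$p2, cells, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out)[-(1:3)] <- gm$offspring
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype TSV written by [write_genotypes()]
#'
#' @param path input file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  d <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(d) < 4 || !identical(names(d)[1:3], c("marker_id", "P1", "P2")))
    stop("not a genotype TSV: expected columns marker_id, P1, P2, offspring...")
  if (any(d$P1 == "-" | d$P2 == "-"))
    stop("parental genotypes must not be missing")
  genotype_matrix(data.frame(id = d$marker_id, p1 = d$P1, p2 = d$P2,
                             stringsAsFactors = FALSE),
                  as.matrix(d[, -(1:3), drop = FALSE]))
}

#' Write/read 12-column tabular hit files
#'
#' The standard tab-separated homology-hit format (no header): query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score.
#'
#' @param hits data.frame with the 12 standard columns.
#' @param path file path.
#' @export
write_hits <- function(hits, path) {
  .check_hits(hits)
  write.table(hits[, .hit_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12) stop("hit file must have exactly 12 columns")
  names(d) <- .hit_cols
  .check_hits(d)
}

#' Write/read a genetic map TSV (group, rank, marker, position_cM)
#'
#' @param map data.frame as produced by [build_map()].
#' @param path file path.
#' @export
write_map <- function(map, path) {
  out <- map[order(map$group, map$rank), ]
  out$position_cM <- sprintf("%.6f", out$position_cM)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$position_cM <- as.numeric(d$position_cM)
  d
}

#' Write the per-group map summary as CSV
#'
#' @param summary data.frame from [map_summary()].
#' @param path file path.
#' @export
write_map_summary <- function(summary, path) {
  write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write Circos karyotype and link files for collinear blocks
#'
#' Linkage groups are drawn in integer units of cM x 1e4; chromosomes in bp.
#' Karyotype lines follow `chr - id label start end color`; each block emits
#' one link line pairing its cM interval (scaled) with its bp interval.
#'
#' @param blocks blocks data.frame from [detect_blocks()] /
#'   [species_blocks()].
#' @param map data.frame with `group`, `position_cM` (for LG lengths).
#' @param chrom_lengths data.frame with `chrom`, `length_bp`.
#' @param karyotype_path,links_path output files.
#' @export
write_circos <- function(blocks, map, chrom_lengths, karyotype_path,
                         links_path) {
  if (any(blocks$cM_lo < 0) || any(blocks$bp_lo < 0))
    stop("negative coordinates")
  lg_len <- tapply(map$position_cM, map$group, max)
  kar <- c(
    sprintf("chr - %s %s 0 %d grey", names(lg_len), names(lg_len),
            as.integer(round(lg_len * 1e4))),
    sprintf("chr - %s %s 0 %d blue", chrom_lengths$chrom,
            chrom_lengths$chrom, as.integer(round(chrom_lengths$length_bp))))
  writeLines(kar, karyotype_path)
  links <- sprintf("%s %d %d %s %d %d", blocks$lg,
                   as.integer(round(blocks$cM_lo * 1e4)),
                   as.integer(round(blocks$cM_hi * 1e4)),
                   blocks$chrom, as.integer(round(blocks$bp_lo)),
                   as.integer(round(blocks$bp_hi)))
  writeLines(links, links_path)
  invisible(links_path)
}

#' Read a Circos links file back into interval pairs
#'
#' @param path links file written by [write_circos()].
#' @return data.frame with `lg`, `cM_lo`, `cM_hi`, `chrom`, `bp_lo`, `bp_hi`
#'   (cM rescaled back from integer units).
#' @export
read_circos_links <- function(path) {
  ln <- readLines(path)
  if (!length(ln))
    return(data.frame(lg = character(), cM_lo = numeric(), cM_hi = numeric(),
                      chrom = character(), bp_lo = numeric(),
                      bp_hi = numeric(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(ln, " ", fixed = TRUE))
  data.frame(lg = f[, 1], cM_lo = as.numeric(f[, 2]) / 1e4,
             cM_hi = as.numeric(f[, 3]) / 1e4, chrom = f[, 4],
             bp_lo = as.numeric(f[, 5]), bp_hi = as.numeric(f[, 6]),
             stringsAsFactors = FALSE)
}

#' Write a PhenoGram-style annotation table for placements
#'
#' One line per placed transcript: chromosome = linkage group, position =
#' interval midpoint in cM, annotation = transcript id.
#'
#' @param placements placement data.frame.
#' @param path output file.
#' @export
write_phenogram <- function(placements, path) {
  p <- placements[placements$status %in% c("placed", "edge"), , drop = FALSE]
  out <- data.frame(CHR = p$lg,
                    POS = sprintf("%.6f", (p$lo_cM + p$hi_cM) / 2),
                    PHENOTYPE = p$transcript, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the Oxford-grid table
#'
#' @param grid data.frame from [oxford_grid_data()].
#' @param path output file.
#' @export
write_oxford <- function(grid, path) {
  grid$cM <- sprintf("%.6f", grid$cM)
  grid$bp <- as.integer(round(grid$bp))
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the marker QC report
#'
#' @param report data.frame from [filter_markers()].
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the simulate -> QC -> map -> synteny -> collinearity -> placement
#' chain on synthetic data
#'
#' Chains every stage on a simulated family, writing each stage's files into
#' `out_dir` and logging input / retained / dropped counts. Intended both as
#' the end-to-end entry point and as executable documentation of how the
#' pieces fit together.
#'
#' @param out_dir output directory (created if needed).
#' @param n_chromosomes,markers_per_chromosome,mean_length_cM true-map size.
#' @param cross a [cross_spec()].
#' @param config a [map_config()].
#' @param species named list of [rearrangement_spec()]s (one reference
#'   genome each).
#' @param n_transcripts unplaced transcripts to simulate and place.
#' @param seed master seed; stage seeds are derived from it.
#' @param quiet suppress progress messages.
#' @return invisible list with the main stage results.
#' @export
run_pipeline <- function(out_dir, n_chromosomes = 3,
                         markers_per_chromosome = 40, mean_length_cM = 100,
                         cross = cross_spec(), config = map_config(),
                         species = list(spA = rearrangement_spec()),
                         n_transcripts = 50, seed = 1L, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  tm <- simulate_true_map(n_chromosomes, markers_per_chromosome,
                          mean_length_cM, seed = seed)
  cross$seed <- seed + 1L
  gm <- simulate_family(tm, cross)
  write_genotypes(gm, file.path(out_dir, "genotypes.tsv"))
  say("simulate: %d markers x %d offspring", nrow(gm$geno), ncol(gm$geno))
  qc <- filter_markers(gm)
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  drop <- table(factor(qc$report$reason,
                       c("retained", "presence", "distortion", "uninformative")))
  say("qc: input %d / retained %d / presence %d / distortion %d / uninformative %d",
      nrow(qc$report), drop[1], drop[2], drop[3], drop[4])
  fit <- linkage_map(qc$retained, config)
  write_map(fit$map, file.path(out_dir, "map.tsv"))
  write_map_summary(fit$summary, file.path(out_dir, "map_summary.csv"))
  say("map: %d groups, %d loci, %.1f cM, %d unassigned",
      nrow(fit$summary), sum(fit$summary$n_loci), sum(fit$summary$size_cM),
      length(fit$unassigned))
  genomes <- list(); assignments <- list(); chrlens <- list()
  for (k in seq_along(species)) {
    sp <- names(species)[k]
    gen <- derive_reference_genome(tm, species[[k]], species_id = sp,
                                   seed = seed + 10L + k)
    genomes[[sp]] <- gen
    write_hits(gen$hits, file.path(out_dir, paste0("hits_", sp, ".tsv")))
    fh <- filter_hits(gen$hits, e_max = 1e-9)
    asg <- hit_assignments(fh)
    asg$species <- sp
    assignments[[sp]] <- asg
    cl <- gen$chrom_lengths; cl$species <- sp
    chrlens[[sp]] <- cl
    say("hits %s: %d raw / %d assigned", sp, nrow(gen$hits), nrow(asg))
  }
  assignments <- do.call(rbind, assignments)
  chrlens <- do.call(rbind, chrlens)
  syn <- build_synteny_table(fit$map, assignments)
  write.csv(syn$assigned, file.path(out_dir, "synteny.csv"), row.names = FALSE)
  write.csv(syn$lg_totals, file.path(out_dir, "lg_homolog_counts.csv"),
            row.names = FALSE)
  grid <- oxford_grid_data(fit$map, assignments)
  write_oxford(grid, file.path(out_dir, "oxford_grid.tsv"))
  asets <- anchor_sets_from_map(fit$map, assignments, chrlens)
  blocks_by_species <- list()
  for (sp in names(species)) {
    bl <- species_blocks(asets[vapply(asets, function(a) a$species == sp, TRUE)])
    blocks_by_species[[sp]] <- bl
    say("collinear %s: %d blocks", sp, nrow(bl))
  }
  all_blocks <- do.call(rbind, lapply(blocks_by_species, function(b)
    b[, , drop = FALSE]))
  write.csv(all_blocks, file.path(out_dir, "blocks.csv"), row.names = FALSE)
  write_circos(all_blocks, fit$map, chrlens,
               file.path(out_dir, "circos_karyotype.txt"),
               file.path(out_dir, "circos_links.txt"))
  tx <- simulate_unplaced_transcripts(tm, genomes, n_transcripts,
                                      seed = seed + 50L)
  placements <- collinearity_place(tx$hits, blocks_by_species)
  write.table(placements, file.path(out_dir, "placements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_phenogram(placements, file.path(out_dir, "phenogram.tsv"))
  say("placement: %d transcripts, %d placed",
      nrow(placements), sum(placements$status == "placed"))
  invisible(list(true_map = tm, genotypes = gm, qc = qc, fit = fit,
                 synteny = syn, blocks = blocks_by_species,
                 transcripts = tx, placements = placements))
}
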