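# Internal genotype coding
#
# Alleles are the four symbols a,b,c,d (1..4 internally). An unordered
# genotype {i,j} with i <= j is stored as the integer (i-1)*4 + j, so codes
# run 1..16 with 10 valid values; missing calls are NA. Each marker is
# relabelled to a canonical allele frame in which parent 1 is a/b and parent 2
# is a/b, a/c or c/d depending on cross type; the original symbols are kept so
# files round-trip exactly.

ALLELES <- c("a", "b", "c", "d")

.pair_code <- function(i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1L) * 4L + hi
}

.code_alleles <- function(code) {
  c((code - 1L) %/% 4L + 1L, (code - 1L) %% 4L + 1L)
}

#' Parse a genotype string
#'
#' @param x character vector of genotypes `"x/y"` with alleles in a,b,c,d, or
#'   `"-"` for missing.
#' @return integer codes (NA for missing).
#' @keywords internal
.parse_geno <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & x != "-" & x != ""
  if (any(ok)) {
    parts <- strsplit(x[ok], "/", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop("malformed genotype string: ", x[ok][bad][1])
    a1 <- match(vapply(parts, `[`, "", 1L), ALLELES)
    a2 <- match(vapply(parts, `[`, "", 2L), ALLELES)
    if (anyNA(a1) || anyNA(a2)) stop("allele symbols must be one of a,b,c,d")
    out[ok] <- .pair_code(a1, a2)
  }
  out
}

.format_geno <- function(code, symbols = ALLELES) {
  out <- rep("-", length(code))
  ok <- !is.na(code)
  if (any(ok)) {
    al <- vapply(code[ok], .code_alleles, integer(2))
    out[ok] <- paste(symbols[al[1L, ]], symbols[al[2L, ]], sep = "/")
  }
  out
}

#' Classify the cross type of a marker from its parental genotypes
#'
#' In a full-sib outcross family a marker is informative only when both
#' parents are heterozygous. Depending on how many alleles the parents share,
#' the marker segregates as ab x ab (1:2:1), ab x ac (1:1:1:1) or
#' ab x cd (1:1:1:1); any marker with a homozygous parent is uninformative.
#'
#' @param p1,p2 parental genotype strings, e.g. `"a/b"`.
#' @return one of `"AB_x_AB"`, `"AB_x_AC"`, `"AB_x_CD"`, `"UNINFORMATIVE"`.
#' @examples
#' classify_cross_type("a/b", "a/b")  # AB_x_AB
#' classify_cross_type("a/b", "c/d")  # AB_x_CD
#' classify_cross_type("a/a", "a/b")  # UNINFORMATIVE
#' @export
classify_cross_type <- function(p1, p2) {
  stopifnot(length(p1) == length(p2))
  c1 <- .parse_geno(p1); c2 <- .parse_geno(p2)
  if (anyNA(c1) || anyNA(c2)) stop("parental genotypes must not be missing")
  out <- character(length(c1))
  for (k in seq_along(c1)) {
    s1 <- .code_alleles(c1[k]); s2 <- .code_alleles(c2[k])
    if (s1[1] == s1[2] || s2[1] == s2[2]) { out[k] <- "UNINFORMATIVE"; next }
    shared <- length(intersect(s1, s2))
    out[k] <- switch(as.character(shared),
                     "2" = "AB_x_AB", "1" = "AB_x_AC", "0" = "AB_x_CD")
  }
  out
}

# canonical relabelling: returns list(map = int[4] original allele for
# canonical slot (NA if unused), p1, p2 canonical codes)
.canonical_map <- function(s1, s2, cross_type) {
  map <- rep(NA_integer_, 4L)
  if (cross_type == "AB_x_AB") {
    map[1:2] <- sort(s1)
  } else if (cross_type == "AB_x_AC") {
    sh <- intersect(s1, s2)
    map[1] <- sh
    map[2] <- setdiff(s1, sh)
    map[3] <- setdiff(s2, sh)
  } else if (cross_type == "AB_x_CD") {
    map[1:2] <- sort(s1); map[3:4] <- sort(s2)
  } else {
    map[seq_along(unique(c(s1, s2)))] <- sort(unique(c(s1, s2)))
  }
  map
}

#' Construct a genotype matrix for a full-sib outcross family
#'
#' @param markers data.frame with columns `id`, `p1`, `p2` (parental genotype
#'   strings).
#' @param geno character matrix (markers x offspring) of genotype strings,
#'   `"-"` for missing; rownames ignored, row order must match `markers`.
#' @param offspring optional offspring ids (defaults to colnames of `geno`).
#' @return an object of class `geno_matrix`: marker table with cross types, a
#'   canonical integer genotype matrix, and the per-marker allele relabelling.
#' @export
genotype_matrix <- function(markers, geno, offspring = colnames(geno)) {
  stopifnot(is.data.frame(markers), all(c("id", "p1", "p2") %in% names(markers)),
            nrow(markers) == nrow(geno))
  if (anyDuplicated(markers$id)) stop("marker ids must be unique")
  if (is.null(offspring)) offspring <- paste0("off", seq_len(ncol(geno)))
  n_m <- nrow(markers); n_o <- ncol(geno)
  ct <- classify_cross_type(markers$p1, markers$p2)
  codes <- matrix(NA_integer_, n_m, n_o)
  amap <- matrix(NA_integer_, n_m, 4L)
  for (m in seq_len(n_m)) {
    s1 <- .code_alleles(.parse_geno(markers$p1[m]))
    s2 <- .code_alleles(.parse_geno(markers$p2[m]))
    map <- .canonical_map(s1, s2, ct[m])
    amap[m, ] <- map
    raw <- .parse_geno(geno[m, ])
    ok <- !is.na(raw)
    if (any(ok)) {
      inv <- rep(NA_integer_, 4L)
      inv[map[!is.na(map)]] <- which(!is.na(map))
      al <- vapply(raw[ok], .code_alleles, integer(2))
      c1 <- inv[al[1L, ]]; c2 <- inv[al[2L, ]]
      if (anyNA(c1) || anyNA(c2))
        stop("offspring allele not present in parents at marker ", markers$id[m])
      codes[m, ok] <- .pair_code(c1, c2)
    }
  }
  mk <- data.frame(id = as.character(markers$id), p1 = markers$p1,
                   p2 = markers$p2, cross_type = ct, stringsAsFactors = FALSE)
  structure(list(markers = mk, geno = codes, offspring = as.character(offspring),
                 allele_map = amap),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  tab <- table(factor(x$markers$cross_type,
                      levels = c("AB_x_AB", "AB_x_AC", "AB_x_CD", "UNINFORMATIVE")))
  cat("Full-sib outcross genotype matrix\n")
  cat(sprintf("  %d markers x %d offspring\n", nrow(x$geno), ncol(x$geno)))
  cat(sprintf("  cross types: ab x ab %d, ab x ac %d, ab x cd %d, uninformative %d\n",
              tab[1], tab[2], tab[3], tab[4]))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

# subset markers, keeping truth-free bookkeeping consistent
.subset_geno <- function(gm, keep) {
  structure(list(markers = gm$markers[keep, , drop = FALSE],
                 geno = gm$geno[keep, , drop = FALSE],
                 offspring = gm$offspring,
                 allele_map = gm$allele_map[keep, , drop = FALSE]),
            class = "geno_matrix")
}

# offspring genotype classes (canonical codes) and Mendelian expectation per
# cross type. AB_x_AB pools the two heterozygote phase origins into one a/b
# class (they are indistinguishable), hence 1:2:1.
.cross_classes <- function(cross_type) {
  switch(cross_type,
    AB_x_AB = list(codes = c(.pair_code(1L, 1L), .pair_code(1L, 2L), .pair_code(2L, 2L)),
                   labels = c("a/a", "a/b", "b/b"), expected = c(1, 2, 1) / 4),
    AB_x_AC = list(codes = c(.pair_code(1L, 1L), .pair_code(1L, 3L),
                             .pair_code(1L, 2L), .pair_code(2L, 3L)),
                   labels = c("a/a", "a/c", "a/b", "b/c"), expected = rep(1, 4) / 4),
    AB_x_CD = list(codes = c(.pair_code(1L, 3L), .pair_code(1L, 4L),
                             .pair_code(2L, 3L), .pair_code(2L, 4L)),
                   labels = c("a/c", "a/d", "b/c", "b/d"), expected = rep(1, 4) / 4),
    stop("no genotype classes for cross type ", cross_type))
}
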