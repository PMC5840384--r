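#' Chi-square test for Mendelian segregation at one marker
#'
#' Tests observed offspring genotype-class counts against the Mendelian
#' expectation for the marker's cross type: 1:2:1 over aa/ab/bb for ab x ab
#' (df = 2) and 1:1:1:1 over the four classes for ab x ac and ab x cd
#' (df = 3). Missing individuals are excluded before counting.
#'
#' @param counts integer vector of observed genotype-class counts, in the
#'   class order of the cross type (ab x ab: aa, ab, bb).
#' @param cross_type one of `"AB_x_AB"`, `"AB_x_AC"`, `"AB_x_CD"`.
#' @return list with `statistic`, `df`, `p.value`.
#' @examples
#' segregation_chisq(c(30, 20, 30, 20), "AB_x_CD")  # statistic 4, df 3
#' @export
segregation_chisq <- function(counts, cross_type) {
  cls <- .cross_classes(cross_type)
  if (length(counts) != length(cls$expected))
    stop("expected ", length(cls$expected), " genotype classes for ", cross_type)
  n <- sum(counts)
  if (n == 0) stop("zero total count")
  exp <- cls$expected * n
  stat <- sum((counts - exp)^2 / exp)
  df <- length(counts) - 1L
  list(statistic = stat, df = df, p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Filter markers on informativeness, presence and Mendelian segregation
#'
#' Applies the standard retention rules for outcross RAD markers: a marker is
#' kept when (1) it was scored in at least `presence_threshold` of the
#' offspring, (2) its genotype ratios do not depart from Mendelian expectation
#' (chi-square p >= `alpha`), and (3) both parents are heterozygous
#' (informative cross type). Rules are tested in that order and each dropped
#' marker is attributed to the first rule it fails, so the reported reasons
#' partition the input.
#'
#' @param gm a [genotype_matrix()].
#' @param presence_threshold minimum fraction of offspring with a non-missing
#'   call (default 0.80).
#' @param alpha significance level for the segregation chi-square test;
#'   markers with p < alpha are discarded as distorted (default 0.05).
#' @return list with `retained` (a `geno_matrix` of surviving markers) and
#'   `report`, a data.frame with one row per input marker: presence fraction,
#'   cross type, chi-square statistic, df, p-value, retained flag and reason.
#' @export
filter_markers <- function(gm, presence_threshold = 0.80, alpha = 0.05) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nrow(gm$geno) == 0) stop("no markers")
  stopifnot(presence_threshold > 0, presence_threshold <= 1,
            alpha > 0, alpha <= 1)
  n_off <- ncol(gm$geno)
  presence <- rowMeans(!is.na(gm$geno))
  ct <- gm$markers$cross_type
  n_m <- nrow(gm$geno)
  chi2 <- df <- pval <- rep(NA_real_, n_m)
  reason <- rep("retained", n_m)
  for (m in seq_len(n_m)) {
    if (presence[m] < presence_threshold) { reason[m] <- "presence"; next }
    if (ct[m] != "UNINFORMATIVE") {
      cls <- .cross_classes(ct[m])
      obs <- gm$geno[m, ]
      counts <- vapply(cls$codes, function(cd) sum(obs == cd, na.rm = TRUE), 0L)
      ans <- segregation_chisq(counts, ct[m])
      chi2[m] <- ans$statistic; df[m] <- ans$df; pval[m] <- ans$p.value
      if (ans$p.value < alpha) { reason[m] <- "distortion"; next }
    }
    if (ct[m] == "UNINFORMATIVE") reason[m] <- "uninformative"
  }
  retained <- reason == "retained"
  report <- data.frame(marker = gm$markers$id, cross_type = ct,
                       presence = presence, chi2 = chi2, df = df, p = pval,
                       retained = retained, reason = reason,
                       stringsAsFactors = FALSE)
  list(retained = .subset_geno(gm, retained), report = report)
}
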