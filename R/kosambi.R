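#' Kosambi map function
#'
#' Converts a recombination fraction r into map distance
#' d = 25 ln((1 + 2r) / (1 - 2r)) centiMorgan. Fractions at or above 0.4999
#' are capped there with a warning (the transform diverges at r = 0.5).
#'
#' @param rf recombination fraction(s) in \[0, 0.5).
#' @return distance in cM.
#' @examples
#' kosambi_cM(0.25)  # 25 * log(3) ~ 27.465
#' @export
kosambi_cM <- function(rf) {
  if (any(rf < 0, na.rm = TRUE)) stop("recombination fraction must be >= 0")
  if (any(rf >= 0.5, na.rm = TRUE)) stop("recombination fraction must be < 0.5")
  if (any(rf >= 0.4999, na.rm = TRUE)) {
    warning("recombination fraction >= 0.4999 capped")
    rf <- pmin(rf, 0.4999)
  }
  25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' Inverse Kosambi map function
#'
#' Converts a map distance in cM back to a recombination fraction,
#' r = tanh(d / 50) / 2.
#'
#' @param d distance(s) in cM, >= 0.
#' @return recombination fraction in \[0, 0.5).
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be >= 0")
  0.5 * tanh(d / 50)
}
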