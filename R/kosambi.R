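#' Kosambi map function and its inverse
#'
#' `kosambi_cm()` converts a recombination fraction to an additive map
#' distance, `d = 25 * log((1 + 2r) / (1 - 2r))` centimorgans; `kosambi_r()`
#' inverts it, `r = tanh(d / 50) / 2`. The Kosambi function allows for
#' partial crossover interference and is the transform used for all map
#' distances in the package.
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @param d Map distance(s) in centimorgans, `>= 0`.
#' @return Map distance in cM, or recombination fraction, respectively.
#' @export
#' @examples
#' kosambi_cm(0.1)            # 10.14 cM
#' kosambi_r(kosambi_cm(0.2)) # 0.2
kosambi_cm <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @export
kosambi_r <- function(d) {
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}
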