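# Mismatch-distribution smoothness.

#' Raggedness index of a mismatch distribution
#'
#' rg = sum of squared differences between the relative frequencies of
#' successive pairwise-difference classes.  The distribution over classes
#' 0..d is padded with a single zero class after the last observed class,
#' so rg = sum_{i=1}^{d+1} (x_i - x_{i-1})^2 with x_{d+1} = 0; no leading
#' boundary term is added before class 0.  Smooth unimodal ("expansion")
#' distributions give small rg, multimodal equilibrium distributions give
#' large rg.
#'
#' @param x a [mismatch_dist()] object, or a numeric vector of class
#'   frequencies/counts over 0..d (counts are normalized).
#' @return rg >= 0.
#' @examples
#' raggedness(rep(0.2, 5))    # 0.04: only the trailing boundary term
#' raggedness(c(0.5, 0.5))    # 0.25
#' @export
raggedness <- function(x) {
  if (!inherits(x, "mismatch_dist")) x <- mismatch_dist(x)
  sum(diff(c(x$probs, 0))^2)
}
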