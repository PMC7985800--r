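#' Shannon entropy of event counts
#'
#' Computes \eqn{H(X) = -\sum_X P(X) \log_2 P(X)} over discrete events, where
#' \eqn{P(X)} is the relative frequency of event \eqn{X} among the supplied
#' counts (or weights).  Used throughout the feature battery for caller
#' diversity and app-category diversity.
#'
#' Events with zero count contribute nothing (the \eqn{p \log p} limit).
#' With no positive mass the entropy has no basis and the function returns
#' `NaN` with a warning rather than fabricating a zero.
#'
#' @param counts numeric vector of nonnegative counts or weights, optionally
#'   named by event.
#' @return entropy in bits (numeric scalar); `NaN` if all counts are zero.
#' @examples
#' shannon_entropy(c(a = 1, b = 1, c = 1, d = 1))  # 2 bits
#' shannon_entropy(c(a = 4))                       # 0 bits
#' @export
shannon_entropy <- function(counts) {
  if (length(counts) == 0 || all(counts == 0)) {
    warning("entropy of an all-zero count vector is undefined; returning NaN")
    return(NaN)
  }
  stopifnot(all(counts >= 0))
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}
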