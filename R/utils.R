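stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count_scalar <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Shannon entropy of a count or probability vector, in bits
#'
#' Plug-in (empirical-frequency) entropy with the convention
#' \eqn{0 \log 0 = 0}.  Counts are normalized to probabilities first.
#'
#' @param x Nonnegative numeric vector of counts (or probabilities).
#' @return Entropy in bits (log base 2).
#' @examples
#' shannon_entropy(c(1, 1, 1))  # log2(3)
#' shannon_entropy(c(5, 0, 0))  # 0
#' @export
shannon_entropy <- function(x) {
  if (!is.numeric(x) || any(x < 0) || !all(is.finite(x)))
    stopf("entropy requires finite nonnegative counts")
  n <- sum(x)
  if (n == 0) return(0)
  p <- x[x > 0] / n
  -sum(p * log2(p))
}
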