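# Information-theoretic kernel: Shannon entropy, conditional entropy, and
# symmetrical uncertainty over discrete (binned) variables. Empirical
# plug-in probabilities, no smoothing; all entropies in bits (log base 2).

#' Shannon entropy of a discrete vector, in bits
#'
#' Plug-in estimate \eqn{H(X) = -\sum_x p(x)\log_2 p(x)} with empirical
#' frequencies. A constant vector has entropy 0.
#'
#' @param x A non-empty vector of discrete codes (any atomic type).
#' @return Entropy in bits, a single non-negative number.
#' @examples
#' entropy_bits(c(0, 0, 1, 1)) # 1 bit
#' @export
entropy_bits <- function(x) {
  if (length(x) == 0) stop("entropy_bits(): `x` must be non-empty", call. = FALSE)
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log2(p))
}

#' Conditional entropy H(X | Y), in bits
#'
#' \eqn{H(X|Y) = \sum_y p(y) H(X | Y = y)} from the empirical joint
#' distribution. Satisfies \eqn{0 \le H(X|Y) \le H(X)}.
#'
#' @param x,y Equal-length non-empty discrete vectors.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(x, y) {
  if (length(x) == 0) stop("conditional_entropy(): empty input", call. = FALSE)
  if (length(x) != length(y)) {
    stop("conditional_entropy(): `x` and `y` must have equal length", call. = FALSE)
  }
  n <- length(x)
  tab <- table(x, y)
  out <- 0
  for (j in seq_len(ncol(tab))) {
    cnt <- tab[, j]
    ny <- sum(cnt)
    if (ny == 0) next
    p <- cnt[cnt > 0] / ny
    out <- out + (ny / n) * (-sum(p * log2(p)))
  }
  out
}

#' Symmetrical uncertainty between two discrete vectors
#'
#' The normalized mutual information
#' \deqn{SU(X, Y) = \frac{2\,[H(X) - H(X|Y)]}{H(X) + H(Y)}}
#' used by the fast correlation-based filter as both the relevance measure
#' (gene vs. class) and the redundancy measure (gene vs. gene). Lies in
#' \[0, 1\], is symmetric in its arguments, and is invariant to relabeling
#' of category codes. When either vector is constant the score is 0 by
#' convention (a constant variable carries no information).
#'
#' @param x,y Equal-length non-empty discrete vectors.
#' @return A single number in \[0, 1\].
#' @examples
#' symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 0, 1, 1)) # 1
#' symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 1, 0, 1)) # 0
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) {
    stop("symmetrical_uncertainty(): `x` and `y` must have equal length",
         call. = FALSE)
  }
  hx <- entropy_bits(x)
  hy <- entropy_bits(y)
  if (hx + hy == 0) return(0)
  su <- 2 * (hx - conditional_entropy(x, y)) / (hx + hy)
  min(max(su, 0), 1)
}
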