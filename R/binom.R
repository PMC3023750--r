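#' Log10 binomial upper-tail probability
#'
#' The scoring kernel of partial phylogenetic profiling. Given `y` observed
#' trait-positive genomes among `n` distinct genomes drawn under a null
#' prevalence `p`, the score is `log10 P(X >= y)` for `X ~ Binomial(n, p)`:
#' the (log10) probability of seeing at least this many trait-positive
#' genomes by chance. More negative is more surprising.
#'
#' The tail is computed entirely in log space: binomial coefficients via
#' [lchoose()] (log-gamma) and the sum over tail terms via log-sum-exp, so
#' scores far below the smallest double-precision probability (e.g. -95)
#' are exact to working precision. Two identities hold exactly:
#' `y = 0` gives 0 (the empty event has probability 1), and `y = n` gives
#' `n * log10(p)` (the single perfect-prefix term).
#'
#' @param y integer vector, trait-positive count(s), `0 <= y <= n`.
#' @param n integer vector, total count(s); recycled against `y`.
#' @param p scalar prevalence, strictly in (0, 1).
#' @return numeric vector of log10 upper-tail probabilities, all `<= 0`.
#' @examples
#' log10_binom_tail(1, 2, 0.5)   # log10(3/4)
#' log10_binom_tail(53, 53, 10^(-94.521 / 97))
#' @export
log10_binom_tail <- function(y, n, p) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("prevalence `p` must be a single value strictly inside (0, 1)")
  m <- max(length(y), length(n))
  y <- rep_len(as.numeric(y), m)
  n <- rep_len(as.numeric(n), m)
  if (any(y != floor(y) | n != floor(n)))
    stop("`y` and `n` must be integer counts")
  if (any(y < 0 | y > n))
    stop("require 0 <= y <= n")
  vapply(seq_len(m), function(i) .log10_tail1(y[i], n[i], p), numeric(1))
}

.log10_tail1 <- function(y, n, p) {
  if (y == 0) return(0)
  if (y == n) return(n * log10(p))
  k <- y:n
  lt <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  mx <- max(lt)
  (mx + log(sum(exp(lt - mx)))) / log(10)
}

#' Log10 binomial point probability
#'
#' `log10 P(X = y)` for `X ~ Binomial(n, p)`, computed with log-gamma
#' coefficients. Companion to [log10_binom_tail()]; mainly useful for
#' checking that point masses normalize.
#'
#' @inheritParams log10_binom_tail
#' @return numeric vector of log10 point probabilities.
#' @export
log10_binom_point <- function(y, n, p) {
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("prevalence `p` must be a single value strictly inside (0, 1)")
  m <- max(length(y), length(n))
  y <- rep_len(as.numeric(y), m)
  n <- rep_len(as.numeric(n), m)
  if (any(y < 0 | y > n)) stop("require 0 <= y <= n")
  (lchoose(n, y) + y * log(p) + (n - y) * log1p(-p)) / log(10)
}
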