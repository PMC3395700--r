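# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementation.

# Exhaustive Poisson-Binomial tails by enumerating all 2^n outcomes.
# Returns P(S >= k) for k = 0..n (element k+1).
.bits_cache <- new.env(parent = emptyenv())
pb_enum_tails <- function(p) {
  n <- length(p)
  key <- as.character(n)
  if (is.null(.bits_cache[[key]])) {
    m <- 2L^n
    .bits_cache[[key]] <- matrix(as.integer(intToBits(0:(m - 1L))),
                                 nrow = m, byrow = TRUE)[, seq_len(n),
                                                         drop = FALSE]
  }
  bits <- .bits_cache[[key]]
  pr <- exp(bits %*% log(p) + (1 - bits) %*% log(1 - p))
  cnt <- rowSums(bits)
  tot <- vapply(0:n, function(j) sum(pr[cnt == j]), 0)
  rev(cumsum(rev(tot)))
}

# Textbook Benjamini-Hochberg step-up: sort ascending, q_(i) =
# min_{j >= i} p_(j) * m / j, capped at 1, mapped back to input order.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
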