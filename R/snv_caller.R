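# Site scoring with the exact Poisson-Binomial tail.
#
# The null model for a site covered by n reads is S = sum of n independent
# Bernoulli trials, one per overlapping read, whose success probability is
# the experiment-wide mismatch rate at the sequencing cycle at which that
# read crosses the site. Mismatches landing on high-error cycles therefore
# carry less evidence than mismatches on clean cycles.

#' Exact Poisson-Binomial upper tail
#'
#' `P(S >= k)` for `S = sum_i Bernoulli(p_i)`, computed by the exact
#' dynamic-programming convolution of the per-trial distributions (the
#' direct equivalent of the classical weight recursion over
#' `w_i = p_i / (1 - p_i)`). The full probability mass function is built
#' with extended-precision (long double) accumulation and the tail is
#' summed directly, so small tails do not suffer 1-minus cancellation.
#'
#' @param k Number of successes (non-negative integer, `k <= length(p)`).
#' @param p Vector of per-trial success probabilities, each in `[0, 1)`.
#' @return `P(S >= k)`, a probability.
#' @examples
#' poisson_binomial_tail(2, c(0.1, 0.2, 0.3))  # 0.098
#' poisson_binomial_tail(5, rep(0.5, 5))       # 0.5^5
#' @export
poisson_binomial_tail <- function(k, p) {
  if (!is.numeric(p) || length(p) < 1L) stop("p must be a non-empty numeric vector")
  if (any(p == 1)) stop("per-trial probability of 1: weights p/(1-p) undefined")
  if (any(p < 0) || any(p > 1)) stop("per-trial probabilities must lie in [0, 1)")
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 0L) stop("k must be a single non-negative integer")
  n <- length(p)
  if (k > n) stop("k exceeds the number of trials (", k, " > ", n, ")")
  .pb_tail_cpp(k, as.numeric(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values (monotone, capped at 1), delegated to
#' [stats::p.adjust()]. Ties share the maximal rank, and the output is
#' invariant to input order and idempotent.
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Score pileup sites with the Poisson-Binomial test
#'
#' For every site with depth `n >= min_depth` and at least one mismatching
#' read, the per-trial probability vector is assembled from the error
#' profile, indexed by the sequencing cycle of *every* overlapping read
#' (matches and mismatches alike), and the site's p-value is
#' `P(S >= k)`. `k` counts all non-reference reads; the reported allele is
#' the modal alternate base. Adjusted values are computed across all scored
#' sites of the run (one pooled family).
#'
#' @param pileup An `shm_pileup` from [pileup_sites()].
#' @param profile An `shm_error_profile` built from the same experiment.
#' @param min_depth Minimum depth for a site to be scored (default 4).
#' @param fdr False-discovery-rate threshold on the adjusted values used to
#'   set the `called` flag (default 0.01).
#' @return A call table: `chrom, pos, ref, alt, n, k, ratio, pvalue, qvalue,
#'   mean_ref_qual, mean_alt_qual, called` plus flag columns initialised to
#'   `NA` (`novel`, `promoter`, ...) that [annotate_calls()] fills in.
#' @export
score_sites <- function(pileup, profile, min_depth = 4L, fdr = 0.01) {
  stopifnot(inherits(pileup, "shm_pileup"), inherits(profile, "shm_error_profile"))
  cand <- pileup$sites[n >= min_depth & k >= 1L]
  empty <- data.table(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), n = integer(0), k = integer(0), ratio = numeric(0),
    pvalue = numeric(0), qvalue = numeric(0), mean_ref_qual = numeric(0),
    mean_alt_qual = numeric(0), quality_ttest_p = numeric(0),
    called = logical(0), novel = logical(0), promoter = logical(0),
    high_confidence = logical(0), gene = character(0),
    shm_context_rgyw = logical(0), shm_context_wa = logical(0))
  if (nrow(cand) == 0L) return(empty)
  det <- pileup$detail
  if (any(det$cycle >= profile$read_length))
    stop("read position ", max(det$cycle),
         " exceeds the error-profile length ", profile$read_length)
  setkey(det, chrom, pos)
  pv <- profile$p
  cyc <- det[cand[, .(chrom, pos)], on = c("chrom", "pos")]  # rows in cand order
  sizes <- cyc[, .N, by = .(chrom, pos)]$N  # groups appear in cand order
  if (length(sizes) != nrow(cand) || any(is.na(cyc$cycle)))
    stop("pileup detail does not cover every scorable site")
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  allcyc <- cyc$cycle
  kk <- cand$k
  pvals <- vapply(seq_len(nrow(cand)), function(i) {
    .pb_tail_cpp(kk[i], pv[allcyc[starts[i]:ends[i]] + 1L])
  }, 0)
  calls <- cand[, .(chrom, pos, ref, alt, n, k, ratio = k / n,
                    pvalue = pvals, mean_ref_qual, mean_alt_qual)]
  calls[, qvalue := bh_adjust(pvalue)]
  calls[, quality_ttest_p := NA_real_]
  calls[, called := qvalue <= fdr]
  calls[, `:=`(novel = NA, promoter = NA, high_confidence = NA,
               gene = NA_character_, shm_context_rgyw = NA,
               shm_context_wa = NA)]
  setcolorder(calls, names(empty))
  calls[]
}
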