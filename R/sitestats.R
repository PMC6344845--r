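# Significance machinery for binding-site overlap: exact Poisson-binomial
# tail tests, odds ratios and Fisher's exact test on 2x2 tables, and exact
# binomial tests.

P_FLOOR <- 1e-15

#' Exact Poisson-binomial probability mass function
#'
#' PMF of the number of successes among independent Bernoulli trials with
#' success probabilities `p`, computed by iterative convolution (dynamic
#' programming over trials), exact up to floating point.
#'
#' @param p vector of success probabilities in \[0, 1\].
#' @return numeric vector of length `length(p) + 1` over counts 0..N.
#' @export
poibin_pmf <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("success probabilities must lie in [0, 1]")
  }
  pmf <- 1
  for (pi in p) {
    pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  }
  pmf
}

#' Poisson-binomial overlap test for sites of interest vs binding sites
#'
#' The N sites of interest are modeled as independent Bernoulli trials.
#' Site i's success probability is the proportion of putative binding sites
#' in its protein (binding residues / protein length). The observed overlap
#' K is compared with the Poisson-binomial distribution of the trial sum:
#' `p_ge = Pr(X >= K)` and `p_le = Pr(X <= K)`. P-values of 0 are floored at
#' 1e-15.
#'
#' @param sites data.frame with columns `protein_id` and `residue_index`
#'   (1-based).
#' @param binding_sites named list of integer vectors: per-protein binding
#'   residue indices.
#' @param proteome_lengths named integer vector of protein lengths.
#' @return object of class `overlap_test` with `K`, `expected`,
#'   `fold_change`, `p_ge`, `p_le`, `n`.
#' @export
overlap_test <- function(sites, binding_sites, proteome_lengths) {
  stopifnot(nrow(sites) >= 1)
  p <- numeric(nrow(sites))
  hit <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    prot <- sites$protein_id[i]
    len <- proteome_lengths[[prot]]
    if (is.null(len) || is.na(len)) stop("unknown protein length for '", prot, "'")
    pos <- sites$residue_index[i]
    if (pos < 1 || pos > len) {
      stop("site ", pos, " beyond length of protein '", prot, "' (", len, ")")
    }
    bs <- binding_sites[[prot]]
    if (is.null(bs)) bs <- integer(0)
    p[i] <- length(bs) / len
    hit[i] <- pos %in% bs
  }
  K <- sum(hit)
  pmf <- poibin_pmf(p)
  p_ge <- min(1, max(P_FLOOR, sum(pmf[(K + 1):length(pmf)])))
  p_le <- min(1, max(P_FLOOR, sum(pmf[1:(K + 1)])))
  expected <- sum(p)
  structure(
    list(
      K = K, expected = expected,
      fold_change = if (expected > 0) K / expected else NA_real_,
      p_ge = p_ge, p_le = p_le, n = nrow(sites)
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "<overlap_test> K = %d of %d sites, E[K] = %.2f (fold change %.2f)\n",
    x$K, x$n, x$expected, x$fold_change
  ))
  cat(sprintf("  Pr(X >= K) = %.3g, Pr(X <= K) = %.3g\n", x$p_ge, x$p_le))
  invisible(x)
}

as_table_2x2 <- function(t) {
  if (is.matrix(t)) t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  stopifnot(length(t) == 4, all(t >= 0), all(t == round(t)))
  as.numeric(t)
}

#' Odds ratio of a 2x2 contingency table
#'
#' For counts (a, b, c, d) laid out row-wise (e.g. binding
#' deleterious/tolerated over non-binding deleterious/tolerated), the odds
#' ratio `(a/b) / (c/d) = ad / bc`. No continuity correction is applied.
#'
#' @param t a 2x2 matrix (rows = groups) or a length-4 vector (a, b, c, d).
#' @return the odds ratio.
#' @export
odds_ratio <- function(t) {
  t <- as_table_2x2(t)
  if (t[2] == 0 || t[3] == 0) stop("odds ratio undefined: zero denominator cell")
  (t[1] * t[4]) / (t[2] * t[3])
}

#' Fisher's exact test on a 2x2 table by direct hypergeometric summation
#'
#' One-sided p-values are hypergeometric tail sums conditional on the table
#' margins; the two-sided p-value sums the probabilities of all tables (with
#' the same margins) no more likely than the observed one.
#'
#' @param t a 2x2 matrix or length-4 vector (a, b, c, d).
#' @param side `"greater"`, `"less"` or `"two"`; "greater" tests for larger
#'   a (more deleterious calls among binding mutations in the Table-style
#'   layout).
#' @return p-value in (0, 1\].
#' @export
fisher_exact <- function(t, side = c("greater", "less", "two")) {
  side <- match.arg(side)
  t <- as_table_2x2(t)
  a <- t[1]
  m <- t[1] + t[2]   # row 1 total
  n <- t[3] + t[4]   # row 2 total
  k <- t[1] + t[3]   # column 1 total
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  pv <- switch(side,
    greater = sum(d[support >= a]),
    less = sum(d[support <= a]),
    two = {
      dobs <- stats::dhyper(a, m, n, k)
      sum(d[d <= dobs * (1 + 1e-7)])
    }
  )
  min(1, pv)
}

#' Exact binomial test
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 null success probability.
#' @param side `"greater"`, `"less"` or `"two"`.
#' @return exact p-value.
#' @export
binomial_test <- function(k, n, p0, side = c("greater", "less", "two")) {
  side <- match.arg(side)
  if (n < 1 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("require integer 0 <= k <= n")
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  switch(side,
    greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = stats::pbinom(k, n, p0),
    two = stats::binom.test(k, n, p0)$p.value
  )
}
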