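# Independent oracles used to freeze and cross-check expected values.
# These deliberately avoid the code paths they verify: the binomial tail is
# summed termwise from the log pmf (not pbinom), the confidence bound is
# found by root search on the binomial CDF (not qbeta), and the consensus
# oracle tallies bases with table() position by position.

# Upper-tail P(X >= k | n, p) by direct pmf summation.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  hi <- min(n, k + 5000 + ceiling(10 * sqrt(n * p)))
  i <- k:hi
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Smallest k with upper-tail probability < alpha, by linear search.
kmin_oracle <- function(n, p, alpha = 0.05) {
  k <- 1
  while (binom_tail_oracle(k, n, p) >= alpha) k <- k + 1
  k
}

# One-sided upper confidence bound by root search on P(X <= x | p) = 1 - conf.
cp_upper_oracle <- function(x, n, conf = 0.95) {
  if (x >= n) return(1)
  stats::uniroot(function(p) stats::pbinom(x, n, p) - (1 - conf),
                 c(1e-12, 1 - 1e-12), tol = 1e-14)$root
}

# Brute-force per-position consensus tally: modal base among non-N bases
# must reach `agreement` (inclusive) of the non-N count, ties and empty
# positions give N. Returns NULL for families below min_size.
consensus_oracle <- function(seqs, min_size = 3, agreement = 0.90) {
  if (length(seqs) < min_size) return(NULL)
  L <- nchar(seqs[1])
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  out <- character(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (length(col) == 0) { out[j] <- "N"; next }
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) { out[j] <- "N"; next }
    out[j] <- if (tab[1] / length(col) >= agreement) names(tab)[1] else "N"
  }
  paste(out, collapse = "")
}

# Random family of aligned sequences for property tests.
random_family <- function(n_reads, len, n_rate = 0.05, mut_rate = 0.15) {
  base <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  vapply(seq_len(n_reads), function(i) {
    s <- base
    for (p in seq_len(len)) {
      r <- runif(1)
      if (r < n_rate) {
        substr(s, p, p) <- "N"
      } else if (r < n_rate + mut_rate) {
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    s
  }, character(1))
}
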