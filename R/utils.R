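# Internal helpers: seeded evaluation, seed derivation, string/base utilities.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded simulation helpers do not perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a substream seed from a master seed
#'
#' All randomness in the simulator flows from one master seed through named
#' substreams, so that e.g. the PCR stage draws do not shift when the number
#' of molecules changes. Simple multiplicative hash kept below 2^31.
#'
#' @param master Integer master seed.
#' @param stream Character stream name.
#' @param index Optional integer (e.g. replicate number).
#' @return A positive integer seed.
#' @keywords internal
derive_seed <- function(master, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (as.double(master) * 48271 + h * 7919 + as.double(index) * 104729) %%
    2147483629
  as.integer(s) + 1L
}

# Hamming distance between each string in `x` and a single string `y`.
# All strings must share one length; no checks here (callers validate).
hamming_to <- function(x, y) {
  yv <- strsplit(y, "", fixed = TRUE)[[1L]]
  m <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
              nrow = length(yv))
  colSums(m != yv)
}

# Random DNA string(s); vectorised over n strings of length len.
random_dna <- function(n, len) {
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Encode integers in [1, 4^len] as DNA strings of length len (base-4 digits).
int_to_umi <- function(i, len) {
  i <- i - 1L
  out <- matrix("", nrow = length(i), ncol = len)
  for (k in seq_len(len)) {
    out[, k] <- DNA_BASES[(i %% 4L) + 1L]
    i <- i %/% 4L
  }
  do.call(paste0, as.data.frame(out, stringsAsFactors = FALSE))
}

# Substitute a random *different* base at given positions of strings.
# `s` character vector, `idx` element index per event, `pos` position per
# event. Returns modified s.
apply_substitutions <- function(s, idx, pos) {
  if (length(idx) == 0L) return(s)
  for (e in seq_along(idx)) {
    i <- idx[e]
    p <- pos[e]
    cur <- substr(s[i], p, p)
    alt <- sample(setdiff(DNA_BASES, cur), 1L)
    substr(s[i], p, p) <- alt
  }
  s
}

#' One-sided exact binomial upper confidence bound
#'
#' Clopper-Pearson upper bound on a binomial proportion: the largest success
#' probability not rejected by a one-sided exact test at level `1 - conf`.
#' Computed via the beta quantile identity; at `x = 0` this reduces to
#' `1 - (1 - conf)^(1/n)`.
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf One-sided confidence level (default 0.95).
#' @param two_sided If `TRUE`, return the upper end of the two-sided
#'   `conf` interval (i.e. one-sided level `(1 + conf) / 2`).
#' @return Upper confidence bound in `[0, 1]`.
#' @export
#' @examples
#' binom_upper(0, 1e6)          # ~3e-6
#' binom_upper(10, 1e6)         # upper bound on 1e-5
binom_upper <- function(x, n, conf = 0.95, two_sided = FALSE) {
  stopifnot(length(x) == 1L, length(n) == 1L, x >= 0, n >= 1, x <= n)
  level <- if (two_sided) 1 - (1 - conf) / 2 else conf
  if (x >= n) return(1)
  stats::qbeta(level, x + 1, n - x)
}

# Upper-tail binomial probability P(X >= k | n, p).
binom_tail <- function(k, n, p) {
  ifelse(k <= 0, 1, stats::pbinom(k - 1, n, p, lower.tail = FALSE))
}
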