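# Independent oracles used across the suite.

# Local alignment score oracle via Biostrings (different codebase from
# the package's DP): align against the pattern repeated ceil(n/m)+2
# times, linear gap penalty.
oracle_local_score <- function(seq, pattern, match = 2, mismatch = -5,
                               gap = 7) {
  mat <- matrix(as.integer(mismatch), 4, 4,
                dimnames = list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")))
  diag(mat) <- as.integer(match)
  k <- ceiling(nchar(seq) / nchar(pattern)) + 2L
  text <- strrep(pattern, k)
  as.numeric(Biostrings::pairwiseAlignment(
    seq, text, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = gap, scoreOnly = TRUE))
}

# Brute-force recursive enumeration of every local alignment (no DP
# matrix): returns the best score of seq vs text over all start pairs
# and operation sequences. Exponential; tiny inputs only.
oracle_enum_score <- function(seq, text, match = 2, mismatch = -5,
                              gap = -7) {
  q <- strsplit(seq, "")[[1]]
  t <- strsplit(text, "")[[1]]
  n <- length(q); m <- length(t)
  ext <- function(i, j) {
    # best score of an alignment starting at (i, j), at least one column
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (q[i] == t[j]) match else mismatch
      best <- max(best, s, s + ext(i + 1, j + 1))
    }
    if (i <= n) best <- max(best, gap, gap + ext(i + 1, j))
    if (j <= m) best <- max(best, gap, gap + ext(i, j + 1))
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, ext(i, j))
  best
}

# Hypergeometric upper-tail by explicit combinatorial summation.
oracle_hyper_tail <- function(k, n_in, K, N) {
  j <- seq(k, min(K, n_in))
  if (!length(j)) return(0)
  sum(choose(K, j) * choose(N - K, n_in - j) / choose(N, n_in))
}

# Benjamini-Hochberg step-up rejections, implemented from the
# definition.
oracle_bh_reject <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) / m * alpha)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# O(n*m) brute-force interval overlap (0-based half-open).
oracle_overlap <- function(a_start, a_end, b_start, b_end) {
  vapply(seq_along(a_start), function(i)
    any(pmin(a_end[i], b_end) - pmax(a_start[i], b_start) >= 1),
    logical(1))
}
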