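# Independent brute-force oracles used to check the package's statistics
# and string operations. Deliberately written with plain loops, not with
# the code paths they verify.

# Exhaustive Mann-Whitney: smaller-U statistic and two-tailed p by full
# enumeration of all group assignments of the pooled values.
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  n <- n1 + n2
  min_u_for <- function(ii) {
    r <- rank(pooled)
    r1 <- sum(r[ii])
    u1 <- r1 - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  }
  obs <- min_u_for(seq_len(n1))
  combos <- utils::combn(n, n1)
  us <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) us[k] <- min_u_for(combos[, k])
  list(u = obs, p = sum(us <= obs + 1e-9) / length(us))
}

# Plain-loop minimum mismatch count over shifted end-to-end alignments,
# written independently of the package's matcher.
oracle_window_mismatches <- function(a, b, max_offset = 2) {
  a <- chartr("t", "u", tolower(a)); b <- chartr("t", "u", tolower(b))
  best <- Inf
  for (s in -max_offset:max_offset) {
    d <- 0; n <- 0
    for (i in seq_len(nchar(a))) {
      j <- i - s
      if (j >= 1 && j <= nchar(b)) {
        n <- n + 1
        if (substr(a, i, i) != substr(b, j, j)) d <- d + 1
      }
    }
    if (n > 0 && d < best) best <- d
  }
  best
}

# Brute-force shared-substring scan: does any exact substring of length k
# of `a` occur in `b` (forward strand only)?
oracle_shares_kmer <- function(a, b, k) {
  if (nchar(a) < k) return(FALSE)
  for (i in seq_len(nchar(a) - k + 1)) {
    if (grepl(substr(a, i, i + k - 1), b, fixed = TRUE)) return(TRUE)
  }
  FALSE
}
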