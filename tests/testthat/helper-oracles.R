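# Independent oracles and shared fixtures for the test suite.

# Brute-force N50: scan the sorted-descending cumulative sum.
n50_oracle <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(s)
  s[which(cs >= sum(s) / 2)[1]]
}

# Exact one-tailed binomial tail by direct enumeration of binomial mass.
binom_tail_oracle <- function(a, b) {
  n <- a + b
  sum(choose(n, b:n)) / 2^n
}

# Exact two-sided signed-rank p-value by full enumeration of all 2^n sign
# assignments (two-sided tails at the observed positive-rank sum).
wilcoxon_oracle <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- as.numeric(signs %*% r)
  tot <- sum(r)
  lo <- min(W_obs, tot - W_obs)
  hi <- max(W_obs, tot - W_obs)
  min(1, mean(Ws <= lo) + mean(Ws >= hi))
}

# 64-base sequence in which every triplet is distinct: a linearised
# de Bruijn sequence of order 3 over ACGT (prefer-smallest construction).
debruijn64 <- function() {
  k <- 3; alphabet <- c("A", "C", "G", "T")
  seen <- new.env()
  seq_v <- rep(alphabet[1], k)
  repeat {
    extended <- FALSE
    for (a in rev(alphabet)) {   # greedy: try largest first
      trip <- paste(c(seq_v[(length(seq_v) - k + 2):length(seq_v)], a),
                    collapse = "")
      if (is.null(seen[[trip]])) {
        seen[[trip]] <- TRUE
        seq_v <- c(seq_v, a)
        extended <- TRUE
        break
      }
    }
    if (!extended) break
  }
  paste(head(seq_v, 64), collapse = "")
}

# One shared synthetic study per test run (deterministic; lazily built).
.truth_cache <- new.env()
shared_truth <- function() {
  if (is.null(.truth_cache$tr)) .truth_cache$tr <- simulate_truth(seed = 11L)
  .truth_cache$tr
}

# Write a VCF from components and read it back through the package reader.
roundtrip_vcf <- function(fixed, gt, ps = NULL) {
  path <- tempfile(fileext = ".vcf")
  write_vcf(path, fixed, gt, ps = ps)
  read_genotypes(path)
}
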