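# Cross-assembly read-mapping comparison.
#
# Reads mapped independently against two assemblies are classified into
# mapped-in-both / A-only / B-only / neither using primary alignments only.
# The discordant counts feed an exact one-tailed sign test (the standard
# discordant-pairs construction of a "two-sample binomial test" on reads
# that map to exactly one assembly, under p = 1/2); per-sample mapped-read
# totals feed a paired Wilcoxon signed-rank test.

#' Classify reads by primary-mapping status on two assemblies
#'
#' @param aln_a,aln_b read tables from [read_sam_flags()] (or equivalently
#'   shaped data frames) for assemblies A and B. Read ids present in only
#'   one table are counted unmapped in the other, with a warning. Duplicate
#'   primary records for one read in one table are an input error.
#' @return list with `counts` (named: both, a_only, b_only, neither),
#'   `n_reads`, `exclusive_a` and `exclusive_b` (each: n, mean_gc over the
#'   exclusive set) and `proper_pairs` (named: a, b).
#' @export
classify_reads <- function(aln_a, aln_b) {
  for (nm in c("a", "b")) {
    d <- if (nm == "a") aln_a else aln_b
    if (anyDuplicated(d$qname)) {
      abort_input("duplicate primary records for read '%s' in stream %s",
                  d$qname[anyDuplicated(d$qname)], toupper(nm))
    }
  }
  universe <- union(aln_a$qname, aln_b$qname)
  if (length(setdiff(universe, aln_a$qname)) ||
      length(setdiff(universe, aln_b$qname))) {
    warning("read universes differ between streams; missing reads counted unmapped")
  }
  ia <- match(universe, aln_a$qname)
  ib <- match(universe, aln_b$qname)
  ma <- ifelse(is.na(ia), FALSE, aln_a$mapped_primary[ia])
  mb <- ifelse(is.na(ib), FALSE, aln_b$mapped_primary[ib])
  gc <- ifelse(!is.na(ia), aln_a$gc[ia], aln_b$gc[ib])
  counts <- c(both = sum(ma & mb), a_only = sum(ma & !mb),
              b_only = sum(!ma & mb), neither = sum(!ma & !mb))
  mean_gc <- function(sel) if (any(sel)) mean(gc[sel], na.rm = TRUE) else NA_real_
  list(
    counts = counts,
    n_reads = length(universe),
    exclusive_a = list(n = unname(counts["a_only"]), mean_gc = mean_gc(ma & !mb)),
    exclusive_b = list(n = unname(counts["b_only"]), mean_gc = mean_gc(!ma & mb)),
    proper_pairs = c(
      a = sum(ifelse(is.na(ia), FALSE, aln_a$proper_pair[ia])),
      b = sum(ifelse(is.na(ib), FALSE, aln_b$proper_pair[ib]))
    )
  )
}

#' One-tailed two-sample binomial (sign) test on discordant reads
#'
#' Tests whether significantly more reads map exclusively to assembly B
#' than exclusively to A: the exact upper-tail probability
#' P(X >= b_only) for X ~ Binomial(a_only + b_only, 1/2). For
#' n > 10,000 discordant reads a normal approximation with continuity
#' correction is used. The raw p-value is returned; [format_pvalue()]
#' renders values below 2.2e-16 as "< 2.2e-16".
#'
#' @param a_only,b_only counts of reads mapping exclusively to A and to B.
#' @return the one-tailed p-value.
#' @export
binomial_one_tailed <- function(a_only, b_only) {
  n <- a_only + b_only
  if (n < 1L) abort_input("need at least one discordant read")
  if (n <= 1e4) {
    pbinom(b_only - 1, n, 0.5, lower.tail = FALSE)
  } else {
    pnorm((b_only - 0.5 - n / 2) / sqrt(n / 4), lower.tail = FALSE)
  }
}

#' Format a p-value, flooring at the conventional 2.2e-16
#' @param p numeric p-value.
#' @return character: "< 2.2e-16" below the floor, otherwise a 2-signif
#'   rendering.
#' @export
format_pvalue <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else format(signif(p, 2), scientific = p < 1e-4)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on a vector of paired differences. Zeros are dropped and
#' ties receive mid-ranks. `mode = "normal_cc"` (default) uses the normal
#' approximation with continuity correction,
#' `z = (W - n(n+1)/4 -/+ 1/2) / sqrt(n(n+1)(2n+1)/24)` with W the
#' positive-rank sum and the half correction taken toward the mean.
#' `mode = "exact"` computes the exact null distribution of W over all 2^n
#' sign assignments (by convolution over the doubled mid-ranks, which is
#' equivalent to full enumeration and handles ties); the two-sided p-value
#' sums both tails at the observed rank sum:
#' P(W <= min(W+, W-)) + P(W >= max(W+, W-)).
#'
#' @param differences numeric vector of signed paired differences.
#' @param mode "normal_cc" or "exact".
#' @return the two-sided p-value.
#' @examples
#' wilcoxon_signed_rank(rep(1, 13))                    # ~0.0017
#' wilcoxon_signed_rank(rep(1, 13), mode = "exact")    # 2/8192
#' @export
wilcoxon_signed_rank <- function(differences, mode = c("normal_cc", "exact")) {
  mode <- match.arg(mode)
  d <- differences[differences != 0]
  if (length(d) == 0L) abort_input("all differences are zero; test undefined")
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (mode == "normal_cc") {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    if (W == mu) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    return(min(1, 2 * pnorm(-abs(z))))
  }
  # exact: distribution of 2*W over sign assignments, via convolution
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1L)
  f[1L] <- 1
  for (ri in r2) {
    g <- f
    g[(ri + 1L):(tot + 1L)] <- g[(ri + 1L):(tot + 1L)] + f[seq_len(tot + 1L - ri)]
    f <- g
  }
  f <- f / 2^n
  w2 <- as.integer(round(2 * W))
  lo <- min(w2, tot - w2)
  hi <- max(w2, tot - w2)
  min(1, sum(f[seq_len(lo + 1L)]) + sum(f[(hi + 1L):(tot + 1L)]))
}

#' Flag transcripts with split projections
#'
#' A transcript is a split-gene candidate when it has two or more
#' projections onto *distinct* target sequences whose extents in source
#' transcript coordinates nearly coincide: start points within `tol` bases
#' of each other and stop points within `tol` bases (the same piece of the
#' transcript landing on two contigs). `mode = "adjacent"` offers the
#' alternative reading — projections that tile the transcript, one
#' projection's stop within `tol` of another's start on a distinct target.
#'
#' @param projections data frame: `transcript`, `target`, `source_start`,
#'   `source_stop` (transcript coordinates, start < stop).
#' @param tol tolerance in bases (default 10).
#' @param mode "same_extent" (default) or "adjacent".
#' @return character vector of flagged transcript ids.
#' @export
split_gene_candidates <- function(projections, tol = 10L,
                                  mode = c("same_extent", "adjacent")) {
  mode <- match.arg(mode)
  if (any(projections$source_start >= projections$source_stop)) {
    abort_input("projection with source_start >= source_stop")
  }
  flagged <- character(0)
  for (tr in unique(projections$transcript)) {
    p <- projections[projections$transcript == tr, , drop = FALSE]
    if (nrow(p) < 2L) next
    hit <- FALSE
    for (i in seq_len(nrow(p) - 1L)) {
      for (j in (i + 1L):nrow(p)) {
        if (p$target[i] == p$target[j]) next
        hit <- if (mode == "same_extent") {
          abs(p$source_start[i] - p$source_start[j]) <= tol &&
            abs(p$source_stop[i] - p$source_stop[j]) <= tol
        } else {
          abs(p$source_stop[i] - p$source_start[j]) <= tol ||
            abs(p$source_stop[j] - p$source_start[i]) <= tol
        }
        if (hit) break
      }
      if (hit) break
    }
    if (hit) flagged <- c(flagged, tr)
  }
  flagged
}
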