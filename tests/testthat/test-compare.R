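# Cross-assembly read classification, the discordant-read sign test, the
# paired Wilcoxon test, and split-gene detection.

read_table <- function(qname, mapped, proper = FALSE, gc = 0.5) {
  data.frame(qname = qname, mapped_primary = mapped,
             proper_pair = rep_len(proper, length(qname)),
             gc = rep_len(gc, length(qname)),
             length = 50L, stringsAsFactors = FALSE)
}

test_that("reads are classified into both/A-only/B-only/neither from primary flags", {
  a <- read_table(paste0("r", 1:4), c(TRUE, TRUE, FALSE, FALSE))
  b <- read_table(paste0("r", 1:4), c(TRUE, FALSE, TRUE, FALSE))
  cl <- classify_reads(a, b)
  expect_equal(unname(cl$counts), c(1, 1, 1, 1))
  expect_equal(sum(cl$counts), cl$n_reads)

  # symmetry: swapping streams transposes the discordant cells
  cl2 <- classify_reads(b, a)
  expect_equal(cl2$counts[["a_only"]], cl$counts[["b_only"]])
  expect_equal(cl2$counts[["b_only"]], cl$counts[["a_only"]])

  # exclusive-set GC summaries
  b2 <- read_table(paste0("r", 1:4), c(TRUE, FALSE, TRUE, TRUE),
                   gc = c(0.5, 0.5, 0.6, 0.4))
  a2 <- read_table(paste0("r", 1:4), c(TRUE, TRUE, FALSE, FALSE),
                   gc = c(0.5, 0.5, 0.6, 0.4))
  cl3 <- classify_reads(a2, b2)
  expect_equal(cl3$exclusive_b$mean_gc, 0.5)

  dup <- read_table(c("r1", "r1"), TRUE)
  expect_error(classify_reads(dup, b), "duplicate primary")
  expect_warning(classify_reads(a[1:3, ], b), "universes differ")
})

test_that("secondary-only SAM records count as unmapped", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ref\tLN:1000",
    paste("r1", 0, "ref", 10, 60, "4M", "*", 0, 0, "ACGT", "IIII", sep = "\t"),
    paste("r2", 256, "ref", 20, 0, "4M", "*", 0, 0, "GGCC", "IIII", sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, "TTAA", "IIII", sep = "\t")
  ), sam)
  tab <- read_sam_flags(sam)
  expect_equal(sort(tab$qname), c("r1", "r3"))  # r2's secondary record dropped
  expect_equal(tab$mapped_primary[tab$qname == "r1"], TRUE)
  expect_equal(tab$mapped_primary[tab$qname == "r3"], FALSE)
  expect_equal(tab$gc[tab$qname == "r1"], 0.5)
})

test_that("the one-tailed sign test matches exact enumeration", {
  expect_equal(binomial_one_tailed(3, 13), 697 / 65536)
  expect_equal(binomial_one_tailed(5, 5), 638 / 1024)
  expect_equal(format_pvalue(binomial_one_tailed(0, 200)), "< 2.2e-16")
  for (a in 0:8) {
    for (b in 0:8) {
      if (a + b == 0) next
      expect_equal(binomial_one_tailed(a, b), binom_tail_oracle(a, b))
    }
  }
  # the two one-sided tails overlap only in the shared midpoint term
  for (i in 1:20) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    if (a + b == 0) next
    n <- a + b
    expect_equal(binomial_one_tailed(a, b) + binomial_one_tailed(b, a),
                 1 + choose(n, b) / 2^n)
  }
})

test_that("wilcoxon matches the printed-formula value and full enumeration", {
  # 13 uniformly improved samples: z = (91 - 45.5 - 0.5)/sqrt(204.75)
  expect_equal(signif(wilcoxon_signed_rank(rep(1, 13)), 2), 0.0017)
  expect_equal(wilcoxon_signed_rank(rep(1, 13), mode = "exact"), 2 / 8192)
  expect_equal(wilcoxon_signed_rank(c(2, -1), mode = "exact"), 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")

  set.seed(53)
  for (i in 1:40) {
    n <- sample(2:10, 1)
    mag <- sample(1:6, n, replace = TRUE)     # duplicates force mid-ranks
    d <- mag * sample(c(-1, 1), n, replace = TRUE)
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d, mode = "exact"), wilcoxon_oracle(d))
  }
})

test_that("split-gene candidates need near-identical extents on distinct targets", {
  proj <- data.frame(
    transcript = c("T1", "T1", "T2", "T3", "T3"),
    target = c("ctgA", "ctgB", "ctgA", "ctgA", "ctgA"),
    source_start = c(1, 3, 1, 1, 2),
    source_stop = c(500, 498, 500, 500, 499), stringsAsFactors = FALSE)
  expect_equal(split_gene_candidates(proj), "T1")
  # adjacent (tiling) reading flags complementary pieces instead
  tiling <- data.frame(transcript = "T4", target = c("ctgA", "ctgB"),
                       source_start = c(1, 505), source_stop = c(500, 900),
                       stringsAsFactors = FALSE)
  expect_equal(split_gene_candidates(tiling), character(0))
  expect_equal(split_gene_candidates(tiling, mode = "adjacent"), "T4")
  expect_error(split_gene_candidates(
    data.frame(transcript = "T", target = "c", source_start = 5, source_stop = 5)),
    "source_start")
})

test_that("classification agrees with simulated truth through SAM files", {
  tr <- shared_truth()
  seqs <- as.character(tr$assembly)
  rd <- simulate_reads(seqs[["scaf2"]], coverage = 1, error_rate = 0,
                      read_len = 50, seed = 13, rname = "scaf2")
  recs <- rd$truth
  # stream A: all mapped; stream B: last 10 reads unmapped
  recs_b <- recs
  n <- nrow(recs_b)
  recs_b$flag[(n - 9):n] <- 4L
  recs_b$rname[(n - 9):n] <- "*"
  recs_b$pos[(n - 9):n] <- 0L
  sa <- tempfile(fileext = ".sam"); sb <- tempfile(fileext = ".sam")
  write_sam(sa, recs, contigs = scaffold_lengths(tr$assembly))
  write_sam(sb, recs_b, contigs = scaffold_lengths(tr$assembly))
  cl <- classify_reads(read_sam_flags(sa), read_sam_flags(sb))
  expect_equal(unname(cl$counts[c("both", "a_only", "b_only", "neither")]),
               c(n - 10, 10, 0, 0))
  expect_equal(cl$n_reads, n)
})
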