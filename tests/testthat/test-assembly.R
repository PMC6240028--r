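test_that("contig segmentation honours the minimum-gap threshold", {
  # 24 Ns stay inside one contig; 25 Ns split it
  below <- segment_contigs(paste0("ACGT", strrep("N", 24), "ACGT"), min_gap = 25)
  expect_equal(nrow(below$contigs), 1)
  expect_equal(below$contigs$length, 32)
  expect_equal(nrow(below$gaps), 0)

  at <- segment_contigs(paste0("ACGT", strrep("N", 25), "ACGT"), min_gap = 25)
  expect_equal(at$contigs$length, c(4, 4))
  expect_equal(at$gaps$length, 25)

  clean <- segment_contigs("ACGTACGT")
  expect_equal(clean$contigs$length, 8)
  expect_equal(nrow(clean$gaps), 0)

  empty <- segment_contigs("")
  expect_equal(nrow(empty$contigs), 0)
  expect_equal(nrow(empty$gaps), 0)

  expect_error(segment_contigs("ACGRT"), "position 4")
})

test_that("contigs and gaps tile the scaffold exactly", {
  set.seed(5)
  for (i in 1:25) {
    pieces <- replicate(sample(1:6, 1), {
      if (runif(1) < 0.4) strrep("N", sample(1:60, 1)) else random_dna(sample(1:80, 1))
    })
    s <- paste(pieces, collapse = "")
    if (nchar(s) == 0) next
    seg <- segment_contigs(s, min_gap = 25)
    parts <- rbind(
      if (nrow(seg$contigs)) cbind(seg$contigs, what = "c"),
      if (nrow(seg$gaps)) cbind(seg$gaps, what = "g")
    )
    parts <- parts[order(parts$start), , drop = FALSE]
    rebuilt <- paste(substr(rep(s, nrow(parts)), parts$start + 1, parts$end),
                     collapse = "")
    expect_identical(rebuilt, s)
    # no threshold N-run survives inside a contig
    for (j in seq_len(nrow(seg$contigs))) {
      ctg <- substr(s, seg$contigs$start[j] + 1, seg$contigs$end[j])
      expect_false(grepl(strrep("N", 25), ctg, fixed = TRUE))
    }
  }
})

test_that("n50 matches examples and the cumulative-sum oracle", {
  expect_equal(n50(100), 100)
  expect_equal(n50(c(40, 30, 20, 10)), 30)
  expect_equal(n50(c(5, 5, 5, 5)), 5)
  expect_error(n50(numeric(0)))
  expect_error(n50(c(10, 0)))

  set.seed(9)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:50, 1), replace = TRUE)
    expect_equal(n50(lens), n50_oracle(lens))
  }
})

test_that("scaffold n50 never decreases when a long scaffold is appended", {
  set.seed(13)
  for (i in 1:20) {
    lens <- sample(1:1000, sample(2:20, 1), replace = TRUE)
    cur <- n50(lens)
    expect_gte(n50(c(lens, cur + sample(0:100, 1))), cur)
  }
})

test_that("assembly stats match a hand-counted toy and degenerate input", {
  a <- assembly(c(s1 = paste0("AC", strrep("N", 25), "GT")))
  st <- assembly_stats(a)
  expect_equal(st$gap_count, 1)
  expect_equal(st$gap_bases, 25)
  expect_equal(st$non_n_bases, 4)
  expect_equal(st$contig_n50, 2)
  expect_equal(st$scaffold_n50, 29)
  expect_equal(st$gc_fraction, 0.5)
  expect_false(st$gc_undefined)

  alln <- assembly_stats(assembly(c(s1 = strrep("N", 30))))
  expect_equal(alln$non_n_bases, 0)
  expect_equal(alln$gc_fraction, 0)
  expect_true(alln$gc_undefined)

  two <- assembly_stats(assembly(c(a = random_dna(100), b = random_dna(50))))
  expect_equal(two$scaffold_n50, 100)
})

test_that("small-scaffold filtering is strict and idempotent", {
  a <- assembly(c(short = strrep("A", 2999), exact = strrep("C", 3000),
                  long = strrep("G", 5000)))
  f <- filter_small_scaffolds(a)
  expect_equal(f$removed$scaffold, "short")
  expect_equal(names(f$assembly), c("exact", "long"))
  f2 <- filter_small_scaffolds(f$assembly)
  expect_equal(nrow(f2$removed), 0)
  expect_identical(as.character(f2$assembly), as.character(f$assembly))

  e <- filter_small_scaffolds(assembly(character(0)))
  expect_equal(length(e$assembly), 0)
  expect_equal(nrow(e$removed), 0)
})

test_that("assembly validation rejects ambiguity codes but accepts case", {
  expect_error(assembly(c(s = "ACGW")), "non-ACGTN")
  low <- assembly(c(s = "acgtn"))
  expect_identical(as.character(low), c(s = "ACGTN"))
  expect_error(assembly(c("ACGT")), "named")
  expect_error(assembly(c(a = "ACGT", a = "GGCC")), "duplicate")
})

test_that("FASTA round-trips through Biostrings with 60-column wrap", {
  a <- assembly(c(s1 = random_dna(150), s2 = paste0(random_dna(40),
                                                    strrep("N", 30),
                                                    random_dna(40))))
  p <- tempfile(fileext = ".fa")
  write_assembly_fasta(a, p)
  expect_lte(max(nchar(readLines(p))), 61)
  b <- read_assembly_fasta(p)
  expect_identical(as.character(b), as.character(a))
})
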