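# Phase-block pseudo-haploidization: block scoring, block vs site modes,
# tie handling, and consistency checks.

hap_fixture <- function() {
  # two-site phase block on a 12-base scaffold, plus cohort counts
  asm <- assembly(c(s1 = "AAAAAAAAAAAA"))   # current ref holds hap1 at both
  sites <- data.frame(
    block_id = "s1:3", scaffold = "s1", pos = c(3L, 7L),
    hap1 = c("A", "A"), hap2 = c("G", "C"), stringsAsFactors = FALSE)
  counts <- data.frame(
    scaffold = "s1", pos = c(3L, 3L, 7L, 7L),
    allele = c("A", "G", "A", "C"), count = c(5L, 3L, 1L, 6L),
    stringsAsFactors = FALSE)
  list(asm = asm, phase = list(sites = sites), counts = counts)
}

test_that("block scores sum per-haplotype cohort counts across sites", {
  fx <- hap_fixture()
  sc <- score_block(fx$phase$sites, fx$counts)
  expect_equal(unname(sc), c(6, 9))        # hap1: 5+1, hap2: 3+6
  one <- score_block(fx$phase$sites[1, ], fx$counts)
  expect_equal(unname(one), c(5, 3))
  none <- score_block(fx$phase$sites,
                      data.frame(scaffold = character(0), pos = integer(0),
                                 allele = character(0), count = integer(0)))
  expect_equal(unname(none), c(0, 0))
})

test_that("block mode rewrites whole blocks; site mode is per-site argmax", {
  fx <- hap_fixture()
  blk <- choose_and_apply(fx$asm, fx$phase, fx$counts, mode = "block")
  # hap2 wins 9 > 6: both sites take hap2 alleles
  expect_equal(substr(as.character(blk$assembly)[["s1"]], 3, 3), "G")
  expect_equal(substr(as.character(blk$assembly)[["s1"]], 7, 7), "C")
  expect_true(all(blk$provenance$chosen_hap == 2))

  sit <- choose_and_apply(fx$asm, fx$phase, fx$counts, mode = "site")
  # site 1: hap1 (5 > 3) keeps A; site 2: hap2 (6 > 1) takes C
  expect_equal(substr(as.character(sit$assembly)[["s1"]], 3, 3), "A")
  expect_equal(substr(as.character(sit$assembly)[["s1"]], 7, 7), "C")
  expect_equal(sit$provenance$chosen_hap, c(1, 2))
})

test_that("score ties keep the current reference base", {
  fx <- hap_fixture()
  tie <- fx$counts
  tie$count <- c(4L, 4L, 4L, 4L)
  res <- choose_and_apply(fx$asm, fx$phase, tie, mode = "block")
  expect_identical(as.character(res$assembly), as.character(fx$asm))
  expect_true(all(res$provenance$chosen_hap == 0))
})

test_that("a reference base matching neither haplotype is a consistency error", {
  fx <- hap_fixture()
  bad <- assembly(c(s1 = "AATAAAAAAAAA"))  # pos 3 = T, alleles are A/G
  expect_error(choose_and_apply(bad, fx$phase, fx$counts), "neither phased allele")
})

test_that("phased VCF parsing groups sites by phase set and skips unphased sites", {
  fixed <- data.frame(CHROM = "s1", POS = c(2L, 5L, 9L),
                      REF = c("A", "A", "A"), ALT = c("G", "C", "T"))
  gt <- matrix(c("0|1", "1|0", "0/1"), ncol = 1,
               dimnames = list(NULL, "focal"))
  ps <- matrix(c("2", "2", "."), ncol = 1, dimnames = list(NULL, "focal"))
  ph <- read_phase_blocks(roundtrip_vcf(fixed, gt, ps = ps), "focal")
  expect_equal(nrow(ph$sites), 2)
  expect_equal(unique(ph$sites$block_id), "s1:2")
  expect_equal(ph$sites$hap1, c("A", "C"))   # left of | is haplotype 1
  expect_equal(ph$sites$hap2, c("G", "A"))
  expect_equal(ph$unphased$pos, 9)
})

test_that("rewritten bases always come from the phased alleles and block mode is haplotype-consistent", {
  tr <- shared_truth()
  ph <- list(sites = with(tr$het_sites, data.frame(
    block_id = block_id, scaffold = scaffold, pos = pos,
    hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)))
  coh <- simulate_cohort(tr, seed = 11)
  cvcf <- roundtrip_vcf(coh$fixed, coh$gt)
  counts <- cohort_allele_counts(cvcf, coh$samples)
  res <- choose_and_apply(tr$assembly, ph, counts, mode = "block")
  expect_identical(scaffold_lengths(res$assembly), scaffold_lengths(tr$assembly))
  out <- as.character(res$assembly)
  for (j in seq_len(nrow(ph$sites))) {
    b <- substr(out[[ph$sites$scaffold[j]]], ph$sites$pos[j], ph$sites$pos[j])
    expect_true(b %in% c(ph$sites$hap1[j], ph$sites$hap2[j]))
  }
  # within each block every site follows the block's chosen haplotype
  pr <- res$provenance
  for (bid in unique(pr$block_id)) {
    expect_length(unique(pr$chosen_hap[pr$block_id == bid]), 1)
  }
})
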