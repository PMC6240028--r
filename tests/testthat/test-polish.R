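# Cohort-corroborated polishing: candidate detection, the corroboration
# rule, and edit bookkeeping, on VCF fixtures built in code.

polish_fixture <- function() {
  asm <- assembly(c(s1 = "ACGTACGTACGTACGTACGT"))
  fixed <- data.frame(
    CHROM = "s1",
    POS = c(2L, 5L, 8L, 11L, 14L),
    REF = c("C", "A", "T", "G", "C"),
    ALT = c("T", "G", "TAG", "A", "A"),
    stringsAsFactors = FALSE
  )
  gt <- matrix(c(
    # focal     c1     c2
    "1/1",    "1/1", "1/1",   # SNV, cohort lacks ref -> applied
    "0/1",    "0/0", "0/0",   # het focal -> not a candidate
    "1/1",    "1/1", "1/1",   # insertion -> skipped_indel
    "1/1",    "0/1", "1/1",   # ref detected in cohort -> not changed
    "1/1",    "./.", "./."    # all-missing cohort -> applied
  ), ncol = 3, byrow = TRUE, dimnames = list(NULL, c("focal", "c1", "c2")))
  list(asm = asm, vcf = roundtrip_vcf(fixed, gt))
}

test_that("candidate detection keeps homozygous SNV differences only", {
  fx <- polish_fixture()
  sites <- find_candidate_sites(fx$vcf, fx$asm, "focal")
  expect_equal(sites$decision,
               c("candidate", "skipped_not_homozygous", "skipped_indel",
                 "candidate", "candidate"))
  expect_equal(sites$alt[sites$decision == "candidate"], c("T", "A", "A"))
})

test_that("the corroboration rule blocks edits when the cohort shows the reference allele", {
  fx <- polish_fixture()
  res <- polish_assembly(fx$asm, fx$vcf, "focal")
  expect_equal(res$changes$decision,
               c("applied", "skipped_not_homozygous", "skipped_indel",
                 "skipped_ref_in_cohort", "applied"))
  out <- as.character(res$assembly)[["s1"]]
  expect_equal(substr(out, 2, 2), "T")    # corrected
  expect_equal(substr(out, 11, 11), "G")  # protected by cohort ref allele
  expect_equal(substr(out, 14, 14), "A")  # all-missing cohort: applied
  # substitutions only: lengths conserved
  expect_identical(scaffold_lengths(res$assembly), scaffold_lengths(fx$asm))
})

test_that("multi-allelic records count non-reference cohort alleles as corroborating", {
  asm <- assembly(c(s1 = "AAAA"))
  fixed <- data.frame(CHROM = "s1", POS = 2L, REF = "A", ALT = "C,G")
  gt <- matrix(c("2/2", "1/1"), ncol = 2,
               dimnames = list(NULL, c("focal", "c1")))
  res <- polish_assembly(asm, roundtrip_vcf(fixed, gt), "focal")
  expect_equal(res$changes$decision, "applied")
  expect_equal(as.character(res$assembly)[["s1"]], "AGAA")
})

test_that("REF/assembly disagreement and overlapping candidates are errors", {
  asm <- assembly(c(s1 = "ACGT"))
  bad <- roundtrip_vcf(data.frame(CHROM = "s1", POS = 2L, REF = "G", ALT = "T"),
                       matrix(c("1/1", "0/0"), ncol = 2,
                              dimnames = list(NULL, c("focal", "c1"))))
  expect_error(find_candidate_sites(bad, asm, "focal"),
               "disagrees with assembly base .* s1:2")

  dup_fixed <- data.frame(CHROM = "s1", POS = c(2L, 2L), REF = "C",
                          ALT = c("T", "G"))
  dup_gt <- matrix(c("1/1", "0/0", "1/1", "0/0"), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("focal", "c1")))
  dup <- roundtrip_vcf(dup_fixed, dup_gt)
  sites <- find_candidate_sites(dup, asm, "focal")
  expect_error(corroborate_and_apply(sites, dup, asm, "focal"), "ambiguous")
})

test_that("polishing the synthetic study corrects every planted error and nothing else", {
  tr <- shared_truth()
  vcf <- list(fixed = tr$polish_vcf$fixed, gt = tr$polish_vcf$gt,
              ps = NULL, samples = tr$polish_vcf$samples)
  res <- polish_assembly(tr$assembly, vcf, "focal")
  applied <- res$changes[res$changes$decision == "applied", ]
  expect_equal(nrow(applied), nrow(tr$ref_errors))
  expect_identical(as.character(res$assembly), as.character(tr$polished_truth))

  # idempotence: with REF fields updated after polishing, the focal animal
  # matches the reference again and a re-run applies nothing
  upd <- vcf
  hit <- paste(vcf$fixed$CHROM, vcf$fixed$POS) %in%
    paste(tr$ref_errors$scaffold, tr$ref_errors$pos)
  upd$fixed$REF[hit] <- vcf$fixed$ALT[hit]
  upd$fixed$ALT[hit] <- vcf$fixed$REF[hit]
  upd$gt[hit, ] <- "0/0"
  res2 <- polish_assembly(res$assembly, upd, "focal")
  expect_equal(sum(res2$changes$decision == "applied"), 0)
  expect_identical(as.character(res2$assembly), as.character(res$assembly))
})
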