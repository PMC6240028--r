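# Cohort-corroborated reference polishing.
#
# When the resequenced animal is the same individual the assembly was built
# from, a homozygous genotype that differs from the reference is either a
# reference error or a genotyping artefact. The rule implemented here edits
# the reference only when no other animal in a genotyping cohort carries the
# reference allele at that position: detection of the reference allele in any
# cohort animal is taken as evidence the reference base is a real allele
# (possibly undersampled in the focal short-read data), and the base is left
# alone.

#' Find candidate polishing sites in a multi-sample VCF
#'
#' Scans the focal sample's genotypes for sites homozygous for a
#' single-nucleotide ALT differing from REF. Indel and multi-nucleotide
#' records are excluded (decision `skipped_indel`); heterozygous or
#' reference-carrying focal genotypes are excluded
#' (`skipped_not_homozygous`). Every VCF record yields exactly one row, so
#' the output doubles as a per-record decision log. REF fields are checked
#' against the assembly; a mismatch raises a consistency error naming the
#' scaffold and position.
#'
#' @param vcf genotype set from [read_genotypes()].
#' @param asm the [assembly()] the VCF was called against.
#' @param focal name of the focal sample (must be in the VCF; the remaining
#'   samples form the corroboration cohort).
#' @return data frame with columns `scaffold`, `pos` (1-based), `ref`,
#'   `alt` (the replacement base, NA for non-candidates) and `decision`
#'   (`candidate`, `skipped_not_homozygous`, `skipped_indel`).
#' @export
find_candidate_sites <- function(vcf, asm, focal) {
  if (!focal %in% vcf$samples) {
    abort_input("focal sample '%s' not in VCF (samples: %s)", focal,
                paste(vcf$samples, collapse = ", "))
  }
  fixed <- vcf$fixed
  n <- nrow(fixed)
  decision <- character(n)
  alt_base <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    scaf <- fixed$CHROM[i]
    if (!scaf %in% names(asm)) {
      abort_consistency("VCF scaffold '%s' absent from assembly", scaf)
    }
    ref <- fixed$REF[i]
    pos <- fixed$POS[i]
    have <- substr(unclass(asm)[[scaf]], pos, pos + nchar(ref) - 1L)
    if (!identical(have, ref)) {
      abort_consistency("VCF REF '%s' disagrees with assembly base '%s' at %s:%d",
                        ref, have, scaf, pos)
    }
    alleles <- allele_strings(ref, fixed$ALT[i])
    g <- parse_gt(vcf$gt[i, focal])
    a <- g$alleles
    hom_alt <- length(a) == 2L && !anyNA(a) && a[1L] == a[2L] && a[1L] > 0L
    if (!hom_alt) {
      decision[i] <- "skipped_not_homozygous"
      next
    }
    rep_allele <- alleles[a[1L] + 1L]
    if (nchar(ref) != 1L || nchar(rep_allele) != 1L) {
      decision[i] <- "skipped_indel"
      next
    }
    decision[i] <- "candidate"
    alt_base[i] <- rep_allele
  }
  data.frame(scaffold = fixed$CHROM, pos = fixed$POS, ref = fixed$REF,
             alt = alt_base, decision = decision, stringsAsFactors = FALSE)
}

#' Corroborate candidate sites against the cohort and apply edits
#'
#' For each candidate site, queries the cohort genotypes: if any non-missing
#' cohort genotype contains the reference allele (index 0), the site is
#' skipped (`skipped_ref_in_cohort`); otherwise the reference base is
#' replaced by the focal homozygous ALT (`applied`). Missing cohort
#' genotypes do not block a change — the rule fires on *detection* of the
#' reference allele, and absent data detects nothing; sites applied with an
#' all-missing cohort are still logged as `applied`. Non-reference alleles
#' other than the focal ALT also do not block. Edits are single-base
#' substitutions, so scaffold lengths are conserved.
#'
#' @param sites decision table from [find_candidate_sites()].
#' @param vcf genotype set from [read_genotypes()] (same one used to find
#'   the sites).
#' @param asm the [assembly()] to polish.
#' @param focal focal sample name; all other samples are the cohort.
#' @return list with `assembly` (polished) and `changes` (data frame:
#'   scaffold, pos, old_base, new_base, decision — one row per VCF record).
#' @export
corroborate_and_apply <- function(sites, vcf, asm, focal) {
  cohort <- setdiff(vcf$samples, focal)
  if (length(cohort) < 1L) abort_input("cohort must contain at least one sample")
  cand <- which(sites$decision == "candidate")
  if (anyDuplicated(paste(sites$scaffold[cand], sites$pos[cand]))) {
    abort_input("overlapping candidate sites at one position: ambiguous edit")
  }
  seqs <- unclass(asm)
  changes <- data.frame(scaffold = sites$scaffold, pos = sites$pos,
                        old_base = sites$ref,
                        new_base = rep(NA_character_, nrow(sites)),
                        decision = sites$decision, stringsAsFactors = FALSE)
  for (i in cand) {
    ref_seen <- FALSE
    for (s in cohort) {
      a <- parse_gt(vcf$gt[i, s])$alleles
      if (!anyNA(a) && any(a == 0L)) { ref_seen <- TRUE; break }
    }
    if (ref_seen) {
      changes$decision[i] <- "skipped_ref_in_cohort"
    } else {
      changes$decision[i] <- "applied"
      changes$new_base[i] <- sites$alt[i]
      substr(seqs[[sites$scaffold[i]]], sites$pos[i], sites$pos[i]) <- sites$alt[i]
    }
  }
  list(assembly = assembly(seqs, name = attr(asm, "name") %||% "assembly"),
       changes = changes)
}

#' Polish an assembly from a multi-sample VCF in one call
#'
#' Convenience wrapper running [find_candidate_sites()] then
#' [corroborate_and_apply()].
#'
#' @inheritParams corroborate_and_apply
#' @param vcf genotype set from [read_genotypes()].
#' @return list with `assembly` and `changes`, as [corroborate_and_apply()].
#' @export
polish_assembly <- function(asm, vcf, focal) {
  sites <- find_candidate_sites(vcf, asm, focal)
  corroborate_and_apply(sites, vcf, asm, focal)
}
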