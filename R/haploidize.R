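# Population-guided pseudo-haploidization.
#
# A haploid reference built from a diploid genome must pick one allele at
# every heterozygous site. Rather than keeping the assembler's arbitrary
# choice, each phase block (a set of heterozygous sites whose alleles have
# been consistently assigned to the two parental haplotypes) is rewritten to
# the haplotype whose alleles are most common in a genotyping cohort, pulling
# the reference toward the population average. A per-site mode is also
# offered, taking the cohort-major allele independently at every site.

#' Extract phase blocks from a phased VCF
#'
#' Collects the focal sample's phased heterozygous single-nucleotide sites
#' and groups them into phase blocks by the PS tag. Unphased heterozygous
#' sites are left out of the blocks and returned separately for logging.
#' Sites within a block are ordered by position.
#'
#' @param vcf genotype set from [read_genotypes()] (needs PS to be present
#'   for phased sites; sites without PS get a per-scaffold singleton block).
#' @param focal focal (phased) sample name.
#' @return list with `sites` (data frame: block_id, scaffold, pos, hap1,
#'   hap2 — alleles carried by haplotype 1 and 2) and `unphased` (data frame
#'   of skipped heterozygous sites).
#' @export
read_phase_blocks <- function(vcf, focal) {
  if (!focal %in% vcf$samples) abort_input("focal sample '%s' not in VCF", focal)
  fixed <- vcf$fixed
  keep <- logical(nrow(fixed))
  block <- hap1 <- hap2 <- character(nrow(fixed))
  unphased <- integer(0)
  for (i in seq_len(nrow(fixed))) {
    g <- parse_gt(vcf$gt[i, focal])
    a <- g$alleles
    if (length(a) != 2L || anyNA(a) || a[1L] == a[2L]) next
    alleles <- allele_strings(fixed$REF[i], fixed$ALT[i])
    h1 <- alleles[a[1L] + 1L]; h2 <- alleles[a[2L] + 1L]
    if (nchar(h1) != 1L || nchar(h2) != 1L) next   # SNVs only
    if (!g$phased) { unphased <- c(unphased, i); next }
    ps <- if (!is.null(vcf$ps)) vcf$ps[i, focal] else NA_character_
    if (is.na(ps) || ps == ".") ps <- "nops"
    keep[i] <- TRUE
    block[i] <- paste0(fixed$CHROM[i], ":", ps)
    hap1[i] <- h1; hap2[i] <- h2
  }
  sites <- data.frame(block_id = block[keep], scaffold = fixed$CHROM[keep],
                      pos = fixed$POS[keep], hap1 = hap1[keep],
                      hap2 = hap2[keep], stringsAsFactors = FALSE)
  sites <- sites[order(sites$scaffold, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  list(
    sites = sites,
    unphased = data.frame(scaffold = fixed$CHROM[unphased],
                          pos = fixed$POS[unphased], stringsAsFactors = FALSE)
  )
}

#' Count cohort alleles at a set of sites
#'
#' Tallies, for every VCF site, how many cohort chromosomes carry each
#' allele (two per non-missing diploid genotype; missing genotypes
#' contribute nothing).
#'
#' @param vcf genotype set from [read_genotypes()].
#' @param cohort sample names to count (e.g. everything but the focal).
#' @return data frame with `scaffold`, `pos`, `allele`, `count`.
#' @export
cohort_allele_counts <- function(vcf, cohort) {
  missing <- setdiff(cohort, vcf$samples)
  if (length(missing)) abort_input("cohort samples not in VCF: %s",
                                   paste(missing, collapse = ", "))
  fixed <- vcf$fixed
  out <- vector("list", nrow(fixed))
  for (i in seq_len(nrow(fixed))) {
    alleles <- allele_strings(fixed$REF[i], fixed$ALT[i])
    obs <- character(0)
    for (s in cohort) {
      a <- parse_gt(vcf$gt[i, s])$alleles
      if (!anyNA(a)) obs <- c(obs, alleles[a + 1L])
    }
    if (length(obs)) {
      tab <- table(obs)
      out[[i]] <- data.frame(scaffold = fixed$CHROM[i], pos = fixed$POS[i],
                             allele = names(tab), count = as.integer(tab),
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(scaffold = character(0), pos = integer(0),
                      allele = character(0), count = integer(0))
  }
  rownames(res) <- NULL
  res
}

# Cohort count of one allele at one site (0 when unobserved).
lookup_count <- function(counts, scaffold, pos, allele) {
  hit <- counts$scaffold == scaffold & counts$pos == pos & counts$allele == allele
  if (any(hit)) sum(counts$count[hit]) else 0L
}

#' Score a phase block against cohort allele counts
#'
#' Each haplotype's score is the sum over the block's sites of the cohort
#' count of that haplotype's allele. Sites absent from the counts contribute
#' zero to both.
#'
#' @param block_sites rows of the `sites` table from [read_phase_blocks()]
#'   belonging to one block.
#' @param counts allele counts from [cohort_allele_counts()].
#' @return named numeric vector `c(score_h1, score_h2)`.
#' @export
score_block <- function(block_sites, counts) {
  s1 <- s2 <- 0L
  for (i in seq_len(nrow(block_sites))) {
    s1 <- s1 + lookup_count(counts, block_sites$scaffold[i],
                            block_sites$pos[i], block_sites$hap1[i])
    s2 <- s2 + lookup_count(counts, block_sites$scaffold[i],
                            block_sites$pos[i], block_sites$hap2[i])
  }
  c(score_h1 = s1, score_h2 = s2)
}

#' Rewrite the reference to the cohort-major haplotype
#'
#' In `mode = "block"` (default), each phase block is scored with
#' [score_block()] and every site in the block receives the allele of the
#' higher-scoring haplotype, keeping the output haplotype-consistent within
#' the block. In `mode = "site"`, each site independently takes whichever of
#' its two alleles is more common in the cohort. Ties keep the current
#' reference base, so re-running is a no-op. A site whose current reference
#' base matches neither phased allele raises a consistency error.
#'
#' @param asm the [assembly()] to rewrite.
#' @param phase phase blocks from [read_phase_blocks()].
#' @param counts allele counts from [cohort_allele_counts()].
#' @param mode `"block"` or `"site"`.
#' @return list with `assembly` and `provenance` (data frame: block_id,
#'   scaffold, pos, score_h1, score_h2, chosen_hap (1, 2 or 0 for
#'   tie/keep), old_base, new_base).
#' @export
choose_and_apply <- function(asm, phase, counts, mode = c("block", "site")) {
  mode <- match.arg(mode)
  sites <- phase$sites
  if (nrow(sites) && anyDuplicated(paste(sites$scaffold, sites$pos))) {
    abort_input("phase blocks overlap: duplicate site position")
  }
  seqs <- unclass(asm)
  prov <- vector("list", length(unique(sites$block_id)))
  bi <- 0L
  for (bid in unique(sites$block_id)) {
    bs <- sites[sites$block_id == bid, , drop = FALSE]
    sc <- score_block(bs, counts)
    cur <- vapply(seq_len(nrow(bs)), function(i) {
      substr(seqs[[bs$scaffold[i]]], bs$pos[i], bs$pos[i])
    }, character(1))
    bad <- cur != bs$hap1 & cur != bs$hap2
    if (any(bad)) {
      abort_consistency("reference base '%s' at %s:%d matches neither phased allele",
                        cur[bad][1L], bs$scaffold[bad][1L], bs$pos[bad][1L])
    }
    if (mode == "block") {
      chosen <- if (sc[1L] > sc[2L]) 1L else if (sc[2L] > sc[1L]) 2L else 0L
      new <- switch(as.character(chosen), "1" = bs$hap1, "2" = bs$hap2, "0" = cur)
      chosen_vec <- rep(chosen, nrow(bs))
    } else {
      chosen_vec <- integer(nrow(bs))
      new <- cur
      for (i in seq_len(nrow(bs))) {
        c1 <- lookup_count(counts, bs$scaffold[i], bs$pos[i], bs$hap1[i])
        c2 <- lookup_count(counts, bs$scaffold[i], bs$pos[i], bs$hap2[i])
        if (c1 > c2) { chosen_vec[i] <- 1L; new[i] <- bs$hap1[i] }
        else if (c2 > c1) { chosen_vec[i] <- 2L; new[i] <- bs$hap2[i] }
      }
    }
    for (i in seq_len(nrow(bs))) {
      if (new[i] != cur[i]) {
        substr(seqs[[bs$scaffold[i]]], bs$pos[i], bs$pos[i]) <- new[i]
      }
    }
    bi <- bi + 1L
    prov[[bi]] <- data.frame(block_id = bid, scaffold = bs$scaffold,
                             pos = bs$pos, score_h1 = sc[[1L]],
                             score_h2 = sc[[2L]], chosen_hap = chosen_vec,
                             old_base = cur, new_base = new,
                             stringsAsFactors = FALSE)
  }
  provenance <- if (bi) do.call(rbind, prov[seq_len(bi)]) else
    data.frame(block_id = character(0), scaffold = character(0),
               pos = integer(0), score_h1 = numeric(0), score_h2 = numeric(0),
               chosen_hap = integer(0), old_base = character(0),
               new_base = character(0))
  rownames(provenance) <- NULL
  list(assembly = assembly(seqs, name = attr(asm, "name") %||% "assembly"),
       provenance = provenance)
}
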