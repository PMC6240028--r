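# Seeded synthetic-data generators.
#
# Every input the finishing pipeline consumes can be generated here with
# known ground truth: a diploid genome with gapped scaffolds, heterozygous
# sites grouped into phase blocks, planted reference errors, a genotyping
# cohort sharing allele frequencies with the focal animal, STS markers with
# unique primer pairs, a misassembled copy carrying one planted inversion,
# injected microbial contaminant contigs, a circular mitochondrial genome
# with a tandem 8-mer repeat, and error-bearing shotgun reads. Each
# generator stage draws from its own RNG stream, seeded by (master seed,
# stage name), so stages can be regenerated independently and the whole
# bundle is byte-reproducible under (config, seed).

# Deterministic per-stage seed below 2^31.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer(((abs(seed) %% 1048573) * 1021 + h) %% 2147483647)
}

#' Random DNA sequence with a GC-content knob
#' @param n length in bases.
#' @param gc expected G+C fraction (default 0.5).
#' @return character scalar. Uses the current RNG stream.
#' @export
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
         character(1), USE.NAMES = FALSE)
}

#' Default synthetic-study configuration
#'
#' The study conditions the generators emulate: a handful of ~8 kb gapped
#' scaffolds standing in for chromosome-scale sequence, heterozygosity of
#' 2 sites/kb grouped into 1-6 site phase blocks, a 4-animal corroboration
#' cohort, 20 planted single-base reference errors plus genotyping decoys,
#' 24 STS markers (12 on the first scaffold so a 4-marker inversion fits
#' with flanking markers), 3 microbial contaminant sources, and a 1 kb
#' circular mitochondrial toy with a 4-copy tandem 8-mer in its control
#' region.
#'
#' @param ... overrides for individual fields.
#' @return named list of configuration values.
#' @export
default_sim_config <- function(...) {
  cfg <- list(
    n_scaffolds = 4L,
    scaffold_length = 8000L,
    gaps_per_scaffold = 2L,
    gap_length = c(25L, 120L),
    het_density = 0.002,
    block_sites = c(1L, 6L),
    n_ref_errors = 20L,
    n_decoy_sites = 10L,
    n_cohort = 4L,
    marker_counts = NULL,        # per-scaffold; default: 12 on scaffold 1, 4 elsewhere
    primer_len = 20L,
    amplicon_range = c(50L, 500L),
    inversion_markers = c(5L, 8L),
    n_contaminants = 3L,
    contaminant_source_len = 600L,
    contaminant_contig_len = 300L,
    mito_length = 1000L,
    mito_repeat_copies = 4L,
    mito_flank_len = 25L,
    mito_start_subs = 5L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Simulate the full ground-truth bundle
#'
#' Generates the complete synthetic study under one master seed: working
#' assembly (gapped scaffolds, arbitrary pseudo-haploid choices at
#' heterozygous sites, planted reference errors), both haplotypes, polish
#' and phased VCF components, marker set with true placements, a
#' misassembled copy with one planted inversion, contaminant sources with a
#' contaminated assembly, and the mitochondrial toy. Regenerating with the
#' same (config, seed) reproduces the bundle exactly.
#'
#' @param config configuration from [default_sim_config()].
#' @param seed master seed (integer).
#' @return a `truth_bundle` list; see the individual fields' documentation
#'   in the package vignette.
#' @export
simulate_truth <- function(config = default_sim_config(), seed = 1L) {
  cfg <- config
  ns <- cfg$n_scaffolds
  lens <- rep_len(cfg$scaffold_length, ns)
  scaf_names <- paste0("scaf", seq_len(ns))
  marker_counts <- cfg$marker_counts
  if (is.null(marker_counts)) {
    marker_counts <- c(12L, rep(4L, ns - 1L))
  }
  marker_counts <- rep_len(marker_counts, ns)
  if (cfg$inversion_markers[2L] + 1L > marker_counts[1L]) {
    abort_input("inversion span needs a flanking marker on each side on scaffold 1")
  }
  # scaffolds 1..2 share chr1 (multi-scaffold chromosome); the rest get own
  chrom_of <- setNames(c("chr1", if (ns > 1L) "chr1",
                         if (ns > 2L) paste0("chr", seq_len(ns - 2L) + 1L)),
                       scaf_names)[seq_len(ns)]

  set.seed(stage_seed(seed, "genome"))
  genome0 <- setNames(vapply(lens, function(L) random_dna(L), character(1)),
                      scaf_names)

  # --- markers: regular slots, unique primers checked after assembly ----
  set.seed(stage_seed(seed, "markers"))
  marker_rows <- list(); amplicons <- list()
  for (i in seq_len(ns)) {
    k <- marker_counts[i]
    if (k == 0L) { amplicons[[i]] <- cbind(start = integer(0), end = integer(0)); next }
    slot <- lens[i] %/% k
    amax <- min(cfg$amplicon_range[2L], slot - 40L)
    if (amax < max(cfg$amplicon_range[1L], 2L * cfg$primer_len + 1L)) {
      abort_input("scaffold %d too short for %d markers", i, k)
    }
    a0 <- a1 <- integer(k)
    for (j in seq_len(k)) {
      alen <- sample(seq(max(cfg$amplicon_range[1L], 2L * cfg$primer_len + 10L), amax), 1L)
      off <- sample(seq(10L, slot - alen - 10L), 1L)
      a0[j] <- (j - 1L) * slot + off          # 0-based
      a1[j] <- a0[j] + alen
    }
    fwd <- substr(rep(genome0[[i]], k), a0 + 1L, a0 + cfg$primer_len)
    rev <- revcomp(substr(rep(genome0[[i]], k), a1 - cfg$primer_len + 1L, a1))
    marker_rows[[i]] <- data.frame(
      id = sprintf("%s_mk%02d", scaf_names[i], seq_len(k)),
      map_chromosome = chrom_of[[scaf_names[i]]],
      map_position = NA_real_,
      fwd_primer = fwd, rev_primer = rev, stringsAsFactors = FALSE)
    amplicons[[i]] <- cbind(start = a0, end = a1)
  }
  markers <- do.call(rbind, marker_rows)
  # map positions: truth order within each chromosome (scaffold order, then coordinate)
  for (ch in unique(markers$map_chromosome)) {
    sel <- markers$map_chromosome == ch
    markers$map_position[sel] <- seq_len(sum(sel))
  }
  marker_truth <- do.call(rbind, lapply(seq_len(ns), function(i) {
    if (marker_counts[i] == 0L) return(NULL)
    data.frame(id = marker_rows[[i]]$id, scaffold = scaf_names[i],
               amplicon_start = amplicons[[i]][, "start"],
               amplicon_end = amplicons[[i]][, "end"], strand = "+",
               stringsAsFactors = FALSE)
  }))

  # --- free-position bookkeeping (1-based), then gaps ------------------
  free <- lapply(seq_len(ns), function(i) {
    f <- rep(TRUE, lens[i])
    a <- amplicons[[i]]
    for (j in seq_len(nrow(a))) f[(a[j, "start"] + 1L):a[j, "end"]] <- FALSE
    f
  })
  set.seed(stage_seed(seed, "gaps"))
  gap_rows <- list()
  for (i in seq_len(ns)) {
    for (g in seq_len(cfg$gaps_per_scaffold)) {
      glen <- sample(seq(cfg$gap_length[1L], cfg$gap_length[2L]), 1L)
      for (try in 1:200) {
        s <- sample(lens[i] - glen, 1L)               # 1-based start
        if (all(free[[i]][s:(s + glen - 1L)])) break
        s <- NA_integer_
      }
      if (is.na(s)) abort_input("could not place gap on scaffold %d", i)
      free[[i]][s:(s + glen - 1L)] <- FALSE
      substr(genome0[[i]], s, s + glen - 1L) <- strrep("N", glen)
      gap_rows[[length(gap_rows) + 1L]] <-
        data.frame(scaffold = scaf_names[i], start = s - 1L, end = s - 1L + glen)
    }
  }
  gaps <- do.call(rbind, gap_rows)

  # --- heterozygous sites grouped into phase blocks --------------------
  set.seed(stage_seed(seed, "variants"))
  het_rows <- list()
  for (i in seq_len(ns)) {
    n_het <- round(cfg$het_density * lens[i])
    pos <- sort(sample(which(free[[i]]), n_het))
    free[[i]][pos] <- FALSE
    hap1 <- substr(rep(genome0[[i]], n_het), pos, pos)
    hap2 <- other_base(hap1)
    # group consecutive sites into blocks
    block <- integer(n_het); b <- 0L; left <- 0L
    for (j in seq_len(n_het)) {
      if (left == 0L) {
        b <- b + 1L
        left <- sample(seq(cfg$block_sites[1L], cfg$block_sites[2L]), 1L)
      }
      block[j] <- b
      left <- left - 1L
    }
    het_rows[[i]] <- data.frame(
      scaffold = scaf_names[i], pos = pos,
      block_id = sprintf("%s_pb%03d", scaf_names[i], block),
      hap1 = hap1, hap2 = hap2, stringsAsFactors = FALSE)
  }
  het <- do.call(rbind, het_rows)

  # assembly: arbitrary pseudo-haploid choice at het sites
  set.seed(stage_seed(seed, "haploid-choice"))
  assembly_seqs <- genome0
  het$ref_is_hap1 <- runif(nrow(het)) < 0.5
  het$assembly_base <- ifelse(het$ref_is_hap1, het$hap1, het$hap2)
  for (j in seq_len(nrow(het))) {
    substr(assembly_seqs[[het$scaffold[j]]], het$pos[j], het$pos[j]) <-
      het$assembly_base[j]
  }
  hap2_seqs <- genome0
  for (j in seq_len(nrow(het))) {
    substr(hap2_seqs[[het$scaffold[j]]], het$pos[j], het$pos[j]) <- het$hap2[j]
  }

  # --- planted reference errors and genotyping decoys ------------------
  set.seed(stage_seed(seed, "errors"))
  split_even <- function(n) {
    k <- rep(n %/% ns, ns)
    if (n %% ns) k[seq_len(n %% ns)] <- k[seq_len(n %% ns)] + 1L
    k
  }
  err_rows <- list(); decoy_rows <- list()
  n_err <- split_even(cfg$n_ref_errors); n_dec <- split_even(cfg$n_decoy_sites)
  for (i in seq_len(ns)) {
    pos <- sample(which(free[[i]]), n_err[i] + n_dec[i])
    free[[i]][pos] <- FALSE
    epos <- sort(pos[seq_len(n_err[i])])
    dpos <- sort(pos[n_err[i] + seq_len(n_dec[i])])
    true_base <- substr(rep(genome0[[i]], length(epos)), epos, epos)
    wrong <- other_base(true_base)
    for (j in seq_along(epos)) {
      substr(assembly_seqs[[i]], epos[j], epos[j]) <- wrong[j]
    }
    err_rows[[i]] <- data.frame(scaffold = scaf_names[i], pos = epos,
                                assembly_base = wrong, true_base = true_base,
                                stringsAsFactors = FALSE)
    dbase <- substr(rep(genome0[[i]], length(dpos)), dpos, dpos)
    decoy_rows[[i]] <- data.frame(scaffold = scaf_names[i], pos = dpos,
                                  assembly_base = dbase,
                                  alt = other_base(dbase), stringsAsFactors = FALSE)
  }
  ref_errors <- do.call(rbind, err_rows)
  decoys <- do.call(rbind, decoy_rows)

  asm <- assembly(assembly_seqs, name = "synthetic")
  polished_truth <- assembly_seqs
  for (j in seq_len(nrow(ref_errors))) {
    substr(polished_truth[[ref_errors$scaffold[j]]],
           ref_errors$pos[j], ref_errors$pos[j]) <- ref_errors$true_base[j]
  }
  polished_truth <- assembly(polished_truth, name = "synthetic-polished")

  # primer uniqueness across the working assembly (regenerate-level check)
  subj <- Biostrings::DNAStringSet(setNames(as.character(assembly_seqs), scaf_names))
  for (p in c(markers$fwd_primer, markers$rev_primer)) {
    n_occ <- sum(Biostrings::vcountPattern(p, subj)) +
      sum(Biostrings::vcountPattern(revcomp(p), subj))
    if (n_occ != 1L) abort_input("non-unique primer in synthetic genome; change seed")
  }

  # --- polish VCF components (focal + cohort) --------------------------
  set.seed(stage_seed(seed, "polish-vcf"))
  cohort_names <- paste0("cohort", seq_len(cfg$n_cohort))
  n_het_rec <- min(10L, nrow(het))
  het_rec <- het[sort(sample(nrow(het), n_het_rec)), , drop = FALSE]
  pf <- rbind(
    data.frame(CHROM = ref_errors$scaffold, POS = ref_errors$pos,
               REF = ref_errors$assembly_base, ALT = ref_errors$true_base,
               kind = "error", stringsAsFactors = FALSE),
    data.frame(CHROM = decoys$scaffold, POS = decoys$pos,
               REF = decoys$assembly_base, ALT = decoys$alt,
               kind = "decoy", stringsAsFactors = FALSE),
    data.frame(CHROM = het_rec$scaffold, POS = het_rec$pos,
               REF = het_rec$assembly_base,
               ALT = ifelse(het_rec$ref_is_hap1, het_rec$hap2, het_rec$hap1),
               kind = "het", stringsAsFactors = FALSE)
  )
  pf <- pf[order(match(pf$CHROM, scaf_names), pf$POS), , drop = FALSE]
  gt <- matrix("0/0", nrow(pf), 1L + cfg$n_cohort,
               dimnames = list(NULL, c("focal", cohort_names)))
  gt[pf$kind == "error", "focal"] <- "1/1"
  gt[pf$kind == "error", cohort_names] <- "1/1"   # cohort lacks the erroneous allele
  gt[pf$kind == "decoy", "focal"] <- "1/1"
  gt[pf$kind == "decoy", cohort_names] <- "1/1"
  gt[pf$kind == "decoy", cohort_names[1L]] <- "0/1"  # reference allele detected
  gt[pf$kind == "het", "focal"] <- "0/1"
  polish_vcf <- list(fixed = pf[, c("CHROM", "POS", "REF", "ALT")],
                     gt = gt, kind = pf$kind, samples = colnames(gt))

  # --- phased VCF components (focal only) ------------------------------
  phased_fixed <- data.frame(
    CHROM = het$scaffold, POS = het$pos, REF = het$assembly_base,
    ALT = ifelse(het$ref_is_hap1, het$hap2, het$hap1), stringsAsFactors = FALSE)
  phased_gt <- matrix(ifelse(het$ref_is_hap1, "0|1", "1|0"),
                      ncol = 1L, dimnames = list(NULL, "focal"))
  block_first <- stats::ave(het$pos, het$block_id, FUN = min)
  phased_ps <- matrix(as.character(block_first), ncol = 1L,
                      dimnames = list(NULL, "focal"))
  phased_vcf <- list(fixed = phased_fixed, gt = phased_gt, ps = phased_ps,
                     samples = "focal")

  # --- planted inversion (misassembled copy) ---------------------------
  mk1 <- marker_truth[marker_truth$scaffold == scaf_names[1L], , drop = FALSE]
  iv <- cfg$inversion_markers
  inv_start <- mk1$amplicon_start[iv[1L]] - 5L     # 0-based
  inv_end <- mk1$amplicon_end[iv[2L]] + 5L
  inverted_seqs <- assembly_seqs
  s1 <- inverted_seqs[[1L]]
  seg <- substr(s1, inv_start + 1L, inv_end)
  substr(s1, inv_start + 1L, inv_end) <- revcomp(seg)
  inverted_seqs[[1L]] <- s1
  inversion <- list(
    scaffold = scaf_names[1L], start = inv_start, end = inv_end,
    marker_ids = mk1$id[iv[1L]:iv[2L]],
    boundary_pairs = data.frame(
      marker1 = mk1$id[c(iv[1L] - 1L, iv[2L])],
      marker2 = mk1$id[c(iv[1L], iv[2L] + 1L)], stringsAsFactors = FALSE))

  # --- microbial contaminants ------------------------------------------
  set.seed(stage_seed(seed, "contaminants"))
  sources <- setNames(
    vapply(seq_len(cfg$n_contaminants),
           function(k) random_dna(cfg$contaminant_source_len), character(1)),
    paste0("microbe", seq_len(cfg$n_contaminants)))
  contam_seqs <- assembly_seqs
  contam_ids <- character(cfg$n_contaminants)
  for (k in seq_len(cfg$n_contaminants)) {
    off <- sample(cfg$contaminant_source_len - cfg$contaminant_contig_len, 1L)
    contam_ids[k] <- paste0("contam", k)
    contam_seqs[[contam_ids[k]]] <-
      substr(sources[[k]], off + 1L, off + cfg$contaminant_contig_len)
  }
  contaminated <- assembly(contam_seqs, name = "synthetic-contaminated")

  # --- circular mitochondrial toy --------------------------------------
  set.seed(stage_seed(seed, "mito"))
  unit <- random_dna(8L)
  rep_block <- strrep(unit, cfg$mito_repeat_copies)
  body_len <- cfg$mito_length - nchar(rep_block)
  for (try in 1:100) {
    body <- random_dna(body_len)
    at <- body_len %/% 3                           # repeat sits inside, off origin
    mito_seq <- paste0(substr(body, 1L, at), rep_block,
                       substr(body, at + 1L, body_len))
    lf <- substr(mito_seq, at - cfg$mito_flank_len + 1L, at)
    rf <- substr(mito_seq, at + nchar(rep_block) + 1L,
                 at + nchar(rep_block) + cfg$mito_flank_len)
    ok <- !grepl(unit, lf, fixed = TRUE) && !grepl(unit, rf, fixed = TRUE) &&
      length(gregexpr(lf, mito_seq, fixed = TRUE)[[1L]]) == 1L &&
      length(gregexpr(rf, mito_seq, fixed = TRUE)[[1L]]) == 1L
    if (ok) break
  }
  if (!ok) abort_input("could not build mitochondrial toy; change seed")
  # starting reference: same length, a few substitutions outside the repeat
  sub_at <- sample(setdiff(seq_len(nchar(mito_seq)),
                           (at + 1L):(at + nchar(rep_block))),
                   cfg$mito_start_subs)
  ref_start <- mito_seq
  for (p in sub_at) {
    substr(ref_start, p, p) <- other_base(substr(ref_start, p, p))
  }
  spanning_read <- substr(mito_seq, at - cfg$mito_flank_len + 1L,
                          at + nchar(rep_block) + cfg$mito_flank_len)
  mito <- list(truth = mito_seq, ref_start = ref_start, unit = unit,
               copies = cfg$mito_repeat_copies, left_flank = lf,
               right_flank = rf, spanning_read = spanning_read,
               repeat_at = at, start_subs = sort(sub_at))

  structure(list(
    config = cfg, seed = seed,
    assembly = asm, haplotypes = list(hap1 = genome0, hap2 = hap2_seqs),
    gaps = gaps, het_sites = het, ref_errors = ref_errors, decoys = decoys,
    polished_truth = polished_truth,
    polish_vcf = polish_vcf, phased_vcf = phased_vcf,
    markers = markers, marker_truth = marker_truth, chromosome_of = chrom_of,
    inverted_assembly = assembly(inverted_seqs, name = "synthetic-inverted"),
    inversion = inversion,
    contaminant_sources = sources, contaminated_assembly = contaminated,
    contaminant_ids = contam_ids,
    mito = mito
  ), class = "truth_bundle")
}

#' Simulate cohort genotypes over the phased heterozygous sites
#'
#' Draws each cohort animal's two alleles per site independently: the
#' population-major haplotype's allele (haplotype 1) with probability
#' `major_freq`, otherwise haplotype 2's allele. Genotypes go missing with
#' probability `missing_rate`.
#'
#' @param truth a `truth_bundle` from [simulate_truth()].
#' @param n_animals cohort size (default 4).
#' @param major_freq population frequency of the major haplotype's alleles
#'   (default 0.9).
#' @param missing_rate per-genotype missing probability (default 0.05).
#' @param seed RNG seed for this stage.
#' @return list with `fixed` (as the bundle's phased VCF) and `gt`
#'   (character matrix, sites x animals, allele indexes relative to that
#'   fixed table) plus `samples`.
#' @export
simulate_cohort <- function(truth, n_animals = 4L, major_freq = 0.9,
                            missing_rate = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "truth_bundle"))
  if (major_freq < 0 || major_freq > 1 || missing_rate < 0 || missing_rate > 1) {
    abort_input("major_freq and missing_rate must be in [0, 1]")
  }
  set.seed(stage_seed(seed, "cohort"))
  het <- truth$het_sites
  fixed <- truth$phased_vcf$fixed
  # allele index of hap1/hap2 relative to REF/ALT
  idx_h1 <- ifelse(het$ref_is_hap1, 0L, 1L)
  idx_h2 <- 1L - idx_h1
  samples <- paste0("animal", seq_len(n_animals))
  gt <- matrix("./.", nrow(fixed), n_animals, dimnames = list(NULL, samples))
  for (a in seq_len(n_animals)) {
    for (j in seq_len(nrow(fixed))) {
      if (runif(1) < missing_rate) next
      al <- ifelse(runif(2) < major_freq, idx_h1[j], idx_h2[j])
      gt[j, a] <- paste(sort(al), collapse = "/")
    }
  }
  list(fixed = fixed, gt = gt, samples = samples)
}

#' Simulate shotgun reads from a sequence
#'
#' Uniformly placed fixed-length reads with i.i.d. substitution errors.
#' `circular = TRUE` lets reads wrap around the origin (for mitochondrial
#' toys). `paired = TRUE` emits proper FR pairs (`/1` forward, `/2` reverse
#' complemented) with a fixed insert of three read lengths. The returned
#' truth table holds every read's true position and SAM flag, so it can be
#' written with [write_sam()] and used as an alignment oracle.
#'
#' @param sequence template sequence (character scalar).
#' @param coverage target mean coverage (> 0).
#' @param error_rate per-base substitution probability (in `[0, 0.5)`).
#' @param read_len read length in bases (default 50).
#' @param paired emit FR read pairs (default FALSE).
#' @param circular allow reads to wrap the origin (default FALSE).
#' @param seed RNG seed for this stage.
#' @param rname reference name recorded in the truth table.
#' @return list with `reads` (named character vector) and `truth`
#'   (data frame: qname, flag, rname, pos, seq).
#' @export
simulate_reads <- function(sequence, coverage = 40, error_rate = 0.01,
                           read_len = 50L, paired = FALSE, circular = FALSE,
                           seed = 1L, rname = "ref") {
  if (coverage <= 0) abort_input("coverage must be positive")
  if (error_rate < 0 || error_rate >= 0.5) abort_input("error_rate must be in [0, 0.5)")
  L <- nchar(sequence)
  if (!circular && read_len > L) abort_input("read_len exceeds sequence length")
  set.seed(stage_seed(seed, "reads"))
  n <- round(coverage * L / read_len)
  if (paired && n %% 2L) n <- n + 1L

  grab <- function(start) {                        # 1-based, wraps if circular
    if (start + read_len - 1L <= L) return(substr(sequence, start, start + read_len - 1L))
    paste0(substr(sequence, start, L),
           substr(sequence, 1L, start + read_len - 1L - L))
  }
  mutate <- function(s) {
    hits <- which(runif(read_len) < error_rate)
    for (p in hits) substr(s, p, p) <- other_base(substr(s, p, p))
    s
  }

  if (!paired) {
    starts <- if (circular) sample(L, n, replace = TRUE) else
      sample(L - read_len + 1L, n, replace = TRUE)
    reads <- vapply(starts, function(s) mutate(grab(s)), character(1))
    qn <- sprintf("read%05d", seq_len(n))
    truth <- data.frame(qname = qn, flag = 0L, rname = rname, pos = starts,
                        seq = reads, stringsAsFactors = FALSE)
    return(list(reads = setNames(reads, qn), truth = truth))
  }

  insert <- 3L * read_len
  n_frag <- n %/% 2L
  max_start <- if (circular) L else L - insert + 1L
  if (max_start < 1L) abort_input("sequence too short for paired inserts")
  fstart <- sample(max_start, n_frag, replace = TRUE)
  r1 <- vapply(fstart, function(s) mutate(grab(s)), character(1))
  m2start <- ((fstart + insert - read_len - 1L) %% L) + 1L
  r2 <- vapply(m2start, function(s) mutate(revcomp(grab(s))), character(1))
  qn <- sprintf("frag%05d", seq_len(n_frag))
  truth <- rbind(
    data.frame(qname = qn, flag = 0x1 + 0x2 + 0x40 + 0x20, rname = rname,
               pos = fstart, seq = r1, stringsAsFactors = FALSE),
    data.frame(qname = qn, flag = 0x1 + 0x2 + 0x80 + 0x10, rname = rname,
               pos = m2start, seq = r2, stringsAsFactors = FALSE))
  truth <- truth[order(truth$qname), , drop = FALSE]
  rownames(truth) <- NULL
  list(reads = setNames(c(rbind(r1, r2)), paste0(rep(qn, each = 2L), c("/1", "/2"))),
       truth = truth)
}

#' Write the synthetic bundle's pipeline inputs to a directory
#'
#' Emits the file formats the pipeline consumes: working/inverted/
#' contaminated assemblies and microbial sources as FASTA, polish and phased
#' VCFs, the marker table and truth tables as TSV, and the mitochondrial
#' truth/starting reference as FASTA.
#'
#' @param truth a `truth_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_assembly_fasta(truth$assembly, fp("assembly.fa"))
  write_assembly_fasta(truth$inverted_assembly, fp("assembly_inverted.fa"))
  write_assembly_fasta(truth$contaminated_assembly, fp("assembly_contaminated.fa"))
  write_assembly_fasta(assembly(truth$contaminant_sources, name = "microbes"),
                       fp("microbial_sources.fa"))
  lens <- scaffold_lengths(truth$assembly)
  write_vcf(fp("polish.vcf"), truth$polish_vcf$fixed, truth$polish_vcf$gt,
            contigs = lens)
  write_vcf(fp("phased.vcf"), truth$phased_vcf$fixed, truth$phased_vcf$gt,
            ps = truth$phased_vcf$ps, contigs = lens)
  tsv <- function(d, name) write.table(d, fp(name), sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  tsv(truth$markers, "markers.tsv")
  tsv(truth$marker_truth, "marker_truth.tsv")
  tsv(truth$ref_errors, "ref_errors.tsv")
  tsv(truth$het_sites, "het_sites.tsv")
  tsv(truth$gaps, "gaps.tsv")
  writeLines(c(">mito_truth", truth$mito$truth), fp("mito_truth.fa"))
  writeLines(c(">mito_ref_start", truth$mito$ref_start), fp("mito_ref_start.fa"))
  invisible(dir)
}
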