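# STS marker placement, chromosome assignment and concordance.

toy_marker <- function(fwd, rev, chrom = "chr1", pos = 1, id = "m1") {
  data.frame(id = id, map_chromosome = chrom, map_position = pos,
             fwd_primer = fwd, rev_primer = rev, stringsAsFactors = FALSE)
}

test_that("placement needs unique inward-facing primer hits within the size limit", {
  set.seed(21)
  fwd <- random_dna(20); rev <- random_dna(20)
  pad <- function(n) random_dna(n)
  # FWD ... 30 bp ... revcomp(REV): amplicon 20+30+20 = 70
  g <- assembly(c(s1 = paste0(pad(40), fwd, pad(30), revcomp(rev), pad(40))))
  hit <- place_markers(toy_marker(fwd, rev), g)
  expect_equal(hit$status, "placed")
  expect_equal(hit$amplicon_end - hit$amplicon_start, 70)
  expect_equal(hit$strand, "+")
  expect_equal(hit$position, hit$amplicon_start + 35)

  dup <- assembly(c(s1 = paste0(fwd, pad(30), revcomp(rev), pad(20), fwd)))
  expect_equal(place_markers(toy_marker(fwd, rev), dup)$status, "non_unique")

  out <- assembly(c(s1 = paste0(pad(30), fwd, pad(30), rev, pad(30))))
  expect_equal(place_markers(toy_marker(fwd, rev), out)$status, "bad_orientation")

  none <- assembly(c(s1 = paste0(pad(30), fwd, pad(30))))
  expect_equal(place_markers(toy_marker(fwd, rev), none)$status, "missing_primer")

  far <- assembly(c(s1 = paste0(fwd, pad(2000), revcomp(rev))))
  expect_equal(place_markers(toy_marker(fwd, rev), far)$status, "oversized")
  expect_equal(place_markers(toy_marker(fwd, rev), far,
                             max_amplicon = 3000)$status, "placed")
})

test_that("placement is strand-symmetric under whole-assembly reverse complement", {
  tr <- shared_truth()
  fwd_hits <- place_markers(tr$markers, tr$assembly)
  rc <- assembly(setNames(revcomp(as.character(tr$assembly)),
                          names(tr$assembly)))
  rc_hits <- place_markers(tr$markers, rc)
  expect_equal(rc_hits$status, fwd_hits$status)
  expect_equal(rc_hits$amplicon_end - rc_hits$amplicon_start,
               fwd_hits$amplicon_end - fwd_hits$amplicon_start)
  placed <- fwd_hits$status == "placed"
  expect_true(all(rc_hits$strand[placed] != fwd_hits$strand[placed]))
})

test_that("scaffolds are assigned by marker majority with map-order and orientation", {
  markers <- data.frame(
    id = paste0("m", 1:7),
    map_chromosome = c("chr1", "chr1", "chr2", "chr1", "chr1", "chr1", "chr1"),
    map_position = c(1, 2, 1, 10, 11, 12, 13),
    fwd_primer = "A", rev_primer = "A", stringsAsFactors = FALSE)
  hits <- data.frame(
    id = paste0("m", 1:7), status = "placed",
    scaffold = c("sA", "sA", "sA", "sB", "sB", "sB", "sB"),
    amplicon_start = 0L, amplicon_end = 0L,
    position = c(100, 200, 300, 400, 300, 200, 100),
    strand = "+", stringsAsFactors = FALSE)
  asn <- assign_scaffolds(hits, markers)
  expect_equal(asn$chromosome[asn$scaffold == "sA"], "chr1")  # 2-vs-1 majority
  expect_equal(asn$orientation[asn$scaffold == "sB"], "-")    # map up, coords down
  # order along chr1 follows median map position: sA (1.5) before sB (11.5)
  chr1 <- asn[which(asn$chromosome == "chr1"), ]
  expect_equal(chr1$scaffold[order(chr1$order_index)], c("sA", "sB"))
})

test_that("pair concordance distinguishes concordant, misoriented and unassessable", {
  markers <- data.frame(id = c("m1", "m2", "m3"), map_chromosome = "chr1",
                        map_position = 1:3, fwd_primer = "A", rev_primer = "A",
                        stringsAsFactors = FALSE)
  pl <- data.frame(id = c("m1", "m2", "m3"), coord = c(100, 200, NA),
                   strand = c("+", "+", NA), stringsAsFactors = FALSE)
  conc <- pair_concordance(markers, pl)
  expect_equal(conc$status, c("concordant", "unassessable"))

  pl$coord <- c(200, 100, NA)
  expect_equal(pair_concordance(markers, pl)$status[1], "misoriented")

  # order-only semantics when strand information is withheld
  pl2 <- data.frame(id = c("m1", "m2", "m3"), coord = c(100, 200, 300),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  expect_equal(pair_concordance(markers, pl2, strands = NULL)$status,
               c("concordant", "concordant"))
  expect_equal(pair_concordance(markers, pl2)$status,
               c("misoriented", "misoriented"))
})

test_that("a planted inversion is flagged at exactly its two boundary pairs", {
  tr <- shared_truth()
  run <- function(asm) {
    hits <- place_markers(tr$markers, asm)
    asn <- assign_scaffolds(hits, tr$markers)
    pl <- marker_global_coords(hits, asn, tr$markers, asm)
    pair_concordance(tr$markers, pl)
  }
  clean <- run(tr$assembly)
  expect_true(all(clean$status == "concordant"))
  inv <- run(tr$inverted_assembly)
  mis <- inv[inv$status == "misoriented", ]
  expect_equal(nrow(mis), 2)
  expect_equal(mis$marker1, tr$inversion$boundary_pairs$marker1)
  expect_equal(mis$marker2, tr$inversion$boundary_pairs$marker2)
})

test_that("cross-assembly partition counts are disjoint and reconcile to totals", {
  set.seed(3)
  status_a <- sample(c("concordant", "misoriented", "unassessable"), 200,
                     replace = TRUE, prob = c(0.6, 0.2, 0.2))
  status_b <- sample(c("concordant", "misoriented", "unassessable"), 200,
                     replace = TRUE, prob = c(0.6, 0.2, 0.2))
  mk <- function(st) data.frame(chromosome = "chr1",
                                marker1 = sprintf("m%03d", 1:200),
                                marker2 = sprintf("m%03d", 2:201),
                                status = st, stringsAsFactors = FALSE)
  pc <- cross_assembly_partition(mk(status_a), mk(status_b))
  expect_equal(pc$misoriented_b,
               pc$both_misoriented + pc$b_only_a_concordant + pc$b_only_a_unassessable)
  expect_equal(pc$misoriented_a,
               pc$both_misoriented + pc$a_only_b_concordant + pc$a_only_b_unassessable)
  expect_equal(pc$b_only_total, pc$b_only_a_concordant + pc$b_only_a_unassessable)
  expect_error(cross_assembly_partition(mk(status_a)[1:100, ], mk(status_b)),
               "universe")
})
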