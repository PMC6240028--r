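# Iterative reference-guided consensus for a circular mitochondrial genome.
#
# Reads are aligned each round against the current consensus, doubled to
# handle circularity (a read crossing the origin aligns contiguously to the
# doubled sequence; its columns are folded back modulo the genome length).
# Per-site base counts feed a coverage/agreement filter: a site keeps its
# majority base only with >= 10-fold coverage and >= 90% agreement,
# otherwise it becomes N. The updated consensus seeds the next round, and
# iteration stops early at a fixed point.

#' Consensus call for one site
#'
#' Returns the majority base iff coverage (total of base and deletion
#' counts) is at least `min_cov` and the majority base's fraction of the
#' coverage is at least `min_frac`; otherwise N. Deletion-majority sites and
#' exact 50/50 ties also yield N (the consensus is substitution-only). The
#' call depends only on count proportions above the coverage threshold, so
#' scaling all counts by a positive integer never changes it.
#'
#' @param counts named numeric vector with elements A, C, G, T and
#'   optionally `del` (deleted-base observations).
#' @param min_cov minimum coverage (default 10).
#' @param min_frac minimum majority fraction (default 0.90).
#' @return single character: "A", "C", "G", "T" or "N".
#' @examples
#' consensus_call(c(A = 9, C = 0, G = 0, T = 0))          # "N": coverage 9
#' consensus_call(c(A = 9, C = 0, G = 1, T = 0))          # "A": 10x, 90%
#' @export
consensus_call <- function(counts, min_cov = 10L, min_frac = 0.90) {
  bases <- c("A", "C", "G", "T")
  b <- counts[bases]
  b[is.na(b)] <- 0
  del <- if ("del" %in% names(counts)) counts[["del"]] else 0
  cov <- sum(b) + del
  if (cov < min_cov) return("N")
  top <- max(b)
  if (del >= top) return("N")                  # deletion-majority or tie
  if (sum(b == top) > 1L) return("N")          # tied bases cannot reach 90%
  if (top / cov < min_frac) return("N")
  bases[which.max(b)]
}

#' Built-in local aligner (aligner-contract reference implementation)
#'
#' Aligns each read locally against a subject sequence with match +1,
#' mismatch -1 and gap -2 scoring, via [Biostrings::pairwiseAlignment()].
#' Any function with this signature and return shape can replace it in
#' [iterate_consensus()] — e.g. one that replays pre-computed SAM
#' alignments.
#'
#' @param reads character vector of read sequences.
#' @param subject subject sequence (character scalar; for circular targets
#'   the caller passes the doubled sequence).
#' @return data frame with one row per read: `start` (1-based subject
#'   position of the alignment), `pattern` and `subject` (aligned strings of
#'   equal length, gaps as '-').
#' @export
align_local <- function(reads, subject) {
  letters5 <- c("A", "C", "G", "T", "N")
  mat <- matrix(-1, 5, 5, dimnames = list(letters5, letters5))
  diag(mat) <- 1
  mat["N", ] <- -1; mat[, "N"] <- -1           # N matches nothing, not even N
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  data.frame(
    start = IRanges::start(Biostrings::subject(aln)),
    pattern = as.character(Biostrings::alignedPattern(aln)),
    subject = as.character(Biostrings::alignedSubject(aln)),
    stringsAsFactors = FALSE
  )
}

# Tally per-site counts (A,C,G,T,del) over a subject of length L2 from a
# set of alignments in align_local() shape.
tally_alignments <- function(aln, L2) {
  counts <- matrix(0L, nrow = 5L, ncol = L2,
                   dimnames = list(c("A", "C", "G", "T", "del"), NULL))
  for (i in seq_len(nrow(aln))) {
    p <- strsplit(aln$pattern[i], "")[[1L]]
    s <- strsplit(aln$subject[i], "")[[1L]]
    pos <- aln$start[i]
    for (j in seq_along(s)) {
      if (s[j] == "-") next                    # insertion in read: no column
      if (p[j] == "-") {
        counts["del", pos] <- counts["del", pos] + 1L
      } else if (p[j] %in% c("A", "C", "G", "T")) {
        counts[p[j], pos] <- counts[p[j], pos] + 1L
      }
      pos <- pos + 1L
    }
  }
  counts
}

#' Iterative reference-guided circular consensus
#'
#' Each round doubles the current reference to linearise the circle, aligns
#' all reads with the supplied aligner, folds alignment columns back onto
#' the circle (column p maps to `((p - 1) mod L) + 1`), tallies per-site
#' base and deletion counts, and calls each site with [consensus_call()].
#' The called sequence becomes the next round's reference; iteration stops
#' early when a round leaves the consensus unchanged.
#'
#' @param reads character vector of read sequences.
#' @param reference starting reference (character scalar).
#' @param rounds maximum refinement rounds (default 3; the reference-update
#'   schedule of a two-stage reassembly plus one verification pass).
#' @param min_cov,min_frac site filter passed to [consensus_call()].
#' @param aligner function with the [align_local()] contract.
#' @return list with `consensus` (character scalar, N at filtered sites),
#'   `track` (per-site data frame: pos, A, C, G, T, del, coverage,
#'   agreement, call) and `rounds_run`.
#' @export
iterate_consensus <- function(reads, reference, rounds = 3L,
                              min_cov = 10L, min_frac = 0.90,
                              aligner = align_local) {
  L <- nchar(reference)
  if (length(reads) == 0L) {
    warning("no reads supplied; consensus is all N")
    track <- data.frame(pos = seq_len(L), A = 0L, C = 0L, G = 0L, T = 0L,
                        del = 0L, coverage = 0L, agreement = NA_real_,
                        call = "N")
    return(list(consensus = strrep("N", L), track = track, rounds_run = 0L))
  }
  cur <- toupper(reference)
  folded <- NULL
  r_used <- 0L
  for (r in seq_len(rounds)) {
    r_used <- r
    doubled <- paste0(cur, cur)
    aln <- aligner(reads, doubled)
    counts <- tally_alignments(aln, nchar(doubled))
    folded <- counts[, seq_len(L), drop = FALSE] +
      counts[, L + seq_len(L), drop = FALSE]
    calls <- vapply(seq_len(L), function(p) {
      consensus_call(c(folded[1:4, p], del = folded["del", p]),
                     min_cov = min_cov, min_frac = min_frac)
    }, character(1))
    new <- paste(calls, collapse = "")
    if (identical(new, cur)) break
    cur <- new
  }
  cov <- colSums(folded)
  top <- apply(folded[1:4, , drop = FALSE], 2L, max)
  track <- data.frame(pos = seq_len(L),
                      A = folded["A", ], C = folded["C", ],
                      G = folded["G", ], T = folded["T", ],
                      del = folded["del", ],
                      coverage = cov,
                      agreement = ifelse(cov > 0, top / cov, NA_real_),
                      call = strsplit(cur, "")[[1L]])
  list(consensus = cur, track = track, rounds_run = r_used)
}

#' Adjudicate the copy number of a tandem repeat from one spanning read
#'
#' Given a read that contains the unique left and right flanking anchors of
#' a tandem-repeat region, counts how many whole copies of the repeat unit
#' lie between them. The interior must be an exact integral tandem of the
#' unit; otherwise the adjudication fails (reported, no update). A flank
#' that is missing or occurs more than once violates the precondition and
#' raises an error.
#'
#' @param read the spanning read sequence (character scalar).
#' @param left_flank,right_flank anchor sequences, each occurring exactly
#'   once in the read, left before right; neither may contain the unit.
#' @param unit the repeat unit (8 bases).
#' @return list with `copy_number` (integer, NA on failure) and `status`
#'   ("ok" or "failure").
#' @export
adjudicate_repeat_count <- function(read, left_flank, right_flank, unit) {
  if (nchar(unit) != 8L) abort_input("repeat unit must be 8 bases")
  if (grepl(unit, left_flank, fixed = TRUE) ||
      grepl(unit, right_flank, fixed = TRUE)) {
    abort_input("flank contains the repeat unit; anchors are ambiguous")
  }
  locate <- function(anchor, label) {
    m <- gregexpr(anchor, read, fixed = TRUE)[[1L]]
    if (m[1L] == -1L || length(m) != 1L) {
      abort_input("%s flank must occur exactly once in the spanning read", label)
    }
    c(start = as.integer(m), end = as.integer(m) + nchar(anchor) - 1L)
  }
  lf <- locate(left_flank, "left")
  rf <- locate(right_flank, "right")
  if (lf[["end"]] >= rf[["start"]]) {
    abort_input("left flank must precede the right flank in the read")
  }
  interior <- substr(read, lf[["end"]] + 1L, rf[["start"]] - 1L)
  n <- nchar(interior) / nchar(unit)
  if (n != as.integer(n) || !identical(interior, strrep(unit, n))) {
    return(list(copy_number = NA_integer_, status = "failure"))
  }
  list(copy_number = as.integer(n), status = "ok")
}
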