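# Exact k-mer contamination screening.
#
# Microbial reference sequences are low-complexity-masked with a DUST-style
# triplet score, decomposed into canonical 32-mers, and any assembly contig
# sharing at least one exact canonical 32-mer with the microbial set is
# flagged as a contaminant. Matching is exact and strand-canonical: every
# stored k-mer is the lexicographic minimum of itself and its reverse
# complement, so screening is invariant under reverse-complementing either
# side. Membership is an exact hash-set lookup — at the scale of assembly
# contigs vs. reference databases there is no need for probabilistic
# structures, and exactness is the point of the rule.

#' DUST-style low-complexity masking
#'
#' Slides a window along the sequence and scores each window by
#' over-representation of nucleotide triplets:
#' `S = sum(c_t * (c_t - 1) / 2) / (n_trip - 1)` over triplet counts `c_t`,
#' with `n_trip = window - 2` triplets per window. Windows scoring strictly
#' above `threshold` are masked and overlapping masked windows are merged.
#' A threshold of 2.0 on this score approximates the default masking level
#' of the standard DUST implementation (which scales scores by 10);
#' exactness against that binary is not claimed. Triplets containing N do
#' not count toward the score. Sequences shorter than the window are scored
#' as a single window when at least 5 bases long.
#'
#' @param sequence character scalar (ACGTN).
#' @param window window width in bases (default 64; must be >= 3).
#' @param threshold mask windows with score strictly greater than this
#'   (default 2.0).
#' @return data frame of merged mask intervals: `start`, `end` (0-based
#'   half-open).
#' @examples
#' dust_mask(strrep("A", 64))         # fully masked
#' dust_mask(strrep("ACGT", 16))      # period-4 repeat: masked
#' @export
dust_mask <- function(sequence, window = 64L, threshold = 2.0) {
  if (window < 3L) abort_input("window must be >= 3")
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  none <- data.frame(start = integer(0), end = integer(0))
  if (L < 5L) return(none)
  w <- min(window, L)
  base <- match(strsplit(sequence, "")[[1L]], c("A", "C", "G", "T"))
  n_tri <- L - 2L
  tri <- 16L * (base[seq_len(n_tri)] - 1L) +
    4L * (base[seq_len(n_tri) + 1L] - 1L) +
    (base[seq_len(n_tri) + 2L] - 1L) + 1L       # NA when any base is N
  w_tri <- w - 2L                               # triplets per window
  denom <- w_tri - 1L
  if (denom < 1L) return(none)

  counts <- integer(64L)
  sum_pairs <- 0                                # sum of c*(c-1)/2
  add <- function(t) {
    if (!is.na(t)) {
      sum_pairs <<- sum_pairs + counts[t]
      counts[t] <<- counts[t] + 1L
    }
  }
  drop <- function(t) {
    if (!is.na(t)) {
      counts[t] <<- counts[t] - 1L
      sum_pairs <<- sum_pairs - counts[t]
    }
  }
  for (i in seq_len(w_tri)) add(tri[i])
  n_win <- L - w + 1L
  masked <- logical(n_win)
  masked[1L] <- sum_pairs / denom > threshold
  if (n_win > 1L) {
    for (s in 2:n_win) {
      drop(tri[s - 1L])
      add(tri[s + w_tri - 1L])
      masked[s] <- sum_pairs / denom > threshold
    }
  }
  if (!any(masked)) return(none)
  ir <- IRanges::reduce(IRanges::IRanges(start = which(masked), width = w))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# Canonical form of a k-mer vector: lexicographic min of k-mer and its
# reverse complement. K-mers containing N return NA.
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  has_n <- grepl("N", kmers, fixed = TRUE)
  out <- rep(NA_character_, length(kmers))
  if (any(!has_n)) {
    km <- kmers[!has_n]
    rc <- revcomp(km)
    out[!has_n] <- ifelse(km <= rc, km, rc)
  }
  out
}

# All k-mers of one sequence as a character vector (empty when too short).
seq_kmers <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  substring(sequence, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' Build a canonical k-mer database from reference sequences
#'
#' Masks each input sequence for low complexity (unless precomputed masks
#' are supplied), then stores every canonical k-mer that lies fully inside
#' an unmasked stretch. K-mers containing N are skipped.
#'
#' @param sequences named character vector of reference sequences (e.g. a
#'   microbial reference set read with [read_assembly_fasta()]).
#' @param k k-mer size (default 32).
#' @param masks optional list of mask-interval data frames (as from
#'   [dust_mask()]), one per sequence, named like `sequences`; when NULL,
#'   [dust_mask()] is run on each sequence.
#' @param dust_window,dust_threshold parameters passed to [dust_mask()].
#' @return a `kmer_db` object: list with `k`, `kmers` (sorted unique
#'   canonical k-mers), `source` (parallel vector: which input sequence each
#'   stored k-mer first came from) and `source_counts`.
#' @export
build_kmer_db <- function(sequences, k = 32L, masks = NULL,
                          dust_window = 64L, dust_threshold = 2.0) {
  sequences <- toupper(unlist(sequences))
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  all_kmers <- character(0)
  all_src <- character(0)
  source_counts <- setNames(integer(length(sequences)), names(sequences))
  for (nm in names(sequences)) {
    s <- sequences[[nm]]
    m <- if (is.null(masks)) dust_mask(s, window = dust_window,
                                       threshold = dust_threshold) else masks[[nm]]
    # unmasked intervals (0-based half-open)
    if (is.null(m) || nrow(m) == 0L) {
      um <- data.frame(start = 0L, end = nchar(s))
    } else {
      keep <- IRanges::gaps(IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end)),
                            start = 1L, end = nchar(s))
      um <- data.frame(start = IRanges::start(keep) - 1L, end = IRanges::end(keep))
    }
    for (j in seq_len(nrow(um))) {
      piece <- substr(s, um$start[j] + 1L, um$end[j])
      km <- canonical_kmers(seq_kmers(piece, k))
      km <- unique(km[!is.na(km)])
      source_counts[[nm]] <- source_counts[[nm]] + length(km)
      new <- !(km %in% all_kmers)
      all_kmers <- c(all_kmers, km[new])
      all_src <- c(all_src, rep(nm, sum(new)))
    }
  }
  ord <- order(all_kmers)
  structure(list(k = as.integer(k), kmers = all_kmers[ord],
                 source = all_src[ord], source_counts = source_counts),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("<kmer_db> k=%d, %d canonical k-mers from %d sources\n",
              x$k, length(x$kmers), length(x$source_counts)))
  invisible(x)
}

#' Screen assembly contigs against a contaminant k-mer database
#'
#' Segments every scaffold into contigs (N-runs of at least `min_gap` are
#' gaps) and flags any contig sharing at least one exact canonical k-mer
#' with the database. By default a flagged contig inside a multi-contig
#' scaffold is replaced by an equal-length run of N, preserving scaffold
#' coordinates, while a scaffold consisting of a single flagged contig is
#' dropped entirely. With `drop = TRUE`, flagged contigs are excised from
#' their scaffolds instead (scaffolds left empty are dropped).
#'
#' @param asm an [assembly()].
#' @param db a `kmer_db` from [build_kmer_db()].
#' @param min_gap minimum N-run length treated as a gap (default 25).
#' @param drop excise flagged contigs instead of masking them (default
#'   FALSE).
#' @return list with `flags` (data frame: scaffold, start, end,
#'   first_match_offset — 0-based offset of the first matching k-mer within
#'   the contig — and matched_source) and `assembly` (the filtered
#'   assembly).
#' @export
screen_contigs <- function(asm, db, min_gap = 25L, drop = FALSE) {
  stopifnot(inherits(db, "kmer_db"))
  flags <- list()
  seqs <- unclass(asm)
  keep_scaffold <- rep(TRUE, length(seqs))
  names(keep_scaffold) <- names(seqs)
  for (nm in names(seqs)) {
    seg <- segment_contigs(seqs[[nm]], min_gap = min_gap, name = nm)
    ctg <- seg$contigs
    flagged_rows <- logical(nrow(ctg))
    for (j in seq_len(nrow(ctg))) {
      piece <- substr(seqs[[nm]], ctg$start[j] + 1L, ctg$end[j])
      km <- canonical_kmers(seq_kmers(piece, db$k))
      hit <- match(km, db$kmers)
      first <- which(!is.na(hit))[1L]
      if (!is.na(first)) {
        flagged_rows[j] <- TRUE
        flags[[length(flags) + 1L]] <- data.frame(
          scaffold = nm, start = ctg$start[j], end = ctg$end[j],
          first_match_offset = first - 1L,
          matched_source = db$source[hit[first]], stringsAsFactors = FALSE)
      }
    }
    if (!any(flagged_rows)) next
    if (all(flagged_rows) && nrow(ctg) == 1L && !drop) {
      keep_scaffold[[nm]] <- FALSE
    } else if (drop) {
      keep <- sort(c(which(!flagged_rows)))
      parts <- character(0)
      # retain unflagged contigs and the gaps between retained material
      for (j in keep) parts <- c(parts, substr(seqs[[nm]], ctg$start[j] + 1L, ctg$end[j]))
      new_seq <- paste(parts, collapse = strrep("N", min_gap))
      if (nchar(new_seq) == 0L) keep_scaffold[[nm]] <- FALSE else seqs[[nm]] <- new_seq
    } else {
      for (j in which(flagged_rows)) {
        substr(seqs[[nm]], ctg$start[j] + 1L, ctg$end[j]) <-
          strrep("N", ctg$length[j])
      }
    }
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(scaffold = character(0), start = integer(0), end = integer(0),
               first_match_offset = integer(0), matched_source = character(0))
  rownames(flags) <- NULL
  list(flags = flags,
       assembly = assembly(seqs[keep_scaffold],
                           name = attr(asm, "name") %||% "assembly"))
}
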