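# Assembly container and contiguity accounting.
#
# An assembly is a named character vector of upper-case A/C/G/T/N sequences
# (one element per scaffold) carrying class "assembly". Coordinates are
# 0-based half-open everywhere in this package; 1-based only at VCF
# boundaries, where conversion happens at I/O.

#' Construct an assembly from scaffold sequences
#'
#' Validates and normalises a set of scaffold sequences into the package's
#' assembly container. Sequences are upper-cased; any character outside
#' A, C, G, T, N is rejected with an error naming the scaffold and offending
#' position. Lower-case input is accepted and upper-cased; IUPAC ambiguity
#' codes other than N are rejected rather than silently converted, because
#' every downstream step (segmentation, k-mer screening, polishing) assumes
#' the ACGTN alphabet.
#'
#' @param sequences named character vector of nucleotide strings; names are
#'   scaffold names and must be unique.
#' @param name optional label for the assembly.
#' @return an `assembly` object (named character vector, attribute `name`).
#' @examples
#' asm <- assembly(c(s1 = "ACGTNNNNACGT", s2 = "GGCC"))
#' scaffold_lengths(asm)
#' @export
assembly <- function(sequences, name = "assembly") {
  if (length(sequences) == 0L) {
    out <- character(0)
    attr(out, "name") <- name
    class(out) <- "assembly"
    return(out)
  }
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    abort_input("every scaffold must be named")
  }
  if (anyDuplicated(names(sequences))) {
    abort_input("duplicate scaffold name: %s",
                names(sequences)[anyDuplicated(names(sequences))])
  }
  seqs <- toupper(as.character(sequences))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort_input("scaffold '%s' contains non-ACGTN character '%s' at position %d",
                names(sequences)[i], substr(seqs[i], bad[i], bad[i]), bad[i])
  }
  out <- setNames(seqs, names(sequences))
  attr(out, "name") <- name
  class(out) <- "assembly"
  out
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s'> %d scaffolds, %s bp total\n",
              attr(x, "name") %||% "assembly", length(x),
              format(sum(nchar(x)), big.mark = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
as.character.assembly <- function(x, ...) {
  out <- unclass(x)
  attr(out, "name") <- NULL
  out
}

#' Scaffold lengths of an assembly
#' @param asm an [assembly()].
#' @return named integer vector of sequence lengths.
#' @export
scaffold_lengths <- function(asm) {
  setNames(nchar(unclass(asm)), names(asm))
}

#' Segment a scaffold into contigs and gaps
#'
#' Splits a scaffold at runs of N of length at least `min_gap`; shorter
#' N-runs are treated as sequence and stay inside contigs, matching the
#' convention that gaps under the minimum-gap threshold are ignored when
#' computing contig statistics. Contigs and gaps tile the scaffold:
#' concatenating them in coordinate order reproduces the input sequence.
#'
#' @param sequence a single scaffold sequence (character scalar, ACGTN).
#' @param min_gap minimum N-run length that counts as a gap (default 25).
#' @param name scaffold label recorded in the output tables.
#' @return list with two data frames, `contigs` and `gaps`, each with
#'   columns `scaffold`, `start`, `end` (0-based half-open), `length`.
#' @examples
#' segment_contigs(paste0("ACGT", strrep("N", 25), "ACGT"))
#' @export
segment_contigs <- function(sequence, min_gap = 25L, name = "scaffold") {
  stopifnot(length(sequence) == 1L)
  if (min_gap < 1L) abort_input("min_gap must be >= 1")
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L) {
    abort_input("scaffold '%s' contains non-ACGTN character at position %d",
                name, bad)
  }
  empty <- function() {
    data.frame(scaffold = character(0), start = integer(0),
               end = integer(0), length = integer(0))
  }
  L <- nchar(sequence)
  if (L == 0L) return(list(contigs = empty(), gaps = empty()))

  m <- gregexpr("N+", sequence)[[1L]]
  if (m[1L] == -1L) {
    runs_start <- integer(0); runs_len <- integer(0)
  } else {
    runs_start <- as.integer(m) - 1L            # to 0-based
    runs_len <- attr(m, "match.length")
  }
  keep <- runs_len >= min_gap
  gap_start <- runs_start[keep]
  gap_end <- gap_start + runs_len[keep]

  # contigs are the complement of the gaps
  bounds <- c(0L, rbind(gap_start, gap_end), L)
  cs <- bounds[seq(1L, length(bounds) - 1L, by = 2L)]
  ce <- bounds[seq(2L, length(bounds), by = 2L)]
  nonempty <- ce > cs
  cs <- cs[nonempty]; ce <- ce[nonempty]

  list(
    contigs = data.frame(scaffold = rep(name, length(cs)), start = cs,
                         end = ce, length = ce - cs),
    gaps = data.frame(scaffold = rep(name, length(gap_start)),
                      start = gap_start, end = gap_end,
                      length = gap_end - gap_start)
  )
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length >= L sum to at least
#' half the total length. When half the total is reached exactly at a
#' sequence boundary, the sequence reaching the threshold defines the N50
#' (a `>=` comparison on the cumulative sum).
#'
#' @param lengths positive numeric vector of sequence lengths.
#' @return the N50 (same units as `lengths`).
#' @examples
#' n50(c(40, 30, 20, 10)) # 30
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) abort_input("n50 of an empty length set is undefined")
  if (any(lengths <= 0)) abort_input("all lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Contiguity and composition statistics for an assembly
#'
#' Computes contig and scaffold N50, counts of contigs/scaffolds, the gap
#' census over threshold gaps (N-runs of length >= `min_gap`), the count of
#' non-N bases, and the GC fraction of non-N bases. Scaffold length is the
#' full sequence length, N bases included. Sub-threshold N-runs count
#' toward neither gaps nor non-N bases.
#'
#' @param asm an [assembly()].
#' @param min_gap minimum N-run length that counts as a gap (default 25).
#' @return one-row data frame with columns `contig_n50`, `scaffold_n50`,
#'   `contig_count`, `scaffold_count`, `gap_count`, `gap_bases`,
#'   `non_n_bases`, `gc_fraction`, `gc_undefined`. On an assembly with no
#'   non-N bases, `gc_fraction` is reported as 0 with `gc_undefined = TRUE`.
#' @export
assembly_stats <- function(asm, min_gap = 25L) {
  segs <- lapply(names(asm), function(nm) {
    segment_contigs(unclass(asm)[[nm]], min_gap = min_gap, name = nm)
  })
  contig_lengths <- unlist(lapply(segs, function(s) s$contigs$length))
  gaps <- do.call(rbind, lapply(segs, `[[`, "gaps"))
  slen <- scaffold_lengths(asm)

  base_tab <- colSums(do.call(rbind, lapply(unclass(asm), function(s) {
    counts <- table(factor(strsplit(s, "")[[1L]], levels = c("A", "C", "G", "T", "N")))
    as.integer(counts)
  })))
  names(base_tab) <- c("A", "C", "G", "T", "N")
  non_n <- sum(base_tab[c("A", "C", "G", "T")])
  gc_undef <- non_n == 0L
  gc <- if (gc_undef) 0 else unname((base_tab[["G"]] + base_tab[["C"]]) / non_n)

  data.frame(
    contig_n50 = if (length(contig_lengths)) n50(contig_lengths) else 0,
    scaffold_n50 = if (length(slen)) n50(slen) else 0,
    contig_count = length(contig_lengths),
    scaffold_count = length(asm),
    gap_count = if (is.null(gaps)) 0L else nrow(gaps),
    gap_bases = if (is.null(gaps)) 0L else sum(gaps$length),
    non_n_bases = non_n,
    gc_fraction = gc,
    gc_undefined = gc_undef
  )
}

#' Remove scaffolds below a minimum length
#'
#' Drops every scaffold strictly smaller than `min_len` bases (a scaffold of
#' exactly `min_len` is retained). Retained scaffold order is preserved.
#'
#' @param asm an [assembly()].
#' @param min_len minimum retained scaffold length in bases (default 3000).
#' @return list with `assembly` (the filtered assembly) and `removed`
#'   (data frame of removed scaffold names and lengths).
#' @export
filter_small_scaffolds <- function(asm, min_len = 3000L) {
  if (min_len < 0L) abort_input("min_len must be >= 0")
  len <- scaffold_lengths(asm)
  drop <- len < min_len
  list(
    assembly = assembly(unclass(asm)[!drop], name = attr(asm, "name") %||% "assembly"),
    removed = data.frame(scaffold = names(asm)[drop],
                         length = unname(len[drop]))
  )
}

#' Read an assembly from a FASTA file
#' @param path FASTA file (multi-line records, any wrap width).
#' @param name label for the assembly (defaults to the file name).
#' @return an [assembly()].
#' @export
read_assembly_fasta <- function(path, name = basename(path)) {
  if (!file.exists(path)) abort_input("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  assembly(setNames(as.character(ss), names(ss)), name = name)
}

#' Write an assembly to a FASTA file (60-column wrap)
#' @param asm an [assembly()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(asm, path) {
  ss <- Biostrings::DNAStringSet(setNames(as.character(unclass(asm)), names(asm)))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
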