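# Radiation-hybrid-map marker placement and concordance.
#
# STS markers from a physical map are located on an assembly by exact
# matching of their primer pairs (a stand-in for exact super-maximal primer
# alignment: primers are short and matched exactly, so unique hits behave
# identically). A marker is placed only when both primers occur exactly once
# genome-wide, on the same scaffold, facing inward, with an amplicon no
# larger than `max_amplicon`. Placed markers then vote scaffolds onto
# chromosomes, and map-adjacent marker pairs are scored for orientation
# concordance between map and assembly, within and across assemblies.

#' Reverse complement of nucleotide strings
#' @param x character vector of ACGTN sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All exact occurrences of `pattern` in the assembly (as a DNAStringSet).
# Returns data.frame(scaffold, start, end) with 0-based half-open coords.
exact_hits <- function(pattern, subject_set) {
  m <- Biostrings::vmatchPattern(pattern, subject_set)
  res <- lapply(seq_along(m), function(i) {
    r <- m[[i]]
    if (length(r) == 0L) return(NULL)
    data.frame(scaffold = names(subject_set)[i],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(scaffold = character(0), start = integer(0),
                               end = integer(0)) else out
}

#' Place STS markers on an assembly by exact primer matching
#'
#' For each marker, both primers are searched exactly on both strands of the
#' whole assembly. Status is `placed` when each primer hits exactly once,
#' both hits are on one scaffold, the pair faces inward (forward primer on
#' the plus strand upstream of the reverse-complemented reverse primer, or
#' the mirrored arrangement on the minus strand), and the amplicon spans at
#' most `max_amplicon` bases. Otherwise the marker gets `missing_primer`
#' (a primer with zero exact occurrences), `non_unique` (more than one),
#' `bad_orientation` (unique hits on different scaffolds or not facing
#' inward) or `oversized`.
#'
#' @param markers data frame with columns `id`, `map_chromosome`,
#'   `map_position`, `fwd_primer`, `rev_primer`.
#' @param asm an [assembly()].
#' @param max_amplicon maximum allowed amplicon span in bases (default 1000).
#' @return data frame of marker hits: `id`, `status`, `scaffold`,
#'   `amplicon_start`, `amplicon_end` (0-based half-open), `position`
#'   (amplicon midpoint), `strand`.
#' @export
place_markers <- function(markers, asm, max_amplicon = 1000L) {
  need <- c("id", "map_chromosome", "map_position", "fwd_primer", "rev_primer")
  if (!all(need %in% names(markers))) {
    abort_input("markers table must have columns: %s", paste(need, collapse = ", "))
  }
  subject <- Biostrings::DNAStringSet(setNames(as.character(unclass(asm)), names(asm)))
  out <- vector("list", nrow(markers))
  for (i in seq_len(nrow(markers))) {
    out[[i]] <- place_one_marker(markers$id[i], markers$fwd_primer[i],
                                 markers$rev_primer[i], subject, max_amplicon)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

place_one_marker <- function(id, fwd, rev, subject, max_amplicon) {
  miss <- function(status) {
    data.frame(id = id, status = status, scaffold = NA_character_,
               amplicon_start = NA_integer_, amplicon_end = NA_integer_,
               position = NA_real_, strand = NA_character_,
               stringsAsFactors = FALSE)
  }
  for (p in c(fwd, rev)) {
    if (!nzchar(p) || grepl("[^ACGT]", p)) abort_input("primer of marker '%s' must be non-empty ACGT", id)
  }
  f_plus <- exact_hits(fwd, subject); f_minus <- exact_hits(revcomp(fwd), subject)
  r_plus <- exact_hits(rev, subject); r_minus <- exact_hits(revcomp(rev), subject)
  nf <- nrow(f_plus) + nrow(f_minus)
  nr <- nrow(r_plus) + nrow(r_minus)
  if (nf == 0L || nr == 0L) return(miss("missing_primer"))
  if (nf > 1L || nr > 1L) return(miss("non_unique"))

  if (nrow(f_plus) == 1L && nrow(r_minus) == 1L &&
      f_plus$scaffold == r_minus$scaffold && f_plus$start < r_minus$start) {
    a0 <- f_plus$start; a1 <- r_minus$end; strand <- "+"; scaf <- f_plus$scaffold
  } else if (nrow(f_minus) == 1L && nrow(r_plus) == 1L &&
             f_minus$scaffold == r_plus$scaffold && r_plus$start < f_minus$start) {
    a0 <- r_plus$start; a1 <- f_minus$end; strand <- "-"; scaf <- f_minus$scaffold
  } else {
    return(miss("bad_orientation"))
  }
  if (a1 - a0 > max_amplicon) return(miss("oversized"))
  data.frame(id = id, status = "placed", scaffold = scaf,
             amplicon_start = a0, amplicon_end = a1,
             position = (a0 + a1) / 2, strand = strand,
             stringsAsFactors = FALSE)
}

#' Assign scaffolds to chromosomes by marker majority vote
#'
#' Each scaffold with at least one placed marker is assigned to the
#' chromosome carrying the majority of its markers (ties leave the scaffold
#' unassigned and flagged). Scaffolds are ordered along each chromosome by
#' the median map position of their assigned-chromosome markers, and
#' orientation is the sign of the Spearman rank correlation between map
#' position and scaffold coordinate of those markers (zero or undefined
#' correlation defaults to '+' and is flagged).
#'
#' @param hits marker hits from [place_markers()].
#' @param markers the marker table the hits came from.
#' @return data frame: `scaffold`, `chromosome` (NA when tied),
#'   `median_map_position`, `order_index` (rank along the chromosome),
#'   `orientation`, `n_markers`, `flagged`.
#' @export
assign_scaffolds <- function(hits, markers) {
  placed <- merge(hits[hits$status == "placed", , drop = FALSE],
                  markers[, c("id", "map_chromosome", "map_position")], by = "id")
  if (nrow(placed) == 0L) abort_input("no placed markers to assign from")
  rows <- lapply(split(placed, placed$scaffold), function(d) {
    tab <- sort(table(d$map_chromosome), decreasing = TRUE)
    tie <- length(tab) > 1L && tab[1L] == tab[2L]
    chrom <- if (tie) NA_character_ else names(tab)[1L]
    dd <- if (is.na(chrom)) d else d[d$map_chromosome == chrom, , drop = FALSE]
    ori <- "+"; ori_flag <- FALSE
    if (!is.na(chrom) && nrow(dd) >= 2L &&
        stats::sd(dd$map_position) > 0 && stats::sd(dd$position) > 0) {
      rho <- suppressWarnings(cor(dd$map_position, dd$position, method = "spearman"))
      if (is.na(rho) || rho == 0) ori_flag <- TRUE else ori <- if (rho > 0) "+" else "-"
    } else {
      ori_flag <- TRUE
    }
    data.frame(scaffold = d$scaffold[1L], chromosome = chrom,
               median_map_position = median(dd$map_position),
               orientation = ori, n_markers = nrow(d),
               flagged = tie || ori_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$order_index <- NA_integer_
  for (ch in unique(stats::na.omit(out$chromosome))) {
    sel <- which(out$chromosome == ch)
    out$order_index[sel] <- rank(out$median_map_position[sel], ties.method = "first")
  }
  out <- out[, c("scaffold", "chromosome", "median_map_position", "order_index",
                 "orientation", "n_markers", "flagged")]
  rownames(out) <- NULL
  out
}

#' Chromosome-scale coordinates for placed markers
#'
#' Lays the scaffolds assigned to each chromosome end to end in their
#' [assign_scaffolds()] order, flipping scaffolds with '-' orientation, and
#' returns each placed marker's resulting coordinate. Markers whose scaffold
#' is unassigned, or assigned to a chromosome different from the marker's
#' map chromosome, get NA (they cannot be ordered against the map).
#'
#' @param hits marker hits from [place_markers()].
#' @param assignment table from [assign_scaffolds()].
#' @param markers the marker table.
#' @param asm the [assembly()] (for scaffold lengths when flipping).
#' @return data frame with one row per marker: `id`, `coord` (NA when not
#'   comparable) and `strand` (the placement strand after applying scaffold
#'   orientation; NA when not comparable).
#' @export
marker_global_coords <- function(hits, assignment, markers, asm) {
  slen <- scaffold_lengths(asm)
  out <- data.frame(id = markers$id, coord = NA_real_,
                    strand = NA_character_, stringsAsFactors = FALSE)
  offsets <- list()
  for (ch in unique(stats::na.omit(assignment$chromosome))) {
    a <- assignment[which(assignment$chromosome == ch), , drop = FALSE]
    a <- a[order(a$order_index), , drop = FALSE]
    off <- cumsum(c(0, slen[a$scaffold]))[seq_len(nrow(a))]
    offsets[[ch]] <- setNames(off, a$scaffold)
  }
  placed <- hits[hits$status == "placed", , drop = FALSE]
  for (i in seq_len(nrow(placed))) {
    scaf <- placed$scaffold[i]
    row <- assignment[assignment$scaffold == scaf, , drop = FALSE]
    if (nrow(row) != 1L || is.na(row$chromosome)) next
    j <- match(placed$id[i], out$id)
    mch <- markers$map_chromosome[j]
    if (!identical(row$chromosome, mch)) next
    p <- placed$position[i]
    s <- placed$strand[i]
    if (row$orientation == "-") {
      p <- slen[[scaf]] - p
      s <- if (s == "+") "-" else "+"
    }
    out$coord[j] <- offsets[[row$chromosome]][[scaf]] + p
    out$strand[j] <- s
  }
  out
}

#' Orientation concordance of map-adjacent marker pairs
#'
#' Pairs are consecutive markers in map order within a chromosome (position
#' ties broken by marker id, deterministically). A pair is `unassessable`
#' when either marker lacks an assembly coordinate. When placement strands
#' are available (the default pipeline output of [marker_global_coords()]),
#' a pair is `concordant` iff both markers sit on the same strand and their
#' coordinate order follows that strand's direction (increasing on '+',
#' decreasing on '-'); a mixed-strand pair is `misoriented`. This makes a
#' clean internal inversion show up as exactly its two boundary pairs: the
#' markers inside the inversion flip in both order and strand, so interior
#' pairs remain locally consistent, while the two pairs straddling the
#' breakpoints mix strands. With `strands = NULL` the strand signal is
#' ignored and a pair is concordant iff its coordinate order matches map
#' order. With `all_pairs = TRUE`, every within-chromosome marker pair is
#' scored instead of adjacent pairs only.
#'
#' @param markers marker table (all chromosomes; pairing is per chromosome).
#' @param placement data frame from [marker_global_coords()] (`id`, `coord`,
#'   `strand`), or a named numeric vector of coordinates.
#' @param strands set to NULL to force order-only concordance even when the
#'   placement carries strands; by default strands are taken from the
#'   placement when present.
#' @param all_pairs score all within-chromosome pairs instead of adjacent
#'   ones (default FALSE).
#' @return data frame: `chromosome`, `marker1`, `marker2`, `status`.
#' @export
pair_concordance <- function(markers, placement, strands, all_pairs = FALSE) {
  if (is.data.frame(placement)) {
    coords <- setNames(placement$coord, placement$id)
    if (missing(strands)) strands <- setNames(placement$strand, placement$id)
  } else {
    coords <- placement
    if (missing(strands)) strands <- NULL
  }
  rows <- list()
  for (ch in unique(markers$map_chromosome)) {
    m <- markers[markers$map_chromosome == ch, , drop = FALSE]
    m <- m[order(m$map_position, m$id), , drop = FALSE]
    if (nrow(m) < 2L) next
    idx <- if (all_pairs) {
      which(upper.tri(diag(nrow(m))), arr.ind = TRUE)
    } else {
      cbind(seq_len(nrow(m) - 1L), seq_len(nrow(m) - 1L) + 1L)
    }
    c1 <- coords[m$id[idx[, 1L]]]
    c2 <- coords[m$id[idx[, 2L]]]
    if (is.null(strands)) {
      ok <- c2 > c1
    } else {
      s1 <- strands[m$id[idx[, 1L]]]
      s2 <- strands[m$id[idx[, 2L]]]
      ok <- s1 == s2 & ifelse(s1 == "+", c2 > c1, c2 < c1)
    }
    status <- ifelse(is.na(c1) | is.na(c2), "unassessable",
                     ifelse(ok, "concordant", "misoriented"))
    rows[[ch]] <- data.frame(chromosome = ch, marker1 = m$id[idx[, 1L]],
                             marker2 = m$id[idx[, 2L]], status = status,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(chromosome = character(0),
                                      marker1 = character(0),
                                      marker2 = character(0),
                                      status = character(0))
  rownames(out) <- NULL
  out
}

#' Cross-assembly partition of misoriented marker pairs
#'
#' Given per-pair concordance on two assemblies A and B over the same pair
#' universe, partitions the misoriented pairs into the mutually exclusive
#' categories: misoriented identically on both; misoriented on B only with
#' A concordant; misoriented on B only with A unassessable; misoriented on
#' A only with B concordant; misoriented on A only with B unassessable.
#'
#' @param conc_a,conc_b concordance tables from [pair_concordance()] for
#'   assemblies A and B (same marker pairs).
#' @return named list of counts: `misoriented_a`, `misoriented_b`,
#'   `both_misoriented`, `b_only_a_concordant`, `b_only_a_unassessable`,
#'   `b_only_total`, `a_only_b_concordant`, `a_only_b_unassessable`,
#'   `a_only_total`.
#' @export
cross_assembly_partition <- function(conc_a, conc_b) {
  key <- function(d) paste(d$chromosome, d$marker1, d$marker2, sep = "\r")
  if (nrow(conc_a) != nrow(conc_b) || !setequal(key(conc_a), key(conc_b))) {
    abort_input("concordance tables cover different marker-pair universes")
  }
  b <- conc_b[match(key(conc_a), key(conc_b)), , drop = FALSE]
  sa <- conc_a$status; sb <- b$status
  list(
    misoriented_a = sum(sa == "misoriented"),
    misoriented_b = sum(sb == "misoriented"),
    both_misoriented = sum(sa == "misoriented" & sb == "misoriented"),
    b_only_a_concordant = sum(sb == "misoriented" & sa == "concordant"),
    b_only_a_unassessable = sum(sb == "misoriented" & sa == "unassessable"),
    b_only_total = sum(sb == "misoriented" & sa != "misoriented"),
    a_only_b_concordant = sum(sa == "misoriented" & sb == "concordant"),
    a_only_b_unassessable = sum(sa == "misoriented" & sb == "unassessable"),
    a_only_total = sum(sa == "misoriented" & sb != "misoriented")
  )
}
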