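# SAM boundary. Text SAM files are converted to BAM in a temporary
# directory with Rsamtools and read back with scanBam; only the fields the
# comparison statistics need (qname, flag, seq) are extracted.

#' Read per-read primary-mapping status from a SAM file
#'
#' Keeps primary records only (secondary 0x100 and supplementary 0x800
#' records are discarded before counting, so a read whose sole records are
#' secondary counts as unmapped) and derives, per read: whether it is
#' primary-mapped, whether it maps in a proper pair (flag 0x2), its GC
#' fraction and its length. Mates of paired reads are distinguished by
#' appending `/1` and `/2` to the read name.
#'
#' @param path SAM (or BAM) file.
#' @return data frame: `qname`, `mapped_primary`, `proper_pair`, `gc`,
#'   `length`.
#' @export
read_sam_flags <- function(path) {
  if (!file.exists(path)) abort_input("SAM file not found: %s", path)
  bam <- if (grepl("\\.bam$", path)) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "seq")))[[1L]]
  flag <- rec$flag
  primary <- bitwAnd(flag, 0x100) == 0L & bitwAnd(flag, 0x800) == 0L
  qname <- rec$qname[primary]
  flag <- flag[primary]
  seqs <- as.character(rec$seq[primary])
  paired <- bitwAnd(flag, 0x1) != 0L
  mate <- ifelse(bitwAnd(flag, 0x40) != 0L, "/1",
                 ifelse(bitwAnd(flag, 0x80) != 0L, "/2", ""))
  qname <- ifelse(paired, paste0(qname, mate), qname)
  gc <- vapply(seqs, function(s) {
    if (!nzchar(s) || s == "*") return(NA_real_)
    b <- strsplit(s, "")[[1L]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(qname = qname,
             mapped_primary = bitwAnd(flag, 0x4) == 0L,
             proper_pair = bitwAnd(flag, 0x2) != 0L,
             gc = gc, length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a minimal SAM file
#'
#' Emits a header and one record per row; used by the synthetic-data module
#' to record true read placements.
#'
#' @param path output path.
#' @param records data frame with `qname`, `flag`, `rname`, `pos` (1-based;
#'   0 with rname "*" for unmapped), `seq`.
#' @param contigs named vector of reference lengths for the header.
#' @return `path`, invisibly.
#' @export
write_sam <- function(path, records, contigs) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  cigar <- ifelse(bitwAnd(records$flag, 0x4) != 0L, "*",
                  paste0(nchar(records$seq), "M"))
  mapq <- ifelse(bitwAnd(records$flag, 0x4) != 0L, 0L, 60L)
  body <- paste(records$qname, records$flag, records$rname, records$pos,
                mapq, cigar, "*", 0L, 0L, records$seq,
                strrep("I", nchar(records$seq)), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
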