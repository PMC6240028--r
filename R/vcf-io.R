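# Thin VCF boundary. Parsing is delegated to vcfR; only the GT (and PS)
# FORMAT fields are consumed, which is all the finishing steps need.

#' Read genotypes from a multi-sample VCF
#'
#' Loads the fixed fields and per-sample GT strings (and PS phase-set tags
#' when present) from a VCF v4.x file. Positions stay 1-based as in the VCF;
#' downstream code converts at the point of use.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return list with `fixed` (data frame: CHROM, POS, REF, ALT), `gt`
#'   (character matrix, sites x samples, e.g. "0/1", "1|0", "./."), `ps`
#'   (phase-set matrix or NULL) and `samples`.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort_input("VCF file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixed <- data.frame(
    CHROM = vcfR::getCHROM(v),
    POS = vcfR::getPOS(v),
    REF = vcfR::getREF(v),
    ALT = vcfR::getALT(v),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  ps <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = "PS")),
                 error = function(e) NULL)
  list(fixed = fixed, gt = gt, ps = ps, samples = colnames(gt))
}

# Split one GT string into integer allele indexes (NA when missing).
# Returns list(alleles = integer vector, phased = logical).
parse_gt <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
    return(list(alleles = NA_integer_, phased = FALSE))
  }
  phased <- grepl("|", gt, fixed = TRUE)
  parts <- strsplit(gt, "[/|]")[[1L]]
  alleles <- suppressWarnings(as.integer(parts))
  list(alleles = alleles, phased = phased)
}

# Map allele indexes to allele strings for one site (0 = REF, k = k-th ALT).
allele_strings <- function(ref, alt) c(ref, strsplit(alt, ",", fixed = TRUE)[[1L]])

#' Write a minimal multi-sample VCF
#'
#' Emits a spec-conformant VCF v4.2 text file with GT (and optionally PS)
#' FORMAT fields — the fields the rest of the pipeline reads back.
#'
#' @param path output path.
#' @param fixed data frame with CHROM, POS, REF, ALT.
#' @param gt character matrix (sites x samples) of GT strings.
#' @param ps optional character matrix of PS phase-set values ("." for none).
#' @param contigs optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(path, fixed, gt, ps = NULL, contigs = NULL) {
  stopifnot(nrow(fixed) == nrow(gt))
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(ps)) {
    hdr <- c(hdr, '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">')
  }
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  fmt <- if (is.null(ps)) "GT" else "GT:PS"
  sample_cols <- if (is.null(ps)) gt else {
    matrix(paste(gt, ps, sep = ":"), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  body <- apply(cbind(fixed$CHROM, fixed$POS, ".", fixed$REF, fixed$ALT,
                      ".", "PASS", ".", fmt, sample_cols),
                1L, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
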