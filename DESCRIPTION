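Package: finishr
Title: Genome Assembly Finishing and Assessment Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the finishing and quality-assessment steps of a
    reference genome assembly project: gap-aware contig segmentation and
    contiguity statistics (N50, gap census, GC content), cohort-corroborated
    polishing of homozygous reference errors from multi-sample VCF genotypes,
    population-guided pseudo-haploidization of phased variants per phase
    block, STS-marker placement by exact primer-pair matching with radiation
    hybrid map chromosome assignment and marker-pair orientation concordance,
    exact 32-mer contamination screening with DUST-style low-complexity
    masking, iterative reference-guided consensus for circular mitochondrial
    genomes, and cross-assembly read-mapping comparison statistics. A seeded
    synthetic-data module generates every input the pipeline consumes with
    known ground truth, so all stages are testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
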