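#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Builds the ground-truth bundle — a gapped diploid toy genome with planted
# reference errors, phased heterozygous sites, STS markers, a misassembled
# copy carrying one inversion, injected microbial contaminants, and a
# circular mitochondrial genome — and writes every pipeline input under
# results/sim/.

suppressPackageStartupMessages(library(finishr))

seed <- 11L
tr <- simulate_truth(seed = seed)
dir.create("results", showWarnings = FALSE)
write_truth_bundle(tr, "results/sim")

cat(sprintf("seed %d: %d scaffolds, %d planted errors, %d het sites in %d blocks,\n",
            seed, length(tr$assembly), nrow(tr$ref_errors),
            nrow(tr$het_sites), length(unique(tr$het_sites$block_id))))
cat(sprintf("%d markers, inversion %s:%d-%d, %d contaminants, mito %d bp x %d repeat copies\n",
            nrow(tr$markers), tr$inversion$scaffold, tr$inversion$start,
            tr$inversion$end, length(tr$contaminant_ids),
            nchar(tr$mito$truth), tr$mito$copies))
cat("inputs written to results/sim/\n")
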