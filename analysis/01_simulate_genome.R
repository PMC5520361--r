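#!/usr/bin/env Rscript
# Simulate a toy assembly: contigs with planted perfect/compound/imperfect
# microsatellite tracts, a coverage sidecar and the ground-truth table.
# Outputs under results/synthetic/.

suppressPackageStartupMessages(library(ssrpipe))

outdir <- "results/synthetic"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

tracts <- data.frame(
  motif = c("AT", "CT", "GT", "AAG", "ATC", "AGAT", "AAAT", "AT", "TA",
            "AAG"),
  repeat_count = c(8, 12, 4, 5, 6, 4, 3, 10, 6, 4),
  purity = c(rep("perfect", 8), "compound", "imperfect"),
  motif2 = c(rep(NA, 8), "GA", NA),
  contig = 1:10)

spec <- sim_spec(seed = 1, n_contigs = 10, contig_length = c(2800, 4500),
                 gc = 0.42, tracts = tracts,
                 coverage = c(12, 25, 22, 30, 18, 28, 35, 24, 26, 21))
g <- generate_contigs(spec)

write_contigs(g$contigs, file.path(outdir, "contigs.fasta"))
write_coverage(g$coverage, file.path(outdir, "coverage.tsv"))
write.table(g$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("simulated %d contigs (%d-%d bp) carrying %d planted tracts",
                length(g$contigs), min(nchar(g$contigs)),
                max(nchar(g$contigs)), nrow(g$truth)))
message("wrote contigs.fasta, coverage.tsv and truth.tsv to ", outdir)
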