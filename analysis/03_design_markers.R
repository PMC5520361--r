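#!/usr/bin/env Rscript
# Run the full marker-development funnel on the simulated assembly:
# mine -> 15X candidates -> marker-grade selection (2.5 kb / 20X / 3 copies /
# no adjacent SSR) -> primer design -> multiplex panels.

suppressPackageStartupMessages(library(ssrpipe))

ind <- "results/synthetic"
out <- run_pipeline(file.path(ind, "contigs.fasta"),
                    file.path(ind, "coverage.tsv"),
                    config = pipeline_config(),
                    outdir = "results/markers")

s <- out$summary
message(sprintf(
  "funnel: %d loci -> %d perfect -> %d candidates (15X) -> %d marker-grade -> %d designed markers in %d panels",
  s$n_loci, s$n_perfect, s$n_candidates, s$n_selected, s$n_markers,
  s$n_panels))
if (s$n_skipped > 0) {
  message("skipped designs:")
  print(out$skipped)
}
message("marker and panel tables written under results/markers/")
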