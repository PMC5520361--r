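#!/usr/bin/env Rscript
# Descriptive statistics. Part 1 reproduces the published 42-marker summary
# row from the shipped panel table; part 2 computes the same statistics on
# synthetic Hardy-Weinberg genotypes with known frequencies, demonstrating
# binning, size concordance and the polymorphism-vs-repeat-class exact test.

suppressPackageStartupMessages(library(ssrpipe))

outdir <- "results/stats"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

## published panel ----------------------------------------------------------
d <- brpe_marker_stats()
sm <- summarize_panel(d, n_tested = 60, n_amplifying = 57)
print(sm)
panel18 <- d[d$rank %in% c(1:16, 18, 19), ]
message(sprintf("18-marker transfer panel: mean PIC %.2f (range %.2f-%.2f)",
                round_half_up(mean(panel18$pic), 2), min(panel18$pic),
                max(panel18$pic)))

## synthetic genotype screen ------------------------------------------------
loci <- default_genotype_loci(50, 10)
# a small screen always carries some monomorphic markers; fix a few loci to a
# single allele so the polymorphism contrast is represented
for (i in seq(5, 60, by = 5)) loci[[i]]$p <- 1
spec <- sim_spec(seed = 1, n_samples = 10, missing_rate = 0.02, loci = loci)
gg <- generate_genotypes(spec)
write_genotypes(gg$genotypes, file.path(outdir, "genotypes.tsv"))

st <- marker_statistics(gg$genotypes)
write.table(st, file.path(outdir, "marker_statistics.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(summarize_panel(st))

# Tandem-style binning of jittered fragment sizes for one marker
raw <- st$size_min[1] + 2 * sample(0:5, 12, replace = TRUE) +
  runif(12, -0.3, 0.3)
b <- bin_alleles(raw, 2)
message(sprintf("binning: offset %.1f bp, max residual %.2f bp, %d flagged",
                b$offset, max(abs(b$residual)), sum(b$flagged)))

# size concordance of expected vs observed ranges
cc <- amplicon_size_concordance(st$size_min + 4, st$size_min, st$size_max)
message(sprintf("amplicon sizes within 5%% of expected: %.0f%% (exact: %.0f%%)",
                100 * cc$prop_within, 100 * cc$prop_exact))

# di vs tri polymorphism association
ml <- attr(gg$genotypes, "motif_length")[st$marker]
tab <- table(ifelse(ml == 2, "di", "tri"),
             ifelse(st$polymorphic, "poly", "mono"))
if (all(dim(tab) == c(2, 2))) {
  message(sprintf("Fisher exact p (polymorphism x repeat class) = %.3f",
                  fisher_exact_2x2(tab)))
} else {
  message("all markers in one polymorphism class; exact test skipped")
}
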