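# ssrpipe

An R implementation of the microsatellite (SSR) marker-development and
validation workflow used in plant genetic-resource studies, written for
researchers who need to go from assembled contigs to a validated,
multiplex-ready marker panel and its diversity statistics - and to test
every step of that funnel against known ground truth.

The pipeline covers:

* **mining** - detection of maximal *perfect* tandem repeats of primitive
  2-6 bp motifs (default thresholds: >= 4 copies for di-, >= 3 for tri- and
  tetra-nucleotides), purity classification (perfect / compound /
  imperfect), motif-class canonicalization under rotation and reverse
  complement, and repeat-content summaries;
* **marker selection & design** - the 15X candidate coverage filter; the
  marker-grade filter (contig >= 2.5 kb, >= 20X, >= 3 motif copies, no
  adjacent SSR within a configurable window); a documented primer-design
  heuristic (length 18-24 bp, GC 40-60%, no homopolymer >= 5,
  `Tm = 64.9 + 41 (GC - 16.4)/len`, product 70-300 bp, annealing
  temperature from {55, 57, 60} °C); greedy multiplex-panel packing;
* **genotype statistics** - for allele frequencies `p_i` over `n` typed
  diploids: observed heterozygosity `Ho`, unbiased expected heterozygosity
  `He = (2n/(2n-1)) (1 - Σ p_i²)`, polymorphic information content
  `PIC = 1 - Σ p_i² - Σ_{i<j} 2 p_i² p_j²`, Tandem-style allele binning
  onto the motif grid, amplicon-size concordance, and a two-sided Fisher
  exact test by full hypergeometric enumeration;
* **transferability & diversity** - presence/absence cross-species
  summaries, Band-coefficient (Dice) distances on allele-presence sets,
  principal coordinate analysis (Gower double-centering, negative
  eigenvalues reported but excluded), Evanno
  `ΔK = mean|L''(K)| / sd(lnP(D))` model selection, and the inclusive
  `Q >= 0.70` cluster-assignment rule;
* **synthetic data** - one seeded spec (`sim_spec()`) drives generators for
  contigs with planted tracts at known coordinates, Hardy-Weinberg
  genotypes, Bernoulli transfer matrices and ln P(D) series with a planted
  change-point, so everything above is testable end to end.

Two plain-text reference tables ship in `inst/extdata`: the descriptive
statistics of a published panel of 42 polymorphic *Passiflora edulis*
("BrPe") markers, and the 79-species x 18-marker cross-amplification
matrix; the package reproduces their summary rows exactly.

## Worked example

Simulate two contigs with planted tracts, mine them, select marker-grade
loci and design primers:

```r
library(ssrpipe)

spec <- sim_spec(seed = 1, n_contigs = 2, contig_length = c(3000, 3000),
                 tracts = data.frame(motif = c("AT", "AAG"),
                                     repeat_count = c(8, 5), contig = 1:2),
                 coverage = c(25, 30))
g    <- generate_contigs(spec)
loci <- mine_contigs(g$contigs)
loci[, c("contig_id", "start", "end", "motif", "repeat_count", "purity")]
#>    contig_id start  end motif repeat_count  purity
#> 1 contig_001  1500 1516    AT            8 perfect
#> 2 contig_002  1500 1515   AAG            5 perfect

sel <- select_marker_grade(
  filter_candidate_sites(loci[loci$purity == "perfect", ], g$coverage),
  loci, data.frame(contig_id = names(g$contigs), length = nchar(g$contigs)),
  g$coverage)
design_markers(sel, g$contigs)$markers[
  , c("name", "motif", "left_primer", "right_primer", "ta_c", "expected_size")]
#>       name motif         left_primer           right_primer ta_c expected_size
#> 1 BrPe0001    AT  ATCTGGACAACGAGCCCA CGGAGATGTTCAAGAGGTTAAT   55            78
#> 2 BrPe0002   AAG GGACGTATTCGCATGTCCA GAGCGAACCAGCTCTAATAATA   55            89
```

Both planted tracts come back at their exact coordinates, pass the
candidate (25X, 30X >= 15X) and marker-grade filters, and get primer pairs
whose product sizes (78 and 89 bp) are the distance from the left primer
start to the right primer 3' end.

Summarizing the shipped reference panel and transfer matrix:

```r
summarize_panel(brpe_marker_stats(), n_tested = 60, n_amplifying = 57)
#> Panel summary: 60 tested, 57 amplifying, 42 polymorphic (74%)
#>   total alleles 137; alleles/locus mean 3.26 (range 2-7)
#>   He mean 0.55 (0.19-0.84); Ho mean 0.35 (0.00-1.00); PIC mean 0.45 (0.16-0.77)

s <- transferability_summary(brpe_transfer_matrix(),
                             reference = "Passiflora edulis")
s$overall_pct   # 72
s$universal     # "BrPe0032" "BrPe0038" "BrPe3011"
```

That is: 74% of amplifying markers polymorphic with 137 alleles in total
(3.26 per locus on average), and 72% of marker x species combinations
amplifying across 79 species, with three markers working in every species.

## The analysis workflow

The `analysis/` directory holds numbered drivers that run the study as a
narrative, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_genome.R` | simulate contigs + coverage with planted tracts |
| `02_mine_ssrs.R` | mine, classify, repeat-content summaries, GFF3/BED |
| `03_design_markers.R` | the full funnel: candidates -> marker-grade -> primers -> panels |
| `04_marker_statistics.R` | panel summary of the reference table; He/Ho/PIC on synthetic genotypes; binning; size concordance; Fisher test |
| `05_transferability.R` | transfer-rate summaries (reference + synthetic matrix) |
| `06_diversity.R` | band distances, PCoA, Evanno delta-K, Q-rule assignment |

Run them in order from the repository root, e.g.
`Rscript analysis/01_simulate_genome.R`.

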