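---
title: "Microsatellite marker development and diversity statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite marker development and diversity statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpipe)
```

## What the package models

Microsatellites (simple sequence repeats, SSRs) are tandem arrays of a 2-6 bp
DNA motif whose allele length varies by repeat-copy number. Developing SSR
markers from a draft assembly follows a fixed funnel: detect perfect repeat
tracts in contigs, discard tracts on poorly supported contigs, keep loci
isolated enough to genotype cleanly, design primer pairs in the flanks, and
multiplex the resulting markers. Validation then runs the markers on a
germplasm panel and reports heterozygosity and information-content
statistics, cross-species amplification rates, and ordination/cluster
analyses of the genotypes. `ssrpipe` implements this whole funnel with every
threshold exposed, plus a seeded synthetic-data module so each stage can be
tested against known ground truth.

## Repeat mining

`find_tandem_repeats()` reports **maximal perfect runs**: a tract of a
primitive motif (not itself a repetition of a shorter word, never a
homopolymer) repeated in tandem with no interruptions, which cannot be
extended by a full or partial motif copy on either side. Reported
coordinates cover whole copies only; a trailing partial copy neither extends
the tract nor increments the repeat count, because a perfect microsatellite
is defined by exact tandem copies. Runs never cross an `N` (assembly gaps
must not produce chimeric loci), and a tract is reported once, at the
leftmost phase of its run - so an `(AT)n` array is never also reported as
`(TA)n` or `(ATAT)m`. Coordinates are 0-based half-open everywhere inside
the package; the GFF3 writer converts to 1-based inclusive at that boundary
only.

Discovery thresholds default to four or more copies for di-nucleotide motifs
and three or more for tri- and tetra-nucleotides. Note the deliberate
asymmetry with the later marker-grade filter, which demands only a minimum
of three motif copies: both thresholds are applied exactly as stated, each
at its own stage, because they gate different decisions (cataloguing repeat
content vs. selecting marker loci).

Motifs are grouped into classes by `canonicalize_motif()`: the
lexicographically smallest string among all rotations of the motif and of
its reverse complement. Observed strand pairs such as GAA/TTC therefore
share one deterministic representative (`AAG`); reports can print the full
alias list where readers expect the observed-pair notation.

### Purity classification

`classify_tracts()` labels mined runs:

* runs separated by at most `compound_gap` (default 10 bp, a PHOBOS-style
  interruption tolerance) form a cluster; clusters mixing **distinct motif
  classes** are `compound` (more than one motif in one repeat region);
* clusters of runs of a **single motif class** are `imperfect` - an
  interrupted repeat of one motif is not a compound locus, since compound
  means more than one motif;
* an isolated run is `imperfect` when a degenerate copy of its own motif
  (at most one mismatch) sits **immediately at a tract boundary**, and
  `perfect` otherwise.

The degenerate-copy check is deliberately restricted to gap-0 adjacency.
For a di-nucleotide motif, a one-mismatch 2-mer occurs in about 44% of
random flank words, so a gap-tolerant version of the rule would relabel
roughly two-thirds of genuine perfect di-nucleotide tracts. The purpose of
the pass is to keep non-perfect loci out of marker selection, not to
delimit imperfect repeats precisely, and the boundary-only rule achieves
that without poisoning the perfect class. Only `perfect` loci propagate to
marker selection.

`summarize_repeat_content()` tallies loci by motif length and purity, counts
long tracts, and tabulates motif-class frequencies, optionally restricted to
contigs above a coverage floor. "More than 5 repeats" is counted strictly
(`repeat_count >= 6`) as the primary tally, with a `>= 5` column alongside,
because the phrase is ambiguous in common usage; the strict reading is the
one consistent with "more than".

## Marker selection and design

Two sequential filters mirror marker-development practice:

1. `filter_candidate_sites()`: contig mean coverage >= 15X (closed bound:
   exactly 15.0 passes). Shallow contigs carry assembly errors that corrupt
   expected product sizes.
2. `select_marker_grade()`: contig >= 2500 bp and >= 20X, repeat count >= 3,
   and no other detected SSR (any purity) within `adjacency_window`
   (default 200 bp; "no adjacent SSR" is a qualitative requirement in
   marker-development practice, so the window is exposed as a parameter) of
   either flank. These maximize locus independence and allele-calling quality.
   All four predicates are monotone, so relaxing any threshold can only
   grow the selection - a property the test suite checks.

`design_markers()` is a documented heuristic, not a thermodynamic model:
per flank it takes the primer window nearest the locus with length 18-24 bp,
GC between 40% and 60%, no mononucleotide run of five or more, and a GC-rule
melting temperature `Tm = 64.9 + 41 (GC - 16.4) / length` within 5 °C of the
annealing-temperature set. If the minimal product is shorter than 70 bp the
right primer moves outward; products above 300 bp are rejected (the bounds
bracket the 74-297 bp allele ranges typical of such panels and are
configurable). Each marker's annealing temperature is the nearest member of
{55, 57, 60} °C (ties to the lower value) to the mean primer Tm, matching a
three-temperature PCR protocol. Infeasible loci are skipped with a reason
code rather than silently dropped. Names are a configurable prefix
(`BrPe` by default) plus a 4-digit ordinal, restarting at 0001 per run. An
external thermodynamic designer can replace this stage; the surrounding
funnel is agnostic to how the primers were chosen.

`build_multiplex_panels()` packs markers greedily, first-fit, in descending
PIC order when provided: a panel accepts a marker only with the same
annealing temperature, free capacity (default 3, for duos/trios), and
either a different dye or expected-size windows separated by at least 20 bp.
Greedy first-fit is deterministic given the input order and always yields a
feasible partition; optimal panel minimization is NP-hard bin packing and
is not attempted.

## Genotype statistics

With allele frequencies `p_i` estimated by counting gene copies over typed
individuals (missing genotypes excluded; `n` is the per-marker typed count):

* `Ho` = heterozygotes / typed individuals;
* `He` = `(2n / (2n - 1)) (1 - sum p_i^2)`, the unbiased finite-sample
  estimator - the convention of the CERVUS-style toolchain such reports are
  built with; the uncorrected gene diversity is available via
  `unbiased = FALSE`;
* `PIC` = `1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`; always `PIC <= He`,
  strictly so for k >= 2 with all frequencies positive;
* a marker is polymorphic iff it shows >= 2 alleles in the typed sample (no
  minor-allele-frequency floor).

Rounding to the 2-decimal / whole-percent report convention (half-up, via
`round_half_up()`) happens only in the reporting layer
(`summarize_panel()`), never inside estimators.

`bin_alleles()` implements Tandem-style binning: a grid search over offsets
`o` in `[0, m)` at 0.1 bp resolution (ties to the smallest offset)
minimizing the summed distance of fragment sizes to the grid `o + k m`,
then snapping each size to its nearest rung. Residuals above `m/4` flag
alleles that cannot sit on the repeat grid (off-ladder alleles or size-calling
problems). Binning its own output is a fixed point.

`fisher_exact_2x2()` enumerates all tables with the observed margins and
sums hypergeometric probabilities at most that of the observed table, with
1e-7 relative slack against floating-point ties; the suite cross-checks it
against `stats::fisher.test`, which serves as reference only.

## Transferability and diversity

`transferability_summary()` counts `+` calls over non-NA calls per species,
per marker and overall; an all-NA row yields NA rather than 0. The overall
rate both including and excluding the reference species row is reported,
since published percentages use either convention; the all-rows figure is
primary. The weighted mean of species rates (weights = non-NA counts)
equals the overall rate exactly before rounding - an identity the tests
assert.

The **Band coefficient** is implemented as the Dice-type band similarity
`S = 2a / (n_x + n_y)` on allele-presence sets (every distinct
marker:size pair in a sample; a homozygote contributes one band), markers
missing in either sample excluded pairwise, distance `1 - S`. The source
literature for this coefficient does not pin a formula in the material this
design follows, so the Dice convention - the BAND coefficient of the
classical clustering software - is a documented assumption, with a Jaccard
alternative behind `method = "jaccard"`.

`pcoa()` performs classical metric scaling: Gower double-centering
`B = -1/2 J D^2 J`, symmetric eigendecomposition, coordinates scaled by
`sqrt(lambda)`. Band distances need not be Euclidean, so negative
eigenvalues can occur: they are reported, excluded from coordinates, and
percent variance is taken over positive eigenvalues only (summing to 100
within 1e-6). Eigenvalues within `1e-9` of zero relative to the largest are
treated as null to keep coordinates numerically stable.

`evanno_delta_k()` computes, for each interior K of a contiguous grid,
`deltaK = mean_r | lnPD(K+1, r) - 2 lnPD(K, r) + lnPD(K-1, r) | / sd_r lnPD(K, r)`
- the absolute second difference taken per replicate run, averaged, scaled
by the across-run standard deviation. Grid endpoints are NA by definition,
and a zero standard deviation is an explicit error (the estimator is
undefined; jitter or more runs are advised). `assign_clusters()` applies
the inclusive `Q >= 0.70` rule; a maximum membership of exactly 0.70 is
assigned, anything lower is flagged admixed. The admixture sampler itself
is out of scope - Q-matrices and ln P(D) series are inputs (or synthetic).

## The synthetic-data generators

`sim_spec()` routes one integer seed through every generator, so identical
specs give bit-identical files. The generators emulate:

* **contigs** with planted tracts at exact, recorded coordinates over an
  i.i.d. background at a requested GC. Planted perfect tracts are
  *hardened*: the flanking motif-length words are set to Hamming distance
  >= 2 from the aligned motif copy (so the tract can be neither extended nor
  relabeled imperfect), and a 200 bp window on each side is resampled until
  free of spurious SSRs at default thresholds. Background sequence may
  still contain SSRs elsewhere - by design, truth-checking is "100% recall
  of planted loci" plus oracle-verified behavior on the rest, which avoids
  rejection-sampling the whole contig;
* **genotypes** drawn under Hardy-Weinberg equilibrium from per-locus
  frequency vectors, alleles on the motif grid, missingness independent per
  sample and locus. Defaults follow a ten-accession screen of 50 di- and 10
  tri-nucleotide markers;
* **transfer matrices** as independent Bernoulli calls at a per-species
  probability (default 79 species x 18 markers at p = 0.72), reference row
  all positive;
* **ln P(D) series** with a mean curve rising steeply to the true K then
  plateauing (slope ratio 20:1), Gaussian replicate noise, defaults K =
  1..10 with 20 runs.

What the generators do **not** emulate - and hence what passing tests do
not certify about real data: relatedness or population structure within the
genotyped panel (samples are unrelated HWE draws), null alleles and stutter,
size-calling error beyond the binning demonstration, sequencing or assembly
error inside contigs, and realistic genome-scale repeat abundance. The
fixtures shipped in `inst/extdata` are transcriptions of a published
42-marker statistics table and a 79 x 18 amplification matrix; the
package reproduces their *summary* quantities, while per-marker He/Ho/PIC
and ordination axis percentages of the original study are not recomputable
without the unpublished raw genotypes.

## Numerical choices and problem sizes

* Report rounding is half-up (`round_half_up()`); R's banker's rounding is
  never used for report parity.
* The mining property suite compares against an O(n^2) brute-force oracle
  on 100+ random sequences of 0.5-2.5 kb with occasional Ns - sizes chosen
  so the exhaustive oracle itself stays exact and the property holds with
  margin across lengths; the scanner is linear-time per motif length.
* Parameter-recovery tests use n = 5000 diploid samples (binomial standard
  error ~0.005 on frequencies, comfortably inside the +/-0.02 band) and the
  delta-K detector is evaluated over 100 seeded scenarios (true K = 4,
  sd = 5, 20 runs).
* `bin_alleles()` searches offsets at 0.1 bp, the resolution of typical
  fragment size calling; ties go to the smallest offset for determinism.
* Degenerate inputs are contracts, not surprises: empty sequences mine to
  empty tables, an empty FASTA runs the pipeline to a clean zero-marker
  report, zero typed individuals / zero bands / zero sd are explicit
  errors.

## Known limitations

Primer design ignores secondary structure, dimers and salt-corrected
thermodynamics; motif lengths above 6 are out of scope; approximate
(weighted) repeat scoring is not implemented; panel packing is greedy, not
optimal; and the admixture model selection consumes externally computed
(or simulated) ln P(D) and Q inputs rather than running an MCMC sampler.
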