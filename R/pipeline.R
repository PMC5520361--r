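#' Pipeline configuration
#'
#' Collects every tunable threshold of the marker-development pipeline with
#' the study defaults: mining thresholds (di >= 4 copies, tri/tetra >= 3),
#' the 15X candidate coverage floor, the marker-grade filters (2500 bp
#' contig, 20X coverage, >= 3 motif copies, 200 bp locus-independence
#' window), the 10 bp compound gap, primer/product constraints, multiplex
#' capacity and size gap, the binning residual limit (m/4 is built into
#' [bin_alleles()]), and the Q >= 0.70 assignment threshold. Unknown keys are
#' rejected.
#'
#' @param ... overrides of the defaults (see source for the full key list)
#' @param yaml optional path to a YAML file of overrides (applied before
#'   `...`)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(..., yaml = NULL) {
  defaults <- list(
    thresholds = default_mining_thresholds(),
    compound_gap = 10L,
    coverage_min = 15,
    marker_min_contig_len = 2500,
    marker_min_cov = 20,
    marker_min_repeats = 3,
    adjacency_window = 200,
    name_prefix = "BrPe",
    primer_length = 18:24,
    gc_range = c(0.40, 0.60),
    max_homopolymer = 5L,
    product_size = c(70, 300),
    max_flank = 300L,
    ta_set = c(55, 57, 60),
    panel_capacity = 3L,
    panel_size_gap = 20,
    q_threshold = 0.70)
  over <- list(...)
  if (!is.null(yaml)) over <- utils::modifyList(yaml::read_yaml(yaml), over)
  unknown <- setdiff(names(over), names(defaults))
  .check(length(unknown) == 0, "unknown config key '%s'",
         if (length(unknown)) unknown[1] else "")
  cfg <- utils::modifyList(defaults, over)
  .check(all(cfg$thresholds >= 2), "mining thresholds must be >= 2")
  for (key in c("coverage_min", "marker_min_contig_len", "marker_min_cov",
                "marker_min_repeats", "adjacency_window", "panel_capacity",
                "panel_size_gap")) {
    .check(is.numeric(cfg[[key]]) && cfg[[key]] > 0,
           "config key '%s' must be a positive number", key)
  }
  .check(cfg$q_threshold > 0 && cfg$q_threshold <= 1,
         "q_threshold must be in (0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the marker-development pipeline end to end
#'
#' mine -> classify -> coverage filter -> marker-grade selection -> primer
#' design -> multiplex panels, with stage-tagged locus counts logged to
#' stderr and all tables written under `outdir` (GFF3 of loci, marker TSV,
#' panel TSV, summary JSON) when one is given.
#'
#' @param contigs named character vector / DNAStringSet, or a FASTA path
#' @param coverage data.frame `contig_id`, `mean_coverage`, or a TSV path;
#'   required because the candidate and marker-grade filters are
#'   coverage-gated
#' @param config a [pipeline_config()]
#' @param intervals optional annotation intervals (path or data.frame) for
#'   genomic-context labeling
#' @param outdir optional output directory
#' @return list: `loci`, `candidates`, `selected`, `markers`, `skipped`,
#'   `panels`, `summary` (stage counts), invisibly
#' @export
run_pipeline <- function(contigs, coverage, config = pipeline_config(),
                         intervals = NULL, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(contigs) && length(contigs) == 1L &&
        file.exists(contigs)) {
    cr <- read_contigs(contigs,
                       if (is.character(coverage)) coverage else NULL)
    contigs <- cr$contigs
    if (is.character(coverage)) coverage <- cr$coverage
  }
  .check(is.data.frame(coverage),
         "a coverage table (contig_id, mean_coverage) is required")
  seqs <- .as_contig_chr(contigs)
  lens <- data.frame(contig_id = names(seqs), length = nchar(seqs),
                     row.names = NULL, stringsAsFactors = FALSE)
  log_stage <- function(stage, n, unit = "loci") {
    message(sprintf("[%s] %d %s", stage, n, unit))
  }
  loci <- mine_contigs(seqs, config$thresholds, config$compound_gap)
  log_stage("mine", nrow(loci))
  perfect <- loci[loci$purity == "perfect", , drop = FALSE]
  log_stage("perfect", nrow(perfect))
  candidates <- filter_candidate_sites(perfect, coverage,
                                       config$coverage_min)
  log_stage("candidates", nrow(candidates))
  selected <- select_marker_grade(candidates, loci, lens, coverage,
                                  config$marker_min_contig_len,
                                  config$marker_min_cov,
                                  config$marker_min_repeats,
                                  config$adjacency_window)
  log_stage("marker_grade", nrow(selected))
  des <- design_markers(selected, seqs, prefix = config$name_prefix,
                        primer_length = config$primer_length,
                        gc_range = config$gc_range,
                        max_homopolymer = config$max_homopolymer,
                        product_size = config$product_size,
                        max_flank = config$max_flank,
                        ta_set = config$ta_set)
  n_markers <- if (is.null(des$markers)) 0L else nrow(des$markers)
  log_stage("designed", n_markers, "markers")
  for (r in seq_len(nrow(des$skipped))) {
    message(sprintf("[design] skipped %s:%d-%d (%s)",
                    des$skipped$contig_id[r], des$skipped$start[r],
                    des$skipped$end[r], des$skipped$reason[r]))
  }
  if (!is.null(intervals) && n_markers > 0) {
    iv <- if (is.character(intervals)) read_intervals(intervals) else
      intervals
    des$markers <- label_genomic_context(des$markers, iv)
  }
  panels <- if (n_markers > 0) {
    build_multiplex_panels(des$markers, config$panel_capacity,
                           config$panel_size_gap)
  } else {
    data.frame(panel = integer(), name = character(), ta_c = numeric(),
               size_min = numeric(), size_max = numeric(),
               dye = character(), stringsAsFactors = FALSE)
  }
  log_stage("panels", length(unique(panels$panel)), "panels")
  summary <- list(n_loci = nrow(loci), n_perfect = nrow(perfect),
                  n_candidates = nrow(candidates),
                  n_selected = nrow(selected), n_markers = n_markers,
                  n_skipped = nrow(des$skipped),
                  n_panels = length(unique(panels$panel)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(loci)) write_loci_gff3(loci, file.path(outdir, "loci.gff3"))
    if (n_markers > 0) {
      utils::write.table(des$markers, file.path(outdir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(panels, file.path(outdir, "panels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(loci = loci, candidates = candidates, selected = selected,
                 markers = des$markers, skipped = des$skipped,
                 panels = panels, summary = summary))
}
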