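#' Default minimum repeat counts for SSR discovery
#'
#' Four or more copies for di-nucleotide motifs and three or more for tri- and
#' tetra-nucleotide motifs, the discovery thresholds used to build the repeat
#' database.
#'
#' @return named integer vector, names are motif lengths
#' @export
default_mining_thresholds <- function() {
  c(`2` = 4L, `3` = 3L, `4` = 3L)
}

#' Find maximal perfect tandem repeats in one sequence
#'
#' Scans a DNA sequence for perfect microsatellite tracts: maximal runs of a
#' primitive 2-6 bp motif repeated in tandem with no interruptions. A run is
#' maximal when it cannot be extended by a full or partial motif copy on
#' either side; reported coordinates cover only whole motif copies (a trailing
#' partial copy neither extends the tract nor increments the repeat count).
#' Runs never cross an N, nested reports are suppressed (an (AT)n tract is not
#' also reported as (ATAT)m because ATAT is not primitive), and homopolymer
#' runs are never reported.
#'
#' @param sequence single DNA string over ACGTN (case-insensitive)
#' @param thresholds named integer vector of minimum repeat counts keyed by
#'   motif length, e.g. `c("2" = 4, "3" = 3, "4" = 3)`; all must be >= 2
#' @param contig_id id recorded in the output table
#' @return data.frame with columns `contig_id`, `start` (0-based), `end`
#'   (exclusive), `motif` (as read on the given strand), `motif_class`,
#'   `motif_length`, `repeat_count`, `tract_length`, `purity` (all `"perfect"`
#'   at this stage; see [classify_tracts()])
#' @seealso [classify_tracts()], [summarize_repeat_content()]
#' @export
find_tandem_repeats <- function(sequence,
                                thresholds = default_mining_thresholds(),
                                contig_id = "seq") {
  .check(is.character(sequence) && length(sequence) == 1L,
         "sequence must be a single string")
  .check(!is.null(names(thresholds)) && all(thresholds >= 2),
         "thresholds must be named by motif length and all >= 2")
  sequence <- toupper(sequence)
  .check(!grepl("[^ACGTN]", sequence),
         "sequence contains characters outside ACGTN")
  n <- nchar(sequence)
  if (n == 0L) return(.empty_loci())
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ok <- chars != "N"
  out <- list()
  for (mi in seq_along(thresholds)) {
    m <- as.integer(names(thresholds)[mi])
    thr <- as.integer(thresholds[mi])
    if (n < m * thr) next
    idx <- (m + 1L):n
    v <- chars[idx] == chars[idx - m] & ok[idx] & ok[idx - m]
    r <- rle(v)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= (thr - 1L) * m)) {
      j0 <- run_start[ri]                  # tract raw start, 1-based char pos
      L <- r$lengths[ri]
      k <- (L + m) %/% m                   # full copies only
      if (k < thr) next
      motif <- substr(sequence, j0, j0 + m - 1L)
      mchars <- chars[j0:(j0 + m - 1L)]
      if (length(unique(mchars)) == 1L || !.is_primitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        contig_id = contig_id, start = j0 - 1L, end = j0 - 1L + k * m,
        motif = motif, motif_class = canonicalize_motif(motif),
        motif_length = m, repeat_count = k, tract_length = k * m,
        purity = "perfect", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_loci())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine perfect tandem repeats across a contig set
#'
#' @param contigs named character vector, named list or
#'   `Biostrings::DNAStringSet` of contig sequences
#' @param thresholds see [find_tandem_repeats()]
#' @param compound_gap see [classify_tracts()]
#' @return locus table combining all contigs, classified for purity with
#'   [classify_tracts()] per contig
#' @export
mine_contigs <- function(contigs, thresholds = default_mining_thresholds(),
                         compound_gap = 10L) {
  seqs <- .as_contig_chr(contigs)
  res <- lapply(names(seqs), function(id) {
    loci <- find_tandem_repeats(seqs[[id]], thresholds, contig_id = id)
    classify_tracts(loci, seqs[[id]], compound_gap = compound_gap)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- .empty_loci()
  rownames(res) <- NULL
  res
}

#' Label repeat tracts as perfect, compound or imperfect
#'
#' Two or more maximal runs separated by at most `compound_gap` bases form a
#' cluster: clusters mixing distinct motif classes are labeled `compound`
#' (more than one motif in one repeat region), clusters of a single motif
#' class are labeled `imperfect` (an interrupted repeat of one motif). An
#' isolated run is labeled `imperfect` when a degenerate copy of its own motif
#' (at most one mismatch) sits immediately at either tract boundary, and
#' `perfect` otherwise. Only perfect loci propagate to marker selection.
#'
#' @param loci locus table from [find_tandem_repeats()] on the same sequence
#' @param sequence the sequence the loci were mined from
#' @param compound_gap maximum gap in bp between runs counted as adjacent
#' @return `loci` with the `purity` column filled in
#' @export
classify_tracts <- function(loci, sequence, compound_gap = 10L) {
  .check(compound_gap >= 0, "compound_gap must be non-negative")
  if (nrow(loci) == 0L) return(loci)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  o <- order(loci$start)
  loci <- loci[o, , drop = FALSE]
  grp <- cumsum(c(1L, ifelse(
    loci$start[-1L] - loci$end[-nrow(loci)] > compound_gap, 1L, 0L)))
  purity <- character(nrow(loci))
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) > 1L) {
      purity[sel] <- if (length(unique(loci$motif_class[sel])) > 1L)
        "compound" else "imperfect"
    } else {
      purity[sel] <- if (.degenerate_neighbor(loci[sel, ], chars))
        "imperfect" else "perfect"
    }
  }
  loci$purity <- purity
  rownames(loci) <- NULL
  loci
}

# is there a <=1-mismatch copy of the motif flush against either boundary?
.degenerate_neighbor <- function(locus, chars) {
  m <- locus$motif_length
  motif <- strsplit(locus$motif, "", fixed = TRUE)[[1]]
  dist_to <- function(word) {
    sum(word != motif | word == "N")
  }
  left_from <- locus$start - m + 1L           # 1-based window start
  if (left_from >= 1L &&
      dist_to(chars[left_from:(left_from + m - 1L)]) <= 1L) return(TRUE)
  right_from <- locus$end + 1L
  if (right_from + m - 1L <= length(chars) &&
      dist_to(chars[right_from:(right_from + m - 1L)]) <= 1L) return(TRUE)
  FALSE
}

#' Summarize repeat content of a mined locus set
#'
#' Tallies loci by motif length and purity, counts long perfect tracts, and
#' tabulates perfect-locus motif-class frequencies, optionally restricted to
#' contigs at or above a coverage floor (the convention used when reporting
#' repeat content of well-supported contigs only). "More than 5 repeats" is
#' tallied under the strict reading (repeat_count >= 6); a `ge5` tally is also
#' emitted for comparison.
#'
#' @param loci classified locus table
#' @param coverage data.frame with columns `contig_id`, `mean_coverage`;
#'   required when `coverage_min` is given and must cover every contig in
#'   `loci`
#' @param coverage_min restrict to contigs with coverage >= this value (X)
#' @return object of class `repeat_summary`: list with `by_length_purity`,
#'   `long_tracts` (per motif length, perfect loci with > 5 repeats),
#'   `by_motif_class` (perfect loci), `n_loci`
#' @export
summarize_repeat_content <- function(loci, coverage = NULL,
                                     coverage_min = NULL) {
  if (!is.null(coverage_min)) {
    .check(!is.null(coverage), "coverage table needed for coverage filtering")
    miss <- setdiff(unique(loci$contig_id), coverage$contig_id)
    .check(length(miss) == 0L,
           "contig '%s' missing from the coverage table",
           if (length(miss)) miss[1] else "")
    keep <- coverage$contig_id[coverage$mean_coverage >= coverage_min]
    loci <- loci[loci$contig_id %in% keep, , drop = FALSE]
  }
  lengths <- sort(unique(c(2L, 3L, 4L, loci$motif_length)))
  purities <- c("perfect", "compound", "imperfect")
  tab <- table(factor(loci$motif_length, levels = lengths),
               factor(loci$purity, levels = purities))
  by_lp <- as.data.frame.matrix(tab)
  by_lp <- cbind(motif_length = lengths, by_lp, total = rowSums(by_lp))
  rownames(by_lp) <- NULL
  perf <- loci[loci$purity == "perfect", , drop = FALSE]
  long <- data.frame(
    motif_length = lengths,
    gt5 = vapply(lengths, function(l) {
      sum(perf$motif_length == l & perf$repeat_count >= 6L)
    }, integer(1)),
    ge5 = vapply(lengths, function(l) {
      sum(perf$motif_length == l & perf$repeat_count >= 5L)
    }, integer(1)))
  cls <- if (nrow(perf)) {
    t0 <- sort(table(perf$motif_class), decreasing = TRUE)
    data.frame(motif_class = names(t0), count = as.integer(t0),
               frequency = as.numeric(t0) / nrow(perf),
               stringsAsFactors = FALSE)
  } else {
    data.frame(motif_class = character(), count = integer(),
               frequency = numeric())
  }
  structure(list(by_length_purity = by_lp, long_tracts = long,
                 by_motif_class = cls, n_loci = nrow(loci)),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat("Repeat content summary (", x$n_loci, " loci)\n", sep = "")
  cat("\nCounts by motif length and purity:\n")
  print(x$by_length_purity, row.names = FALSE)
  cat("\nPerfect tracts with >5 repeats (strict; ge5 for comparison):\n")
  print(x$long_tracts, row.names = FALSE)
  if (nrow(x$by_motif_class)) {
    cat("\nTop perfect motif classes:\n")
    print(utils::head(x$by_motif_class, 10), row.names = FALSE)
  }
  invisible(x)
}
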