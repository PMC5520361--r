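#' Filter mined loci to marker-development candidates by contig coverage
#'
#' Keeps perfect loci located on contigs whose mean coverage meets the floor
#' (15X by default, the depth at which an assembled repeat is considered
#' reliable enough for marker development). Order-stable.
#'
#' @param loci classified locus table (see [mine_contigs()])
#' @param coverage data.frame `contig_id`, `mean_coverage`
#' @param coverage_min minimum mean coverage in X
#' @return the subset of `loci` passing the filter
#' @export
filter_candidate_sites <- function(loci, coverage, coverage_min = 15) {
  if (nrow(loci) == 0L) return(loci)
  miss <- setdiff(unique(loci$contig_id), coverage$contig_id)
  .check(length(miss) == 0L, "contig '%s' missing from the coverage table",
         if (length(miss)) miss[1] else "")
  cov <- stats::setNames(coverage$mean_coverage, coverage$contig_id)
  loci[cov[loci$contig_id] >= coverage_min, , drop = FALSE]
}

#' Select marker-grade loci
#'
#' Applies the marker-quality filters on top of the candidate set: a perfect
#' locus is marker-grade when it has at least `min_repeats` motif copies, sits
#' on a contig of at least `min_contig_len` bp with mean coverage at least
#' `min_cov` X, and has no other detected SSR locus (of any purity) within
#' `adjacency_window` bp of either flank - maximizing locus independence and
#' allele-calling quality.
#'
#' @param candidates candidate loci (already coverage-filtered, perfect)
#' @param all_loci every detected locus on the same contigs, used for the
#'   adjacency test
#' @param contig_lengths data.frame `contig_id`, `length`
#' @param coverage data.frame `contig_id`, `mean_coverage`
#' @param min_contig_len minimum contig length in bp
#' @param min_cov minimum contig mean coverage in X
#' @param min_repeats minimum motif copy number
#' @param adjacency_window bp; no other SSR may start or end within this
#'   distance of the locus
#' @return the marker-grade subset of `candidates`, order-stable
#' @export
select_marker_grade <- function(candidates, all_loci, contig_lengths,
                                coverage, min_contig_len = 2500,
                                min_cov = 20, min_repeats = 3,
                                adjacency_window = 200) {
  if (nrow(candidates) == 0L) return(candidates)
  len <- stats::setNames(contig_lengths$length, contig_lengths$contig_id)
  cov <- stats::setNames(coverage$mean_coverage, coverage$contig_id)
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x <- candidates[i, ]
    if (is.na(len[x$contig_id]) || len[x$contig_id] < min_contig_len) next
    if (is.na(cov[x$contig_id]) || cov[x$contig_id] < min_cov) next
    if (x$repeat_count < min_repeats) next
    nb <- all_loci[all_loci$contig_id == x$contig_id &
                     !(all_loci$start == x$start & all_loci$end == x$end), ,
                   drop = FALSE]
    if (nrow(nb) && any(nb$end > x$start - adjacency_window &
                          nb$start < x$end + adjacency_window)) next
    keep[i] <- TRUE
  }
  candidates[keep, , drop = FALSE]
}

#' Primer melting temperature (Wallace/GC rule)
#'
#' `Tm = 64.9 + 41 * (GC_count - 16.4) / length`, the simple GC-count formula
#' used by the primer-design heuristic.
#'
#' @param primer primer sequence(s)
#' @return Tm in degrees C
#' @export
primer_tm <- function(primer) {
  n <- nchar(primer)
  gc <- nchar(gsub("[^GCgc]", "", primer))
  64.9 + 41 * (gc - 16.4) / n
}

# first feasible primer window on one flank, scanning away from the locus.
# flank: character vector of the flank, locus-proximal end LAST for the left
# flank and FIRST for the right flank (dir = +1 scans left flank right-to-left
# window starts). Returns list(offset from locus, length, seq) or NULL.
.find_primer_window <- function(flank, lengths, gc_range, max_homo, tm_range,
                                min_offset = 0L) {
  nf <- length(flank)
  for (d in min_offset:(nf - min(lengths))) {     # distance from locus edge
    for (len in lengths) {
      if (d + len > nf) next
      w <- flank[(nf - d - len + 1L):(nf - d)]
      s <- paste(w, collapse = "")
      gc <- sum(w %in% c("G", "C")) / len
      if (gc < gc_range[1] || gc > gc_range[2]) next
      if (max(rle(w)$lengths) >= max_homo) next
      tm <- primer_tm(s)
      if (tm < tm_range[1] || tm > tm_range[2]) next
      return(list(offset = d, length = len, seq = s, tm = tm))
    }
  }
  NULL
}

#' Design primer pairs for selected loci
#'
#' A documented heuristic (not a thermodynamic model): per flank, the primer
#' window closest to the locus is chosen among lengths `primer_length`
#' satisfying GC content in `gc_range`, no mononucleotide run of
#' `max_homopolymer` or more, and Tm (GC rule, see [primer_tm()]) inside
#' `tm_range`. If the minimal product is shorter than `product_size[1]`, the
#' right primer is pushed outward until the product fits. The marker's
#' annealing temperature is the member of `ta_set` nearest the mean primer Tm
#' (ties to the lower temperature). Loci without a feasible design are
#' skipped with a reason code.
#'
#' @param selected marker-grade locus table
#' @param contigs contig sequences (named character vector or DNAStringSet)
#' @param prefix marker name prefix; names are `prefix` + 4-digit ordinal
#' @param primer_length candidate primer lengths in bp, tried shortest first
#'   at each offset
#' @param gc_range allowed primer GC fraction
#' @param max_homopolymer a run of this many identical bases disqualifies a
#'   window
#' @param tm_range allowed primer Tm in degrees C (defaults to the `ta_set`
#'   range widened by 5 degrees each side)
#' @param product_size allowed expected product size in bp
#' @param max_flank bp of flank searched on each side
#' @param ta_set available annealing temperatures in degrees C
#' @return list with `markers` (data.frame: name, contig_id, locus
#'   coordinates, motif, repeat_count, primer sequences/coordinates/Tm/GC,
#'   `ta_c`, `expected_size`, `size_min`, `size_max`) and `skipped`
#'   (data.frame: contig_id, start, end, reason)
#' @export
design_markers <- function(selected, contigs, prefix = "BrPe",
                           primer_length = 18:24,
                           gc_range = c(0.40, 0.60),
                           max_homopolymer = 5L,
                           tm_range = NULL,
                           product_size = c(70, 300),
                           max_flank = 300L,
                           ta_set = c(55, 57, 60)) {
  seqs <- .as_contig_chr(contigs)
  if (is.null(tm_range)) tm_range <- c(min(ta_set) - 5, max(ta_set) + 5)
  markers <- list()
  skipped <- list()
  skip <- function(x, why) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      contig_id = x$contig_id, start = x$start, end = x$end, reason = why,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(selected))) {
    x <- selected[i, ]
    s <- seqs[[x$contig_id]]
    n <- nchar(s)
    lf_n <- min(x$start, max_flank)
    rf_n <- min(n - x$end, max_flank)
    if (lf_n < min(primer_length) || rf_n < min(primer_length)) {
      skip(x, "flank_too_short"); next
    }
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    left_flank <- ch[(x$start - lf_n + 1L):x$start]
    right_flank <- rev(ch[(x$end + 1L):(x$end + rf_n)])
    lw <- .find_primer_window(left_flank, primer_length, gc_range,
                              max_homopolymer, tm_range)
    if (is.null(lw)) { skip(x, "no_feasible_left_primer"); next }
    rw <- .find_primer_window(right_flank, primer_length, gc_range,
                              max_homopolymer, tm_range)
    if (is.null(rw)) { skip(x, "no_feasible_right_primer"); next }
    prod <- function(l, r) {
      (x$end + r$offset + r$length) - (x$start - l$offset - l$length)
    }
    while (prod(lw, rw) < product_size[1]) {
      rw2 <- .find_primer_window(right_flank, primer_length, gc_range,
                                 max_homopolymer, tm_range,
                                 min_offset = rw$offset + 1L)
      if (is.null(rw2)) break
      rw <- rw2
    }
    psize <- prod(lw, rw)
    if (psize < product_size[1] || psize > product_size[2]) {
      skip(x, "product_size_out_of_bounds"); next
    }
    left_start <- x$start - lw$offset - lw$length      # 0-based on contig
    right_start <- x$end + rw$offset                   # 0-based, fwd strand
    right_seq <- .revcomp(paste(ch[(right_start + 1L):
                                     (right_start + rw$length)],
                                collapse = ""))
    ta <- ta_set[which.min(abs(ta_set - mean(c(lw$tm, rw$tm))))]
    markers[[length(markers) + 1L]] <- data.frame(
      name = NA_character_, contig_id = x$contig_id, start = x$start,
      end = x$end, motif = x$motif, motif_class = x$motif_class,
      repeat_count = x$repeat_count,
      left_primer = lw$seq, left_start = left_start,
      left_length = lw$length, left_tm = lw$tm,
      left_gc = sum(strsplit(lw$seq, "")[[1]] %in% c("G", "C")) / lw$length,
      right_primer = right_seq, right_start = right_start,
      right_length = rw$length, right_tm = rw$tm,
      right_gc = sum(strsplit(rw$seq, "")[[1]] %in% c("G", "C")) / rw$length,
      expected_size = psize, ta_c = ta,
      size_min = psize - 10, size_max = psize + 10,
      stringsAsFactors = FALSE)
  }
  markers <- if (length(markers)) do.call(rbind, markers) else NULL
  if (!is.null(markers)) {
    markers$name <- sprintf("%s%04d", prefix, seq_len(nrow(markers)))
    rownames(markers) <- NULL
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(contig_id = character(), start = integer(), end = integer(),
               reason = character(), stringsAsFactors = FALSE)
  list(markers = markers, skipped = skipped)
}

#' Label markers by genomic context
#'
#' A marker is `functional` when its repeat tract overlaps an annotated
#' coding/genic interval by at least 1 bp, `structural` when its contig is
#' annotated but no interval overlaps, and `unknown` when the contig is
#' absent from the annotation.
#'
#' @param markers marker table from [design_markers()]
#' @param intervals a `GRanges`, or a data.frame with `contig_id`, `start`,
#'   `end` (0-based half-open), e.g. from [read_intervals()]
#' @return `markers` with a `genomic_context` column
#' @export
label_genomic_context <- function(markers, intervals) {
  if (methods::is(intervals, "GRanges")) {
    intervals <- data.frame(
      contig_id = as.character(GenomicRanges::seqnames(intervals)),
      start = GenomicRanges::start(intervals) - 1L,
      end = GenomicRanges::end(intervals), stringsAsFactors = FALSE)
  }
  lv <- union(markers$contig_id, intervals$contig_id)  # shared seqlevels
  gr_m <- GenomicRanges::GRanges(
    factor(markers$contig_id, levels = lv),
    IRanges::IRanges(markers$start + 1L, markers$end))
  gr_i <- GenomicRanges::GRanges(
    factor(intervals$contig_id, levels = lv),
    IRanges::IRanges(intervals$start + 1L, intervals$end))
  hits <- GenomicRanges::countOverlaps(gr_m, gr_i, minoverlap = 1L)
  ctx <- ifelse(hits > 0L, "functional", "structural")
  ctx[!(markers$contig_id %in% intervals$contig_id)] <- "unknown"
  markers$genomic_context <- ctx
  markers
}

#' Pack markers into multiplex panels
#'
#' Greedy first-fit assignment in the given order (descending PIC when
#' `order_by` is supplied): each marker joins the first open panel sharing
#' its annealing temperature with free capacity where, against every member,
#' it either carries a different dye or its expected-size window is separated
#' by at least `size_gap` bp. Otherwise a new panel is opened. Deterministic
#' given the input order.
#'
#' @param markers marker table with `name`, `ta_c`, `size_min`, `size_max`
#'   and optionally `dye`
#' @param capacity maximum markers per panel
#' @param size_gap minimum bp between size windows of same-dye members
#' @param order_by optional numeric vector (e.g. PIC); markers are placed in
#'   decreasing order of it
#' @return data.frame `panel`, `name`, `ta_c`, `size_min`, `size_max`, `dye`
#' @export
build_multiplex_panels <- function(markers, capacity = 3L, size_gap = 20,
                                   order_by = NULL) {
  .check(capacity >= 1, "capacity must be >= 1")
  if (is.null(markers$dye)) markers$dye <- NA_character_
  if (!is.null(order_by)) {
    markers <- markers[order(-order_by), , drop = FALSE]
  }
  panels <- list()     # each: list(ta, members = row indices)
  assign_row <- integer(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    placed <- FALSE
    for (p in seq_along(panels)) {
      pn <- panels[[p]]
      if (pn$ta != markers$ta_c[i] || length(pn$members) >= capacity) next
      ok <- TRUE
      for (j in pn$members) {
        same_dye <- is.na(markers$dye[i]) || is.na(markers$dye[j]) ||
          markers$dye[i] == markers$dye[j]
        if (same_dye) {
          gap <- max(markers$size_min[i] - markers$size_max[j],
                     markers$size_min[j] - markers$size_max[i])
          if (gap < size_gap) { ok <- FALSE; break }
        }
      }
      if (ok) {
        panels[[p]]$members <- c(pn$members, i)
        assign_row[i] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      panels[[length(panels) + 1L]] <- list(ta = markers$ta_c[i],
                                            members = i)
      assign_row[i] <- length(panels)
    }
  }
  out <- data.frame(panel = assign_row, name = markers$name,
                    ta_c = markers$ta_c, size_min = markers$size_min,
                    size_max = markers$size_max, dye = markers$dye,
                    stringsAsFactors = FALSE)
  out[order(out$panel), , drop = FALSE]
}
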