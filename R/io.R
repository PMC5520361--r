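#' Read assembled contigs, with an optional coverage sidecar
#'
#' Sequences are upper-cased and validated against the ACGTN alphabet;
#' duplicate FASTA ids are rejected, as is a sidecar id absent from the
#' FASTA.
#'
#' @param fasta path to a FASTA file
#' @param coverage optional path to a two-column TSV `contig_id`,
#'   `mean_coverage` (header optional but recommended)
#' @return list with `contigs` (named uppercase character vector), `coverage`
#'   (data.frame or NULL) and `lengths` (data.frame `contig_id`, `length`)
#' @export
read_contigs <- function(fasta, coverage = NULL) {
  seqs <- Biostrings::readBStringSet(fasta)   # keep invalid letters visible
  ids <- sub("\\s.*$", "", names(seqs))
  .check(!anyDuplicated(ids), "duplicate FASTA id '%s'",
         ids[duplicated(ids)][1])
  x <- toupper(as.character(seqs))
  names(x) <- ids
  for (i in seq_along(x)) {
    bad <- regexpr("[^ACGTN]", x[[i]])
    .check(bad < 0, "record '%s' has a non-ACGTN character at offset %d",
           ids[i], as.integer(bad))
  }
  cov <- NULL
  if (!is.null(coverage)) {
    cov <- utils::read.delim(coverage, header = TRUE,
                             stringsAsFactors = FALSE)
    if (!all(c("contig_id", "mean_coverage") %in% names(cov))) {
      cov <- utils::read.delim(coverage, header = FALSE,
                               col.names = c("contig_id", "mean_coverage"),
                               stringsAsFactors = FALSE)
    }
    miss <- setdiff(cov$contig_id, ids)
    .check(length(miss) == 0, "sidecar contig '%s' missing from FASTA",
           if (length(miss)) miss[1] else "")
  }
  list(contigs = x, coverage = cov,
       lengths = data.frame(contig_id = ids, length = nchar(x),
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Write contigs as FASTA (wrapped at 80 columns)
#'
#' @param contigs named character vector or DNAStringSet
#' @param path output path
#' @export
write_contigs <- function(contigs, path) {
  x <- .as_contig_chr(contigs)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 80L)
  invisible(path)
}

#' Write the coverage sidecar TSV
#' @param coverage data.frame `contig_id`, `mean_coverage`
#' @param path output path
#' @export
write_coverage <- function(coverage, path) {
  utils::write.table(coverage[, c("contig_id", "mean_coverage")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a diploid genotype table
#'
#' Long-format TSV with header `sample`, `marker`, `allele1`, `allele2`;
#' allele sizes in bp, missing encoded as `0` in both columns. A half-missing
#' call (one allele 0, the other not) is rejected.
#'
#' @param path TSV path
#' @param motif_length optional named vector of repeat-unit lengths per
#'   marker, attached as an attribute
#' @return a `genotype_table` data.frame
#' @export
read_genotypes <- function(path, motif_length = NULL) {
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("sample", "marker", "allele1", "allele2") %in% names(g)),
         "genotype TSV needs columns sample, marker, allele1, allele2")
  half <- xor(g$allele1 == 0, g$allele2 == 0)
  .check(!any(half), "half-missing diploid call at row %d",
         if (any(half)) which(half)[1] else 0L)
  lo <- pmin(g$allele1, g$allele2)
  g$allele2 <- pmax(g$allele1, g$allele2)
  g$allele1 <- lo
  if (!is.null(motif_length)) attr(g, "motif_length") <- motif_length
  class(g) <- c("genotype_table", "data.frame")
  g
}

#' Write a genotype table (long TSV, `0` = missing)
#' @param genotypes genotype table
#' @param path output path
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.table(
    as.data.frame(genotypes)[, c("sample", "marker", "allele1", "allele2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export mined loci as GFF3
#'
#' One `microsatellite` feature per locus with attributes `motif`,
#' `motif_class`, `repeat_count` and `purity`; coordinates converted to the
#' 1-based inclusive GFF3 convention at this boundary only.
#'
#' @param loci locus table (0-based half-open coordinates)
#' @param path output path
#' @export
write_loci_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    loci$contig_id, IRanges::IRanges(loci$start + 1L, loci$end),
    type = "microsatellite", motif = loci$motif,
    motif_class = loci$motif_class, repeat_count = loci$repeat_count,
    purity = loci$purity)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Export mined loci as BED (0-based half-open)
#' @param loci locus table
#' @param path output path
#' @export
write_loci_bed <- function(loci, path) {
  bed <- data.frame(loci$contig_id, loci$start, loci$end,
                    paste0(loci$motif, "x", loci$repeat_count), 0, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read annotation intervals from BED or GFF3
#'
#' Both dialects are accepted and normalized to 0-based half-open
#' coordinates. The format is taken from the file extension (`.bed`, `.gff`,
#' `.gff3`) unless given.
#'
#' @param path interval file
#' @param format `"auto"`, `"bed"` or `"gff3"`
#' @return data.frame `contig_id`, `start` (0-based), `end` (exclusive)
#' @export
read_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else
      "gff3"
  }
  .pre_validate_intervals(path, format)
  gr <- if (format == "bed") rtracklayer::import.bed(path) else
    rtracklayer::import.gff3(path)
  data.frame(contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), row.names = NULL,
             stringsAsFactors = FALSE)
}

# cheap structural validation so malformed lines are reported by number
.pre_validate_intervals <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  min_cols <- if (format == "bed") 3L else 9L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") ||
          (format == "bed" && grepl("^(track|browser)", ln))) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    .check(length(f) >= min_cols,
           "malformed %s line %d: expected >= %d tab-separated fields",
           format, i, min_cols)
    pos <- if (format == "bed") f[2:3] else f[4:5]
    .check(!anyNA(suppressWarnings(as.numeric(pos))),
           "malformed %s line %d: non-numeric coordinates", format, i)
  }
  invisible(TRUE)
}

#' Read a cross-species transferability matrix
#'
#' TSV with a `species` column followed by one column per marker; cells `+`,
#' `-` or NA.
#'
#' @param path TSV path
#' @return character matrix, species in rows
#' @export
read_transfer_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  .check(names(d)[1] == "species", "first column must be 'species'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$species
  .check(all(m %in% c("+", "-") | is.na(m)), "cells must be '+', '-' or NA")
  m
}

#' Read ln P(D) replicate runs (`K<TAB>run<TAB>lnPD`)
#' @param path TSV path
#' @return data.frame `K`, `run`, `lnPD`
#' @export
read_structure_runs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("K", "run", "lnPD") %in% names(d)),
         "expected columns K, run, lnPD")
  d
}

#' Read a Q-matrix (samples x clusters TSV, first column = sample id)
#' @param path TSV path
#' @return numeric matrix with sample rownames
#' @export
read_q_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

#' Published descriptive statistics of the 42 polymorphic BrPe markers
#'
#' The shipped reference panel: per-marker repeat motif, annealing
#' temperature, allele count, allele size range and He/Ho/PIC of the 42
#' polymorphic microsatellite markers from the sour passion fruit
#' (*Passiflora edulis*) marker screen, used for report-parity checks.
#'
#' @return data.frame, one row per marker
#' @export
brpe_marker_stats <- function() {
  utils::read.delim(system.file("extdata", "brpe_marker_panel.tsv",
                                package = "ssrpipe"),
                    stringsAsFactors = FALSE)
}

#' Published 79-species x 18-marker cross-amplification matrix
#'
#' Presence/absence calls of the 18 highest-PIC BrPe markers across 79
#' *Passiflora* species (reference species *P. edulis* included as the
#' all-positive row).
#'
#' @return character matrix of `+`/`-` calls
#' @export
brpe_transfer_matrix <- function() {
  read_transfer_matrix(system.file("extdata", "brpe_transferability.tsv",
                                   package = "ssrpipe"))
}
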