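#' Round half away from zero
#'
#' Report-layer rounding used everywhere a printed table value is reproduced
#' (R's `round()` rounds half to even, which does not match how genotyping
#' reports are conventionally rounded).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f + sign(x) * 0.5 + sign(x) * 1e-9) / f
}

# internal: stop unless condition, with sprintf-style message
.check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# internal: coerce a contig container (DNAStringSet, named list or named
# character vector) to a named uppercase character vector
.as_contig_chr <- function(contigs) {
  if (methods::is(contigs, "DNAStringSet")) {
    x <- as.character(contigs)
  } else {
    x <- unlist(contigs, use.names = TRUE)
    x <- toupper(as.character(x))
    names(x) <- names(contigs)
  }
  .check(!is.null(names(x)) && !anyNA(names(x)) && all(nzchar(names(x))),
         "contigs must be named")
  x
}

# internal: reverse complement of a plain character motif
.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# internal: empty locus table with the canonical column set
.empty_loci <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             motif = character(), motif_class = character(),
             motif_length = integer(), repeat_count = integer(),
             tract_length = integer(), purity = character(),
             stringsAsFactors = FALSE)
}
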