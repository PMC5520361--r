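#' Canonical representative of a repeat motif class
#'
#' Microsatellite motifs are equivalent under cyclic rotation and reverse
#' complementation: an (AT)n tract read on the other strand is (TA)n, and a
#' GAA repeat is the same locus as TTC. The canonical representative is the
#' lexicographically smallest string among all rotations of the motif and all
#' rotations of its reverse complement, giving every member of a class one
#' deterministic name (e.g. the GAA/TTC class canonicalizes to "AAG").
#'
#' @param motif DNA string over ACGT, length 2-6, primitive (not itself a
#'   tandem repetition of a shorter word) and not homopolymeric.
#' @return single character string, the class representative
#' @examples
#' canonicalize_motif("TA")   # "AT"
#' canonicalize_motif("TTC")  # "AAG"
#' @export
canonicalize_motif <- function(motif) {
  .check(is.character(motif) && length(motif) == 1L && !is.na(motif),
         "motif must be a single string")
  motif <- toupper(motif)
  n <- nchar(motif)
  .check(n >= 2L && n <= 6L, "motif length must be 2-6, got %d", n)
  .check(grepl("^[ACGT]+$", motif), "motif '%s' contains non-ACGT characters",
         motif)
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  .check(length(unique(chars)) > 1L, "motif '%s' is homopolymeric", motif)
  .check(.is_primitive(motif),
         "motif '%s' is a repetition of a shorter motif", motif)
  min(c(.rotations(motif), .rotations(.revcomp(motif))))
}

# all cyclic rotations of a word
.rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(x, k + 1L, n), substr(x, 1L, k))
  }, character(1))
}

# TRUE unless the word is a whole-number repetition of a shorter word
.is_primitive <- function(x) {
  n <- nchar(x)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        x == strrep(substr(x, 1L, d), n %/% d)) {
      return(FALSE)
    }
  }
  TRUE
}
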