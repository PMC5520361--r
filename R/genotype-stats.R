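#' Snap fragment sizes onto the motif grid (Tandem-style allele binning)
#'
#' Electrophoretic fragment sizes are fractional; true alleles of a perfect
#' microsatellite differ by whole motif units. The binning picks the grid
#' offset `o` in `[0, m)` (searched at 0.1 bp resolution, ties to the
#' smallest `o`) minimizing the summed distance of all sizes to the grid
#' `o + k * m`, snaps each size to its nearest grid point and rounds to whole
#' bp. Any allele whose residual exceeds `m / 4` is flagged as problematic
#' (it cannot be confidently assigned to a repeat rung).
#'
#' @param sizes numeric fragment sizes in bp (NA / 0 entries ignored)
#' @param motif_length repeat unit length `m` in bp, 2-6
#' @return list: `binned` (integer sizes, same length as input, NA where
#'   input was missing), `offset`, `residual` (signed, bp), `flagged`
#'   (logical, residual > m/4)
#' @export
bin_alleles <- function(sizes, motif_length) {
  m <- as.integer(motif_length)
  .check(m >= 2L && m <= 6L, "motif_length must be in 2..6")
  obs <- !is.na(sizes) & sizes > 0
  .check(any(obs), "no observed allele sizes to bin")
  s <- sizes[obs]
  offsets <- seq(0, m - 0.1, by = 0.1)
  cost <- vapply(offsets, function(o) {
    sum(abs(s - (o + m * round((s - o) / m))))
  }, numeric(1))
  o <- offsets[which(cost <= min(cost) + 1e-12)[1]]   # ties to smallest o
  grid_val <- o + m * round((s - o) / m)
  residual <- s - grid_val
  binned <- rep(NA_integer_, length(sizes))
  binned[obs] <- as.integer(round(grid_val))
  res_full <- rep(NA_real_, length(sizes))
  res_full[obs] <- residual
  flagged <- rep(NA, length(sizes))
  flagged[obs] <- abs(residual) > m / 4
  list(binned = binned, offset = o, residual = res_full, flagged = flagged)
}

# allele frequencies over typed individuals of one marker
.allele_freqs <- function(a1, a2) {
  typed <- a1 > 0 & a2 > 0
  alleles <- c(a1[typed], a2[typed])
  tab <- table(alleles)
  list(p = as.numeric(tab) / length(alleles),
       sizes = as.numeric(names(tab)), n_typed = sum(typed),
       het = sum(a1[typed] != a2[typed]))
}

#' Expected heterozygosity from allele frequencies
#'
#' Unbiased (finite-sample) form `(2n / (2n - 1)) * (1 - sum p_i^2)` with `n`
#' the number of typed diploid individuals; set `unbiased = FALSE` for the
#' plain gene-diversity `1 - sum p_i^2`.
#'
#' @param p allele frequency vector
#' @param n typed individuals (required when `unbiased = TRUE`)
#' @param unbiased apply the 2n/(2n-1) gene-copy correction
#' @return expected heterozygosity in `[0, 1]`
#' @export
expected_het <- function(p, n = NULL, unbiased = TRUE) {
  h <- 1 - sum(p^2)
  if (!unbiased) return(h)
  .check(!is.null(n) && n >= 1, "n (typed individuals) needed for unbiased He")
  2 * n / (2 * n - 1) * h
}

#' Polymorphic information content
#'
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`: the probability that a
#' random offspring is informative for linkage given parents drawn at these
#' allele frequencies. Always `PIC <= He`.
#'
#' @param p allele frequency vector
#' @return PIC in `[0, 1)`
#' @export
pic_value <- function(p) {
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Per-marker descriptive statistics
#'
#' For every marker of a genotype table: allele count `k`, size range,
#' observed heterozygosity `Ho` (heterozygotes / typed individuals), unbiased
#' expected heterozygosity `He`, `PIC`, typed count and a polymorphic flag
#' (`k >= 2`). Statistics are computed over typed individuals only; a marker
#' with zero typed individuals is an error.
#'
#' @param genotypes a `genotype_table` (long data.frame `sample`, `marker`,
#'   `allele1`, `allele2`; 0 = missing), e.g. from [generate_genotypes()] or
#'   [read_genotypes()]
#' @param unbiased use the 2n/(2n-1) correction in He
#' @return data.frame: `marker`, `n_typed`, `k`, `size_min`, `size_max`,
#'   `ho`, `he`, `pic`, `polymorphic`
#' @export
marker_statistics <- function(genotypes, unbiased = TRUE) {
  .check(all(c("sample", "marker", "allele1", "allele2") %in%
               names(genotypes)), "not a genotype table")
  out <- lapply(split(genotypes, genotypes$marker), function(g) {
    f <- .allele_freqs(g$allele1, g$allele2)
    .check(f$n_typed > 0, "marker '%s' has no typed individuals",
           g$marker[1])
    data.frame(marker = g$marker[1], n_typed = f$n_typed,
               k = length(f$p),
               size_min = min(f$sizes), size_max = max(f$sizes),
               ho = f$het / f$n_typed,
               he = expected_het(f$p, f$n_typed, unbiased = unbiased),
               pic = pic_value(f$p),
               polymorphic = length(f$p) >= 2L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[match(unique(genotypes$marker), res$marker), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Panel-level summary of marker statistics
#'
#' Aggregates a set of per-marker statistics the way a marker-development
#' report does: counts of tested / amplifying / polymorphic markers, then
#' totals, means and ranges of allele count, He, Ho and PIC over the
#' polymorphic markers. Means are reported to 2 decimals and the polymorphic
#' rate as a whole percent of amplifying markers (half-up rounding at the
#' report layer only).
#'
#' @param stats per-marker statistics: data.frame with `k` (or `n_alleles`),
#'   `he`, `ho`, `pic` and optionally `polymorphic`
#' @param n_tested,n_amplifying panel-level counts; default to `nrow(stats)`
#' @return object of class `panel_summary` (a list; see fields in source)
#' @export
summarize_panel <- function(stats, n_tested = nrow(stats),
                            n_amplifying = nrow(stats)) {
  k <- if (!is.null(stats$k)) stats$k else stats$n_alleles
  .check(!is.null(k), "stats needs an allele-count column (k or n_alleles)")
  poly <- if (!is.null(stats$polymorphic)) stats$polymorphic else k >= 2L
  s <- stats[poly, , drop = FALSE]
  kp <- k[poly]
  structure(list(
    n_tested = n_tested, n_amplifying = n_amplifying,
    n_polymorphic = sum(poly),
    polymorphic_rate_pct = round_half_up(100 * sum(poly) / n_amplifying),
    total_alleles = sum(kp),
    mean_k = round_half_up(mean(kp), 2), k_range = range(kp),
    mean_he = round_half_up(mean(s$he), 2), he_range = range(s$he),
    mean_ho = round_half_up(mean(s$ho), 2), ho_range = range(s$ho),
    mean_pic = round_half_up(mean(s$pic), 2), pic_range = range(s$pic)),
    class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Panel summary: %d tested, %d amplifying, %d polymorphic (%d%%)\n",
           "  total alleles %d; alleles/locus mean %.2f (range %d-%d)\n",
           "  He mean %.2f (%.2f-%.2f); Ho mean %.2f (%.2f-%.2f); ",
           "PIC mean %.2f (%.2f-%.2f)\n"),
    x$n_tested, x$n_amplifying, x$n_polymorphic, x$polymorphic_rate_pct,
    x$total_alleles, x$mean_k, x$k_range[1], x$k_range[2],
    x$mean_he, x$he_range[1], x$he_range[2],
    x$mean_ho, x$ho_range[1], x$ho_range[2],
    x$mean_pic, x$pic_range[1], x$pic_range[2]))
  invisible(x)
}

#' Concordance of observed allele ranges with expected product sizes
#'
#' Two per-marker flags: `within_tol` when the expected size falls inside the
#' observed range widened by the fractional tolerance (or an observed range
#' edge lies within `tolerance * expected` of the expected size), and `exact`
#' when the expected size lies inside the raw observed range.
#'
#' @param expected expected product sizes in bp
#' @param obs_min,obs_max observed allele size range per marker
#' @param tolerance fractional tolerance (default 5%)
#' @return list with `within_tol`, `exact` (logical vectors) and
#'   `prop_within`, `prop_exact`
#' @export
amplicon_size_concordance <- function(expected, obs_min, obs_max,
                                      tolerance = 0.05) {
  .check(all(expected > 0), "expected sizes must be positive")
  within <- (expected >= obs_min * (1 - tolerance) &
               expected <= obs_max * (1 + tolerance)) |
    abs(obs_min - expected) <= tolerance * expected |
    abs(obs_max - expected) <= tolerance * expected
  exact <- expected >= obs_min & expected <= obs_max
  list(within_tol = within, exact = exact,
       prop_within = mean(within), prop_exact = mean(exact))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Direct enumeration over all tables with the observed margins: the
#' two-sided p-value sums the hypergeometric probabilities of every table at
#' most as probable as the observed one (with 1e-7 relative slack on the
#' comparison, the usual guard against floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts
#' @return two-sided p-value
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  .check(all(dim(tab) == c(2L, 2L)), "need a 2x2 table")
  .check(all(tab >= 0) && all(tab == floor(tab)),
         "counts must be non-negative integers")
  .check(sum(tab) >= 1, "empty table")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0L, r1 + c1 - n); a_max <- min(r1, c1)
  a_all <- a_min:a_max
  pr <- stats::dhyper(a_all, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}
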