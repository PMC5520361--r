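#' Simulation specification for the synthetic-data generators
#'
#' One seeded specification drives every generator in the package:
#' contigs with planted repeat tracts ([generate_contigs()]), Hardy-Weinberg
#' diploid genotypes ([generate_genotypes()]), cross-species amplification
#' matrices ([generate_transfer_matrix()]) and ln P(D) replicate series with a
#' change-point at a known number of clusters ([generate_structure_runs()]).
#' All randomness flows from the single integer `seed`, so identical specs
#' give bit-identical outputs.
#'
#' Defaults mirror the study conditions the pipeline is built around: ten
#' genotyped accessions, a 79-species x 18-marker transfer screen with a 72%
#' amplification probability, and ln P(D) curves for K = 1..10 with 20
#' replicate runs per K.
#'
#' @param seed integer seed (< 2^31 - 100); fixes all randomness end-to-end
#' @param n_contigs number of contigs to simulate
#' @param contig_length length-2 vector, min and max contig length in bp
#' @param gc background GC fraction in (0, 1)
#' @param tracts data.frame of tracts to plant, columns `motif`,
#'   `repeat_count`, optional `purity` (`perfect`/`compound`/`imperfect`,
#'   default perfect), optional `motif2`, `repeat_count2` (compound tracts),
#'   optional `contig` (1-based index) and `start` (0-based bp); unassigned
#'   tracts are spread round-robin across contigs
#' @param coverage per-contig mean coverage (X); either a vector of length
#'   `n_contigs` or a length-2 range to sample uniformly
#' @param flank_window bp on each side of a planted tract guaranteed free of
#'   other SSRs at the default mining thresholds
#' @param n_samples diploid samples for the genotype generator
#' @param loci per-locus allele-frequency specs for the genotype generator: a
#'   list of lists with `name`, `p` (frequencies summing to 1), `motif_length`
#'   and `offset_bp`; default [default_genotype_loci()]
#' @param missing_rate per-sample-per-locus missing genotype probability
#' @param transfer list with `n_species` (including the reference row),
#'   `n_markers` and `prob` (scalar or per-non-reference-species vector)
#' @param deltak list with `true_k`, `k_max`, `n_runs`, `noise_sd` describing
#'   the simulated ln P(D) change-point scenario
#' @return validated object of class `sim_spec`
#' @export
sim_spec <- function(seed = 1L,
                     n_contigs = 3L,
                     contig_length = c(3000L, 5000L),
                     gc = 0.38,
                     tracts = NULL,
                     coverage = c(5, 40),
                     flank_window = 200L,
                     n_samples = 10L,
                     loci = NULL,
                     missing_rate = 0,
                     transfer = list(n_species = 79L, n_markers = 18L,
                                     prob = 0.72),
                     deltak = list(true_k = 4L, k_max = 10L, n_runs = 20L,
                                   noise_sd = 5)) {
  .check(is.numeric(seed) && length(seed) == 1L && seed == floor(seed) &&
           seed < 2^31 - 100, "seed must be a single integer below 2^31-100")
  .check(n_contigs >= 1, "n_contigs must be >= 1")
  .check(length(contig_length) == 2L && contig_length[1] <= contig_length[2] &&
           contig_length[1] > 0, "contig_length must be a valid (min, max)")
  .check(gc > 0 && gc < 1, "GC fraction must be in (0, 1)")
  .check(missing_rate >= 0 && missing_rate < 1,
         "missing_rate must be in [0, 1)")
  if (is.null(loci)) loci <- default_genotype_loci()
  for (lc in loci) {
    .check(abs(sum(lc$p) - 1) <= 1e-9,
           "allele frequencies for locus '%s' do not sum to 1", lc$name)
    .check(all(lc$p >= 0), "negative allele frequency for locus '%s'", lc$name)
  }
  .check(all(transfer$prob >= 0 & transfer$prob <= 1),
         "transfer probabilities must be in [0, 1]")
  .check(transfer$n_species >= 1 && transfer$n_markers >= 1,
         "transfer matrix needs at least one species and one marker")
  .check(deltak$n_runs >= 2, "at least 2 runs per K (sd undefined otherwise)")
  .check(deltak$true_k >= 2 && deltak$true_k <= deltak$k_max - 1,
         "true K must lie in [2, k_max - 1]")
  if (!is.null(tracts)) {
    .check(is.data.frame(tracts) &&
             all(c("motif", "repeat_count") %in% names(tracts)),
           "tracts needs columns motif and repeat_count")
    if (is.null(tracts$purity)) tracts$purity <- "perfect"
    .check(all(tracts$purity %in% c("perfect", "compound", "imperfect")),
           "unknown tract purity")
    for (mo in tracts$motif) {
      .check(grepl("^[ACGT]{2,4}$", mo), "tract motif '%s' must be 2-4 bp ACGT",
             mo)
      .check(length(unique(strsplit(mo, "")[[1]])) > 1L,
             "tract motif '%s' is homopolymeric", mo)
    }
    .check(all(tracts$repeat_count >= 1), "repeat_count must be >= 1")
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length), gc = gc,
                 tracts = tracts, coverage = coverage,
                 flank_window = as.integer(flank_window),
                 n_samples = as.integer(n_samples), loci = loci,
                 missing_rate = missing_rate, transfer = transfer,
                 deltak = deltak),
            class = "sim_spec")
}

#' Default per-locus allele-frequency specifications
#'
#' A deterministic panel emulating a marker screen dominated by di-nucleotide
#' repeats with a smaller tri-nucleotide fraction; allele counts cycle over
#' 2..5 with geometric-decay frequencies, allele sizes sit on the motif grid.
#'
#' @param n_di,n_tri number of di- and tri-nucleotide loci
#' @return list of per-locus specs for [sim_spec()]
#' @export
default_genotype_loci <- function(n_di = 50L, n_tri = 10L) {
  mk <- function(i, m) {
    k <- 2L + (i - 1L) %% 4L
    w <- 0.6^(0:(k - 1L))
    list(name = sprintf("L%s%02d", if (m == 2L) "d" else "t", i),
         p = w / sum(w), motif_length = m,
         offset_bp = 100L + m * ((i * 7L) %% 40L))
  }
  c(lapply(seq_len(n_di), mk, m = 2L),
    lapply(seq_len(n_tri), mk, m = 3L))
}

# expand one tract spec into its planted sequence and truth span
.tract_sequence <- function(tr) {
  m <- nchar(tr$motif)
  base <- strrep(tr$motif, tr$repeat_count)
  if (tr$purity == "perfect") {
    base
  } else if (tr$purity == "compound") {
    .check(!is.null(tr$motif2) && !is.na(tr$motif2),
           "compound tract needs motif2")
    k2 <- if (is.null(tr$repeat_count2) || is.na(tr$repeat_count2))
      tr$repeat_count else tr$repeat_count2
    paste0(base, strrep(tr$motif2, k2))
  } else {                                  # imperfect: one degenerate copy
    k1 <- ceiling(tr$repeat_count / 2)
    bad <- strsplit(tr$motif, "")[[1]]
    alt <- setdiff(c("A", "C", "G", "T"), bad[1])[1]
    bad[1] <- alt
    paste0(strrep(tr$motif, k1), paste(bad, collapse = ""),
           strrep(tr$motif, tr$repeat_count - k1))
  }
}

# a word at Hamming distance >= 2 from `motif`, deterministic
.guard_word <- function(motif) {
  ch <- strsplit(motif, "")[[1]]
  vapply(ch, function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1)) |>
    paste(collapse = "")
}

#' Generate contigs with planted SSR tracts and known truth
#'
#' Background bases are i.i.d. at the requested GC content. Each planted
#' tract is recorded in the truth table with exact 0-based half-open
#' coordinates; the bases flanking a planted tract are hardened (Hamming
#' distance >= 2 from the aligned motif copy) so a planted perfect tract can
#' be neither extended nor reclassified, and a `flank_window` on each side is
#' resampled until free of spurious SSRs at the default mining thresholds.
#'
#' @param spec a [sim_spec()]
#' @return list with `contigs` (named uppercase character vector,
#'   FASTA-writable via [write_contigs()]), `coverage` (data.frame
#'   `contig_id`, `mean_coverage`) and `truth` (data.frame of planted loci:
#'   `contig_id`, `start`, `end`, `motif`, `repeat_count`, `purity`)
#' @export
generate_contigs <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  lens <- if (spec$contig_length[1] == spec$contig_length[2])
    rep(spec$contig_length[1], spec$n_contigs)
  else
    sample(spec$contig_length[1]:spec$contig_length[2], spec$n_contigs,
           replace = TRUE)
  ids <- sprintf("contig_%03d", seq_len(spec$n_contigs))
  gc <- spec$gc
  bg <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE,
                           prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                    (1 - gc) / 2))
  seqs <- lapply(lens, bg)
  names(seqs) <- ids

  tracts <- spec$tracts
  truth <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      repeat_count = integer(), purity = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(tracts) && nrow(tracts)) {
    if (is.null(tracts$contig)) {
      tracts$contig <- rep_len(seq_len(spec$n_contigs), nrow(tracts))
    }
    if (is.null(tracts$start)) tracts$start <- NA_integer_
    margin <- spec$flank_window + 2L * 4L
    for (ci in unique(tracts$contig)) {
      rows <- which(tracts$contig == ci)
      clen <- lens[ci]
      # auto-place unpositioned tracts evenly inside the margins
      auto <- rows[is.na(tracts$start[rows])]
      if (length(auto)) {
        span <- clen - 2L * margin
        .check(span > 0, "contig %d too short for planted tracts", ci)
        pos <- margin + floor(span * (seq_along(auto) - 0.5) /
                                length(auto))
        tracts$start[auto] <- as.integer(pos)
      }
      spans <- lapply(rows, function(r) {
        tr <- as.list(tracts[r, ])
        len <- nchar(.tract_sequence(tr))
        c(tracts$start[r], tracts$start[r] + len)
      })
      .check(all(vapply(spans, function(s) s[1] >= nchar(tracts$motif[1]) &&
                          s[2] <= clen, logical(1))),
             "planted tract does not fit inside contig %d (%d bp)", ci, clen)
      if (length(spans) > 1L) {
        o <- order(vapply(spans, `[`, numeric(1), 1))
        s <- spans[o]
        for (j in seq_len(length(s) - 1L)) {
          .check(s[[j]][2] <= s[[j + 1L]][1],
                 "planted tracts overlap on contig %d", ci)
        }
      }
    }
    for (r in seq_len(nrow(tracts))) {
      tr <- as.list(tracts[r, ])
      ci <- tr$contig
      tseq <- strsplit(.tract_sequence(tr), "")[[1]]
      a <- tr$start                       # 0-based
      seqs[[ci]][(a + 1L):(a + length(tseq))] <- tseq
      m <- nchar(tr$motif)
      g <- strsplit(.guard_word(tr$motif), "")[[1]]
      if (a - m >= 0L) seqs[[ci]][(a - m + 1L):a] <- g
      b <- a + length(tseq)
      if (b + m <= lens[ci]) seqs[[ci]][(b + 1L):(b + m)] <- g
      truth <- rbind(truth, data.frame(
        contig_id = ids[ci], start = a, end = a + length(tseq),
        motif = tr$motif, repeat_count = tr$repeat_count,
        purity = tr$purity, stringsAsFactors = FALSE))
    }
    # scrub spurious SSRs out of the planted flank windows
    for (ci in unique(tracts$contig)) {
      rows <- which(tracts$contig == ci)
      planted <- truth[truth$contig_id == ids[ci], , drop = FALSE]
      protect <- unlist(lapply(seq_len(nrow(planted)), function(j) {
        (planted$start[j] - nchar(planted$motif[j]) + 1L):
          (planted$end[j] + nchar(planted$motif[j]))
      }))
      for (iter in seq_len(100L)) {
        found <- find_tandem_repeats(paste(seqs[[ci]], collapse = ""),
                                     contig_id = ids[ci])
        bad <- integer(0)
        for (j in seq_len(nrow(planted))) {
          w0 <- planted$start[j] - spec$flank_window
          w1 <- planted$end[j] + spec$flank_window
          hit <- found[found$end > w0 & found$start < w1, , drop = FALSE]
          for (h in seq_len(nrow(hit))) {
            if (any(hit$start[h] == planted$start &
                      hit$end[h] <= planted$end)) next  # the planted tract
            if (hit$start[h] >= planted$start[j] &&
                  hit$end[h] <= planted$end[j]) next    # inside planted span
            bad <- c(bad, (hit$start[h] + 1L):hit$end[h])
          }
        }
        bad <- setdiff(bad, protect)
        if (!length(bad)) break
        seqs[[ci]][bad] <- bg(length(bad))
        if (iter == 100L) stop("could not clear flanking SSRs; relax spec",
                               call. = FALSE)
      }
    }
  }
  cov <- spec$coverage
  cov <- if (length(cov) == spec$n_contigs) {
    as.numeric(cov)                       # per-contig coverage, as given
  } else {
    .check(length(cov) == 2L, "coverage must be per-contig or a (min, max)")
    stats::runif(spec$n_contigs, cov[1], cov[2])
  }
  .check(all(cov > 0), "coverage must be positive")
  list(contigs = vapply(seqs, paste, character(1), collapse = ""),
       coverage = data.frame(contig_id = ids, mean_coverage = cov,
                             stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate Hardy-Weinberg diploid genotypes with known allele frequencies
#'
#' For each locus, allele sizes sit on the motif grid
#' (`offset_bp + motif_length * 0:(k-1)`) and the two gene copies of each
#' sample are drawn independently from the locus frequency vector. Missing
#' genotypes (both alleles 0) are sampled per sample per locus at
#' `missing_rate`.
#'
#' @param spec a [sim_spec()]
#' @return list with `genotypes` (a `genotype_table`, see
#'   [read_genotypes()] for the layout) and `freqs` (data.frame `marker`,
#'   `allele_bp`, `freq` of the true frequencies)
#' @export
generate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 11L)
  rows <- list()
  freqs <- list()
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  for (lc in spec$loci) {
    sizes <- lc$offset_bp + lc$motif_length * (seq_along(lc$p) - 1L)
    a1 <- sizes[sample.int(length(sizes), spec$n_samples, replace = TRUE,
                           prob = lc$p)]
    a2 <- sizes[sample.int(length(sizes), spec$n_samples, replace = TRUE,
                           prob = lc$p)]
    lo <- pmin(a1, a2); hi <- pmax(a1, a2)
    if (spec$missing_rate > 0) {
      miss <- stats::runif(spec$n_samples) < spec$missing_rate
      lo[miss] <- 0L; hi[miss] <- 0L
    }
    rows[[lc$name]] <- data.frame(sample = samples, marker = lc$name,
                                  allele1 = lo, allele2 = hi,
                                  stringsAsFactors = FALSE)
    freqs[[lc$name]] <- data.frame(marker = lc$name, allele_bp = sizes,
                                   freq = lc$p, stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, rows)
  rownames(gt) <- NULL
  ml <- vapply(spec$loci, `[[`, numeric(1), "motif_length")
  names(ml) <- vapply(spec$loci, `[[`, character(1), "name")
  attr(gt, "motif_length") <- ml
  class(gt) <- c("genotype_table", "data.frame")
  list(genotypes = gt, freqs = do.call(rbind, freqs))
}

#' Generate a synthetic cross-species amplification matrix
#'
#' Row 1 is the reference species (all `+`); every other cell is an
#' independent Bernoulli draw at the per-species transfer probability.
#'
#' @param spec a [sim_spec()]
#' @return character matrix of `+`/`-` calls, species in rows, markers in
#'   columns
#' @export
generate_transfer_matrix <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 23L)
  ns <- spec$transfer$n_species
  nm <- spec$transfer$n_markers
  p <- rep_len(spec$transfer$prob, ns - 1L)
  m <- matrix("-", ns, nm,
              dimnames = list(
                c("reference", sprintf("species_%02d", seq_len(ns - 1L))),
                sprintf("M%02d", seq_len(nm))))
  m[1L, ] <- "+"
  if (ns > 1L) {
    draw <- matrix(stats::runif((ns - 1L) * nm) < p, ns - 1L, nm)
    m[-1L, ][draw] <- "+"
  }
  m
}

#' Generate ln P(D) replicate series with a change-point at a true K
#'
#' The mean log-likelihood curve rises steeply up to the true number of
#' clusters and then plateaus (slope ratio 20:1); each of the `n_runs`
#' replicates adds independent Gaussian noise of sd `noise_sd`, emulating
#' across-run variation of an admixture sampler.
#'
#' @param spec a [sim_spec()]
#' @return data.frame with columns `K`, `run`, `lnPD`
#' @export
generate_structure_runs <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed + 37L)
  dk <- spec$deltak
  K <- seq_len(dk$k_max)
  mean_curve <- -5000 + 400 * pmin(K, dk$true_k) + 20 * pmax(0, K - dk$true_k)
  out <- expand.grid(run = seq_len(dk$n_runs), K = K)[, c("K", "run")]
  out <- out[order(out$K, out$run), ]
  out$lnPD <- mean_curve[out$K] + stats::rnorm(nrow(out), sd = dk$noise_sd)
  rownames(out) <- NULL
  out
}
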