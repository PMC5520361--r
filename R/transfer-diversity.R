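#' Summarize a cross-species amplification matrix
#'
#' Rates are "+" calls over non-NA calls: per species (row), per marker
#' (column) and overall. Universal markers amplify in every species. Reported
#' percentages are rounded half-up to whole percent; unrounded proportions
#' are kept alongside. When a reference species row is present, the overall
#' rate excluding it is also emitted (the two rarely differ by more than a
#' point, but both conventions are in use).
#'
#' @param mat character matrix of `+` / `-` / NA calls, species in rows,
#'   markers in columns
#' @param reference optional reference species row name; that row must be all
#'   `+`
#' @return list: `per_species` (data.frame with counts, `rate`, `pct`),
#'   `per_marker`, `overall_rate`, `overall_pct`,
#'   `overall_rate_excl_reference` (NA when no reference), `universal`
#'   (marker names)
#' @export
transferability_summary <- function(mat, reference = NULL) {
  .check(is.matrix(mat) && nrow(mat) >= 1 && ncol(mat) >= 1,
         "need a species x marker matrix")
  .check(all(mat %in% c("+", "-") | is.na(mat)),
         "calls must be '+', '-' or NA")
  if (!is.null(reference)) {
    .check(reference %in% rownames(mat), "reference '%s' not found", reference)
    .check(all(mat[reference, ] == "+", na.rm = TRUE) &&
             !anyNA(mat[reference, ]),
           "reference species row must be all '+'")
  }
  pos <- mat == "+"
  nn <- !is.na(mat)
  sp_pos <- rowSums(pos, na.rm = TRUE); sp_n <- rowSums(nn)
  mk_pos <- colSums(pos, na.rm = TRUE); mk_n <- colSums(nn)
  sp_rate <- ifelse(sp_n > 0, sp_pos / sp_n, NA_real_)
  mk_rate <- ifelse(mk_n > 0, mk_pos / mk_n, NA_real_)
  overall <- sum(pos, na.rm = TRUE) / sum(nn)
  excl <- if (!is.null(reference)) {
    keep <- rownames(mat) != reference
    sum(pos[keep, ], na.rm = TRUE) / sum(nn[keep, ])
  } else NA_real_
  universal <- colnames(mat)[vapply(seq_len(ncol(mat)), function(j) {
    all(!is.na(mat[, j]) & mat[, j] == "+")
  }, logical(1))]
  list(
    per_species = data.frame(species = rownames(mat), n_pos = sp_pos,
                             n_called = sp_n, rate = sp_rate,
                             pct = round_half_up(100 * sp_rate),
                             row.names = NULL, stringsAsFactors = FALSE),
    per_marker = data.frame(marker = colnames(mat), n_pos = mk_pos,
                            n_called = mk_n, rate = mk_rate,
                            pct = round_half_up(100 * mk_rate),
                            row.names = NULL, stringsAsFactors = FALSE),
    overall_rate = overall, overall_pct = round_half_up(100 * overall),
    overall_rate_excl_reference = excl,
    universal = universal)
}

#' Band-coefficient (Dice) distance matrix from codominant genotypes
#'
#' Each sample is reduced to its band-presence set: every distinct
#' (marker, allele size) it carries, a homozygote contributing a single band,
#' exactly as co-dominant alleles appear as bands on a gel. For a sample pair
#' the similarity is the Dice form `S = 2 a / (n_x + n_y)` over shared bands
#' `a`, markers missing in either sample excluded pairwise; the distance is
#' `1 - S`. `method = "jaccard"` uses `S = a / (n_x + n_y - a)` instead.
#'
#' @param genotypes a genotype table (long format; 0 = missing)
#' @param method `"dice"` (the Band coefficient) or `"jaccard"`
#' @return symmetric distance matrix with zero diagonal, entries in `[0, 1]`
#' @export
band_distance_matrix <- function(genotypes, method = c("dice", "jaccard")) {
  method <- match.arg(method)
  samples <- unique(genotypes$sample)
  .check(length(samples) >= 2, "need at least two samples")
  bands <- lapply(samples, function(s) {
    g <- genotypes[genotypes$sample == s, , drop = FALSE]
    g <- g[g$allele1 > 0 & g$allele2 > 0, , drop = FALSE]
    if (nrow(g) == 0L) {
      return(list(markers = character(0), bands = character(0)))
    }
    list(markers = unique(g$marker),
         bands = unique(c(paste0(g$marker, ":", g$allele1),
                          paste0(g$marker, ":", g$allele2))))
  })
  names(bands) <- samples
  empty <- samples[vapply(bands, function(b) length(b$bands) == 0,
                          logical(1))]
  .check(length(empty) == 0, "sample '%s' has zero scored bands",
         if (length(empty)) empty[1] else "")
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  band_marker <- function(b) sub(":.*$", "", b)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared_markers <- intersect(bands[[i]]$markers, bands[[j]]$markers)
      bi <- bands[[i]]$bands[band_marker(bands[[i]]$bands) %in% shared_markers]
      bj <- bands[[j]]$bands[band_marker(bands[[j]]$bands) %in% shared_markers]
      a <- length(intersect(bi, bj))
      s <- if (length(bi) + length(bj) == 0) {
        0
      } else if (method == "dice") {
        2 * a / (length(bi) + length(bj))
      } else {
        a / (length(bi) + length(bj) - a)
      }
      d[i, j] <- d[j, i] <- 1 - s
    }
  }
  d
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centering `B = -1/2 J D^2 J` with `J = I - 11'/n`, followed
#' by a symmetric eigendecomposition. Coordinates are eigenvectors scaled by
#' `sqrt(lambda)` for positive eigenvalues; negative eigenvalues (possible
#' for non-Euclidean distances such as band distances) are reported but
#' excluded from coordinates, and percent variance per axis is taken over the
#' positive eigenvalues only.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal
#' @param axes number of coordinate axes to return (default all positive)
#' @return list: `coordinates` (n x m), `eigenvalues` (all, descending),
#'   `percent_variance` (per positive axis, sums to 100)
#' @export
pcoa <- function(d, axes = NULL) {
  d <- as.matrix(d)
  .check(nrow(d) == ncol(d) && max(abs(d - t(d))) < 1e-8,
         "distance matrix must be square and symmetric")
  .check(all(d >= 0) && all(abs(diag(d)) < 1e-12),
         "distances must be non-negative with a zero diagonal")
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lambda <- e$values
  pos <- which(lambda > max(lambda[1], 0) * 1e-9 & lambda > 0)
  m <- if (is.null(axes)) length(pos) else min(axes, length(pos))
  coords <- if (m > 0) {
    sweep(e$vectors[, pos[seq_len(m)], drop = FALSE], 2,
          sqrt(lambda[pos[seq_len(m)]]), `*`)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(d)
  if (m > 0) colnames(coords) <- paste0("Axis", seq_len(m))
  pv <- if (length(pos)) 100 * lambda[pos] / sum(lambda[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = lambda,
       percent_variance = pv)
}

#' Assign samples to clusters by the Q-threshold rule
#'
#' A sample is allocated to its majority cluster when its largest membership
#' coefficient reaches the threshold (inclusive); otherwise it is considered
#' intermediate/admixed.
#'
#' @param q Q-matrix: samples x clusters membership proportions, rows summing
#'   to 1 (tolerance 1e-6)
#' @param threshold minimum majority membership for assignment
#' @return data.frame `sample`, `cluster` (NA when admixed), `max_q`,
#'   `admixed`
#' @export
assign_clusters <- function(q, threshold = 0.70) {
  q <- as.matrix(q)
  bad <- which(abs(rowSums(q) - 1) > 1e-6)
  .check(length(bad) == 0, "Q row %s does not sum to 1",
         if (length(bad)) bad[1] else "")
  max_q <- apply(q, 1, max)
  cl <- apply(q, 1, which.max)
  admixed <- max_q < threshold
  data.frame(sample = if (is.null(rownames(q))) seq_len(nrow(q)) else
    rownames(q),
    cluster = ifelse(admixed, NA_integer_, cl), max_q = max_q,
    admixed = admixed, row.names = NULL, stringsAsFactors = FALSE)
}

#' Evanno delta-K from ln P(D) replicate runs
#'
#' For each K with both neighbors on the grid,
#' `deltaK(K) = mean_r |lnPD(K+1, r) - 2 lnPD(K, r) + lnPD(K-1, r)| / sd_r
#' lnPD(K, r)`: the absolute second difference of the log-likelihood taken
#' per run, averaged across runs, scaled by the across-run standard
#' deviation. Its argmax estimates the number of clusters. Endpoints of the K
#' grid are undefined (NA).
#'
#' @param runs data.frame `K`, `run`, `lnPD` with >= 2 runs per K and a
#'   contiguous K grid (e.g. from [generate_structure_runs()] or
#'   [read_structure_runs()])
#' @return list: `table` (per K: `mean_lnPD`, `sd_lnPD`, `delta_k`),
#'   `best_k` (argmax of delta-K)
#' @export
evanno_delta_k <- function(runs) {
  .check(all(c("K", "run", "lnPD") %in% names(runs)),
         "runs needs columns K, run, lnPD")
  ks <- sort(unique(runs$K))
  .check(identical(ks, seq(min(ks), max(ks))), "K grid must be contiguous")
  counts <- table(runs$run, runs$K)
  .check(all(counts == 1L), "each (K, run) cell needs exactly one lnPD value")
  wide <- tapply(runs$lnPD, list(runs$run, runs$K), mean)
  .check(nrow(wide) >= 2, "need at least 2 runs per K")
  sd_k <- apply(wide, 2, stats::sd)
  inner <- 2:(length(ks) - 1L)
  .check(length(ks) >= 3, "need at least 3 K values")
  .check(all(sd_k[inner] > 0),
         "sd of lnPD is zero at some K; add jitter or more runs")
  delta <- rep(NA_real_, length(ks))
  for (i in inner) {
    d2 <- abs(wide[, i + 1L] - 2 * wide[, i] + wide[, i - 1L])
    delta[i] <- mean(d2) / sd_k[i]
  }
  tab <- data.frame(K = ks, mean_lnPD = colMeans(wide), sd_lnPD = sd_k,
                    delta_k = delta, row.names = NULL)
  list(table = tab, best_k = ks[which.max(delta)])
}
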