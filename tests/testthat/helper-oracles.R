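# Independent oracles used across the suite. They re-derive results from the
# definitions by exhaustive scanning, so they stay independent of the code
# paths they check.

# brute-force perfect-SSR scan: tests every (position, motif-length) pair,
# counts exact full copies by substring comparison, keeps runs meeting the
# threshold that cannot be extended left by even a partial copy
bf_scan <- function(sequence, thresholds = default_mining_thresholds()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- list()
  for (mi in seq_along(thresholds)) {
    m <- as.integer(names(thresholds)[mi])
    thr <- as.integer(thresholds[mi])
    if (n < m * thr) next
    for (p in 1:(n - m * thr + 1L)) {
      motif <- substr(sequence, p, p + m - 1L)
      if (grepl("N", motif, fixed = TRUE)) next
      mch <- ch[p:(p + m - 1L)]
      if (length(unique(mch)) == 1L) next
      prim <- TRUE
      for (d in seq_len(m - 1L)) {
        if (m %% d == 0L && motif == strrep(substr(motif, 1, d), m / d)) {
          prim <- FALSE; break
        }
      }
      if (!prim) next
      # leftmost phase: must not be extendable left by a partial copy
      if (p > 1L && ch[p - 1L] != "N" && ch[p - 1L] == ch[p - 1L + m]) next
      k <- 0L
      q <- p
      while (q + m - 1L <= n &&
               substr(sequence, q, q + m - 1L) == motif) {
        k <- k + 1L
        q <- q + m
      }
      if (k < thr) next
      out[[length(out) + 1L]] <- data.frame(
        start = p - 1L, end = p - 1L + k * m, motif = motif,
        motif_length = m, repeat_count = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_length = integer(),
                      repeat_count = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$motif_length), , drop = FALSE]
}

# locus tables as comparable key strings
locus_key <- function(df) {
  sort(sprintf("%d:%d:%s", df$start, df$end, df$motif))
}

# random DNA string, optionally salted with Ns
random_dna <- function(n, gc = 0.4, n_rate = 0) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ch <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p)
  if (n_rate > 0) ch[runif(n) < n_rate] <- "N"
  paste(ch, collapse = "")
}

# closed-form He (plain gene diversity) and PIC from a frequency vector
he_closed <- function(p) 1 - sum(p^2)
pic_closed <- function(p) {
  s <- 0
  k <- length(p)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) s <- s + 2 * p[i]^2 * p[j]^2
  }
  1 - sum(p^2) - s
}

# direct counting of allele frequencies from a long genotype table
count_freqs <- function(gt, marker) {
  g <- gt[gt$marker == marker & gt$allele1 > 0, ]
  a <- c(g$allele1, g$allele2)
  table(a) / length(a)
}
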