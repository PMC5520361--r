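# a compact mined-locus scenario reused across filter tests
design_fixture <- function() {
  loci <- data.frame(
    contig_id = c("c1", "c2", "c3", "c4", "c4"),
    start = c(1000L, 1000L, 1000L, 1000L, 1060L),
    end = c(1016L, 1016L, 1016L, 1016L, 1076L),
    motif = "AT", motif_class = "AT", motif_length = 2L,
    repeat_count = 8L, tract_length = 16L, purity = "perfect",
    stringsAsFactors = FALSE)
  list(loci = loci,
       lengths = data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                            length = c(3000L, 2400L, 3000L, 3000L)),
       coverage = data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                             mean_coverage = c(25, 25, 14.9, 25)))
}

test_that("candidate filter applies the 15X floor with a closed boundary", {
  fx <- design_fixture()
  cov <- data.frame(contig_id = c("a", "b"), mean_coverage = c(14.9, 15.0))
  loci <- fx$loci[1:2, ]
  loci$contig_id <- c("a", "b")
  kept <- filter_candidate_sites(loci, cov, coverage_min = 15)
  expect_identical(kept$contig_id, "b")
  expect_equal(nrow(filter_candidate_sites(fx$loci[0, ], cov)), 0L)
  expect_error(filter_candidate_sites(loci, cov[1, , drop = FALSE]),
               "missing from the coverage")
})

test_that("marker-grade selection enforces contig length, coverage, copies and adjacency", {
  fx <- design_fixture()
  cand <- filter_candidate_sites(fx$loci, fx$coverage, 15)
  sel <- select_marker_grade(cand, fx$loci, fx$lengths, fx$coverage)
  # c2 fails the 2.5 kb floor, c3 failed 15X already, c4 has two adjacent loci
  expect_identical(sel$contig_id, "c1")

  # predicate-by-predicate oracle on the same inputs
  cov <- setNames(fx$coverage$mean_coverage, fx$coverage$contig_id)
  len <- setNames(fx$lengths$length, fx$lengths$contig_id)
  oracle <- vapply(seq_len(nrow(cand)), function(i) {
    x <- cand[i, ]
    ok <- len[x$contig_id] >= 2500 && cov[x$contig_id] >= 20 &&
      x$repeat_count >= 3
    nb <- fx$loci[fx$loci$contig_id == x$contig_id &
                    fx$loci$start != x$start, ]
    ok && !(nrow(nb) && any(abs(nb$start - x$start) < 200 + 76))
  }, logical(1))
  expect_identical(paste(sel$contig_id, sel$start),
                   paste(cand$contig_id[oracle], cand$start[oracle]))
})

test_that("relaxing any marker-grade threshold never shrinks the selection", {
  set.seed(31)
  spec <- sim_spec(seed = 31, n_contigs = 6, contig_length = c(2000, 4000),
                   tracts = data.frame(motif = rep(c("AT", "AAG"), 3),
                                       repeat_count = c(8, 5, 4, 3, 6, 7)),
                   coverage = c(10, 18, 22, 30, 25, 16))
  g <- generate_contigs(spec)
  loci <- mine_contigs(g$contigs)
  lens <- data.frame(contig_id = names(g$contigs),
                     length = nchar(g$contigs))
  perfect <- loci[loci$purity == "perfect", ]
  base <- select_marker_grade(perfect, loci, lens, g$coverage)
  for (relaxed in list(
    select_marker_grade(perfect, loci, lens, g$coverage,
                        min_contig_len = 1000),
    select_marker_grade(perfect, loci, lens, g$coverage, min_cov = 5),
    select_marker_grade(perfect, loci, lens, g$coverage, min_repeats = 1),
    select_marker_grade(perfect, loci, lens, g$coverage,
                        adjacency_window = 0))) {
    expect_true(all(paste(base$contig_id, base$start) %in%
                      paste(relaxed$contig_id, relaxed$start)))
  }
})

test_that("the GC-rule Tm formula is applied verbatim", {
  expect_equal(primer_tm(paste0(strrep("G", 10), strrep("A", 10))),
               64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(primer_tm(strrep("AG", 10)), 51.78, tolerance = 1e-10)
})

test_that("designed primers respect every constraint and never overlap the repeat", {
  spec <- sim_spec(seed = 17, n_contigs = 4, contig_length = c(3000, 3000),
                   gc = 0.5,
                   tracts = data.frame(motif = c("AT", "AAG", "AGAT", "CT"),
                                       repeat_count = c(8, 5, 4, 10)),
                   coverage = rep(25, 4))
  g <- generate_contigs(spec)
  loci <- mine_contigs(g$contigs)
  sel <- loci[loci$purity == "perfect" &
                paste(loci$contig_id, loci$start) %in%
                paste(g$truth$contig_id, g$truth$start), ]
  des <- design_markers(sel, g$contigs)
  expect_equal(nrow(des$markers), nrow(sel))
  m <- des$markers
  expect_false(any(duplicated(m$name)))
  expect_true(all(grepl("^BrPe\\d{4}$", m$name)))
  expect_true(all(m$left_start + m$left_length <= m$start))
  expect_true(all(m$right_start >= m$end))
  expect_true(all(m$expected_size >= 70 & m$expected_size <= 300))
  expect_true(all(m$left_gc >= 0.4 & m$left_gc <= 0.6))
  expect_true(all(m$right_gc >= 0.4 & m$right_gc <= 0.6))
  expect_true(all(m$ta_c %in% c(55, 57, 60)))
  expect_true(all(abs(m$left_tm - m$ta_c) <= 8))
  # product size = right primer 3' end minus left primer start
  expect_equal(m$expected_size,
               m$right_start + m$right_length - m$left_start)
  # primer sequences match the contig (right primer reverse-complemented)
  for (i in seq_len(nrow(m))) {
    s <- g$contigs[[m$contig_id[i]]]
    expect_identical(substr(s, m$left_start[i] + 1,
                            m$left_start[i] + m$left_length[i]),
                     m$left_primer[i])
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(m$right_primer[i], "")[[1]]),
                       collapse = ""))
    expect_identical(substr(s, m$right_start[i] + 1,
                            m$right_start[i] + m$right_length[i]), rc)
  }
})

test_that("loci with insufficient flanks are skipped with a reason code", {
  s <- paste0(strrep("AT", 8), random_dna(300, gc = 0.5))
  loci <- find_tandem_repeats(s, contig_id = "c")
  locus <- loci[loci$start == 0, ]
  des <- design_markers(locus, c(c = s))
  expect_null(des$markers)
  expect_identical(des$skipped$reason, "flank_too_short")
})

test_that("genomic-context labels match a brute-force overlap check", {
  mk <- function(contig, start, end) {
    data.frame(name = "m", contig_id = contig, start = start, end = end)
  }
  iv <- data.frame(contig_id = "c1", start = 110L, end = 200L)
  expect_identical(
    label_genomic_context(mk("c1", 100L, 120L), iv)$genomic_context,
    "functional")
  # half-open: locus ending where the interval starts does not overlap
  iv2 <- data.frame(contig_id = "c1", start = 120L, end = 200L)
  expect_identical(
    label_genomic_context(mk("c1", 100L, 120L), iv2)$genomic_context,
    "structural")
  expect_identical(
    label_genomic_context(mk("c9", 100L, 120L), iv)$genomic_context,
    "unknown")

  set.seed(23)
  markers <- data.frame(name = sprintf("m%d", 1:50),
                        contig_id = sample(c("c1", "c2", "c3"), 50, TRUE),
                        start = sample(0:900, 50))
  markers$end <- markers$start + sample(10:40, 50, TRUE)
  ivs <- data.frame(contig_id = sample(c("c1", "c2"), 30, TRUE),
                    start = sample(0:900, 30))
  ivs$end <- ivs$start + sample(20:120, 30, TRUE)
  got <- label_genomic_context(markers, ivs)$genomic_context
  want <- vapply(seq_len(nrow(markers)), function(i) {
    if (!markers$contig_id[i] %in% ivs$contig_id) return("unknown")
    hit <- any(ivs$contig_id == markers$contig_id[i] &
                 ivs$start < markers$end[i] & ivs$end > markers$start[i])
    if (hit) "functional" else "structural"
  }, character(1))
  expect_identical(got, want)
})

test_that("multiplex packing satisfies all pairwise constraints", {
  mk <- function(name, ta, lo, hi, dye = NA_character_) {
    data.frame(name = name, ta_c = ta, size_min = lo, size_max = hi,
               dye = dye, stringsAsFactors = FALSE)
  }
  two <- rbind(mk("a", 60, 100, 120), mk("b", 60, 150, 170))
  p <- build_multiplex_panels(two, size_gap = 20)
  expect_equal(length(unique(p$panel)), 1L)

  clash <- rbind(mk("a", 60, 100, 120), mk("b", 60, 110, 130))
  p2 <- build_multiplex_panels(clash, size_gap = 20)
  expect_equal(length(unique(p2$panel)), 2L)

  # different dyes lift the size-gap constraint
  dyed <- rbind(mk("a", 60, 100, 120, "FAM"), mk("b", 60, 110, 130, "HEX"))
  p3 <- build_multiplex_panels(dyed, size_gap = 20)
  expect_equal(length(unique(p3$panel)), 1L)

  set.seed(47)
  n <- 60
  rnd <- data.frame(name = sprintf("m%02d", 1:n),
                    ta_c = sample(c(55, 57, 60), n, TRUE),
                    size_min = sample(seq(80, 260, 2), n, TRUE),
                    dye = sample(c("FAM", "HEX", NA), n, TRUE),
                    stringsAsFactors = FALSE)
  rnd$size_max <- rnd$size_min + 15
  out <- build_multiplex_panels(rnd, capacity = 3, size_gap = 20)
  # partition of the input
  expect_setequal(out$name, rnd$name)
  expect_equal(nrow(out), n)
  # every pairwise constraint holds inside each panel
  for (pid in unique(out$panel)) {
    g <- out[out$panel == pid, ]
    expect_lte(nrow(g), 3)
    expect_equal(length(unique(g$ta_c)), 1L)
    if (nrow(g) > 1) {
      for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
        same_dye <- is.na(g$dye[i]) || is.na(g$dye[j]) ||
          g$dye[i] == g$dye[j]
        if (same_dye) {
          gap <- max(g$size_min[i] - g$size_max[j],
                     g$size_min[j] - g$size_max[i])
          expect_gte(gap, 20)
        }
      }
    }
  }
  expect_lte(length(unique(out$panel)), n)
})
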