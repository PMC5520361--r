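test_that("transferability rates follow direct counting", {
  all_pos <- matrix("+", 4, 3,
                    dimnames = list(paste0("s", 1:4), paste0("m", 1:3)))
  sm <- transferability_summary(all_pos)
  expect_true(all(sm$per_species$pct == 100))
  expect_equal(sm$overall_pct, 100)
  expect_setequal(sm$universal, paste0("m", 1:3))

  set.seed(53)
  m <- matrix(sample(c("+", "-", NA), 200, TRUE, prob = c(.6, .3, .1)),
              20, 10, dimnames = list(paste0("s", 1:20), paste0("m", 1:10)))
  sm2 <- transferability_summary(m)
  # independent tally
  expect_equal(sm2$overall_rate,
               sum(m == "+", na.rm = TRUE) / sum(!is.na(m)))
  for (i in 1:20) {
    expect_equal(sm2$per_species$rate[i],
                 sum(m[i, ] == "+", na.rm = TRUE) / sum(!is.na(m[i, ])))
  }
  # weighted mean of species rates equals the overall rate exactly
  w <- sm2$per_species$n_called
  expect_equal(sum(sm2$per_species$rate * w) / sum(w), sm2$overall_rate)

  # all-NA row reported as NA
  m[3, ] <- NA
  sm3 <- transferability_summary(m)
  expect_true(is.na(sm3$per_species$rate[3]))

  ref <- all_pos
  ref[2, 1] <- "-"
  expect_error(transferability_summary(ref, reference = "s2"), "all")
})

test_that("band distances implement the Dice form on allele-presence sets", {
  gt <- data.frame(
    sample = c("x", "x", "y", "y"),
    marker = c("A", "B", "A", "B"),
    allele1 = c(100, 200, 100, 204),
    allele2 = c(102, 200, 102, 204))
  d <- band_distance_matrix(gt)
  expect_equal(diag(d), c(x = 0, y = 0))
  # x bands {A:100, A:102, B:200}, y bands {A:100, A:102, B:204}
  expect_equal(d["x", "y"], 1 - 2 * 2 / (3 + 3))

  # identical samples: d = 0; fully disjoint: d = 1
  gt2 <- gt
  gt2$allele1[3:4] <- c(110, 210)
  gt2$allele2[3:4] <- c(112, 210)
  expect_equal(band_distance_matrix(gt2)["x", "y"], 1)

  # two bands {A,B} vs {B,C}: S = 2*1/(2+2)
  gt3 <- data.frame(sample = c("x", "y"), marker = "A",
                    allele1 = c(100, 102), allele2 = c(102, 104))
  expect_equal(band_distance_matrix(gt3)["x", "y"], 0.5)
  expect_equal(band_distance_matrix(gt3, method = "jaccard")["x", "y"],
               1 - 1 / 3)

  # markers missing in either sample are excluded pairwise
  gt4 <- rbind(gt, data.frame(sample = c("x", "y"), marker = "C",
                              allele1 = c(300, 0), allele2 = c(300, 0)))
  expect_equal(band_distance_matrix(gt4)["x", "y"], d["x", "y"])

  gt5 <- data.frame(sample = c("x", "y"), marker = "A",
                    allele1 = c(100, 0), allele2 = c(102, 0))
  expect_error(band_distance_matrix(gt5), "zero scored bands")

  # validity on random genotype tables
  set.seed(59)
  spec <- sim_spec(seed = 59, n_samples = 12, missing_rate = 0.05,
                   loci = default_genotype_loci(8, 2))
  dm <- band_distance_matrix(generate_genotypes(spec)$genotypes)
  expect_equal(dm, t(dm))
  expect_true(all(dm >= 0 & dm <= 1))
  expect_true(all(diag(dm) == 0))
})

test_that("PCoA recovers closed-form and round-trips Euclidean distances", {
  # three points, all pairwise distances 1: two equal eigenvalues at 50%
  d <- matrix(1, 3, 3) - diag(3)
  p <- pcoa(d)
  expect_equal(p$percent_variance, c(50, 50), tolerance = 1e-9)
  expect_equal(as.matrix(dist(p$coordinates)) - d,
               matrix(0, 3, 3), ignore_attr = TRUE, tolerance = 1e-9)

  # identical points collapse to coinciding coordinates
  d0 <- matrix(0, 2, 2)
  p0 <- pcoa(d0)
  expect_true(all(abs(p0$eigenvalues) < 1e-12))

  set.seed(61)
  for (i in 1:5) {
    x <- matrix(rnorm(8 * 3), 8, 3)
    D <- as.matrix(dist(x))
    pr <- pcoa(D)
    expect_equal(as.matrix(dist(pr$coordinates)), D, ignore_attr = TRUE,
                 tolerance = 1e-8)
    # positive eigenvalues account for the trace of the centered matrix
    n <- nrow(D)
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% D^2 %*% J
    expect_equal(sum(pr$eigenvalues[pr$eigenvalues > 0]), sum(diag(B)),
                 tolerance = 1e-8)
    # coordinates centered at the origin
    expect_equal(colMeans(pr$coordinates), rep(0, ncol(pr$coordinates)),
                 ignore_attr = TRUE, tolerance = 1e-8)
    # cross-check against the reference implementation
    ref <- ape::pcoa(D)
    expect_equal(sort(pr$eigenvalues[pr$eigenvalues > 1e-8]),
                 sort(ref$values$Eigenvalues[ref$values$Eigenvalues > 1e-8]),
                 tolerance = 1e-6)
  }
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA separates synthetic clusters with distinct allele pools", {
  mkloci <- function(offset) {
    lapply(1:6, function(i) {
      list(name = sprintf("L%d", i), p = c(0.5, 0.5), motif_length = 2,
           offset_bp = offset + 10 * i)
    })
  }
  ga <- generate_genotypes(sim_spec(seed = 67, n_samples = 6,
                                    loci = mkloci(100)))$genotypes
  gb <- generate_genotypes(sim_spec(seed = 68, n_samples = 6,
                                    loci = mkloci(300)))$genotypes
  gb$sample <- sub("^S0", "T0", gb$sample)
  both <- rbind(ga, gb)
  d <- band_distance_matrix(both)
  co <- pcoa(d)$coordinates
  a1 <- co[startsWith(rownames(co), "S"), 1]
  b1 <- co[startsWith(rownames(co), "T"), 1]
  expect_true(max(a1) < min(b1) || max(b1) < min(a1))
})

test_that("the Q-threshold rule assigns inclusively at 0.70 and flags admixture", {
  q <- rbind(c(1, 0, 0, 0), c(0.70, 0.10, 0.10, 0.10),
             c(0.52, 0.30, 0.09, 0.09), c(0.25, 0.25, 0.25, 0.25))
  a <- assign_clusters(q)
  expect_equal(a$cluster, c(1L, 1L, NA, NA))
  expect_equal(a$admixed, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(assign_clusters(rbind(c(0.5, 0.4))), "sum to 1")
})

test_that("Evanno delta-K finds the planted change-point and is zero on lines", {
  # noiseless kink at K = 3 (vanishing noise keeps sd > 0)
  runs <- generate_structure_runs(sim_spec(
    seed = 71, deltak = list(true_k = 3, k_max = 8, n_runs = 10,
                             noise_sd = 1e-9)))
  ev <- evanno_delta_k(runs)
  expect_equal(ev$best_k, 3)
  expect_true(all(is.na(ev$table$delta_k[c(1, 8)])))

  # a linear mean curve has |L''| ~ 0 relative to the signal scale
  lin <- expand.grid(run = 1:10, K = 1:8)
  set.seed(3)
  lin$lnPD <- -1000 + 100 * lin$K + rnorm(nrow(lin), sd = 2)
  evl <- evanno_delta_k(lin)
  # second differences of per-run noise: E|d2| ~ sd*sqrt(6)*sqrt(2/pi);
  # delta-K stays near its noise floor, far below a change-point signal
  expect_lt(max(evl$table$delta_k, na.rm = TRUE), 10)

  # degenerate runs: zero sd is an explicit error
  z <- expand.grid(run = 1:3, K = 1:5)
  z$lnPD <- -100 * (5 - z$K)^2
  expect_error(evanno_delta_k(z), "sd of lnPD is zero")
  expect_error(evanno_delta_k(lin[lin$run == 1, ]), "2 runs")
})
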