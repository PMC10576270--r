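test_that("zscore_rows standardizes rows with sample SD and zeros constants", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_error(zscore_rows(matrix(1:5)), "2 columns")

  withr::local_seed(41)
  r <- matrix(rnorm(200), 50, 4)
  zr <- zscore_rows(r)
  expect_true(all(abs(rowMeans(zr)) < 1e-9))
  expect_true(all(abs(apply(zr, 1, sd) - 1) < 1e-9))

  # location/scale invariance: zscore(a*x + b) = zscore(x), a > 0
  expect_equal(zscore_rows(3.7 * r + 11), zr)
})

test_that("mann_whitney_u matches pair-count and enumeration oracles", {
  # worked case: x below y entirely
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$method, "exact")

  # identical multisets: U = nx * ny / 2 by symmetry
  expect_equal(mann_whitney_u(c(2, 5, 9), c(2, 5, 9))$U, 4.5)

  withr::local_seed(43)
  for (rep in 1:40) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    v <- sample.int(1000, nx + ny)  # no ties
    x <- v[seq_len(nx)]
    y <- v[-seq_len(nx)]
    res <- mann_whitney_u(x, y)
    expect_equal(res$U, pair_count_u(x, y))
    expect_equal(res$p, enumeration_p(x, y))
  }

  # ties force the normal approximation
  res <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_equal(res$method, "normal_approx")
  expect_equal(res$U, pair_count_u(c(1, 2, 2), c(2, 3, 4)))

  expect_error(mann_whitney_u(numeric(), 1:3), "empty")
})

test_that("mann_whitney_u U equals the O(n^2) oracle on larger draws", {
  withr::local_seed(47)
  for (rep in 1:10) {
    x <- round(rnorm(6), 1)
    y <- round(rnorm(6), 1)
    expect_equal(mann_whitney_u(x, y)$U, pair_count_u(x, y))
  }
})

test_that("pileup_profile averages per-bin scaled density over peaks", {
  peak <- data.frame(chrom = "chr1", summit = 1000L)
  # all tags at the summit -> only the bin containing the summit is nonzero
  lib <- tags_at(rep("chr1", 10), rep(1000L, 10))
  prof <- pileup_profile(peak, lib, halfwidth = 200L, bin_size = 50L)
  expect_equal(nrow(prof), 8L)
  hot <- prof$offset_start == 0
  expect_equal(prof$density[hot], 10 / 50)
  expect_true(all(prof$density[!hot] == 0))

  # uniform tags -> flat profile
  unif <- tags_at(rep("chr1", 400), 800L + seq_len(400) - 1L)
  prof2 <- pileup_profile(peak, unif, 200L, 50L)
  expect_true(all(abs(prof2$density - prof2$density[1]) < 1e-12))

  expect_error(pileup_profile(peak, lib, 200L, 60L), "multiple")
})

test_that("pileup_profile matches the per-peak loop oracle and mirrors", {
  withr::local_seed(53)
  peaks <- data.frame(chrom = sample(c("chrA", "chrB"), 100, replace = TRUE),
                      summit = sample(2000:3000, 100, replace = TRUE))
  n <- 5000
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  pos <- sample(1500:3500, n, replace = TRUE)
  lib <- tag_library("l", chrom, pos, 2e7)
  hw <- 300L
  bs <- 100L
  prof <- pileup_profile(peaks, lib, hw, bs)
  # oracle: explicit double loop over peaks and bins
  offsets <- seq(-hw, hw - bs, by = bs)
  oracle <- vapply(offsets, function(off) {
    per_peak <- vapply(seq_len(nrow(peaks)), function(i) {
      v <- lib$sites[[peaks$chrom[i]]]
      lo <- peaks$summit[i] + off
      sum(v >= lo & v < lo + bs) * lib$scale / bs
    }, 0)
    mean(per_peak)
  }, 0)
  expect_equal(prof$density, oracle)

  # mirrored tags give the mirrored profile
  mpos <- 2L * 2500L - 1L - pos
  mlib <- tag_library("m", chrom, mpos, 2e7)
  mpeaks <- peaks
  mpeaks$summit <- 2L * 2500L - peaks$summit
  mprof <- pileup_profile(mpeaks, mlib, hw, bs)
  expect_equal(mprof$density, rev(prof$density))
})

test_that("moving_average_density uses a centered window clipped at edges", {
  expect_equal(moving_average_density(c(1, 2, 3, 4, 5), 3),
               c(1.5, 2, 3, 4, 4.5))
  x <- rnorm(10)
  expect_equal(moving_average_density(x, 1), x)
  expect_error(moving_average_density(x, 4), "odd")
  expect_error(moving_average_density(x, 11), "larger")

  withr::local_seed(59)
  v <- rnorm(200)
  w <- 51L
  k <- 25L
  oracle <- vapply(seq_along(v), function(i) {
    mean(v[max(1, i - k):min(length(v), i + k)])
  }, 0)
  expect_equal(moving_average_density(v, w), oracle)
})

test_that("fold_change_screen keeps genes with pseudocounted FC above cutoff", {
  a <- c(g1 = 10, g2 = 4, g3 = 0, g4 = 100, g5 = 7, g6 = 3)
  b <- c(g1 = 4, g2 = 4, g3 = 9, g4 = 10, g5 = 0, g6 = 3.0001)
  kept <- fold_change_screen(a, b)
  # hand enumeration with pseudocount 1: 11/5, 5/5, 1/10, 101/11, 8/1, 4/4.0001
  expect_equal(kept, c("g1", "g4", "g5"))
  # a = b gives FC = 1, excluded by the strict inequality
  expect_equal(fold_change_screen(c(g = 5), c(g = 5)), character())
  # log2 mode
  expect_equal(fold_change_screen(a, b, fc_threshold = 1, log2 = TRUE),
               c("g1", "g4", "g5"))
  # g5 has log2 FC exactly 3 (8/1) and is excluded by the strict inequality
  expect_equal(fold_change_screen(a, b, fc_threshold = 3, log2 = TRUE),
               "g4")
  expect_error(fold_change_screen(c(g = -1), c(g = 2)), "negative")
  expect_error(fold_change_screen(c(g1 = 1), c(g2 = 1)), "rosters")

  # idempotence: screening the survivors again changes nothing
  expect_equal(fold_change_screen(a[kept], b[kept]), kept)
})

test_that("motif_filter keeps p < 0.01 and target/background ratio > 1.5", {
  rec <- data.frame(
    motif = paste0("m", 1:10),
    p_value = c(0.005, 0.02, 0.005, 1e-30, 0.009, 0.011, 1e-5, 0.005,
                0.0099, 0.5),
    percent_target = c(15, 15, 6, 40, 10, 80, 0, 9, 3, 90),
    percent_background = c(5, 5, 5, 10, 0, 1, 0, 6, 1.9, 30))
  out <- motif_filter(rec)
  # hand enumeration: m1 (ratio 3), m4 (4), m5 (inf), m7 fails target 0,
  # m8 ratio 1.5 not > 1.5, m9 ratio ~1.58, m2/m6/m10 fail p or ratio
  expect_equal(out$motif, c("m1", "m4", "m5", "m9"))
  # idempotence
  expect_equal(motif_filter(out), out)
  bad <- rec
  bad$p_value[1] <- 0
  expect_error(motif_filter(bad), "p_value")
  bad <- rec
  bad$percent_target[1] <- 150
  expect_error(motif_filter(bad), "percent")
})
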