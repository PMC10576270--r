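test_that("partition_by_state maps open/closed pairs to the four states", {
  nv <- c(1L, 1L, 0L, 0L)
  pr <- c(1L, 0L, 1L, 0L)
  expect_equal(partition_by_state(nv, pr),
               c("both_open", "naive_specific", "primed_specific",
                 "both_closed"))
  expect_error(partition_by_state(c(1L, 0L), 1L), "mismatch")
})

test_that("intersect_chip assigns C1-C4 by >= min_overlap interval overlap", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(100L, 1000L, 2000L, 3000L, 4000L),
                      end = c(300L, 1200L, 2200L, 3200L, 4200L),
                      name = paste0("p", 1:5))
  states <- c("naive_specific", "naive_specific", "primed_specific",
              "primed_specific", "both_open")
  chip <- data.frame(chrom = "chr1", start = c(250L, 2100L, 4100L),
                     end = c(500L, 2150L, 4150L))
  cg <- intersect_chip(peaks, states, chip)
  expect_equal(cg, c("C3", "C4", "C1", "C2", "none"))

  # 1-base overlap counts at min_overlap = 1, not at min_overlap = 2
  touch <- data.frame(chrom = "chr1", start = 299L, end = 400L)
  expect_equal(intersect_chip(peaks[1, ], "naive_specific", touch), "C3")
  expect_equal(intersect_chip(peaks[1, ], "naive_specific", touch,
                              min_overlap = 2L), "C4")
  # bookended ChIP peak does not overlap
  book <- data.frame(chrom = "chr1", start = 300L, end = 400L)
  expect_equal(intersect_chip(peaks[1, ], "naive_specific", book), "C4")
})

test_that("planted group sizes are recovered exactly via interval overlap", {
  withr::local_seed(37)
  sizes <- c(C1 = 40L, C2 = 60L, C3 = 30L, C4 = 70L)
  n <- sum(sizes)
  # disjoint peaks on a long chromosome
  start <- seq(0L, by = 1000L, length.out = n)
  peaks <- data.frame(chrom = "chr1", start = start, end = start + 200L,
                      name = sprintf("p%03d", seq_len(n)))
  lab <- sample(rep(names(sizes), sizes))
  states <- ifelse(lab %in% c("C1", "C2"), "primed_specific",
                   "naive_specific")
  bound <- lab %in% c("C1", "C3")
  chip <- data.frame(chrom = "chr1", start = start[bound] + 150L,
                     end = start[bound] + 400L)
  cg <- intersect_chip(peaks, states, chip)
  expect_equal(cg, lab)

  # brute-force any-overlap oracle agrees
  oracle_bound <- vapply(seq_len(n), function(i) {
    any(chip$start < peaks$end[i] & chip$end > peaks$start[i])
  }, TRUE)
  expect_equal(oracle_bound, bound)

  g <- state_groups(peaks, states, cg)
  s <- group_summary(g)
  expect_equal(s$cgroup[c("C1", "C2", "C3", "C4")], sizes)
  expect_equal(s$cgroup[["C1"]] + s$cgroup[["C2"]],
               s$state[["primed_specific"]])
  expect_equal(s$cgroup[["C3"]] + s$cgroup[["C4"]],
               s$state[["naive_specific"]])
  expect_equal(sum(s$state), n)
})

test_that("group_summary handles degenerate partitions", {
  peaks <- data.frame(chrom = "chr1", start = c(0L, 500L),
                      end = c(100L, 600L), name = c("a", "b"))
  g <- state_groups(peaks, rep("both_open", 2), rep("none", 2))
  s <- group_summary(g)
  expect_equal(s$cgroup[["none"]], 2L)
  expect_equal(sum(s$cgroup[c("C1", "C2", "C3", "C4")]), 0L)

  empty <- state_groups(peaks[0, ], character(), character())
  expect_true(all(unlist(group_summary(empty)) == 0L))
})

test_that("state_groups enforces the state/cgroup consistency invariants", {
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 100L, name = "a")
  expect_error(state_groups(peaks, "both_open", "C1"), "invariant")
  expect_error(state_groups(peaks, "naive_specific", "C1"), "invariant")
  expect_error(state_groups(peaks, "naive_specific", "none"), "invariant")
  expect_silent(state_groups(peaks, "naive_specific", "C3"))
})

test_that("state group BED6+2 serialization round-trips", {
  peaks <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 10L),
                      end = c(100L, 50L), name = c("a", "b"),
                      signal = c(1.5, 0))
  g <- state_groups(peaks, c("naive_specific", "both_open"), c("C4", "none"))
  tf <- withr::local_tempfile(fileext = ".bed")
  write_state_groups(g, tf)
  back <- read_state_groups(tf)
  expect_equal(back$state, g$state)
  expect_equal(back$cgroup, g$cgroup)
  expect_equal(back$start, g$start)
})
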