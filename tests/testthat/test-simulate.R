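test_that("sim_config validates its parameters", {
  expect_s3_class(small_sim_config(), "sim_config")
  expect_error(small_sim_config(open_density_multiple = 0.9), "multiple")
  expect_error(small_sim_config(closed_density_multiple = 1.2), "multiple")
  expect_error(small_sim_config(reads_per_library = 0), "positive")
  expect_error(small_sim_config(timepoints = c(0, 0.5)), "between")
  expect_error(sim_config(tf_bound_fraction = c(both_open = 2,
                                                naive_specific = 0,
                                                primed_specific = 0)),
               "\\[0, 1\\]")
  # loci that cannot fit the genome are a config error
  expect_error(simulate_dataset(sim_config(
    chrom_lengths = c(chr1 = 20000))), "fit")
})

test_that("the generator is deterministic given the seed", {
  a <- simulate_dataset(small_sim_config(seed = 5))
  b <- simulate_dataset(small_sim_config(seed = 5))
  expect_identical(a$truth, b$truth)
  expect_identical(a$tags$naive$sites, b$tags$naive$sites)
  expect_identical(a$expression, b$expression)
  c <- simulate_dataset(small_sim_config(seed = 6))
  expect_false(identical(a$tags$naive$sites, c$tags$naive$sites))

  # written fixtures are byte-identical across runs and directories
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(small_sim_config(seed = 5), outdir = d1)
  simulate_dataset(small_sim_config(seed = 5), outdir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("truth structure is internally consistent", {
  ds <- simulate_dataset(small_sim_config(seed = 9))
  tr <- ds$truth
  expect_equal(nrow(tr), 90L)
  # cgroup consistent with state and binding
  expect_true(all(tr$cgroup[tr$state == "both_open"] == "none"))
  expect_true(all(tr$cgroup[tr$state == "naive_specific" & tr$tf_bound] == "C3"))
  expect_true(all(tr$cgroup[tr$state == "primed_specific" & !tr$tf_bound] == "C2"))
  # terminal-state truth follows the state class
  expect_equal(tr$open_naive, as.integer(tr$state %in%
                                           c("both_open", "naive_specific")))
  expect_equal(tr$open_primed, as.integer(tr$state %in%
                                            c("both_open", "primed_specific")))
  # ChIP peaks overlap exactly the bound loci
  expect_equal(nrow(ds$chip_peaks), sum(tr$tf_bound))
  # expression couples to openness: open >> closed in the naive library
  mu_open <- mean(ds$expression[tr$open_naive == 1, "naive"])
  mu_closed <- mean(ds$expression[tr$open_naive == 0, "naive"])
  expect_gt(mu_open, 5 * mu_closed)
})

test_that("realized open-locus tag counts match the configured mean", {
  cfg <- sim_config(seed = 21,
                    n_loci = c(both_open = 100L, naive_specific = 100L,
                               primed_specific = 100L),
                    timepoints = numeric())
  ds <- simulate_dataset(cfg)
  w <- cfg$window_halfwidth
  open_idx <- which(ds$truth$open_naive == 1)  # 200 open loci in naive
  counts <- vapply(open_idx, function(i) {
    v <- ds$tags$naive$sites[[ds$truth$chrom[i]]]
    sum(v >= ds$truth$summit[i] - w & v < ds$truth$summit[i] + w)
  }, 0)
  # expected: open mean + uniform background inside the window
  lam <- cfg$open_density_multiple * cfg$threshold * 2 * w +
    cfg$background_multiple * cfg$threshold * 2 * w
  se <- sqrt(lam / length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
})

test_that("classification accuracy is monotone in the open-density multiple", {
  acc <- vapply(c(1.5, 3, 6), function(mult) {
    ds <- simulate_dataset(small_sim_config(
      seed = 77, open_density_multiple = mult, timepoints = numeric()))
    sl <- build_superlist(ds$peaks)
    oc <- classify_open_closed(
      build_matrix(sl, ds$tags, ds$config$window_halfwidth, ds$layout),
      ds$config$threshold)
    st <- partition_by_state(oc[, "naive"], oc[, "primed"])
    g <- state_groups(sl$peaks, st,
                      intersect_chip(sl$peaks, st, ds$chip_peaks))
    truth_report(ds$truth, g, oc)$open_closed_accuracy
  }, 0)
  expect_true(all(diff(acc) >= 0))
  expect_gte(acc[3], 0.99)
})

test_that("truth_report flags perfect recovery and localizes single flips", {
  ds <- simulate_dataset(small_sim_config(seed = 31))
  sl <- build_superlist(ds$peaks)
  oc <- classify_open_closed(
    build_matrix(sl, ds$tags, ds$config$window_halfwidth, ds$layout),
    ds$config$threshold)
  st <- partition_by_state(oc[, "naive"], oc[, "primed"])
  g <- state_groups(sl$peaks, st, intersect_chip(sl$peaks, st, ds$chip_peaks))
  rep <- truth_report(ds$truth, g, oc)
  expect_true(rep$state_exact)
  expect_true(rep$cgroup_exact)
  expect_true(all(rep$state_confusion[row(rep$state_confusion) !=
                                        col(rep$state_confusion)] == 0))

  # flip one state label: one off-diagonal entry, exact flag drops
  g2 <- g
  i <- which(g2$state == "naive_specific")[1]
  g2$state[i] <- "primed_specific"
  g2$cgroup[i] <- "C2"
  rep2 <- truth_report(ds$truth, g2)
  expect_false(rep2$state_exact)
  expect_equal(sum(rep2$state_confusion[row(rep2$state_confusion) !=
                                          col(rep2$state_confusion)]), 1)

  # unmatched loci are an error
  expect_error(truth_report(ds$truth, g[-1, ]), "1-1")

  # gene recovery through the annotation route: a 500-base window is below
  # the inter-locus spacing, so each peak maps only its own linked gene
  mapping <- tss_within_window(g, ds$genes, 500L)
  rep3 <- truth_report(ds$truth, g, oc, mapping)
  expect_equal(unname(rep3$gene_jaccard), rep(1, 4))
})
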