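# Shared fixtures and independent brute-force oracles. The oracles are kept
# deliberately naive (per-base masks, O(n^2) pair counts, full enumeration,
# all-pairs scans) so they share no code with the implementation they check.

# random interval table on a small multi-chromosome genome
rand_intervals <- function(n, chrom_lengths = c(chrA = 5000, chrB = 5000,
                                                chrC = 5000),
                           max_width = 200L) {
  chrom <- sample(names(chrom_lengths), n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(chrom_lengths[[chrom[i]]] - width[i], 1L) - 1L
  }, 0L)
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

rand_peaks <- function(n, ...) {
  iv <- rand_intervals(n, ...)
  iv$name <- sprintf("p%04d", seq_len(n))
  iv$signal <- round(stats::runif(n, 0, 100), 2)
  iv$summit <- iv$start + vapply(iv$end - iv$start,
                                 function(w) sample.int(w, 1L) - 1L, 0L)
  iv
}

# per-base boolean-mask union: covered positions per chromosome
mask_union <- function(intervals, chrom_lengths) {
  masks <- lapply(chrom_lengths[sort(names(chrom_lengths))], logical)
  for (i in seq_len(nrow(intervals))) {
    cn <- intervals$chrom[i]
    idx <- (intervals$start[i] + 1L):intervals$end[i]
    masks[[cn]][idx] <- TRUE
  }
  masks
}

# O(n^2) Mann-Whitney U for sample x
pair_count_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# exact two-sided p by full enumeration of rank assignments (no ties)
enumeration_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  u_obs <- pair_count_u(x, y)
  combos <- utils::combn(n, nx)
  r <- rank(c(x, y))
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# all-pairs TSS-to-peak distance scan
brute_tss_scan <- function(peaks, genes, window) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      tss <- genes$tss[j]
      d <- if (tss >= peaks$start[i] && tss <= peaks$end[i] - 1L) 0L
      else min(abs(tss - peaks$start[i]), abs(tss - (peaks$end[i] - 1L)))
      if (d <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          peak_id = peaks$name[i], gene_id = genes$gene_id[j],
          distance = as.integer(d), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$peak_id, out$gene_id, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# in-memory tag library from explicit positions
tags_at <- function(chrom, pos, total = 1e7, name = "lib") {
  tag_library(name, chrom, pos, total)
}

# small simulated dataset scaled for fast tests
small_sim_config <- function(seed = 1L, ...) {
  sim_config(seed = seed,
             chrom_lengths = c(chr1 = 3e5, chr2 = 3e5, chr3 = 3e5),
             n_loci = c(both_open = 30L, naive_specific = 30L,
                        primed_specific = 30L),
             ...)
}

# assemble a pipeline_config from a written sim dataset
sim_pipeline_config <- function(ds, outdir, ...) {
  libs <- data.frame(name = ds$libraries$name,
                     peaks_bed = unname(ds$paths$peaks[ds$libraries$name]),
                     tags_bed = unname(ds$paths$tags[ds$libraries$name]),
                     total_unique_reads = ds$config$reads_per_library,
                     stringsAsFactors = FALSE)
  pipeline_config(libs, "naive", "primed", outdir,
                  chip_bed = ds$paths$chip,
                  chrom_sizes = ds$paths$chrom_sizes,
                  genes_bed = ds$paths$genes,
                  expression_tsv = ds$paths$expression,
                  threshold = ds$config$threshold,
                  window_halfwidth = ds$config$window_halfwidth, ...)
}
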