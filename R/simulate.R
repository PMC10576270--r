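# Config-driven synthetic dataset generator with ground truth. Emulates the
# structure of a naive/primed ATAC time course at desk scale: loci open in
# one, both or neither terminal state, time-course libraries interpolating
# between the states, a TF bound at a subset of loci, and expression coupled
# to locus openness.

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the generator emulates: three
#' modest chromosomes; 100 loci per state class; the TF bound at 40% of
#' primed-specific, 30% of naive-specific and 35% of both-open loci; 10^7
#' unique reads per library (scale factor 1); open loci at 5x and closed
#' loci at 0.2x the classification threshold with Poisson tag counts over a
#' uniform background at 0.05x; three time-course libraries interpolating
#' the naive-to-primed transition; negative-binomial expression (dispersion
#' 0.1) high where a gene's enhancer is open.
#'
#' @param seed RNG seed; a single stream drives all draws.
#' @param chrom_lengths named chromosome lengths in bases.
#' @param n_loci named counts per state class (`both_open`,
#'   `naive_specific`, `primed_specific`).
#' @param tf_bound_fraction named fractions in `[0, 1]` of each class bound
#'   by the TF.
#' @param reads_per_library total unique reads per library (sets the depth
#'   scale factor `10^7 / reads`).
#' @param open_density_multiple,closed_density_multiple locus mean density
#'   as a multiple of `threshold` when open / closed; must satisfy
#'   open > 1 > closed >= 0.
#' @param background_multiple uniform background density as a multiple of
#'   `threshold`.
#' @param threshold,window_halfwidth classification threshold and
#'   summit-window halfwidth the data are calibrated to.
#' @param timepoints interpolation fractions in (0, 1) for the time-course
#'   libraries (0 = naive, 1 = primed).
#' @param expr_high_mean,expr_low_mean,expr_dispersion negative-binomial
#'   expression means (normalized tag counts) for open/closed enhancer
#'   states and the NB dispersion (size = 1/dispersion).
#' @return validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6),
                       n_loci = c(both_open = 100L, naive_specific = 100L,
                                  primed_specific = 100L),
                       tf_bound_fraction = c(both_open = 0.35,
                                             naive_specific = 0.30,
                                             primed_specific = 0.40),
                       reads_per_library = 1e7,
                       open_density_multiple = 5,
                       closed_density_multiple = 0.2,
                       background_multiple = 0.05,
                       threshold = 0.2734,
                       window_halfwidth = 150L,
                       timepoints = c(0.25, 0.5, 0.75),
                       expr_high_mean = 1000,
                       expr_low_mean = 50,
                       expr_dispersion = 0.1) {
  classes <- c("both_open", "naive_specific", "primed_specific")
  if (!all(classes %in% names(n_loci))) {
    stop("n_loci must name all of ", paste(classes, collapse = ", "))
  }
  if (!all(classes %in% names(tf_bound_fraction))) {
    stop("tf_bound_fraction must name all of ", paste(classes, collapse = ", "))
  }
  if (any(n_loci[classes] <= 0)) stop("all locus counts must be positive")
  if (any(tf_bound_fraction < 0 | tf_bound_fraction > 1)) {
    stop("tf_bound_fraction outside [0, 1]")
  }
  if (!(open_density_multiple > 1 && closed_density_multiple < 1 &&
        closed_density_multiple >= 0)) {
    stop("need open_density_multiple > 1 > closed_density_multiple >= 0")
  }
  if (reads_per_library <= 0) stop("reads_per_library must be positive")
  if (threshold <= 0 || window_halfwidth <= 0) {
    stop("threshold and window_halfwidth must be positive")
  }
  if (length(timepoints) && any(timepoints <= 0 | timepoints >= 1)) {
    stop("timepoints must lie strictly between 0 and 1")
  }
  structure(list(seed = as.integer(seed),
                 chrom_lengths = chrom_lengths,
                 n_loci = n_loci[classes],
                 tf_bound_fraction = tf_bound_fraction[classes],
                 reads_per_library = reads_per_library,
                 open_density_multiple = open_density_multiple,
                 closed_density_multiple = closed_density_multiple,
                 background_multiple = background_multiple,
                 threshold = threshold,
                 window_halfwidth = as.integer(window_halfwidth),
                 timepoints = sort(timepoints),
                 expr_high_mean = expr_high_mean,
                 expr_low_mean = expr_low_mean,
                 expr_dispersion = expr_dispersion),
            class = "sim_config")
}

# place loci on a regular grid, round-robin over chromosomes, with gaps of
# at least twice the measurement window between locus windows
.place_loci <- function(config) {
  w <- config$window_halfwidth
  window_len <- 2L * w
  step <- 4L * window_len          # >= 2 windows of clearance between loci
  margin <- 2L * window_len + 4000L  # room for the linked TSS downstream
  n_total <- sum(config$n_loci)
  slots <- list()
  for (cn in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[cn]]
    centers <- seq(margin, len - margin, by = step)
    if (length(centers)) {
      slots[[cn]] <- data.frame(chrom = cn, summit = as.integer(centers),
                                stringsAsFactors = FALSE)
    }
  }
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n_total) {
    stop("config error: ", n_total, " loci do not fit the genome at ",
         step, "-base spacing")
  }
  # round-robin across chromosomes so classes are not confounded with position
  ord <- order(stats::ave(seq_len(nrow(slots)), slots$chrom, FUN = seq_along),
               slots$chrom)
  loci <- slots[ord[seq_len(n_total)], , drop = FALSE]
  loci$start <- loci$summit - w
  loci$end <- loci$summit + w
  rownames(loci) <- NULL
  loci
}

#' Simulate a multi-library dataset with ground truth
#'
#' Generates per-library called-peak BEDs, tag BEDs (cut sites), a TF
#' ChIP-seq peak BED, a gene TSS annotation, an expression table and a truth
#' table, all consistent with one planted state assignment. Tag counts per
#' locus window are Poisson with mean
#' `density_multiple * threshold * window_length / scale`; background tags
#' are uniform at `background_multiple * threshold` density; time-course
#' libraries interpolate locus means linearly between the terminal states.
#' Deterministic given `config$seed`; when `outdir` is given the files
#' written there are byte-identical across runs.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when non-NULL all fixtures are written
#'   there (`peaks/<lib>.bed`, `tags/<lib>.bed`, `chip.bed`, `genes.bed`,
#'   `expression.tsv`, `chrom.sizes`, `truth.tsv`, `libraries.tsv`).
#' @return list of class `"sim_dataset"`: `config`, `layout`, `libraries`
#'   (data.frame name/fraction), `peaks` (named list of peak data.frames),
#'   `tags` (named list of [tag_library()]s), `chip_peaks`, `genes`,
#'   `expression` (matrix), `truth` (data.frame with per-locus state,
#'   cgroup, linked gene and per-library open/closed truth), and `paths`
#'   when written.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- config$window_halfwidth
  window_len <- 2L * w
  scale <- 1e7 / config$reads_per_library
  layout <- genome_layout(config$chrom_lengths)

  loci <- .place_loci(config)
  n_total <- nrow(loci)
  state <- sample(rep(names(config$n_loci), times = config$n_loci))
  loci$locus_id <- sprintf("locus_%04d", seq_len(n_total))
  loci$state <- state

  # TF binding: a per-class fraction of loci, chosen at random
  bound <- logical(n_total)
  for (cls in names(config$tf_bound_fraction)) {
    idx <- which(state == cls)
    k <- round(config$tf_bound_fraction[[cls]] * length(idx))
    if (k > 0) bound[sample(idx, k)] <- TRUE
  }
  loci$tf_bound <- bound
  loci$cgroup <- ifelse(state == "primed_specific", ifelse(bound, "C1", "C2"),
                        ifelse(state == "naive_specific",
                               ifelse(bound, "C3", "C4"), "none"))

  # per-library density multiples: linear interpolation naive -> primed
  m_naive <- ifelse(state %in% c("both_open", "naive_specific"),
                    config$open_density_multiple,
                    config$closed_density_multiple)
  m_primed <- ifelse(state %in% c("both_open", "primed_specific"),
                     config$open_density_multiple,
                     config$closed_density_multiple)
  fractions <- c(0, config$timepoints, 1)
  lib_names <- c("naive",
                 if (length(config$timepoints))
                   sprintf("npt_d%d", seq_along(config$timepoints)),
                 "primed")
  libraries <- data.frame(name = lib_names, fraction = fractions,
                          stringsAsFactors = FALSE)

  peaks <- list()
  tags <- list()
  truth_open <- matrix(0L, n_total, length(lib_names),
                       dimnames = list(loci$locus_id, lib_names))
  for (j in seq_along(lib_names)) {
    t <- fractions[j]
    mult <- (1 - t) * m_naive + t * m_primed
    truth_open[, j] <- as.integer(mult >= 1)

    # locus tags: Poisson counts, uniform positions inside the window
    mean_counts <- mult * config$threshold * window_len / scale
    counts <- stats::rpois(n_total, mean_counts)
    tag_chrom <- rep(loci$chrom, counts)
    tag_pos <- rep(loci$summit - w, counts) +
      floor(stats::runif(sum(counts), 0, window_len))

    # uniform background across each chromosome
    for (cn in names(config$chrom_lengths)) {
      len <- config$chrom_lengths[[cn]]
      bg_n <- stats::rpois(1, config$background_multiple * config$threshold *
                                len / scale)
      if (bg_n > 0) {
        tag_chrom <- c(tag_chrom, rep(cn, bg_n))
        tag_pos <- c(tag_pos, floor(stats::runif(bg_n, 0, len)))
      }
    }
    tags[[lib_names[j]]] <- tag_library(lib_names[j], tag_chrom,
                                        as.integer(tag_pos),
                                        config$reads_per_library)

    # the library's called peaks: loci whose expected density clears the
    # threshold (what a well-behaved caller would report)
    called <- which(mult >= 1)
    peaks[[lib_names[j]]] <- data.frame(
      chrom = loci$chrom[called], start = loci$start[called],
      end = loci$end[called], name = loci$locus_id[called],
      signal = mult[called], summit = loci$summit[called],
      source = lib_names[j], stringsAsFactors = FALSE)
  }

  chip_hw <- 100L
  chip_idx <- which(loci$tf_bound)
  chip_peaks <- data.frame(chrom = loci$chrom[chip_idx],
                           start = loci$summit[chip_idx] - chip_hw,
                           end = loci$summit[chip_idx] + chip_hw,
                           name = sprintf("chip_%04d", seq_along(chip_idx)),
                           signal = 1,
                           summit = loci$summit[chip_idx],
                           stringsAsFactors = FALSE)

  # one gene per locus, TSS a fixed 300 bases downstream of the locus
  # window; closer to its own locus than to any neighbour, so exact
  # gene-group recovery is testable with a sub-spacing assignment window
  genes <- data.frame(gene_id = paste0("g_", loci$locus_id),
                      chrom = loci$chrom,
                      tss = loci$end + 300L,
                      strand = "+", stringsAsFactors = FALSE)
  mu_naive <- ifelse(m_naive >= 1, config$expr_high_mean, config$expr_low_mean)
  mu_primed <- ifelse(m_primed >= 1, config$expr_high_mean, config$expr_low_mean)
  expression <- matrix(0, n_total, length(lib_names),
                       dimnames = list(genes$gene_id, lib_names))
  for (j in seq_along(lib_names)) {
    t <- fractions[j]
    mu <- (1 - t) * mu_naive + t * mu_primed
    expression[, j] <- stats::rnbinom(n_total, mu = mu,
                                      size = 1 / config$expr_dispersion)
  }

  truth <- cbind(loci[, c("locus_id", "chrom", "start", "end", "summit",
                          "state", "tf_bound", "cgroup")],
                 gene_id = genes$gene_id,
                 as.data.frame(truth_open) |>
                   stats::setNames(paste0("open_", lib_names)))
  rownames(truth) <- NULL

  ds <- structure(list(config = config, layout = layout,
                       libraries = libraries, peaks = peaks, tags = tags,
                       chip_peaks = chip_peaks, genes = genes,
                       expression = expression, truth = truth),
                  class = "sim_dataset")
  if (!is.null(outdir)) ds$paths <- .write_sim_dataset(ds, outdir)
  ds
}

# serialize every fixture of a simulated dataset under outdir
.write_sim_dataset <- function(ds, outdir) {
  dir.create(file.path(outdir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "tags"), showWarnings = FALSE)
  paths <- list(peaks = character(), tags = character())
  for (lib in names(ds$peaks)) {
    p <- file.path(outdir, "peaks", paste0(lib, ".bed"))
    write_peaks_bed(ds$peaks[[lib]], p)
    paths$peaks[lib] <- p
    tp <- file.path(outdir, "tags", paste0(lib, ".bed"))
    sites <- ds$tags[[lib]]$sites
    dt <- data.table::data.table(
      chrom = rep(names(sites), lengths(sites)),
      start = unlist(sites, use.names = FALSE))
    dt$end <- dt$start + 1L
    data.table::fwrite(dt, tp, sep = "\t", col.names = FALSE)
    paths$tags[lib] <- tp
  }
  paths$chip <- file.path(outdir, "chip.bed")
  write_peaks_bed(ds$chip_peaks, paths$chip)
  paths$genes <- file.path(outdir, "genes.bed")
  data.table::fwrite(data.table::data.table(
    chrom = ds$genes$chrom, start = ds$genes$tss,
    end = ds$genes$tss + 1L, name = ds$genes$gene_id, score = 0,
    strand = ds$genes$strand), paths$genes, sep = "\t", col.names = FALSE)
  paths$expression <- file.path(outdir, "expression.tsv")
  write_expression(ds$expression, paths$expression)
  paths$chrom_sizes <- file.path(outdir, "chrom.sizes")
  write_chrom_sizes(ds$layout, paths$chrom_sizes)
  paths$truth <- file.path(outdir, "truth.tsv")
  data.table::fwrite(ds$truth, paths$truth, sep = "\t")
  paths$libraries <- file.path(outdir, "libraries.tsv")
  # paths relative to outdir so same-seed outputs are byte-identical
  # wherever they are written
  data.table::fwrite(data.table::data.table(
    name = ds$libraries$name, fraction = ds$libraries$fraction,
    total_unique_reads = ds$config$reads_per_library,
    peaks_bed = file.path("peaks", paste0(ds$libraries$name, ".bed")),
    tags_bed = file.path("tags", paste0(ds$libraries$name, ".bed"))),
    paths$libraries, sep = "\t")
  paths
}

#' Compare pipeline output against the generator's truth
#'
#' Matches truth loci to superlist peaks by interval overlap (the match must
#' be one-to-one) and reports per-stage confusion matrices, accuracies and
#' exact-match flags, plus gene-set recovery Jaccard indices per C-group
#' when a peak-to-gene mapping is supplied.
#'
#' @param truth truth table from [simulate_dataset()].
#' @param groups a [state_groups()] table from the pipeline.
#' @param open_closed optional open/closed matrix (rows = superlist peak
#'   names, columns = libraries) to score against the per-library truth.
#' @param mapping optional [tss_within_window()] mapping for gene recovery.
#' @return list with `state_confusion`, `cgroup_confusion`, `state_accuracy`,
#'   `cgroup_accuracy`, `state_exact`, `cgroup_exact`, and (when inputs are
#'   given) `open_closed_confusion`, `open_closed_accuracy`, `gene_jaccard`.
#' @export
truth_report <- function(truth, groups, open_closed = NULL, mapping = NULL) {
  hits <- GenomicRanges::findOverlaps(.as_granges(truth), .as_granges(groups))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qi) || !setequal(qi, seq_len(nrow(truth)))) {
    stop("truth_report: truth loci and pipeline peaks do not match 1-1")
  }
  peak_of <- si[order(qi)]

  state_pred <- factor(groups$state[peak_of], levels = .STATES)
  state_true <- factor(truth$state, levels = .STATES)
  cgroup_pred <- factor(groups$cgroup[peak_of], levels = .CGROUPS)
  cgroup_true <- factor(truth$cgroup, levels = .CGROUPS)
  out <- list(
    state_confusion = table(truth = state_true, predicted = state_pred),
    cgroup_confusion = table(truth = cgroup_true, predicted = cgroup_pred),
    state_accuracy = mean(state_pred == state_true),
    cgroup_accuracy = mean(cgroup_pred == cgroup_true),
    state_exact = all(state_pred == state_true),
    cgroup_exact = all(cgroup_pred == cgroup_true)
  )

  if (!is.null(open_closed)) {
    libs <- intersect(colnames(open_closed),
                      sub("^open_", "", grep("^open_", names(truth),
                                             value = TRUE)))
    if (!length(libs)) stop("truth_report: no shared libraries")
    pred <- open_closed[groups$name[peak_of], libs, drop = FALSE]
    tr <- as.matrix(truth[, paste0("open_", libs), drop = FALSE])
    out$open_closed_confusion <- table(
      truth = factor(tr, levels = c(0, 1), labels = c("closed", "open")),
      predicted = factor(pred, levels = c(0, 1),
                         labels = c("closed", "open")))
    out$open_closed_accuracy <- mean(pred == tr)
  }

  if (!is.null(mapping)) {
    jac <- vapply(c("C1", "C2", "C3", "C4"), function(g) {
      got <- genes_for_group(groups, mapping, g)
      want <- unique(truth$gene_id[truth$cgroup == g])
      if (!length(got) && !length(want)) return(1)
      length(intersect(got, want)) / length(union(got, want))
    }, 0)
    out$gene_jaccard <- jac
  }
  out
}
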