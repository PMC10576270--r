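# End-to-end orchestration: superlist -> accessibility matrix -> open/closed
# -> state partition -> C-groups -> statistics -> annotation, with serialized
# stage outputs and a machine-readable run manifest.

.PIPELINE_STAGES <- c("superlist", "accessibility", "classify", "groups",
                      "stats", "annotate")

#' Build a pipeline configuration
#'
#' @param libraries data.frame with columns `name`, `peaks_bed`, `tags_bed`,
#'   `total_unique_reads` — one row per ATAC library.
#' @param naive_library,primed_library names of the two terminal-state
#'   libraries used for the state partition.
#' @param outdir run directory (created by [run_pipeline()]).
#' @param chip_bed optional TF ChIP-seq peak BED; without it every
#'   state-specific peak is treated as unbound (C2/C4).
#' @param chrom_sizes optional chromosome-sizes TSV used to clip measurement
#'   windows.
#' @param genes_bed optional TSS BED for peak-to-gene annotation.
#' @param expression_tsv optional expression table (recorded in the
#'   manifest; consumed by downstream screens).
#' @param window_halfwidth,threshold re-calling parameters (bases; scaled
#'   tags per base).
#' @param min_overlap minimum ChIP overlap in bases for C1/C3 membership.
#' @param tss_window TSS-to-peak assignment window in bases.
#' @param ma_window,fc_threshold,fc_log2,pseudocount downstream statistics
#'   parameters (moving-average window over ranked genes; fold-change screen
#'   rules).
#' @param contrasts list of Mann-Whitney contrasts, each a list with
#'   `label`, `group` (state or C-group label), `lib_a`, `lib_b` and
#'   optionally `statistic` (`"zscore"`, the default, or `"density"`).
#' @param exclude_chroms chromosomes dropped from peaks and tags on load.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(libraries, naive_library, primed_library, outdir,
                            chip_bed = NULL, chrom_sizes = NULL,
                            genes_bed = NULL, expression_tsv = NULL,
                            window_halfwidth = 150L, threshold = 0.2734,
                            min_overlap = 1L, tss_window = 10000L,
                            ma_window = 51L, fc_threshold = 1,
                            fc_log2 = FALSE, pseudocount = 1,
                            contrasts = list(), exclude_chroms = "chrM",
                            seed = 1L) {
  libraries <- as.data.frame(libraries, stringsAsFactors = FALSE)
  need <- c("name", "peaks_bed", "tags_bed", "total_unique_reads")
  miss <- setdiff(need, names(libraries))
  if (length(miss)) stop("libraries: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(libraries$name)) stop("duplicate library names")
  for (nm in c(naive_library, primed_library)) {
    if (!nm %in% libraries$name) stop("unknown terminal library: ", nm)
  }
  if (any(libraries$total_unique_reads <= 0)) {
    stop("total_unique_reads must be positive for every library")
  }
  if (window_halfwidth <= 0 || threshold <= 0) {
    stop("window_halfwidth and threshold must be positive")
  }
  structure(list(libraries = libraries, naive_library = naive_library,
                 primed_library = primed_library, outdir = outdir,
                 chip_bed = chip_bed, chrom_sizes = chrom_sizes,
                 genes_bed = genes_bed, expression_tsv = expression_tsv,
                 window_halfwidth = as.integer(window_halfwidth),
                 threshold = threshold,
                 min_overlap = as.integer(min_overlap),
                 tss_window = as.integer(tss_window),
                 ma_window = as.integer(ma_window),
                 fc_threshold = fc_threshold, fc_log2 = fc_log2,
                 pseudocount = pseudocount, contrasts = contrasts,
                 exclude_chroms = exclude_chroms, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `libraries` is a list
#' of per-library maps.
#'
#' @param path YAML path.
#' @param ... overrides applied on top of the file's values (flags win over
#'   config, config wins over defaults).
#' @return a `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  raw$libraries <- do.call(rbind, lapply(raw$libraries, function(l) {
    data.frame(name = l$name, peaks_bed = l$peaks_bed,
               tags_bed = l$tags_bed,
               total_unique_reads = as.numeric(l$total_unique_reads),
               stringsAsFactors = FALSE)
  }))
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

# ---- commented TSV helpers (self-describing stage outputs) ----

.write_tsv <- function(dt, path, comment) {
  writeLines(paste0("# ", comment), path)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE,
                     quote = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "#")))
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  skip = skip))
}

# matrix <-> TSV with a leading id column
.write_matrix_tsv <- function(m, path, id_col, comment) {
  dt <- data.table::data.table(rownames(m))
  data.table::setnames(dt, id_col)
  for (j in colnames(m)) dt[[j]] <- m[, j]
  .write_tsv(dt, path, comment)
}

.read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

# ---- lazy stage-input loaders (from memory or from the run directory) ----

.ctx_layout <- function(config, ctx) {
  if (is.null(ctx$layout) && !is.null(config$chrom_sizes)) {
    ctx$layout <- read_chrom_sizes(config$chrom_sizes)
  }
  ctx$layout
}

.ctx_superlist <- function(config, ctx) {
  if (is.null(ctx$superlist)) {
    ctx$superlist <- read_superlist(file.path(config$outdir, "superlist.bed"))
  }
  ctx$superlist
}

.ctx_density <- function(config, ctx) {
  if (is.null(ctx$density)) {
    ctx$density <- .read_matrix_tsv(file.path(config$outdir, "density.tsv"))
  }
  ctx$density
}

.ctx_open_closed <- function(config, ctx) {
  if (is.null(ctx$open_closed)) {
    oc <- .read_matrix_tsv(file.path(config$outdir, "open_closed.tsv"))
    storage.mode(oc) <- "integer"
    ctx$open_closed <- oc
  }
  ctx$open_closed
}

.ctx_groups <- function(config, ctx) {
  if (is.null(ctx$groups)) {
    ctx$groups <- read_state_groups(file.path(config$outdir, "states.bed"))
  }
  ctx$groups
}

# ---- stages ----

.stage_superlist <- function(config, ctx) {
  peak_sets <- lapply(seq_len(nrow(config$libraries)), function(i) {
    filter_chromosomes(
      read_peaks_bed(config$libraries$peaks_bed[i], config$libraries$name[i]),
      config$exclude_chroms)
  })
  ctx$superlist <- build_superlist(peak_sets)
  .check_fit(ctx$superlist$peaks, .ctx_layout(config, ctx), "superlist")
  write_superlist(ctx$superlist, file.path(config$outdir, "superlist.bed"))
  ctx$rows$superlist <- nrow(ctx$superlist$peaks)
}

.stage_accessibility <- function(config, ctx) {
  sl <- .ctx_superlist(config, ctx)
  libs <- lapply(seq_len(nrow(config$libraries)), function(i) {
    path <- config$libraries$tags_bed[i]
    if (!file.exists(path)) stop("missing tag file: ", path)
    filter_chromosomes(
      read_tags(path, config$libraries$total_unique_reads[i],
                config$libraries$name[i]),
      config$exclude_chroms)
  })
  ctx$density <- build_matrix(sl, libs, config$window_halfwidth,
                              .ctx_layout(config, ctx))
  .write_matrix_tsv(
    ctx$density, file.path(config$outdir, "density.tsv"), "peak_id",
    sprintf(paste0("normalized tag density: scaled cut sites per base in a ",
                   "%d-base summit-centered window; scale = 1e7 / ",
                   "total_unique_reads"), 2L * config$window_halfwidth))
  ctx$rows$accessibility <- nrow(ctx$density)
}

.stage_classify <- function(config, ctx) {
  oc <- classify_open_closed(.ctx_density(config, ctx), config$threshold)
  ctx$open_closed <- oc
  .write_matrix_tsv(
    oc, file.path(config$outdir, "open_closed.tsv"), "peak_id",
    sprintf("open (1) / closed (0) at density threshold %s (density >= threshold is open)",
            format(config$threshold)))
  ctx$rows$classify <- nrow(oc)
}

.stage_groups <- function(config, ctx) {
  sl <- .ctx_superlist(config, ctx)
  oc <- .ctx_open_closed(config, ctx)
  state <- partition_by_state(oc[, config$naive_library],
                              oc[, config$primed_library])
  chip <- if (!is.null(config$chip_bed)) {
    filter_chromosomes(read_peaks_bed(config$chip_bed, "chip"),
                       config$exclude_chroms)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  cgroup <- intersect_chip(sl$peaks, state, chip, config$min_overlap)
  ctx$groups <- state_groups(sl$peaks, state, cgroup)
  write_state_groups(ctx$groups, file.path(config$outdir, "states.bed"))
  summary <- group_summary(ctx$groups)
  jsonlite::write_json(list(state = as.list(summary$state),
                            cgroup = as.list(summary$cgroup)),
                       file.path(config$outdir, "groups_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ctx$rows$groups <- nrow(ctx$groups)
}

.stage_stats <- function(config, ctx) {
  density <- .ctx_density(config, ctx)
  groups <- .ctx_groups(config, ctx)
  z <- zscore_rows(density)
  .write_matrix_tsv(z, file.path(config$outdir, "zscores.tsv"), "peak_id",
                    "row-wise Z scores of normalized tag density (sample SD, ddof = 1); constant rows are 0")

  sel_rows <- function(g) {
    if (g %in% .STATES) groups$name[groups$state == g]
    else if (g %in% .CGROUPS) groups$name[groups$cgroup == g]
    else stop("unknown contrast group: ", g)
  }
  # per-group density quartiles per library
  quart <- list()
  for (g in c(.STATES, c("C1", "C2", "C3", "C4"))) {
    rows <- sel_rows(g)
    if (!length(rows)) next
    for (lib in colnames(density)) {
      q <- stats::quantile(density[rows, lib], c(0.25, 0.5, 0.75),
                           names = FALSE)
      quart[[length(quart) + 1L]] <- data.table::data.table(
        group = g, library = lib, n = length(rows),
        q25 = q[1L], median = q[2L], q75 = q[3L])
    }
  }
  .write_tsv(data.table::rbindlist(quart),
             file.path(config$outdir, "quartiles.tsv"),
             "quartiles of normalized tag density (scaled cut sites per base) per group per library")

  if (length(config$contrasts)) {
    res <- lapply(config$contrasts, function(ct) {
      stat <- if (!is.null(ct$statistic)) ct$statistic else "zscore"
      m <- if (stat == "zscore") z else density
      rows <- sel_rows(ct$group)
      if (!length(rows)) stop("contrast group '", ct$group, "' is empty")
      mw <- mann_whitney_u(m[rows, ct$lib_a], m[rows, ct$lib_b])
      list(label = if (!is.null(ct$label)) ct$label else
             paste(ct$group, ct$lib_a, "vs", ct$lib_b),
           group = ct$group, group_a = ct$lib_a, group_b = ct$lib_b,
           statistic = stat, U = mw$U, p = mw$p, n_a = mw$n_x, n_b = mw$n_y,
           method = mw$method)
    })
    jsonlite::write_json(res, file.path(config$outdir, "mw_tests.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  ctx$rows$stats <- nrow(z)
}

.stage_annotate <- function(config, ctx) {
  if (is.null(config$genes_bed)) return(invisible())
  groups <- .ctx_groups(config, ctx)
  genes <- read_tss_bed(config$genes_bed)
  mapping <- tss_within_window(groups, genes, config$tss_window)
  .write_tsv(data.table::as.data.table(mapping),
             file.path(config$outdir, "peak_gene_map.tsv"),
             sprintf("peak-to-gene assignment: TSS within %d bases of the peak interval (inclusive; 0 = TSS inside peak)",
                     config$tss_window))
  for (g in c("C1", "C2", "C3", "C4")) {
    writeLines(genes_for_group(groups, mapping, g),
               file.path(config$outdir, sprintf("genes_%s.txt", g)))
  }
  ctx$rows$annotate <- nrow(mapping)
}

.STAGE_FNS <- list(superlist = .stage_superlist,
                   accessibility = .stage_accessibility,
                   classify = .stage_classify,
                   groups = .stage_groups,
                   stats = .stage_stats,
                   annotate = .stage_annotate)

#' Pipeline stage names, in execution order
#' @return character vector of stage names.
#' @export
pipeline_stages <- function() .PIPELINE_STAGES

#' Run the analysis pipeline
#'
#' Executes the stages in order (superlist, accessibility, classify, groups,
#' stats, annotate), serializing every stage's output under
#' `config$outdir` and finishing with a machine-readable `manifest.json`
#' (parameters, input/output checksums, stage row counts). All stages are
#' deterministic, so a rerun with identical inputs and configuration is
#' bit-identical. A stage error aborts the run, names the failing stage and
#' leaves a `FAILED` marker (partial outputs are retained).
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to (re)run against an existing run
#'   directory; defaults to all, in order.
#' @return the run directory path, invisibly.
#' @export
run_pipeline <- function(config, stages = .PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(config$outdir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  .write_config_yaml(config, file.path(config$outdir, "config.yaml"))
  ctx <- new.env(parent = emptyenv())
  ctx$rows <- list()
  for (st in stages) {
    tryCatch(.STAGE_FNS[[st]](config, ctx), error = function(e) {
      writeLines(st, failed_marker)
      stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  .write_manifest(config, ctx)
  invisible(config$outdir)
}

.write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg$libraries <- lapply(seq_len(nrow(config$libraries)), function(i) {
    as.list(config$libraries[i, ])
  })
  cfg <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg, path)
}

.write_manifest <- function(config, ctx) {
  inputs <- c(config$libraries$peaks_bed, config$libraries$tags_bed,
              config$chip_bed, config$chrom_sizes, config$genes_bed,
              config$expression_tsv)
  inputs <- inputs[file.exists(inputs)]
  outputs <- setdiff(list.files(config$outdir), c("manifest.json", "FAILED"))
  out_paths <- file.path(config$outdir, outputs)
  params <- unclass(config)
  params$libraries <- NULL
  params$contrasts <- NULL
  manifest <- list(
    parameters = params[!vapply(params, is.null, TRUE)],
    libraries = config$libraries$name,
    inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))), inputs),
    stage_rows = ctx$rows,
    outputs = stats::setNames(as.list(unname(tools::md5sum(out_paths))),
                              outputs)
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Summarize a completed run
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @return list with `state_counts`, `cgroup_counts`, `quartiles`
#'   (data.frame), and `mw_tests` (list, present when contrasts were
#'   configured). Errors if the run is incomplete or failed.
#' @export
report <- function(run_dir) {
  if (file.exists(file.path(run_dir, "FAILED"))) {
    stop("run failed at stage: ",
         readLines(file.path(run_dir, "FAILED"))[1L])
  }
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("incomplete run: no manifest in ",
                                        run_dir)
  summary_path <- file.path(run_dir, "groups_summary.json")
  counts <- jsonlite::read_json(summary_path)
  out <- list(
    state_counts = unlist(counts$state),
    cgroup_counts = unlist(counts$cgroup),
    quartiles = .read_tsv(file.path(run_dir, "quartiles.tsv"))
  )
  mw_path <- file.path(run_dir, "mw_tests.json")
  if (file.exists(mw_path)) out$mw_tests <- jsonlite::read_json(mw_path)
  out
}
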