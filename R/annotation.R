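# Peak-to-gene assignment by TSS proximity, and gene-set accounting.

#' Read gene TSS annotation from BED
#'
#' BED6 where each record marks a transcription start site: the TSS is
#' `start` on the + strand and `end - 1` on the - strand (for single-base
#' records the two coincide). Multi-TSS genes may appear on several lines;
#' all supplied TSSs are used.
#'
#' @param path BED path; column 4 is the gene identifier.
#' @return data.frame `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 4L) stop("TSS BED needs >= 4 columns (gene id in column 4)")
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else rep("+", nrow(dt))
  tss <- ifelse(strand == "-", as.integer(dt[[3L]]) - 1L,
                as.integer(dt[[2L]]))
  data.frame(gene_id = as.character(dt[[4L]]),
             chrom = as.character(dt[[1L]]),
             tss = as.integer(tss), strand = strand,
             stringsAsFactors = FALSE)
}

#' Assign genes to peaks by TSS proximity
#'
#' A gene is assigned to a peak when the distance from its TSS to the peak
#' interval is at most `window` bases (inclusive). The distance is 0 for a
#' TSS inside the peak, otherwise the gap to the nearest covered base
#' (`start` or `end - 1`). Strand is ignored; a peak may map to many genes
#' and vice versa.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`).
#' @param genes gene table from [read_tss_bed()] (`gene_id`, `chrom`, `tss`).
#' @param window maximum TSS-to-peak distance in bases (default 10000).
#' @return data.frame `peak_id`, `gene_id`, `distance`, one row per
#'   assignment, ordered by peak then gene.
#' @export
tss_within_window <- function(peaks, genes, window = 10000L) {
  validate_intervals(peaks, "peaks")
  if (window < 0) stop("window must be non-negative")
  if (is.null(peaks$name)) peaks$name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  if (nrow(peaks) == 0L || nrow(genes) == 0L) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  }
  # widen peaks by the window, then hit TSS points and compute exact gaps
  widened <- data.frame(chrom = peaks$chrom,
                        start = pmax(peaks$start - window, 0L),
                        end = peaks$end + window)
  tss_iv <- data.frame(chrom = genes$chrom, start = genes$tss,
                       end = genes$tss + 1L)
  hits <- GenomicRanges::findOverlaps(.as_granges(widened),
                                      .as_granges(tss_iv))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  tss <- genes$tss[si]
  d <- pmax(peaks$start[qi] - tss, tss - (peaks$end[qi] - 1L), 0L)
  keep <- d <= window
  out <- data.frame(peak_id = peaks$name[qi][keep],
                    gene_id = genes$gene_id[si][keep],
                    distance = as.integer(d[keep]),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$peak_id, out$gene_id, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes linked to a state or C-group label
#'
#' Union (deduplicated) of the genes mapped to peaks carrying the label.
#'
#' @param groups a [state_groups()] table.
#' @param mapping peak-to-gene mapping from [tss_within_window()].
#' @param group_label one of the state labels (`both_open`,
#'   `naive_specific`, `primed_specific`, `both_closed`) or C-group labels
#'   (`C1`-`C4`, `none`).
#' @return sorted character vector of gene identifiers.
#' @export
genes_for_group <- function(groups, mapping, group_label) {
  if (group_label %in% .STATES) {
    sel <- groups$name[groups$state == group_label]
  } else if (group_label %in% .CGROUPS) {
    sel <- groups$name[groups$cgroup == group_label]
  } else {
    stop("unknown group label: ", group_label)
  }
  sort(unique(mapping$gene_id[mapping$peak_id %in% sel]))
}

#' Overlap accounting for two gene sets
#'
#' @param set_a,set_b character vectors of gene identifiers (duplicates
#'   ignored).
#' @return list with `n_common`, `n_only_a`, `n_only_b` and the member
#'   vectors `common`, `only_a`, `only_b`.
#' @export
gene_set_overlap <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  common <- sort(intersect(a, b))
  only_a <- sort(setdiff(a, b))
  only_b <- sort(setdiff(b, a))
  list(n_common = length(common), n_only_a = length(only_a),
       n_only_b = length(only_b), common = common, only_a = only_a,
       only_b = only_b)
}
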