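# Cell-state partition of superlist peaks and the C1-C4 dynamic groups
# obtained by intersecting state-specific peaks with TF ChIP-seq peaks.

.STATES <- c("both_open", "naive_specific", "primed_specific", "both_closed")
.CGROUPS <- c("C1", "C2", "C3", "C4", "none")

#' Partition peaks by terminal cell state
#'
#' Combines the open/closed calls of the two terminal states:
#' open in both -> `both_open`; open only in the naive state ->
#' `naive_specific`; open only in the primed state -> `primed_specific`;
#' open in neither (possible after re-calling) -> `both_closed`.
#'
#' @param open_closed_naive,open_closed_primed per-peak open/closed calls for
#'   the naive and primed terminal libraries (0/1 or logical vectors over the
#'   same superlist, in the same order).
#' @return character vector of state labels, one per peak.
#' @export
partition_by_state <- function(open_closed_naive, open_closed_primed) {
  if (length(open_closed_naive) != length(open_closed_primed)) {
    stop("partition_by_state: open/closed call length mismatch")
  }
  n_open <- as.logical(open_closed_naive)
  p_open <- as.logical(open_closed_primed)
  if (anyNA(n_open) || anyNA(p_open)) stop("partition_by_state: NA call")
  ifelse(n_open & p_open, "both_open",
         ifelse(n_open, "naive_specific",
                ifelse(p_open, "primed_specific", "both_closed")))
}

#' Split state-specific peaks into C1-C4 by TF ChIP overlap
#'
#' The four dynamic groups: primed-specific peaks with/without TF binding
#' (C1/C2) and naive-specific peaks with/without TF binding (C3/C4) — C3
#' being the naive enhancers that are closed in the primed state yet bound
#' by the TF there. Overlap is interval overlap of at least `min_overlap`
#' bases between the superlist peak and any ChIP peak (not summit
#' containment). Peaks open or closed in both states get `none`.
#'
#' @param peaks superlist peak data.frame (`chrom`, `start`, `end`).
#' @param states per-peak state labels from [partition_by_state()].
#' @param chip_peaks interval data.frame of TF ChIP-seq peaks.
#' @param min_overlap minimum overlap in bases (default 1).
#' @return character vector of labels in `C1`, `C2`, `C3`, `C4`, `none`.
#' @export
intersect_chip <- function(peaks, states, chip_peaks, min_overlap = 1L) {
  validate_intervals(peaks, "peaks")
  validate_intervals(chip_peaks, "chip_peaks")
  if (nrow(peaks) != length(states)) {
    stop("intersect_chip: states length does not match peaks")
  }
  if (!all(states %in% .STATES)) stop("intersect_chip: unknown state label")
  bound <- rep(FALSE, nrow(peaks))
  if (nrow(peaks) && nrow(chip_peaks)) {
    hits <- GenomicRanges::findOverlaps(.as_granges(peaks),
                                        .as_granges(chip_peaks),
                                        minoverlap = as.integer(min_overlap))
    bound[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  ifelse(states == "primed_specific", ifelse(bound, "C1", "C2"),
         ifelse(states == "naive_specific", ifelse(bound, "C3", "C4"),
                "none"))
}

#' Assemble per-peak state and C-group labels
#'
#' @param peaks superlist peak data.frame (needs a `name` column).
#' @param state,cgroup label vectors from [partition_by_state()] and
#'   [intersect_chip()].
#' @return object of class `"state_groups"`: the peak table with `state` and
#'   `cgroup` columns, consistency-checked against the group invariants.
#' @export
state_groups <- function(peaks, state, cgroup) {
  stopifnot(nrow(peaks) == length(state), nrow(peaks) == length(cgroup))
  if (!all(state %in% .STATES)) stop("unknown state label")
  if (!all(cgroup %in% .CGROUPS)) stop("unknown cgroup label")
  ok <- (cgroup %in% c("C1", "C2")) == (state == "primed_specific") &
    (cgroup %in% c("C3", "C4")) == (state == "naive_specific") &
    (cgroup == "none") == (state %in% c("both_open", "both_closed"))
  if (!all(ok)) stop("state/cgroup labels violate the partition invariants")
  out <- peaks
  out$state <- state
  out$cgroup <- cgroup
  class(out) <- c("state_groups", "data.frame")
  out
}

#' Count peaks per state and per C-group
#'
#' @param groups a [state_groups()] table.
#' @return list with `state` and `cgroup` named integer count vectors (all
#'   labels present, zero-filled). Counts satisfy C1 + C2 = primed-specific
#'   and C3 + C4 = naive-specific.
#' @export
group_summary <- function(groups) {
  state <- table(factor(groups$state, levels = .STATES))
  cgroup <- table(factor(groups$cgroup, levels = .CGROUPS))
  list(state = stats::setNames(as.integer(state), names(state)),
       cgroup = stats::setNames(as.integer(cgroup), names(cgroup)))
}

#' Serialize state/group labels as BED6+2
#'
#' Columns: chrom, start, end, name, signal, strand, state, cgroup.
#'
#' @param groups a [state_groups()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_groups <- function(groups, path) {
  dt <- data.table::data.table(
    chrom = groups$chrom, start = as.integer(groups$start),
    end = as.integer(groups$end), name = groups$name,
    signal = .num_text(if (!is.null(groups$signal)) groups$signal else 0),
    strand = ".", state = groups$state, cgroup = groups$cgroup)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6+2 state/group file written by [write_state_groups()]
#' @param path input path.
#' @return a `"state_groups"` table.
#' @export
read_state_groups <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "signal", "strand", "state",
                                        "cgroup"),
                          colClasses = list(character = 1))
  peaks <- data.frame(chrom = as.character(dt$chrom),
                      start = as.integer(dt$start),
                      end = as.integer(dt$end), name = dt$name,
                      signal = as.numeric(dt$signal),
                      stringsAsFactors = FALSE)
  state_groups(peaks, dt$state, dt$cgroup)
}
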