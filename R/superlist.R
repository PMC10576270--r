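# Union "superlist" construction: merge peaks called in any library into a
# minimal disjoint set, choosing one canonical summit per merged peak.

#' Merge overlapping intervals into a minimal disjoint set
#'
#' Union semantics: the result is the minimal sorted set of disjoint
#' intervals whose union of covered bases equals that of the input. Overlap
#' of >= 1 base triggers merging; bookended intervals (`[0,100)`, `[100,200)`)
#' are kept separate (half-open convention).
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return data.frame `chrom`, `start`, `end`, sorted by (chrom, start),
#'   pairwise disjoint.
#' @export
merge_intervals <- function(intervals) {
  validate_intervals(intervals, "intervals")
  if (nrow(intervals) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(.as_granges(intervals), min.gapwidth = 0L)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  out <- out[.interval_order(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the cross-library union peak superlist
#'
#' Merges the peaks called in any library into disjoint superlist peaks.
#' Each merged peak takes as its canonical summit the summit of the
#' highest-signal contributing peak (ties broken by the leftmost summit),
#' and records which (library, peak) pairs it absorbed.
#'
#' @param peak_sets a list of per-library peak data.frames (as returned by
#'   [read_peaks_bed()]), or a single peak data.frame with a `source` column.
#' @return object of class `"superlist"`: list with
#'   \describe{
#'     \item{peaks}{data.frame `chrom`, `start`, `end`, `name`, `signal`,
#'       `summit`; sorted, disjoint; `name` is `sl_<i>`.}
#'     \item{provenance}{data.frame `name`, `library`, `peak_name` listing
#'       every contributing input peak.}
#'   }
#' @export
build_superlist <- function(peak_sets) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  if (!length(peak_sets)) stop("build_superlist: need at least one library")
  for (i in seq_along(peak_sets)) {
    p <- peak_sets[[i]]
    validate_intervals(p, sprintf("peak set %d", i))
    if (is.null(p$summit)) p$summit <- (p$start + p$end) %/% 2L
    if (is.null(p$signal)) p$signal <- 0
    if (is.null(p$source)) {
      p$source <- if (!is.null(names(peak_sets)) &&
                      nzchar(names(peak_sets)[i])) names(peak_sets)[i]
                  else sprintf("lib%d", i)
    }
    if (is.null(p$name)) p$name <- sprintf("%s_peak_%d", p$source, seq_len(nrow(p)))
    if (any(p$summit < p$start | p$summit >= p$end)) {
      stop(sprintf("peak set %d: summit outside its interval", i))
    }
    if (any(p$signal < 0)) stop(sprintf("peak set %d: negative signal", i))
    peak_sets[[i]] <- p[, c("chrom", "start", "end", "name", "signal",
                            "summit", "source")]
  }
  all_peaks <- do.call(rbind, peak_sets)
  if (nrow(all_peaks) == 0L) stop("build_superlist: no peaks supplied")

  merged <- merge_intervals(all_peaks)
  hits <- GenomicRanges::findOverlaps(.as_granges(all_peaks),
                                      .as_granges(merged))
  # union-merge guarantees each input peak falls in exactly one merged peak
  stopifnot(length(hits) == nrow(all_peaks))
  grp <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]

  # canonical summit: max signal, ties -> leftmost summit
  ord <- order(grp, -all_peaks$signal, all_peaks$summit)
  first <- ord[!duplicated(grp[ord])]
  canon <- data.frame(grp = grp[first], summit = all_peaks$summit[first],
                      signal = all_peaks$signal[first])
  canon <- canon[order(canon$grp), ]

  peaks <- merged
  peaks$name <- sprintf("sl_%06d", seq_len(nrow(peaks)))
  peaks$signal <- canon$signal
  peaks$summit <- canon$summit
  peaks <- peaks[, c("chrom", "start", "end", "name", "signal", "summit")]

  provenance <- data.frame(name = peaks$name[grp],
                           library = all_peaks$source,
                           peak_name = all_peaks$name,
                           stringsAsFactors = FALSE)
  provenance <- provenance[order(provenance$name, provenance$library,
                                 provenance$peak_name), ]
  rownames(provenance) <- NULL
  structure(list(peaks = peaks, provenance = provenance),
            class = "superlist")
}

#' @export
print.superlist <- function(x, ...) {
  cat(sprintf("superlist: %d merged peaks from %d contributing peaks across %d library(ies)\n",
              nrow(x$peaks), nrow(x$provenance),
              length(unique(x$provenance$library))))
  invisible(x)
}

#' Serialize a superlist
#'
#' Peaks go to BED6+summit (via [write_peaks_bed()]) and provenance to a
#' sidecar TSV.
#'
#' @param sl a [build_superlist()] result.
#' @param bed_path,provenance_path output paths.
#' @return `bed_path`, invisibly.
#' @export
write_superlist <- function(sl, bed_path,
                            provenance_path = paste0(bed_path, ".provenance.tsv")) {
  write_peaks_bed(sl$peaks, bed_path)
  data.table::fwrite(sl$provenance, provenance_path, sep = "\t")
  invisible(bed_path)
}

#' Read a serialized superlist
#' @param bed_path,provenance_path paths written by [write_superlist()].
#' @return a `"superlist"` object.
#' @export
read_superlist <- function(bed_path,
                           provenance_path = paste0(bed_path, ".provenance.tsv")) {
  peaks <- read_peaks_bed(bed_path, "superlist")
  peaks$source <- NULL
  prov <- as.data.frame(data.table::fread(provenance_path, sep = "\t",
                                          header = TRUE))
  structure(list(peaks = peaks, provenance = prov), class = "superlist")
}
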