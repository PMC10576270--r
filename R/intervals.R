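# Interval plumbing shared by all modules. Peaks and intervals travel as
# plain data.frames in BED convention (0-based half-open); GRanges (1-based
# closed) is used internally for overlap arithmetic only.

#' Validate a table of genomic intervals
#'
#' Checks the interval invariants: non-empty chromosome name, `start >= 0`,
#' `end > start`. Called by every constructor that accepts intervals.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param context character scalar used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x, context = "interval table") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(context, ": missing column(s) ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!nzchar(x$chrom) | is.na(x$chrom))) {
    stop(context, ": empty or NA chromosome name")
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop(context, ": NA coordinates")
  }
  if (any(x$start < 0)) stop(context, ": negative start coordinate")
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop(context, ": rejected record with end <= start (record ",
         bad[1L], ": ", x$chrom[bad[1L]], ":", x$start[bad[1L]], "-",
         x$end[bad[1L]], ")")
  }
  invisible(x)
}

# BED half-open -> GRanges (1-based closed), deterministic seqlevel order
.as_granges <- function(x) {
  lev <- sort(unique(as.character(x$chrom)))
  GenomicRanges::GRanges(
    seqnames = factor(as.character(x$chrom), levels = lev),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# order rows by (chrom, start, end) with plain character chromosome sort
.interval_order <- function(x) order(as.character(x$chrom), x$start, x$end)

#' Read a chromosome-sizes table
#'
#' @param path 2-column TSV without header: chromosome name, length in bases.
#' @return named integer vector of chromosome lengths (a genome layout).
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          colClasses = list(character = 1))
  genome_layout(stats::setNames(as.integer(dt$length), dt$chrom))
}

#' Construct a genome layout
#'
#' @param lengths named numeric/integer vector of per-chromosome lengths.
#' @return named integer vector with class `"genome_layout"`.
#' @export
genome_layout <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("genome layout requires named chromosome lengths")
  }
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  structure(stats::setNames(as.integer(lengths), names(lengths)),
            class = "genome_layout")
}

#' Write a chromosome-sizes table
#' @param layout genome layout (named lengths).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  data.table::fwrite(data.table::data.table(chrom = names(layout),
                                            length = as.integer(layout)),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# assert that every interval fits inside its chromosome
.check_fit <- function(x, layout, context = "interval table") {
  if (is.null(layout)) return(invisible(x))
  unknown <- setdiff(unique(x$chrom), names(layout))
  if (length(unknown)) {
    stop(context, ": chromosome(s) not in genome layout: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(x) && any(x$end > layout[as.character(x$chrom)])) {
    stop(context, ": interval extends beyond chromosome end")
  }
  invisible(x)
}
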