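# Readers/writers for the text formats the pipeline touches: BED peaks
# (optionally BED6 + summit-offset column), tag BEDs (cut sites), bedGraph
# coverage, chromosome sizes and expression TSVs.

#' Read a BED file of peaks
#'
#' Accepts BED3 and upward. Column 4 is the peak name, column 5 its signal
#' score, column 6 the strand, and column 7 (when present) the summit offset
#' relative to `start` — the layout written by [write_peaks_bed()]. When no
#' summit column is present the summit defaults to the interval midpoint
#' `floor((start + end) / 2)`; when no score column is present the signal is 0.
#'
#' @param path BED file path.
#' @param library_name identifier recorded in the `source` column of the
#'   result; defaults to the file name without extension.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `signal`,
#'   `summit` (absolute 0-based position), `source`. Coordinates are 0-based
#'   half-open.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300", tf)
#' read_peaks_bed(tf, "libA")$summit  # 200, the midpoint default
#' @export
read_peaks_bed <- function(path,
                           library_name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("peak BED not found: ", path)
  lines <- readLines(path)
  data_idx <- which(nzchar(lines) & !grepl("^(#|track|browser)", lines))
  if (!length(data_idx)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      signal = numeric(), summit = integer(),
                      source = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    ln <- data_idx[which(nf < 3L)[1L]]
    stop("parse error in ", path, " line ", ln, ": expected >= 3 fields")
  }
  col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, "")
  }
  chrom <- col(1L)
  start <- suppressWarnings(as.integer(col(2L)))
  end <- suppressWarnings(as.integer(col(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("parse error in ", path, " line ", data_idx[bad[1L]],
         ": non-numeric coordinates")
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("rejected record in ", path, " line ", data_idx[bad[1L]],
         ": end <= start")
  }
  name <- col(4L)
  name <- ifelse(is.na(name) | name == "." | !nzchar(name),
                 sprintf("%s_peak_%d", library_name, seq_along(chrom)), name)
  signal <- suppressWarnings(as.numeric(col(5L)))
  signal[is.na(signal)] <- 0
  if (any(signal < 0)) stop("negative signal score in ", path)
  offset <- suppressWarnings(as.integer(col(7L)))
  summit <- ifelse(is.na(offset), (start + end) %/% 2L, start + offset)
  peaks <- data.frame(chrom = chrom, start = start, end = end, name = name,
                      signal = signal, summit = as.integer(summit),
                      source = library_name, stringsAsFactors = FALSE)
  validate_intervals(peaks, paste0("peaks from ", path))
  if (any(peaks$summit < peaks$start | peaks$summit >= peaks$end)) {
    stop("summit outside its peak interval in ", path)
  }
  peaks
}

#' Write peaks as BED6 + summit offset
#'
#' Emits `chrom start end name signal strand summit_offset`, the layout
#' [read_peaks_bed()] reads back losslessly.
#'
#' @param peaks data.frame as returned by [read_peaks_bed()] (the `source`
#'   column is optional and not serialized).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  validate_intervals(peaks, "peaks")
  dt <- data.table::data.table(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    name = if (!is.null(peaks$name)) peaks$name else
      sprintf("peak_%d", seq_len(nrow(peaks))),
    signal = .num_text(if (!is.null(peaks$signal)) peaks$signal else 0),
    strand = ".",
    summit_offset = as.integer(
      (if (!is.null(peaks$summit)) peaks$summit
       else (peaks$start + peaks$end) %/% 2L) - peaks$start)
  )
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# serialize doubles with round-trip precision (17 significant digits)
.num_text <- function(x) {
  out <- sprintf("%.17g", as.numeric(x))
  whole <- as.numeric(x) == floor(as.numeric(x)) & abs(as.numeric(x)) < 1e15
  out[whole] <- sprintf("%d", as.integer(x[whole]))
  out
}

#' Construct a tag library from cut-site positions
#'
#' A tag library holds one ATAC-seq library's cut sites plus the total unique
#' read count from alignment, from which the depth scale factor
#' `10^7 / total_unique_reads` is derived (the genomeCoverageBed-style
#' normalization). `total_unique_reads` is supplied as metadata — it is the
#' post-filter unique count, which can exceed the number of sites in the file.
#'
#' @param name library identifier.
#' @param chrom,pos parallel vectors of cut-site chromosome and 0-based
#'   position (a multiset: repeats allowed).
#' @param total_unique_reads positive total unique read count.
#' @return object of class `"tag_library"`: a list with `name`, `sites`
#'   (per-chromosome sorted position vectors), `n_sites`,
#'   `total_unique_reads` and `scale`.
#' @export
tag_library <- function(name, chrom, pos, total_unique_reads) {
  if (length(total_unique_reads) != 1L || is.na(total_unique_reads) ||
      total_unique_reads <= 0) {
    stop("total_unique_reads must be a positive scalar")
  }
  if (length(chrom) != length(pos)) stop("chrom and pos length mismatch")
  if (length(pos) && any(pos < 0)) stop("negative cut-site position")
  sites <- lapply(split(as.integer(pos), as.character(chrom)), sort)
  structure(list(name = name, sites = sites, n_sites = length(pos),
                 total_unique_reads = as.numeric(total_unique_reads),
                 scale = 1e7 / as.numeric(total_unique_reads)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d cut sites on %d chromosome(s), %s unique reads, scale %.6g\n",
              x$name, x$n_sites, length(x$sites),
              format(x$total_unique_reads, big.mark = ","), x$scale))
  invisible(x)
}

#' Read a tag BED into a tag library
#'
#' Each BED record contributes one cut site at its 5' position: `start` for
#' the + strand (or when no strand column is present), `end - 1` for the
#' - strand. No Tn5 offset correction is applied; offsets, if any, are
#' assumed already applied upstream.
#'
#' @param path BED file of sequenced-fragment cut sites (single-base or short
#'   intervals).
#' @param total_unique_reads positive total unique read count for the library
#'   (alignment metadata, not inferred from the file).
#' @param name library identifier; defaults to the file name.
#' @return a [tag_library()].
#' @export
read_tags <- function(path, total_unique_reads,
                      name = sub("\\.[^.]*$", "", basename(path))) {
  if (length(total_unique_reads) != 1L || is.na(total_unique_reads) ||
      total_unique_reads <= 0) {
    stop("total_unique_reads must be a positive scalar")
  }
  if (!file.exists(path)) stop("tag BED not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(tag_library(name, character(), integer(), total_unique_reads))
  }
  if (ncol(dt) < 3L) stop("parse error in ", path, ": expected >= 3 fields")
  start <- as.integer(dt[[2L]])
  end <- as.integer(dt[[3L]])
  if (any(is.na(start)) || any(is.na(end))) {
    stop("parse error in ", path, ": non-numeric coordinates")
  }
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else
    rep(".", nrow(dt))
  pos <- ifelse(strand == "-", end - 1L, start)
  tag_library(name, as.character(dt[[1L]]), pos, total_unique_reads)
}

#' Drop records on excluded chromosomes
#'
#' Mitochondrial removal and similar filters. Works on interval tables
#' (anything with a `chrom` column) and on [tag_library()] objects.
#'
#' @param x interval data.frame or tag library.
#' @param exclude_names chromosome names to remove; defaults to `"chrM"`.
#' @return `x` with all records on excluded chromosomes removed, input order
#'   preserved.
#' @export
filter_chromosomes <- function(x, exclude_names = "chrM") {
  UseMethod("filter_chromosomes")
}

#' @export
filter_chromosomes.data.frame <- function(x, exclude_names = "chrM") {
  if (!length(exclude_names)) return(x)
  out <- x[!(x$chrom %in% exclude_names), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
filter_chromosomes.tag_library <- function(x, exclude_names = "chrM") {
  if (!length(exclude_names)) return(x)
  keep <- setdiff(names(x$sites), exclude_names)
  x$sites <- x$sites[keep]
  x$n_sites <- sum(lengths(x$sites))
  x
}

#' Write per-interval coverage as bedGraph
#'
#' Values are serialized with full double precision so that
#' `read_bedgraph(write_bedgraph(x))` reproduces intervals and values exactly.
#'
#' @param coverage data.frame with columns `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  validate_intervals(coverage, "coverage")
  if (is.null(coverage$value)) stop("coverage: missing 'value' column")
  dt <- data.table::data.table(chrom = coverage$chrom,
                               start = as.integer(coverage$start),
                               end = as.integer(coverage$end),
                               value = .num_text(coverage$value))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph path.
#' @return data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1))
  out <- as.data.frame(dt)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$value <- as.numeric(out$value)
  validate_intervals(out, paste0("bedGraph ", path))
  out
}

#' Read an expression table
#'
#' @param path TSV with a header row; first column gene identifiers,
#'   remaining columns per-sample normalized expression (normalized tag
#'   counts).
#' @return numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  genes <- as.character(dt[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write an expression table
#' @param m genes x samples numeric matrix with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  dt <- data.table::data.table(gene_id = rownames(m))
  for (j in colnames(m)) dt[[j]] <- m[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
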