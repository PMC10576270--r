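# Quantitative comparisons: row-wise Z scores, Mann-Whitney U, summit-
# centered pileup profiles, moving-average density over ranked genes,
# fold-change screens and motif-table post-filtering.

#' Row-wise Z scores
#'
#' Standardizes each row to mean 0, sample SD 1 (`ddof = 1`), emphasising
#' relative dynamics of each locus across samples. Rows with zero spread map
#' to all zeros.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return matrix of the same shape and dimnames.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("zscore_rows: need at least 2 columns")
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  dimnames(z) <- dimnames(m)
  z
}

#' Mann-Whitney U test
#'
#' `U` is reported for the first sample: the number of pairs `(i, j)` with
#' `x_i > y_j`, counting ties as 1/2. The p-value is exact (distribution
#' enumeration) when `n_x + n_y <= 20` and there are no ties, otherwise a
#' normal approximation with tie and continuity correction is used — both
#' routes as implemented in [stats::wilcox.test()].
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`) p; `NULL`
#'   (default) applies the rule above.
#' @return list with `U`, `p`, `n_x`, `n_y`, `method`.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater"), exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("mann_whitney_u: empty sample")
  if (anyNA(x) || anyNA(y)) stop("mann_whitney_u: NA values")
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- (nx + ny <= 20L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(U = unname(U), p = wt$p.value, n_x = nx, n_y = ny,
       method = if (exact && !ties) "exact" else "normal_approx")
}

#' Summit-centered pileup profile
#'
#' Mean scaled cut-site density per bin over a set of peaks, with bins tiling
#' `[summit - halfwidth, summit + halfwidth)`. The per-peak, per-bin value is
#' the scaled cut-site count divided by the bin width; the profile averages
#' these over peaks, so mirrored tag data yields a mirrored profile.
#'
#' @param peaks peak data.frame with `chrom` and `summit`.
#' @param tag_library a [tag_library()].
#' @param halfwidth window halfwidth in bases; must be a multiple of
#'   `bin_size`.
#' @param bin_size bin width in bases.
#' @return data.frame with `offset_start`, `offset_end` (bin bounds relative
#'   to the summit) and `density` (mean scaled tags per base).
#' @export
pileup_profile <- function(peaks, tag_library, halfwidth = 1000L,
                           bin_size = 50L) {
  stopifnot(inherits(tag_library, "tag_library"))
  if (bin_size <= 0 || halfwidth <= 0) stop("positive sizes required")
  if (halfwidth %% bin_size != 0) {
    stop("halfwidth must be a multiple of bin_size")
  }
  if (nrow(peaks) == 0L) stop("pileup_profile: no peaks")
  nbins <- as.integer(2L * halfwidth / bin_size)
  offsets <- -halfwidth + bin_size * (seq_len(nbins) - 1L)
  chrom <- as.character(peaks$chrom)
  density <- vapply(offsets, function(off) {
    s <- as.integer(peaks$summit + off)
    counts <- .count_in_windows(tag_library, chrom, pmax(s, 0L),
                                pmax(s + as.integer(bin_size), 0L))
    mean(counts * tag_library$scale / bin_size)
  }, 0)
  data.frame(offset_start = offsets, offset_end = offsets + bin_size,
             density = density)
}

#' Centered moving average over rank-ordered values
#'
#' Smooths a statistic (e.g. TF binding density) over genes ordered by rank.
#' The window is centered and clipped at the edges: position `i` averages
#' the values at indices `max(1, i-k) .. min(n, i+k)` for window `2k + 1`.
#'
#' @param values numeric vector, already in rank order.
#' @param window odd positive window length, at most `length(values)`.
#' @return numeric vector of smoothed values, same length as the input.
#' @export
moving_average_density <- function(values, window = 51L) {
  n <- length(values)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be odd and >= 1")
  }
  if (window > n) stop("window larger than the number of values")
  if (anyNA(values)) stop("NA values")
  k <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Fold-change screen between two expression samples
#'
#' Keeps genes whose pseudocounted fold change `(a + pc) / (b + pc)` exceeds
#' the threshold (strict `>`). With `log2 = TRUE` the comparison is
#' `log2(FC) > fc_threshold` instead.
#'
#' @param expr_a,expr_b named non-negative expression vectors over the same
#'   gene roster.
#' @param fc_threshold screen threshold (default 1: any increase passes on
#'   the linear scale).
#' @param pseudocount added to both samples before the ratio (default 1).
#' @param log2 apply the threshold to `log2(FC)` instead of linear FC.
#' @return character vector of surviving gene identifiers, in input order.
#' @export
fold_change_screen <- function(expr_a, expr_b, fc_threshold = 1,
                               pseudocount = 1, log2 = FALSE) {
  if (is.null(names(expr_a)) || is.null(names(expr_b))) {
    stop("fold_change_screen: expression vectors must be named by gene")
  }
  if (!setequal(names(expr_a), names(expr_b))) {
    stop("fold_change_screen: gene rosters differ")
  }
  expr_b <- expr_b[names(expr_a)]
  if (any(expr_a < 0) || any(expr_b < 0)) {
    stop("fold_change_screen: negative expression")
  }
  fc <- (expr_a + pseudocount) / (expr_b + pseudocount)
  stat <- if (log2) log2(fc) else fc
  names(expr_a)[stat > fc_threshold]
}

#' Post-filter a motif enrichment table
#'
#' Keeps motifs significantly enriched over background: `p_value < p_max`
#' and `percent_target / percent_background > min_ratio`. A background of 0
#' with a positive target percentage counts as infinitely enriched and is
#' kept (subject to the p-value rule).
#'
#' @param records data.frame with columns `motif`, `p_value`,
#'   `percent_target`, `percent_background` (percentages in 0-100).
#' @param p_max p-value cutoff (default 0.01).
#' @param min_ratio minimum target/background ratio (default 1.5).
#' @return the surviving rows of `records`, original order preserved.
#' @export
motif_filter <- function(records, p_max = 0.01, min_ratio = 1.5) {
  need <- c("motif", "p_value", "percent_target", "percent_background")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("motif_filter: missing column(s) ",
                         paste(miss, collapse = ", "))
  with(records, {
    if (any(p_value <= 0 | p_value > 1)) stop("motif_filter: p_value outside (0, 1]")
    if (any(percent_target < 0 | percent_target > 100 |
            percent_background < 0 | percent_background > 100)) {
      stop("motif_filter: percentages outside [0, 100]")
    }
  })
  ratio_ok <- ifelse(records$percent_background == 0,
                     records$percent_target > 0,
                     records$percent_target / records$percent_background >
                       min_ratio)
  out <- records[records$p_value < p_max & ratio_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}
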