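# Cell-size distributions in 1-um bins and size-stratified retention.
# Bin convention: half-open [d, d+1) um, keyed by the integer lower edge d,
# matching the 1-um subdivisions of automated cell counters ("5-6 um" means
# the bin [5, 6)).

#' Construct a cell-size histogram
#'
#' @param bin_lower integer lower edges of consecutive 1-um bins, um.
#' @param count non-negative cell count (or fraction) per bin.
#' @return data frame with class `size_histogram`, sorted by `bin_lower`.
#' @export
size_histogram <- function(bin_lower, count) {
  df <- data.frame(bin_lower = as.integer(bin_lower), count = as.numeric(count))
  validate_size_histogram(df)
}

validate_size_histogram <- function(df) {
  stopifnot(is.data.frame(df), all(c("bin_lower", "count") %in% names(df)))
  if (nrow(df) == 0L) stop("size histogram is empty", call. = FALSE)
  if (any(df$count < 0)) stop("histogram counts must be >= 0", call. = FALSE)
  if (anyDuplicated(df$bin_lower)) stop("duplicate bin edges", call. = FALSE)
  df <- df[order(df$bin_lower), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- union("size_histogram", class(df))
  df
}

#' A donor-cell sample
#'
#' @param total_count number of cells in the sample.
#' @param viability live fraction in `[0, 1]`.
#' @param size_histogram optional [size_histogram()]; when present its counts
#'   must sum to `total_count`.
#' @return object of class `cell_population`.
#' @export
cell_population <- function(total_count, viability = 1, size_histogram = NULL) {
  if (total_count < 0) stop("'total_count' must be >= 0", call. = FALSE)
  if (viability < 0 || viability > 1) {
    stop("'viability' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(size_histogram)) {
    size_histogram <- validate_size_histogram(size_histogram)
    if (abs(sum(size_histogram$count) - total_count) > 1e-6 * max(1, total_count)) {
      stop("size histogram counts do not sum to 'total_count'", call. = FALSE)
    }
  }
  structure(list(total_count = total_count, viability = viability,
                 size_histogram = size_histogram),
            class = "cell_population")
}

#' Median and mean diameter of a binned size distribution
#'
#' The mean is the count-weighted average of bin midpoints (`d + 0.5` for bin
#' `[d, d+1)`). The median is interpolated linearly within the bin containing
#' the 50th percentile: `d + (0.5 - F(d)) / f`, where `F(d)` is the cumulative
#' fraction below the bin and `f` the bin's fraction. This interpolated-median
#' convention makes binned medians comparable with medians of the underlying
#' continuous diameters.
#'
#' @param hist a [size_histogram()].
#' @return named list with `median` and `mean`, um.
#' @export
summarize_sizes <- function(hist) {
  hist <- validate_size_histogram(as.data.frame(hist))
  tot <- sum(hist$count)
  if (tot <= 0) stop("size histogram has zero total count", call. = FALSE)
  frac <- hist$count / tot
  mean_um <- sum((hist$bin_lower + 0.5) * frac)
  cum <- cumsum(frac)
  i <- which(cum >= 0.5)[1L]
  below <- if (i == 1L) 0 else cum[i - 1L]
  med_um <- hist$bin_lower[i] + (0.5 - below) / frac[i]
  list(median = med_um, mean = mean_um)
}

#' Per-bin retention rates from pre-injection and effluent histograms
#'
#' For each 1-um diameter bin, retention is
#' `(injected_in_bin - effluent_in_bin) / injected_in_bin * 100`. Both
#' histograms must be on identical bin edges and the pre-injection histogram
#' must be scaled to the injected dose (its counts are the injected cells per
#' bin). Bins where the effluent exceeds the injected count are clamped to 0%
#' (raw value kept in `retention_pct_raw`); bins with zero injected cells get
#' `NA` retention; bins with fewer injected cells than `min_support` are
#' flagged `low_support` (they carry too little information for shape
#' comparisons - diameters >= 10 um are under 1% of a typical mononuclear
#' cell population).
#'
#' @param pre [size_histogram()] of the injected population, counts = cells.
#' @param effluent [size_histogram()] of cells recovered in the effluent.
#' @param min_support minimum injected cells per bin before the bin is
#'   considered well supported (default 100).
#' @param clamp clamp negative per-bin retention to 0 (default TRUE).
#' @return data frame: `bin_lower`, `injected`, `effluent`, `retention_pct`,
#'   `retention_pct_raw`, `clamped`, `low_support`.
#' @export
per_bin_retention <- function(pre, effluent, min_support = 100, clamp = TRUE) {
  pre <- validate_size_histogram(as.data.frame(pre))
  effluent <- validate_size_histogram(as.data.frame(effluent))
  if (!identical(pre$bin_lower, effluent$bin_lower)) {
    stop("pre-injection and effluent histograms are on different bin edges",
         call. = FALSE)
  }
  raw <- ifelse(pre$count > 0,
                (pre$count - effluent$count) / pre$count * 100, NA_real_)
  clamped <- !is.na(raw) & raw < 0 & clamp
  val <- raw
  val[clamped] <- 0
  data.frame(bin_lower = pre$bin_lower,
             injected = pre$count,
             effluent = effluent$count,
             retention_pct = val,
             retention_pct_raw = raw,
             clamped = clamped,
             low_support = pre$count < min_support)
}

#' Pooled retention of all bins at or above a diameter cutoff
#'
#' Pools injected and effluent counts over bins with `bin_lower >= cutoff`
#' and computes retention from the pooled totals (a count-weighted
#' combination, not the mean of per-bin percentages).
#'
#' @param bins data frame from [per_bin_retention()].
#' @param lower_cutoff_um diameter cutoff, um, on a bin edge.
#' @param clamp clamp a negative pooled value to 0.
#' @return pooled retention, percent.
#' @export
pooled_retention <- function(bins, lower_cutoff_um, clamp = TRUE) {
  sel <- bins$bin_lower >= lower_cutoff_um
  if (!any(sel)) stop("no bins at or above the cutoff", call. = FALSE)
  inj <- sum(bins$injected[sel])
  eff <- sum(bins$effluent[sel])
  if (inj <= 0) stop("zero injected cells at or above the cutoff", call. = FALSE)
  as.numeric(retention_rate(inj, eff, clamp = clamp))
}

# Pad a histogram with zero-count bins so that it covers `edges` exactly.
# Used to put pre-injection and effluent histograms on a common support.
pad_histogram <- function(hist, edges) {
  hist <- validate_size_histogram(as.data.frame(hist))
  extra <- setdiff(edges, hist$bin_lower)
  if (length(extra)) {
    hist <- rbind(as.data.frame(hist),
                  data.frame(bin_lower = as.integer(extra), count = 0))
  }
  validate_size_histogram(hist[hist$bin_lower %in% edges, ])
}

#' Put two histograms on their common (union) bin support
#'
#' @param a,b [size_histogram()] objects.
#' @return list of the two histograms padded with zero bins to the union of
#'   their edges.
#' @export
align_histograms <- function(a, b) {
  a <- validate_size_histogram(as.data.frame(a))
  b <- validate_size_histogram(as.data.frame(b))
  edges <- sort(union(a$bin_lower, b$bin_lower))
  list(pad_histogram(a, edges), pad_histogram(b, edges))
}
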