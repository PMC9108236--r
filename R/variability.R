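# Observer-variability experiment logic and summary statistics: pairing
# schemes, mean/SD tables, pooled comparisons, group tests, histograms and
# the margin-coverage readout.
#
# The package ships the printed DICE / average-Hausdorff reference values of
# the clinical validation study (five patients, two observers, three repeat
# registrations each; seven patients for the target-volume comparisons) as
# CSV fixtures, so every summary statistic can be recomputed from them.

#' Load a packaged clinical reference table
#'
#' @param which One of `"intra"` (intra-observer variability: patient,
#'   observer, repeat pair, DICE, H-AVE), `"inter"` (inter-observer:
#'   patient, repeat of each observer, DICE, H-AVE) or `"ptv_dice"`
#'   (pairwise DICE of the planning target volumes built by the competing
#'   workflows).
#' @return A data.frame.
#' @export
clinical_reference_table <- function(which = c("intra", "inter", "ptv_dice")) {
  which <- match.arg(which)
  f <- c(intra = "intra_observer_variability.csv",
         inter = "inter_observer_variability.csv",
         ptv_dice = "ptv_dice_comparisons.csv")[[which]]
  path <- system.file("extdata", f, package = "gdmrt", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (which == "ptv_dice")
    df$row <- paste(df$vol_a, "vs", df$vol_b)
  df
}

#' Intra-observer comparison pairs
#'
#' For one patient and one observer with exactly three repeat registrations,
#' the three unordered repeat pairs \{(1,2), (1,3), (2,3)\}; across both
#' observers this yields the six intra-observer measurements per patient.
#'
#' @param repeats Integer vector of repeat identifiers (must be exactly
#'   three distinct values).
#' @return Two-column data.frame (`repeat_a`, `repeat_b`), three rows.
#' @export
enumerate_intra_pairs <- function(repeats = 1:3) {
  repeats <- sort(unique(as.integer(repeats)))
  if (length(repeats) != 3L)
    stop(sprintf("exactly 3 repeats are required for intra-observer pairing (got %d)",
                 length(repeats)))
  cb <- t(utils::combn(repeats, 2))
  data.frame(repeat_a = cb[, 1], repeat_b = cb[, 2])
}

#' Inter-observer comparison pairs
#'
#' All 3 x 3 cross-observer repeat pairs for one patient: nine measurements
#' per patient; forty-five over a five-patient cohort.
#'
#' @param repeats_obs1,repeats_obs2 Integer vectors of repeat identifiers,
#'   exactly three each.
#' @return Two-column data.frame (`repeat_obs1`, `repeat_obs2`), nine rows.
#' @export
enumerate_inter_pairs <- function(repeats_obs1 = 1:3, repeats_obs2 = 1:3) {
  r1 <- sort(unique(as.integer(repeats_obs1)))
  r2 <- sort(unique(as.integer(repeats_obs2)))
  if (length(r1) != 3L || length(r2) != 3L)
    stop(sprintf("both observers need exactly 3 repeats (got %d and %d)",
                 length(r1), length(r2)))
  expand.grid(repeat_obs1 = r1, repeat_obs2 = r2, KEEP.OUT.ATTRS = FALSE)
}

#' Summarize comparison records by group
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of a
#' metric per group, with the display rounding the tables use: DICE to two
#' decimals, H-AVE to one. Unrounded values are retained. Groups of size one
#' get `NA` for the SD.
#'
#' @param records Data.frame of comparison values.
#' @param value Name of the metric column (`"dice"` or `"h_ave_mm"`).
#' @param by Character vector of grouping columns; `NULL` summarizes all
#'   records as one group.
#' @return An object of class `summary_table`: a data.frame with columns
#'   `n`, `mean`, `sd`, `mean_display`, `sd_display` (plus the grouping
#'   columns), and attributes `grand_mean` / `grand_mean_display` holding the
#'   pooled mean over all records.
#' @export
summarize_records <- function(records, value = "dice", by = NULL) {
  if (!value %in% names(records))
    stop(sprintf("no column '%s' in records", value))
  v <- records[[value]]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("at least 2 records are required to summarize")
  digits <- if (value == "dice") 2L else 1L
  groups <- if (is.null(by)) list(all = records)
            else split(records, records[by], drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]][[value]]
    x <- x[!is.na(x)]
    data.frame(group = g, n = length(x), mean = mean(x),
               sd = if (length(x) >= 2L) sd(x) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out$mean_display <- round(out$mean, digits)
  out$sd_display <- round(out$sd, if (value == "dice") 3L else digits)
  attr(out, "grand_mean") <- mean(v)
  attr(out, "grand_mean_display") <- round(mean(v), digits)
  attr(out, "value") <- value
  class(out) <- c("summary_table", class(out))
  out
}

#' Pooled mean and SD over selected records
#'
#' Pools all individual values of the selected rows (not a mean of row
#' means), as used when contrasting groups of comparison types.
#'
#' @param records Data.frame of comparison values.
#' @param select Logical vector (or predicate function taking the data.frame
#'   and returning one) choosing the rows to pool; default all.
#' @param value Metric column name.
#' @return List with `mean`, `sd`, `n`.
#' @export
pooled_mean <- function(records, select = NULL, value = "dice") {
  keep <- if (is.null(select)) rep(TRUE, nrow(records))
          else if (is.function(select)) select(records)
          else as.logical(select)
  x <- records[[value]][keep]
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty selection: nothing to pool")
  list(mean = mean(x), sd = if (length(x) >= 2L) sd(x) else NA_real_,
       n = length(x))
}

#' Two-group test on metric values
#'
#' Two-sided t test at the conventional 5% significance level: Welch's
#' unequal-variance test for independent groups of possibly different size,
#' or a paired test for matched designs.
#'
#' @param values_a,values_b Numeric vectors (equal length required for
#'   `mode = "paired"`).
#' @param mode `"welch"` or `"paired"`.
#' @return List with `statistic`, `p_value`, `significant` (at 0.05),
#'   `mode`, `alpha`.
#' @export
group_test <- function(values_a, values_b, mode = c("welch", "paired")) {
  mode <- match.arg(mode)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("both groups need at least 2 values")
  if (mode == "paired" && length(values_a) != length(values_b))
    stop("paired mode requires equal-length groups")
  # degenerate zero-variance case (e.g. identical groups): no evidence of a
  # difference, p = 1 by convention
  degenerate <- if (mode == "paired") sd(values_a - values_b) == 0
                else sd(values_a) == 0 && sd(values_b) == 0
  if (degenerate && isTRUE(all.equal(mean(values_a), mean(values_b))))
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                mode = mode, alpha = 0.05))
  ht <- if (mode == "paired") t.test(values_a, values_b, paired = TRUE)
        else t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < 0.05, mode = mode, alpha = 0.05)
}

#' Margin covering a fraction of observed surface distances
#'
#' The smallest observed value m such that at least the requested fraction
#' of the average-Hausdorff values are <= m (inclusive empirical quantile).
#' Reading this off the pooled observer-variability distances gives the
#' isotropic ITV-to-PTV margin that covers registration observer
#' variability.
#'
#' @param h_ave_values Non-empty numeric vector of distances (mm).
#' @param coverage_fraction Fraction in (0, 1]; default 0.95.
#' @return Margin in mm.
#' @examples
#' margin_for_coverage(c(1, 2, 3), 2 / 3)  # 2
#' @export
margin_for_coverage <- function(h_ave_values, coverage_fraction = 0.95) {
  x <- sort(h_ave_values[!is.na(h_ave_values)])
  if (length(x) == 0L) stop("no values supplied")
  if (!is.finite(coverage_fraction) || coverage_fraction <= 0 ||
      coverage_fraction > 1)
    stop("coverage_fraction must be in (0, 1]")
  x[ceiling(coverage_fraction * length(x))]
}

#' Histogram report of comparison metrics
#'
#' Differential or cumulative counts with the fixed bin widths used in the
#' study figures: 0.05 for DICE, 0.25 mm for H-AVE. Counts of the
#' differential histogram sum to the record count; the cumulative histogram
#' is monotone non-decreasing. Optionally writes a bar plot to an image
#' file.
#'
#' @param values Numeric vector of metric values.
#' @param metric `"dice"` or `"h_ave"` (sets the bin width).
#' @param kind `"differential"` or `"cumulative"`.
#' @param plot_file Optional path of a PNG to write.
#' @return Data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
histogram_report <- function(values, metric = c("dice", "h_ave"),
                             kind = c("differential", "cumulative"),
                             plot_file = NULL) {
  metric <- match.arg(metric)
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values supplied")
  w <- if (metric == "dice") 0.05 else 0.25
  lo <- floor(min(values) / w) * w
  hi <- ceiling(max(values) / w) * w
  if (hi <= lo) hi <- lo + w
  breaks <- seq(lo, hi, by = w)
  # right-closed bins; the lowest break is included in the first bin
  cnt <- tabulate(findInterval(values, breaks, left.open = TRUE,
                               rightmost.closed = TRUE) + (values <= lo),
                  nbins = length(breaks) - 1L)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    count = if (kind == "cumulative") cumsum(cnt) else cnt)
  if (!is.null(plot_file)) {
    png(plot_file, width = 720, height = 480)
    barplot(out$count,
            names.arg = sprintf("%.2f", out$bin_hi),
            xlab = if (metric == "dice") "DICE" else "H-AVE [mm]",
            ylab = if (kind == "cumulative") "cumulative count" else "count",
            main = sprintf("%s histogram (%s)", kind, metric),
            col = "steelblue")
    dev.off()
  }
  out
}
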