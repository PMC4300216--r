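# Down-core reconstruction versus instrumental series: interval averaging,
# smoothing, trend, two-sample / paired tests, variance attenuation, and
# regression-based extension of short station records.
#
# The mean tests default to Welch's unequal-variance t (interval-averaged
# reconstructions are far less variable than annual instrumental data, so
# pooling variances is not defensible); a switch restores pooled Student's.
# All p-values are two-sided; the variance F-test doubles the smaller tail.

#' Construct an instrumental series
#'
#' Annual values of one climate variable over a contiguous year range.
#'
#' @param variable variable name (e.g. `"feb_mean_temp"`).
#' @param years contiguous integer years AD.
#' @param values numeric values (degrees C), one per year, no gaps.
#' @return an object of class `instrumental_series`.
#' @export
instrumental_series <- function(variable, years, values) {
  years <- as.integer(years)
  if (length(years) != length(values)) stop("one value per year required")
  if (anyNA(values)) stop("gaps (NA) in instrumental series")
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be contiguous")
  structure(list(variable = variable, years = years,
                 values = as.numeric(values)),
            class = "instrumental_series")
}

#' Read an instrumental series from CSV (columns `year`, `value`)
#' @param path file path.
#' @param variable variable name recorded on the series.
#' @return an [instrumental_series()].
#' @export
read_instrumental_series <- function(path, variable = "temperature") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("year", "value") %in% names(df)))
    stop("expected columns year, value")
  df <- df[order(df$year), ]
  instrumental_series(variable, df$year, df$value)
}

#' Extract an instrumental series from a synthetic climate history
#'
#' @param hist a [climate_history()].
#' @param variable one of the history's variables.
#' @param start,end year range AD (inclusive).
#' @return an [instrumental_series()] of the history's annual values
#'   (noise included).
#' @export
history_to_instrumental <- function(hist, variable, start = 1820,
                                    end = max(hist$years)) {
  sel <- hist$years >= start & hist$years <= end
  if (!any(sel)) stop("no history years in range")
  instrumental_series(variable, hist$years[sel], hist$values[sel, variable])
}

#' Construct a reconstruction series
#'
#' Down-core reconstructed climate values on varve-year age intervals.
#'
#' @param start_year,end_year integer interval bounds (inclusive), ordered
#'   and non-overlapping.
#' @param value reconstructed values, degrees C.
#' @param label provenance label (calibration set / variable / model).
#' @return an object of class `reconstruction_series` (a data.frame).
#' @export
reconstruction_series <- function(start_year, end_year, value, label = "") {
  if (any(end_year < start_year)) stop("end_year before start_year")
  if (length(start_year) > 1 &&
      any(start_year[-1] <= end_year[-length(end_year)]))
    stop("intervals must be ordered and non-overlapping")
  out <- data.frame(start_year = as.integer(start_year),
                    end_year = as.integer(end_year),
                    value = as.numeric(value))
  attr(out, "label") <- label
  class(out) <- c("reconstruction_series", "data.frame")
  out
}

#' Reconstruct a fossil record with a transfer function
#'
#' Convenience wrapper: predicts every down-core sample and returns the
#' ages + values as a [reconstruction_series()].
#'
#' @param tf a [fit_wapls()] model.
#' @param fossil a [fossil_record()].
#' @return a `reconstruction_series`.
#' @export
reconstruct <- function(tf, fossil) {
  stopifnot(inherits(fossil, "fossil_record"))
  pred <- predict(tf, fossil$samples)
  reconstruction_series(fossil$intervals$start_year,
                        fossil$intervals$end_year, pred,
                        label = tf$variable)
}

#' Average an instrumental series onto reconstruction intervals
#'
#' For each reconstruction sample whose age interval lies fully inside the
#' instrumental range, takes the unweighted mean of the annual values over
#' `[start_year, end_year]` inclusive -- i.e. the instrumental record is
#' cumulatively averaged exactly as the pollen samples were according to
#' the varve counts. Partially overlapping samples are dropped (message).
#'
#' @param series an [instrumental_series()].
#' @param rec a [reconstruction_series()].
#' @return data.frame with `start_year`, `end_year`, `reconstruction`,
#'   `instrumental` (the paired interval means).
#' @export
align_to_intervals <- function(series, rec) {
  stopifnot(inherits(series, "instrumental_series"))
  lo <- min(series$years)
  hi <- max(series$years)
  full <- rec$start_year >= lo & rec$end_year <= hi
  partial <- !full & rec$end_year >= lo & rec$start_year <= hi
  if (any(partial))
    message(sum(partial), " sample(s) only partially covered; dropped")
  if (!any(full)) stop("no reconstruction samples inside the series range")
  means <- mapply(function(s, e)
    mean(series$values[series$years >= s & series$years <= e]),
    rec$start_year[full], rec$end_year[full])
  data.frame(start_year = rec$start_year[full],
             end_year = rec$end_year[full],
             reconstruction = rec$value[full],
             instrumental = means)
}

comparison_report <- function(test, statistic, df, p_value, estimate = NULL,
                              sds = NULL, n = NULL) {
  structure(list(test = test, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimate = estimate, sds = sds, n = n),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", d.f. = ", paste(format(x$df, digits = 5), collapse = ","),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Two-sample t-test on the means
#'
#' Welch's unequal-variance t by default (the reconstruction and
#' instrumental groups have very different variances); set
#' `var_equal = TRUE` for pooled Student's t. Two-sided.
#'
#' @param a,b numeric value vectors (n >= 2 each).
#' @param var_equal pool the variances (classic Student's t)?
#' @return a `comparison_report` (statistic, d.f. -- fractional for Welch
#'   -- p-value, group means/sds/sizes).
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in both groups")
  ht <- stats::t.test(a, b, var.equal = var_equal)
  comparison_report(if (var_equal) "Student t (pooled)" else "Welch t",
                    ht$statistic, ht$parameter, ht$p.value,
                    estimate = c(mean_a = mean(a), mean_b = mean(b)),
                    sds = c(sd_a = stats::sd(a), sd_b = stats::sd(b)),
                    n = c(length(a), length(b)))
}

#' Two-sided F-test on the variances
#'
#' `F = var(a) / var(b)` on `(n_a - 1, n_b - 1)` degrees of freedom;
#' two-sided p by doubling the smaller tail.
#'
#' @param a,b numeric value vectors (n >= 2 each).
#' @return a `comparison_report`.
#' @export
variance_f_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 in both groups")
  if (stats::var(b) == 0) stop("zero variance in second group")
  ht <- stats::var.test(a, b)
  comparison_report("variance F", ht$statistic,
                    c(ht$parameter[["num df"]], ht$parameter[["denom df"]]),
                    ht$p.value,
                    sds = c(sd_a = stats::sd(a), sd_b = stats::sd(b)),
                    n = c(length(a), length(b)))
}

#' F-test on the variances from summary statistics
#'
#' For recomputing published variance comparisons from reported standard
#' deviations alone: `F = sd_a^2 / sd_b^2` on `(df_a, df_b)` degrees of
#' freedom, two-sided p by doubling the smaller tail.
#'
#' @param sd_a,sd_b group standard deviations (> 0 for `sd_b`).
#' @param df_a,df_b degrees of freedom (group size minus 1).
#' @return a `comparison_report`.
#' @export
variance_f_test_summary <- function(sd_a, sd_b, df_a, df_b) {
  if (sd_b <= 0) stop("sd_b must be > 0")
  f <- sd_a^2 / sd_b^2
  tail <- stats::pf(f, df_a, df_b)
  p <- min(1, 2 * min(tail, 1 - tail))
  comparison_report("variance F (summary)", f, c(df_a, df_b), p,
                    sds = c(sd_a = sd_a, sd_b = sd_b))
}

#' Paired t-test on differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided.
#'
#' @param diffs numeric vector of paired differences (n >= 2).
#' @return a `comparison_report`.
#' @export
paired_t_test <- function(diffs) {
  if (length(diffs) < 2) stop("need n >= 2 differences")
  n <- length(diffs)
  if (stats::sd(diffs) == 0) {
    # degenerate: identical differences; t is 0 (no difference) or infinite
    stat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    return(comparison_report("paired t", stat, n - 1,
                             if (mean(diffs) == 0) 1 else 0,
                             estimate = c(mean_diff = mean(diffs)), n = n))
  }
  ht <- stats::t.test(diffs)
  comparison_report("paired t", ht$statistic, ht$parameter, ht$p.value,
                    estimate = c(mean_diff = mean(diffs)),
                    n = length(diffs))
}

#' Ordinary least squares trend of an instrumental series
#'
#' Regresses value on year and reports the slope, the total change over
#' the record (`slope * (span - 1)` years for a contiguous annual series),
#' and the slope t-test on `n - 2` degrees of freedom.
#'
#' @param series an [instrumental_series()] (n >= 3).
#' @return list: `slope` (degC/yr), `total_change` (degC over the record),
#'   `t`, `df`, `p_value`, `n`.
#' @export
ols_trend <- function(series) {
  stopifnot(inherits(series, "instrumental_series"))
  n <- length(series$years)
  if (n < 3) stop("need n >= 3 years")
  fit <- stats::lm(series$values ~ series$years)
  sm <- stats::summary.lm(fit)$coefficients
  slope <- sm[2, 1]
  se <- sm[2, 2]
  if (se == 0) {  # exact linear series: infinite t, zero p
    tt <- sign(slope) * Inf
    p <- 0
  } else {
    tt <- sm[2, 3]
    p <- sm[2, 4]
  }
  list(slope = slope, total_change = slope * (n - 1),
       t = tt, df = n - 2, p_value = p, n = n)
}

#' Centered moving average
#'
#' Mean over an odd centered window; at the ends the window is truncated
#' to the available points (so the output has the input's length).
#'
#' @param values numeric vector.
#' @param window odd window width (default 5).
#' @return smoothed numeric vector.
#' @export
moving_average <- function(values, window = 5) {
  if (window %% 2 == 0) stop("window must be odd")
  half <- (window - 1) / 2
  n <- length(values)
  vapply(seq_len(n), function(i)
    mean(values[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Period mean of a reconstruction
#'
#' Unweighted mean of the sample values whose interval midpoint lies in
#' `[start, end]`.
#'
#' @param rec a [reconstruction_series()].
#' @param start,end calendar year range AD (inclusive, by midpoint).
#' @return mean reconstructed value, degrees C.
#' @export
period_mean <- function(rec, start, end) {
  mid <- (rec$start_year + rec$end_year) / 2
  sel <- mid >= start & mid <= end
  if (!any(sel)) stop("no samples with midpoint in [", start, ", ", end, "]")
  mean(rec$value[sel])
}

#' Fraction of instrumental variance captured by a reconstruction
#'
#' `100 * var(reconstruction) / var(instrumental)` over interval-aligned
#' pairs (see [align_to_intervals()]): a direct measure of variance
#' attenuation. 100 means the reconstruction is as variable as the
#' aligned instrumental record; interval-averaged pollen reconstructions
#' typically fall far below that.
#'
#' @param rec_aligned,instr_aligned aligned value vectors of equal length.
#' @return percentage of variance captured.
#' @export
variance_captured <- function(rec_aligned, instr_aligned) {
  if (length(rec_aligned) != length(instr_aligned))
    stop("aligned vectors differ in length")
  v <- stats::var(instr_aligned)
  if (v == 0) stop("zero instrumental variance")
  100 * stats::var(rec_aligned) / v
}

#' Extend a short station record by regression on a longer reference
#'
#' Ordinary least squares of the target station on the reference station
#' over their overlapping years; years missing from the target (within
#' the reference range) are filled with fitted values, observed target
#' years are kept verbatim. The classic splice for building an "extended"
#' station record from a nearby long record.
#'
#' @param target_partial [instrumental_series()] to be extended.
#' @param reference_full [instrumental_series()] covering the gap years.
#' @param min_overlap minimum overlapping years (default 10).
#' @return an `instrumental_series` spanning the union of both records,
#'   with attributes `r2_adj` (adjusted R-squared of the overlap
#'   regression) and `filled_years`.
#' @export
extend_series_by_regression <- function(target_partial, reference_full,
                                        min_overlap = 10) {
  stopifnot(inherits(target_partial, "instrumental_series"),
            inherits(reference_full, "instrumental_series"))
  overlap <- intersect(target_partial$years, reference_full$years)
  if (length(overlap) < min_overlap)
    stop("need >= ", min_overlap, " overlapping years; have ",
         length(overlap))
  ty <- target_partial$values[match(overlap, target_partial$years)]
  ry <- reference_full$values[match(overlap, reference_full$years)]
  fit <- stats::lm(ty ~ ry)
  r2_adj <- stats::summary.lm(fit)$adj.r.squared
  all_years <- min(target_partial$years[1], reference_full$years[1]):
    max(target_partial$years[length(target_partial$years)],
        reference_full$years[length(reference_full$years)])
  vals <- rep(NA_real_, length(all_years))
  # fill from reference regression, then overwrite with observed target
  in_ref <- all_years %in% reference_full$years
  vals[in_ref] <- stats::coef(fit)[1] + stats::coef(fit)[2] *
    reference_full$values[match(all_years[in_ref], reference_full$years)]
  in_tgt <- all_years %in% target_partial$years
  vals[in_tgt] <- target_partial$values[match(all_years[in_tgt],
                                              target_partial$years)]
  if (anyNA(vals))
    stop("reference does not cover all gap years; extended series would have gaps")
  out <- instrumental_series(target_partial$variable, all_years, vals)
  attr(out, "r2_adj") <- r2_adj
  attr(out, "filled_years") <- all_years[!in_tgt]
  out
}
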