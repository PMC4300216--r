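# Tabular containers and CSV interchange for the pipeline.
#
# All pollen data travel as a `pollen_matrix`: a numeric sites/samples x taxa
# matrix tagged as raw counts (grains) or as percentages whose rows sum to
# 100. Calibration sets pair a percent matrix with a per-site climate table;
# fossil records pair one with varve-year age intervals.

PERCENT_TOL_INPUT <- 0.5     # rounded legacy files: renormalize with warning
PERCENT_TOL_INTERNAL <- 1e-6 # after internal operations

#' Construct a pollen matrix
#'
#' @param values numeric matrix, sites/samples in rows, taxa in columns.
#' @param ids character vector of site or sample identifiers (row names).
#' @param taxa character vector of taxon names (column names).
#' @param kind `"counts"` (pollen grains) or `"percent"` (rows sum to 100).
#' @param tol row-sum tolerance accepted for percent matrices; rows within
#'   `tol` of 100 are renormalized exactly (a warning is issued if any row
#'   was off by more than [PERCENT_TOL_INTERNAL]).
#' @return an object of class `pollen_matrix`: a list with elements
#'   `values` (named matrix) and `kind`.
#' @export
pollen_matrix <- function(values, ids = rownames(values),
                          taxa = colnames(values),
                          kind = c("counts", "percent"),
                          tol = PERCENT_TOL_INPUT) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(taxa)) stop("taxon names are required")
  ids <- as.character(ids)
  taxa <- as.character(taxa)
  if (length(ids) != nrow(values)) stop("one id per row required")
  if (length(taxa) != ncol(values)) stop("one taxon name per column required")
  if (anyDuplicated(taxa)) stop("duplicate taxon names: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (anyNA(values)) stop("missing values in pollen matrix")
  if (any(values < 0)) stop("negative pollen values")
  dimnames(values) <- list(ids, taxa)
  if (kind == "percent") {
    rs <- rowSums(values)
    off <- abs(rs - 100)
    if (any(off > tol)) {
      bad <- ids[off > tol]
      stop("percent rows must sum to 100 (+/- ", tol, "); offending: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (any(off > PERCENT_TOL_INTERNAL)) {
      warning("renormalizing ", sum(off > PERCENT_TOL_INTERNAL),
              " percent row(s) within the +/- ", tol, " input tolerance")
      values <- values / rs * 100
    }
  }
  structure(list(values = values, kind = kind), class = "pollen_matrix")
}

#' @export
print.pollen_matrix <- function(x, ...) {
  cat("pollen_matrix (", x$kind, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " taxa\n", sep = "")
  invisible(x)
}

#' @export
dim.pollen_matrix <- function(x) dim(x$values)

pm_ids <- function(m) rownames(m$values)
pm_taxa <- function(m) colnames(m$values)

#' Read a pollen matrix from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row of taxon names,
#' a first column named `id` holding site/sample identifiers, and a numeric
#' body. Percent matrices are validated to row sums of 100 within `tol`.
#'
#' @param path file path.
#' @inheritParams pollen_matrix
#' @return a [pollen_matrix()].
#' @export
read_pollen_matrix <- function(path, kind = c("counts", "percent"),
                               tol = PERCENT_TOL_INPUT) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an id column plus at least one taxon")
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  num <- vapply(body, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric pollen values in column(s): ",
                      paste(names(body)[!num], collapse = ", "))
  pollen_matrix(as.matrix(body), ids = ids, taxa = names(body),
                kind = kind, tol = tol)
}

#' Write a pollen matrix to CSV
#'
#' Inverse of [read_pollen_matrix()]; round-trips losslessly (values printed
#' at full double precision).
#'
#' @param m a [pollen_matrix()].
#' @param path file path.
#' @export
write_pollen_matrix <- function(m, path) {
  stopifnot(inherits(m, "pollen_matrix"))
  df <- data.frame(id = pm_ids(m), m$values, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert pollen counts to percentages
#'
#' @param m a counts [pollen_matrix()]; every row sum must be positive.
#' @return a percent `pollen_matrix` whose rows sum to exactly 100.
#' @export
to_percentages <- function(m) {
  stopifnot(inherits(m, "pollen_matrix"))
  if (m$kind != "counts") stop("input must be a counts matrix")
  rs <- rowSums(m$values)
  if (any(rs <= 0)) {
    stop("sample(s) with zero pollen sum: ",
         paste(utils::head(pm_ids(m)[rs <= 0], 5), collapse = ", "))
  }
  pollen_matrix(m$values / rs * 100, kind = "percent",
                tol = PERCENT_TOL_INTERNAL)
}

#' Harmonize the taxonomies of two pollen matrices
#'
#' Expands both matrices to the union of their taxon lists (absent taxa
#' filled with exact zeros) so that one dataset's transfer function can be
#' applied to another dataset's pollen. Matching is exact after trimming
#' whitespace and case-folding; no synonym resolution is attempted.
#'
#' @param a,b [pollen_matrix()] objects.
#' @return a list with elements `a` and `b`, sharing identical taxon order.
#' @export
harmonize_taxa <- function(a, b) {
  stopifnot(inherits(a, "pollen_matrix"), inherits(b, "pollen_matrix"))
  norm <- function(x) tolower(trimws(x))
  for (m in list(a, b)) {
    if (anyDuplicated(norm(pm_taxa(m)))) {
      k <- norm(pm_taxa(m))
      stop("taxa duplicated after case-normalization: ",
           paste(unique(k[duplicated(k)]), collapse = ", "))
    }
  }
  # union keyed on normalized names; display name from first occurrence
  keys <- c(norm(pm_taxa(a)), norm(pm_taxa(b)))
  disp <- c(pm_taxa(a), pm_taxa(b))
  u <- !duplicated(keys)
  union_keys <- keys[u]
  union_disp <- disp[u]
  expand <- function(m) {
    out <- matrix(0, nrow(m$values), length(union_keys),
                  dimnames = list(pm_ids(m), union_disp))
    out[, match(norm(pm_taxa(m)), union_keys)] <- m$values
    pollen_matrix(out, kind = m$kind, tol = PERCENT_TOL_INTERNAL)
  }
  list(a = expand(a), b = expand(b))
}

#' Exclude taxa and renormalize to 100
#'
#' Drops the named columns from a percent matrix and rescales every row to
#' sum to 100 again: the standard sensitivity transform for removing
#' disturbance-indicator taxa (e.g. Ambrosia, Poaceae) from an analysis.
#'
#' @param m percent [pollen_matrix()].
#' @param taxa character vector of taxon names to drop (must all be present).
#' @return percent `pollen_matrix` without the named taxa.
#' @export
exclude_taxa_renormalize <- function(m, taxa) {
  stopifnot(inherits(m, "pollen_matrix"))
  if (m$kind != "percent") stop("input must be a percent matrix")
  missing <- setdiff(taxa, pm_taxa(m))
  if (length(missing)) stop("taxa not present: ", paste(missing, collapse = ", "))
  keep <- !(pm_taxa(m) %in% taxa)
  vals <- m$values[, keep, drop = FALSE]
  rs <- rowSums(vals)
  if (any(rs <= 0)) {
    stop("row(s) consisting entirely of excluded taxa: ",
         paste(utils::head(pm_ids(m)[rs <= 0], 5), collapse = ", "))
  }
  pollen_matrix(vals / rs * 100, kind = "percent", tol = PERCENT_TOL_INTERNAL)
}

#' Construct a climate table
#'
#' Per-site values of one or more climate variables (monthly mean
#' temperatures, degrees C) under a stated normal period.
#'
#' @param site_ids character identifiers, aligned with a pollen matrix.
#' @param ... named numeric vectors, one per climate variable
#'   (e.g. `feb_mean_temp`, `may_mean_temp`).
#' @param normal_period optional length-2 integer year range, e.g.
#'   `c(1895, 1924)`.
#' @return a `climate_table` (a data.frame with an `id` column).
#' @export
climate_table <- function(site_ids, ..., normal_period = NULL) {
  vars <- list(...)
  if (!length(vars) || is.null(names(vars)) || any(!nzchar(names(vars))))
    stop("climate variables must be named")
  n <- length(site_ids)
  for (v in names(vars)) {
    if (length(vars[[v]]) != n) stop("variable ", v, " length != number of sites")
    if (anyNA(vars[[v]])) stop("missing values in climate variable ", v)
  }
  out <- data.frame(id = as.character(site_ids), vars,
                    check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "normal_period") <- normal_period
  class(out) <- c("climate_table", "data.frame")
  out
}

#' Read a climate table from CSV
#'
#' @param path CSV with an `id` first column and numeric variable columns.
#' @param normal_period optional length-2 year range recorded on the table.
#' @return a [climate_table()].
#' @export
read_climate_table <- function(path, normal_period = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "id") stop("first column must be named 'id'")
  vars <- df[, -1, drop = FALSE]
  do.call(climate_table,
          c(list(site_ids = df$id), as.list(vars),
            list(normal_period = normal_period)))
}

#' Write a climate table to CSV
#' @param cl a [climate_table()].
#' @param path file path.
#' @export
write_climate_table <- function(cl, path) {
  utils::write.csv(format(as.data.frame(cl), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a calibration set
#'
#' The training object for a transfer function: a percent pollen matrix
#' paired site-for-site with observed climate values.
#'
#' @param pollen percent [pollen_matrix()].
#' @param climate [climate_table()] with identical site ordering.
#' @param label free-text provenance label (e.g. `"1870"`, `"modern"`).
#' @return an object of class `calibration_set`.
#' @export
calibration_set <- function(pollen, climate, label = "") {
  stopifnot(inherits(pollen, "pollen_matrix"), inherits(climate, "climate_table"))
  if (pollen$kind != "percent") stop("calibration pollen must be percentages")
  if (!identical(pm_ids(pollen), climate$id))
    stop("pollen and climate site ids must match in order")
  structure(list(pollen = pollen, climate = climate, label = label),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  vars <- setdiff(names(x$climate), "id")
  cat("calibration_set '", x$label, "': ", nrow(x$pollen$values), " sites, ",
      ncol(x$pollen$values), " taxa; climate: ",
      paste(vars, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_sites <- function(cal) nrow(cal$pollen$values)

#' Subset a calibration set by site index
#'
#' Used by the resampling cross-validators; duplicated indices are allowed
#' (bootstrap resamples).
#'
#' @param cal a [calibration_set()].
#' @param idx integer site indices.
#' @return a `calibration_set` with the selected sites.
#' @export
cal_subset <- function(cal, idx) {
  vals <- cal$pollen$values[idx, , drop = FALSE]
  rownames(vals) <- make.unique(rownames(vals))
  cl <- cal$climate[idx, , drop = FALSE]
  cl$id <- rownames(vals)
  attr(cl, "normal_period") <- attr(cal$climate, "normal_period")
  class(cl) <- class(cal$climate)
  calibration_set(pollen_matrix(vals, kind = "percent",
                                tol = PERCENT_TOL_INPUT),
                  cl, label = cal$label)
}

#' Construct a fossil record
#'
#' Down-core pollen samples with varve-year age intervals, calendar years
#' AD, inclusive on both ends (a four-year sample "AD 1820-1823" covers the
#' four instrumental years 1820, 1821, 1822, 1823).
#'
#' @param samples percent [pollen_matrix()], one row per core sample.
#' @param intervals data.frame with integer columns `start_year`, `end_year`;
#'   intervals must be ordered, non-overlapping, with
#'   `end_year >= start_year`.
#' @return an object of class `fossil_record`.
#' @export
fossil_record <- function(samples, intervals) {
  stopifnot(inherits(samples, "pollen_matrix"))
  if (samples$kind != "percent") stop("fossil samples must be percentages")
  intervals <- as.data.frame(intervals)
  if (!all(c("start_year", "end_year") %in% names(intervals)))
    stop("intervals need start_year and end_year columns")
  if (nrow(intervals) != nrow(samples$values))
    stop("one interval per sample required")
  if (any(intervals$end_year < intervals$start_year))
    stop("interval end_year before start_year")
  if (nrow(intervals) > 1) {
    if (any(diff(intervals$start_year) <= 0) ||
        any(intervals$start_year[-1] <= intervals$end_year[-nrow(intervals)]))
      stop("intervals must be ordered and non-overlapping")
  }
  structure(list(samples = samples,
                 intervals = intervals[, c("start_year", "end_year")]),
            class = "fossil_record")
}

#' @export
print.fossil_record <- function(x, ...) {
  iv <- x$intervals
  cat("fossil_record: ", nrow(iv), " samples, AD ", min(iv$start_year), "-",
      max(iv$end_year), ", ", ncol(x$samples$values), " taxa\n", sep = "")
  invisible(x)
}

interval_midpoints <- function(rec) {
  (rec$intervals$start_year + rec$intervals$end_year) / 2
}

#' Read a fossil record from CSV
#'
#' Layout: columns `id`, `start_year`, `end_year`, then one column per taxon.
#'
#' @param path file path.
#' @inheritParams pollen_matrix
#' @return a [fossil_record()].
#' @export
read_fossil_record <- function(path, tol = PERCENT_TOL_INPUT) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "start_year", "end_year")
  if (!all(need %in% names(df)[1:3]))
    stop("first three columns must be id, start_year, end_year")
  body <- df[, -(1:3), drop = FALSE]
  pm <- pollen_matrix(as.matrix(body), ids = df$id, taxa = names(body),
                      kind = "percent", tol = tol)
  fossil_record(pm, df[, c("start_year", "end_year")])
}

#' Write a fossil record to CSV
#' @param rec a [fossil_record()].
#' @param path file path.
#' @export
write_fossil_record <- function(rec, path) {
  df <- data.frame(id = pm_ids(rec$samples),
                   start_year = rec$intervals$start_year,
                   end_year = rec$intervals$end_year,
                   rec$samples$values, check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
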