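# Modern analog assessment with the squared chord distance.
#
# d(p, q) = sum_k (sqrt(p_k) - sqrt(q_k))^2, the standard pollen
# dissimilarity. On the percent scale (rows summing to 100) it ranges from
# 0 (identical assemblages) to 200 (fully disjoint). Note squared chord is
# symmetric and zero only at identity but does not satisfy the triangle
# inequality, so it is a dissimilarity, not a metric.

#' Squared chord distance between two assemblages
#'
#' @param p,q non-negative abundance vectors in identical taxon order
#'   (percent scale by convention; see `scale` in [min_analog_series()]).
#' @return the dissimilarity `sum((sqrt(p) - sqrt(q))^2)`.
#' @export
squared_chord_distance <- function(p, q) {
  if (length(p) != length(q)) stop("vectors differ in length")
  if (any(p < 0) || any(q < 0)) stop("negative abundances")
  sum((sqrt(p) - sqrt(q))^2)
}

#' Minimum squared chord distance from fossil samples to a calibration set
#'
#' For every fossil sample, finds the nearest calibration site under the
#' squared chord distance: the classic screen for whether a calibration
#' set contains adequate modern analogs for a sedimentary record. Taxa are
#' matched by name (harmonize beforehand with [harmonize_taxa()] if the
#' lists differ); ties are broken by first site in file order.
#'
#' @param fossil a [fossil_record()] (or percent [pollen_matrix()]).
#' @param cal a [calibration_set()].
#' @param scale `"percent"` (default; distances comparable across studies
#'   reporting on the 0-200 percent scale) or `"proportion"` (values 100x
#'   smaller).
#' @return an object of class `analog_result`: data.frame with columns
#'   `sample_id`, `start_year`, `end_year` (NA when `fossil` is a bare
#'   matrix), `min_distance`, `nearest_site`.
#' @export
min_analog_series <- function(fossil, cal, scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cal, "calibration_set"))
  if (inherits(fossil, "fossil_record")) {
    fm <- fossil$samples
    iv <- fossil$intervals
  } else {
    fm <- fossil
    iv <- data.frame(start_year = rep(NA_integer_, nrow(fm$values)),
                     end_year = NA_integer_)
  }
  if (n_sites(cal) == 0) stop("empty calibration set")
  h <- harmonize_taxa(fm, cal$pollen)
  f <- h$a$values
  g <- h$b$values
  if (scale == "proportion") {
    f <- f / 100
    g <- g / 100
  }
  sf <- sqrt(f)
  sg <- sqrt(g)
  # d(i,j) = |sf_i|^2 + |sg_j|^2 - 2 sf_i . sg_j
  d <- outer(rowSums(sf^2), rowSums(sg^2), `+`) - 2 * tcrossprod(sf, sg)
  d[d < 0] <- 0  # numerical guard
  nearest <- apply(d, 1, which.min)  # which.min takes the first on ties
  ties <- apply(d, 1, function(r) sum(abs(r - min(r)) < 1e-12) > 1)
  if (any(ties))
    message(sum(ties), " sample(s) with tied nearest analogs; first site kept")
  out <- data.frame(sample_id = rownames(f),
                    start_year = iv$start_year, end_year = iv$end_year,
                    min_distance = d[cbind(seq_len(nrow(d)), nearest)],
                    nearest_site = rownames(g)[nearest],
                    stringsAsFactors = FALSE)
  class(out) <- c("analog_result", "data.frame")
  attr(out, "scale") <- scale
  attr(out, "calibration_label") <- cal$label
  out
}

#' Era-mean minimum analog distance
#'
#' Unweighted mean of the minimum squared chord distances over the fossil
#' samples whose interval midpoint lies in `[start, end]`.
#'
#' @param result an [min_analog_series()] result with age intervals.
#' @param start,end calendar year range AD (inclusive, by midpoint).
#' @return the mean minimum distance for the era.
#' @export
era_mean_min_distance <- function(result, start, end) {
  stopifnot(inherits(result, "analog_result"))
  mid <- (result$start_year + result$end_year) / 2
  sel <- !is.na(mid) & mid >= start & mid <= end
  if (!any(sel)) stop("no samples with interval midpoint in [", start, ", ",
                      end, "]")
  mean(result$min_distance[sel])
}
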