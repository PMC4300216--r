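# Synthetic pollen-climate data with known ground truth.
#
# Taxa respond unimodally (Gaussian) to each climate variable, multiplied
# across variables -- the canonical species-response model underlying
# weighted-averaging calibration. On top of that the module generates:
# site calibration sets (expected assemblage + multinomial count noise),
# a land-clearance "disturbed modern" twin of a calibration set (ruderal
# taxa inflated, arboreal/herb taxa suppressed, climate normals warmed),
# and varve-dated down-core records driven by a last-millennium climate
# history (MCA baseline, cooler LIA, post-1850 linear warming).

#' Default climate gradient ranges (degrees C)
#'
#' Site-to-site ranges of February and May monthly mean temperature across
#' the synthetic calibration domain, patterned on the spread found over a
#' network of upper-midwest calibration sites.
#'
#' @return named list of `(lo, hi)` ranges, one per climate variable.
#' @export
default_gradients <- function() {
  list(feb_mean_temp = c(-18, -6), may_mean_temp = c(8, 18))
}

#' Draw a pool of synthetic taxa with unimodal climate responses
#'
#' Each taxon gets, per climate variable, a response optimum (uniform on the
#' gradient), a tolerance (uniform on `tol_range`, degrees C) and an overall
#' height (log-uniform on `height_range`). Taxa are assigned round-robin to
#' the ecological groups `ruderal`, `arboreal`, `herb`, which the
#' disturbance scenario acts upon.
#'
#' @param n_taxa number of taxa (>= 3; a transfer function needs at least 3).
#' @param gradient_ranges named list of `(lo, hi)` degrees C per variable.
#' @param seed integer RNG seed; the pool is fully reproducible from it.
#' @param tol_range tolerance range, degrees C.
#' @param height_range height range (log-uniform).
#' @return an object of class `species_response_model` with fields
#'   `taxa`, `optima` (taxa x variables), `tolerances`, `heights`, `group`,
#'   `gradient_ranges`.
#' @export
make_species_pool <- function(n_taxa, gradient_ranges = default_gradients(),
                              seed = 1, tol_range = c(1, 4),
                              height_range = c(0.5, 2)) {
  if (n_taxa < 3) stop("n_taxa must be >= 3 (transfer function needs >= 3 taxa)")
  vars <- names(gradient_ranges)
  if (is.null(vars)) stop("gradient_ranges must be a named list")
  with_seed(seed, {
    optima <- sapply(vars, function(v) {
      r <- gradient_ranges[[v]]
      stats::runif(n_taxa, r[1], r[2])
    })
    tolerances <- matrix(stats::runif(n_taxa * length(vars),
                                      tol_range[1], tol_range[2]),
                         n_taxa, length(vars), dimnames = list(NULL, vars))
    heights <- exp(stats::runif(n_taxa, log(height_range[1]),
                                log(height_range[2])))
  })
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  dimnames(optima) <- list(taxa, vars)
  dimnames(tolerances) <- list(taxa, vars)
  names(heights) <- taxa
  group <- rep(c("ruderal", "arboreal", "herb"), length.out = n_taxa)
  names(group) <- taxa
  structure(list(taxa = taxa, optima = optima, tolerances = tolerances,
                 heights = heights, group = group,
                 gradient_ranges = gradient_ranges),
            class = "species_response_model")
}

#' Expected pollen assemblage at a climate point
#'
#' Raw abundance of taxon k is
#' `a_k = c_k * prod_v exp(-(x_v - u_kv)^2 / (2 t_kv^2))`
#' (height times the product of Gaussian responses over climate variables);
#' the returned assemblage is `a / sum(a)`, summing to 1.
#'
#' @param model a [make_species_pool()] model.
#' @param climate named numeric vector of climate values (degrees C),
#'   one per model variable.
#' @return numeric proportion vector named by taxon, summing to 1.
#' @export
expected_assemblage <- function(model, climate) {
  vars <- colnames(model$optima)
  if (!all(vars %in% names(climate)))
    stop("climate must supply: ", paste(vars, collapse = ", "))
  loga <- log(model$heights)
  for (v in vars) {
    loga <- loga - (climate[[v]] - model$optima[, v])^2 /
      (2 * model$tolerances[, v]^2)
  }
  a <- exp(loga)
  s <- sum(a)
  if (s == 0 || !is.finite(s))
    stop("all taxon abundances underflow at climate point; ",
         "point is far outside the gradient")
  a / s
}

#' Multinomial pollen count noise
#'
#' Draws a pollen count of `total` grains from an expected assemblage.
#'
#' @param p proportion vector summing to 1.
#' @param total pollen sum (grains counted, >= 1).
#' @param seed integer RNG seed.
#' @return integer count vector summing to `total`.
#' @export
sample_counts <- function(p, total, seed = 1) {
  if (any(p < 0)) stop("negative proportions")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  if (total < 1) stop("total must be >= 1")
  cnt <- with_seed(seed, stats::rmultinom(1, size = total, prob = p))[, 1]
  names(cnt) <- names(p)
  cnt
}

#' Generate a synthetic calibration set
#'
#' Draws per-site climate values (or takes them as given), computes each
#' site's expected assemblage under the species model, adds multinomial
#' count noise and converts to percentages. When `climate_field` is `NULL`,
#' sites are placed along a latent geographic gradient so that the climate
#' variables co-vary across sites, as monthly temperatures do regionally;
#' independent site-level noise (sd `climate_noise_sd`) is added per
#' variable.
#'
#' @param model a [make_species_pool()] model.
#' @param n_sites number of calibration sites (>= 10).
#' @param climate_field optional data.frame of per-site climate values
#'   (one column per model variable); sampled if `NULL`.
#' @param total pollen sum per site (grains).
#' @param seed integer RNG seed.
#' @param climate_noise_sd site-level climate scatter around the latent
#'   gradient, degrees C.
#' @param label label for the resulting calibration set.
#' @return a [calibration_set()] carrying the generating `model` and the
#'   per-site `expected` assemblages (fields used by
#'   [apply_disturbance()] and by parameter-recovery tests).
#' @export
generate_calibration <- function(model, n_sites = 133, climate_field = NULL,
                                 total = 300, seed = 1,
                                 climate_noise_sd = 0.5,
                                 label = "1870-synthetic") {
  if (n_sites < 10) stop("n_sites must be >= 10 for downstream fitting")
  vars <- colnames(model$optima)
  with_seed(seed, {
    if (is.null(climate_field)) {
      g <- stats::runif(n_sites)  # latent position along the regional gradient
      climate_field <- as.data.frame(sapply(vars, function(v) {
        r <- model$gradient_ranges[[v]]
        r[1] + g * (r[2] - r[1]) + stats::rnorm(n_sites, 0, climate_noise_sd)
      }))
    } else {
      climate_field <- as.data.frame(climate_field)
      if (!all(vars %in% names(climate_field)))
        stop("climate_field must supply: ", paste(vars, collapse = ", "))
      if (nrow(climate_field) != n_sites)
        stop("climate_field must have n_sites rows")
    }
    expected <- t(apply(climate_field, 1, function(x)
      expected_assemblage(model, stats::setNames(as.numeric(x[vars]), vars))))
    counts <- t(apply(expected, 1, function(p)
      stats::rmultinom(1, size = total, prob = p)[, 1]))
  })
  ids <- sprintf("site%03d", seq_len(n_sites))
  dimnames(counts) <- list(ids, model$taxa)
  dimnames(expected) <- list(ids, model$taxa)
  pm <- to_percentages(pollen_matrix(counts, kind = "counts"))
  cl <- do.call(climate_table,
                c(list(site_ids = ids),
                  stats::setNames(lapply(vars, function(v) climate_field[[v]]),
                                  vars)))
  cal <- calibration_set(pm, cl, label = label)
  cal$model <- model
  cal$expected <- expected
  cal
}

#' Land-clearance disturbance scenario
#'
#' Multiplicative abundance factors per ecological group, plus the warming
#' offset between the two calibration eras' climate normals. Defaults
#' emulate post-settlement land clearance -- ruderal taxa strongly
#' inflated at the expense of arboreal and herb taxa -- paired with
#' modern normals about 2.1 degrees C warmer in February and 1.6 degrees C
#' warmer in May than the early-instrumental normals.
#'
#' @param ruderal,arboreal,herb multiplicative abundance factors (> 0).
#' @param climate_offset named per-variable warming offset, degrees C.
#' @return an object of class `disturbance_scenario`.
#' @export
disturbance_scenario <- function(ruderal = 3, arboreal = 0.6, herb = 0.8,
                                 climate_offset = c(feb_mean_temp = 2.07,
                                                    may_mean_temp = 1.57)) {
  f <- c(ruderal = ruderal, arboreal = arboreal, herb = herb)
  if (any(f <= 0)) stop("group factors must be > 0")
  structure(list(factors = f, climate_offset = climate_offset),
            class = "disturbance_scenario")
}

#' Apply a disturbance scenario to a synthetic calibration set
#'
#' Emulates building a conventional "modern" calibration set over a
#' disturbed landscape: each site's expected assemblage is reweighted by
#' its taxon-group factor and renormalized, pollen counts are resampled,
#' and the climate table is shifted by the scenario's warming offset. The
#' pollen thus still reflects the undisturbed-era climate (vegetation has
#' not equilibrated to the warming), which is the non-stationarity the
#' hindcasting experiment measures.
#'
#' @param cal a [generate_calibration()] output (needs the stored expected
#'   assemblages and species model).
#' @param scen a [disturbance_scenario()].
#' @param seed integer RNG seed for the count resampling.
#' @param total pollen sum per site; defaults to the observed row sums'
#'   behaviour via 300 grains.
#' @return a [calibration_set()] labelled `"modern-synthetic"`, carrying
#'   its disturbed `expected` assemblages.
#' @export
apply_disturbance <- function(cal, scen, seed = 1, total = 300) {
  stopifnot(inherits(cal, "calibration_set"),
            inherits(scen, "disturbance_scenario"))
  if (is.null(cal$expected) || is.null(cal$model))
    stop("cal must be a synthetic calibration set with stored expected assemblages")
  fac <- scen$factors[cal$model$group]     # per-taxon factor via group
  expected <- sweep(cal$expected, 2, fac, `*`)
  expected <- expected / rowSums(expected)
  counts <- with_seed(seed, t(apply(expected, 1, function(p)
    stats::rmultinom(1, size = total, prob = p)[, 1])))
  dimnames(counts) <- dimnames(cal$expected)
  pm <- to_percentages(pollen_matrix(counts, kind = "counts"))
  cl <- cal$climate
  for (v in names(scen$climate_offset)) {
    if (!v %in% names(cl)) stop("offset variable absent from climate: ", v)
    cl[[v]] <- cl[[v]] + scen$climate_offset[[v]]
  }
  out <- calibration_set(pm, cl, label = "modern-synthetic")
  out$model <- cal$model
  out$expected <- expected
  out$scenario <- scen
  out
}

#' Last-millennium climate history
#'
#' Year-by-year February and May mean temperatures for AD `start`-`end`
#' built from three segments: a Medieval Climate Anomaly baseline, a
#' Little Ice Age plateau `lia_delta` degrees C cooler, and a post-LIA
#' linear warming ramp totalling `post_warming_total` degrees C by `end`.
#' Seeded white interannual noise (sd `noise_sd`) is added on top.
#'
#' @param start,end year range AD (inclusive).
#' @param baseline named per-variable MCA baseline, degrees C.
#' @param lia_delta LIA anomaly relative to baseline, degrees C.
#' @param lia_years `(onset, end)` of the LIA plateau.
#' @param post_warming_total warming from LIA end to `end`, degrees C.
#' @param noise_sd interannual white-noise sd, degrees C.
#' @param seed integer RNG seed.
#' @return an object of class `climate_history`: `years`, `values`
#'   (years x variables, noise included), `anomaly` (deterministic segment
#'   structure), and the parameters.
#' @export
climate_history <- function(start = 1116, end = 2002,
                            baseline = c(feb_mean_temp = -11.5,
                                         may_mean_temp = 13.3),
                            lia_delta = -1.0, lia_years = c(1450, 1850),
                            post_warming_total = 2.0, noise_sd = 1.0,
                            seed = 1) {
  years <- start:end
  anom <- ifelse(years < lia_years[1], 0,
          ifelse(years <= lia_years[2], lia_delta,
                 lia_delta + post_warming_total *
                   (years - lia_years[2]) / (end - lia_years[2])))
  vars <- names(baseline)
  noise <- with_seed(seed,
    matrix(stats::rnorm(length(years) * length(vars), 0, noise_sd),
           length(years), length(vars), dimnames = list(years, vars)))
  values <- outer(anom, rep(1, length(vars))) + rep(baseline, each = length(years)) + noise
  dimnames(values) <- list(years, vars)
  structure(list(years = years, values = values, anomaly = anom,
                 baseline = baseline, lia_delta = lia_delta,
                 lia_years = lia_years,
                 post_warming_total = post_warming_total,
                 noise_sd = noise_sd),
            class = "climate_history")
}

#' Interval means of a climate history
#'
#' @param hist a [climate_history()].
#' @param start_year,end_year inclusive year range.
#' @return named per-variable mean over the years in range.
#' @export
history_interval_mean <- function(hist, start_year, end_year) {
  sel <- hist$years >= start_year & hist$years <= end_year
  if (!any(sel)) stop("no history years in range")
  colMeans(hist$values[sel, , drop = FALSE])
}

#' Generate a varve-dated down-core record
#'
#' Slices the climate history into consecutive `interval_years`-year
#' samples (final interval shortened if the range does not divide evenly),
#' takes the interval-mean climate, and generates each sample's assemblage
#' from the species model with multinomial count noise. Returns the record
#' together with the per-sample true interval-mean climate for
#' parameter-recovery tests.
#'
#' @param model a [make_species_pool()] model.
#' @param history a [climate_history()].
#' @param interval_years sampling resolution in varve years (default 4).
#' @param total pollen sum per sample (grains).
#' @param seed integer RNG seed.
#' @return list with `record` (a [fossil_record()]) and `true_climate`
#'   (data.frame: start_year, end_year, one column per climate variable).
#' @export
generate_downcore <- function(model, history, interval_years = 4,
                              total = 300, seed = 1) {
  yrs <- range(history$years)
  starts <- as.integer(seq(yrs[1], yrs[2], by = interval_years))
  ends <- as.integer(pmin(starts + interval_years - 1, yrs[2]))
  if (ends[length(ends)] - starts[length(starts)] + 1 < interval_years)
    message("final interval shortened to ",
            ends[length(ends)] - starts[length(starts)] + 1, " year(s)")
  vars <- colnames(model$optima)
  true_climate <- t(mapply(function(s, e) history_interval_mean(history, s, e),
                           starts, ends))
  true_climate <- as.data.frame(true_climate)
  counts <- with_seed(seed, t(apply(true_climate, 1, function(x) {
    p <- expected_assemblage(model, stats::setNames(as.numeric(x[vars]), vars))
    stats::rmultinom(1, size = total, prob = p)[, 1]
  })))
  ids <- sprintf("mina%03d", seq_along(starts))
  dimnames(counts) <- list(ids, model$taxa)
  pm <- to_percentages(pollen_matrix(counts, kind = "counts"))
  rec <- fossil_record(pm, data.frame(start_year = starts, end_year = ends))
  list(record = rec,
       true_climate = cbind(data.frame(start_year = starts, end_year = ends),
                            true_climate))
}
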