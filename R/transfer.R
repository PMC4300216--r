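# Weighted-averaging partial least squares (WA-PLS) transfer functions.
#
# With y_ik the pollen value of taxon k at site i (percentages are used
# directly; the algorithm is invariant to row scale), marginal sums y_i+ /
# y_+k, site weights w_i = y_i+ / y_++, and x_i the climate value, each
# component a is extracted as:
#   taxon scores  u_k = sum_i y_ik r_i / y_+k      (r = current residual)
#   site scores   s_i = sum_k y_ik u_k / y_i+
#   s orthogonalized against earlier components under w, standardized to
#   weighted mean 0 / sd 1 (transform stored), then x is regressed on
#   components 1..a by weighted least squares and r set to its residuals.
# Deshrinking is implicit in the final WLS regression (inverse style). On
# percentage data all site weights are equal, so a one-component fit
# coincides with classical weighted averaging + inverse deshrinking.

#' Fit a WA-PLS transfer function
#'
#' @param cal a [calibration_set()].
#' @param variable name of the climate column to calibrate against
#'   (e.g. `"feb_mean_temp"`).
#' @param n_components number of WA-PLS components (default 2, the usual
#'   choice for pollen-temperature work).
#' @param sqrt_transform square-root transform pollen values before
#'   fitting (default `FALSE`).
#' @return an object of class `wapls` holding per-component taxon scores,
#'   the orthogonalization/standardization transforms, regression
#'   coefficients, apparent predictions and RMSE. The stored transforms
#'   suffice to score unseen samples without the training pollen.
#' @export
fit_wapls <- function(cal, variable, n_components = 2,
                      sqrt_transform = FALSE) {
  stopifnot(inherits(cal, "calibration_set"))
  if (!variable %in% names(cal$climate))
    stop("variable not in climate table: ", variable)
  x <- cal$climate[[variable]]
  y <- cal$pollen$values
  if (sqrt_transform) y <- sqrt(y)
  zero <- colSums(y) == 0
  dropped <- colnames(y)[zero]
  if (any(zero)) {
    warning("dropping ", sum(zero), " taxon/taxa with zero column sum: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    y <- y[, !zero, drop = FALSE]
  }
  if (ncol(y) < 3) stop("need >= 3 taxa with nonzero column sums")
  n <- nrow(y)
  if (n < n_components + 2) stop("need >= n_components + 2 sites")
  if (stats::sd(x) == 0) stop("climate variable is constant")
  if (n_components < 1) stop("n_components must be >= 1")

  ysum_site <- rowSums(y)
  ysum_taxon <- colSums(y)
  w <- ysum_site / sum(y)

  r <- x
  comps <- matrix(0, n, n_components)
  u <- matrix(0, ncol(y), n_components,
              dimnames = list(colnames(y), NULL))
  transforms <- vector("list", n_components)
  beta <- NULL
  fitted <- NULL
  for (a in seq_len(n_components)) {
    u[, a] <- colSums(y * r) / ysum_taxon
    s <- as.vector(y %*% u[, a]) / ysum_site
    # orthogonalize against earlier (standardized) components under w
    ortho <- numeric(0)
    if (a > 1) {
      ortho <- vapply(seq_len(a - 1), function(b) sum(w * s * comps[, b]),
                      numeric(1))
      s <- s - comps[, seq_len(a - 1), drop = FALSE] %*% ortho
      s <- as.vector(s)
    }
    m <- sum(w * s)
    s <- s - m
    sdw <- sqrt(sum(w * s^2))
    if (sdw < 1e-12)
      stop("degenerate component ", a, ": site-score sd below 1e-12")
    s <- s / sdw
    comps[, a] <- s
    transforms[[a]] <- list(ortho = ortho, mean = m, sd = sdw)
    fit <- stats::lm.wfit(cbind(1, comps[, seq_len(a), drop = FALSE]), x, w)
    beta <- fit$coefficients
    r <- fit$residuals
    fitted <- x - r
  }
  names(beta) <- c("(Intercept)", paste0("comp", seq_len(n_components)))
  structure(list(variable = variable, n_components = n_components,
                 sqrt_transform = sqrt_transform,
                 taxa = colnames(y), dropped_taxa = dropped,
                 taxon_scores = u, transforms = transforms, beta = beta,
                 site_weights = w, fitted = fitted, residuals = r,
                 observed = x, rmse_app = rms(r)),
            class = "wapls")
}

#' @export
print.wapls <- function(x, ...) {
  cat("WA-PLS transfer function: ", x$variable, ", ", x$n_components,
      " component(s), ", length(x$taxa), " taxa\n",
      "apparent RMSE: ", format(x$rmse_app, digits = 4), " degC\n", sep = "")
  invisible(x)
}

#' Apply a WA-PLS transfer function to pollen samples
#'
#' Samples are matched to the training taxa by name; taxa absent from
#' training are dropped from scoring (after [harmonize_taxa()] these are
#' zero columns), training taxa absent from the samples contribute zero.
#'
#' @param object a fitted [fit_wapls()] model.
#' @param pollen percent [pollen_matrix()] (or any non-negative matrix with
#'   taxon column names; scoring is invariant to row scale).
#' @param ... unused.
#' @return numeric vector of predicted climate values (degrees C), named
#'   by sample id.
#' @export
predict.wapls <- function(object, pollen, ...) {
  y <- if (inherits(pollen, "pollen_matrix")) pollen$values else as.matrix(pollen)
  if (object$sqrt_transform) y <- sqrt(y)
  extra <- setdiff(colnames(y), object$taxa)
  if (length(extra))
    message(length(extra), " taxon/taxa absent from training dropped from scoring")
  ymat <- matrix(0, nrow(y), length(object$taxa),
                 dimnames = list(rownames(y), object$taxa))
  common <- intersect(colnames(y), object$taxa)
  ymat[, common] <- y[, common]
  rs <- rowSums(ymat)
  if (any(rs <= 0)) {
    stop("sample(s) with zero pollen sum over training taxa: ",
         paste(utils::head(rownames(ymat)[rs <= 0], 5), collapse = ", "))
  }
  A <- object$n_components
  scores <- matrix(0, nrow(ymat), A)
  for (a in seq_len(A)) {
    s <- as.vector(ymat %*% object$taxon_scores[, a]) / rs
    tr <- object$transforms[[a]]
    if (a > 1)
      s <- s - as.vector(scores[, seq_len(a - 1), drop = FALSE] %*% tr$ortho)
    s <- (s - tr$mean) / tr$sd
    scores[, a] <- s
  }
  pred <- as.vector(cbind(1, scores) %*% object$beta)
  names(pred) <- rownames(ymat)
  pred
}

#' Classical weighted averaging with inverse deshrinking
#'
#' The textbook two-step weighted-averaging estimator: taxon optima as
#' pollen-weighted averages of the climate variable, site scores as
#' abundance-weighted averages of the optima, then ordinary least squares
#' of climate on the site scores (inverse deshrinking). Kept as an
#' independent reference estimator against which the one-component WA-PLS
#' fit can be checked.
#'
#' @inheritParams fit_wapls
#' @return list with `optima`, `coefficients`, and apparent `fitted`
#'   values; plus a `predict` closure for new percent matrices.
#' @export
fit_wa_inverse <- function(cal, variable) {
  x <- cal$climate[[variable]]
  y <- cal$pollen$values
  y <- y[, colSums(y) > 0, drop = FALSE]
  optima <- colSums(y * x) / colSums(y)
  s <- as.vector(y %*% optima) / rowSums(y)
  co <- stats::coef(stats::lm(x ~ s))
  score <- function(pollen) {
    ym <- if (inherits(pollen, "pollen_matrix")) pollen$values else as.matrix(pollen)
    ym <- ym[, names(optima), drop = FALSE]
    as.vector(ym %*% optima) / rowSums(ym)
  }
  list(optima = optima, coefficients = co,
       fitted = co[1] + co[2] * s,
       predict = function(pollen) co[1] + co[2] * score(pollen))
}

#' Leave-one-out cross-validation of a WA-PLS transfer function
#'
#' Refits the model once per site with that site held out and predicts it,
#' giving the RMSEP_loo estimate of prediction error alongside the full
#' fit's apparent RMSE.
#'
#' @inheritParams fit_wapls
#' @return an object of class `cv_result` with per-site `predicted`,
#'   `residual` (predicted - observed), `rmse_app` and `rmsep_loo`
#'   (degrees C).
#' @export
loo_cross_validate <- function(cal, variable, n_components = 2,
                               sqrt_transform = FALSE) {
  n <- n_sites(cal)
  full <- fit_wapls(cal, variable, n_components, sqrt_transform)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    # taxa going rare in a leave-one-out subset are silently rehandled:
    # the full fit has already reported any empty columns
    tf <- suppressWarnings(
      fit_wapls(cal_subset(cal, setdiff(seq_len(n), i)), variable,
                n_components, sqrt_transform))
    pred[i] <- suppressMessages(
      predict(tf, cal$pollen$values[i, , drop = FALSE]))
  }
  obs <- cal$climate[[variable]]
  resid <- pred - obs
  structure(list(method = "loo", variable = variable,
                 n_components = n_components,
                 predicted = stats::setNames(pred, pm_ids(cal$pollen)),
                 observed = obs, residual = resid,
                 rmse_app = full$rmse_app, rmsep_loo = rms(resid)),
            class = "cv_result")
}

#' Bootstrap RMSEP of a WA-PLS transfer function
#'
#' Site bootstrap of the calibration set: each cycle resamples sites with
#' replacement as training and predicts the out-of-bag sites. The error is
#' decomposed as `s1` (root mean square over sites of the per-site sd of
#' out-of-bag predictions) and `s2` (root mean square over sites of mean
#' out-of-bag prediction minus observed), combined as
#' `RMSEP_boot = sqrt(s1^2 + s2^2)`.
#'
#' @inheritParams fit_wapls
#' @param n_boot number of bootstrap cycles (default 1000).
#' @param seed integer RNG seed; results are reproducible from it.
#' @return a `cv_result` with `rmsep_boot`, components `s1`, `s2`,
#'   per-site mean out-of-bag `predicted` and `residual`, `rmse_app`,
#'   `n_boot` and `seed`.
#' @export
bootstrap_rmsep <- function(cal, variable, n_components = 2, n_boot = 1000,
                            seed = 1, sqrt_transform = FALSE) {
  n <- n_sites(cal)
  full <- fit_wapls(cal, variable, n_components, sqrt_transform)
  obs <- cal$climate[[variable]]
  sum1 <- sum2 <- cnt <- numeric(n)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), idx)
      if (!length(oob)) next
      tf <- suppressWarnings(
        fit_wapls(cal_subset(cal, idx), variable, n_components,
                  sqrt_transform))
      p <- suppressMessages(
        predict(tf, cal$pollen$values[oob, , drop = FALSE]))
      sum1[oob] <- sum1[oob] + p
      sum2[oob] <- sum2[oob] + p^2
      cnt[oob] <- cnt[oob] + 1
    }
  })
  if (any(cnt < 2))
    stop("site(s) out-of-bag fewer than twice after ", n_boot,
         " cycles; increase n_boot")
  mean_oob <- sum1 / cnt
  var_oob <- (sum2 - cnt * mean_oob^2) / (cnt - 1)
  var_oob[var_oob < 0] <- 0  # numerical guard
  s1 <- sqrt(mean(var_oob))
  s2 <- rms(mean_oob - obs)
  structure(list(method = "bootstrap", variable = variable,
                 n_components = n_components,
                 predicted = stats::setNames(mean_oob, pm_ids(cal$pollen)),
                 observed = obs, residual = mean_oob - obs,
                 rmse_app = full$rmse_app,
                 rmsep_boot = sqrt(s1^2 + s2^2), s1 = s1, s2 = s2,
                 n_boot = n_boot, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("WA-PLS cross-validation (", x$method, "), ", x$variable, ":\n",
      "  RMSE_app  ", format(x$rmse_app, digits = 4), " degC\n", sep = "")
  if (!is.null(x$rmsep_loo))
    cat("  RMSEP_loo ", format(x$rmsep_loo, digits = 4), " degC\n", sep = "")
  if (!is.null(x$rmsep_boot))
    cat("  RMSEP_boot ", format(x$rmsep_boot, digits = 4),
        " degC (s1 ", format(x$s1, digits = 4), ", s2 ",
        format(x$s2, digits = 4), "; ", x$n_boot, " cycles)\n", sep = "")
  invisible(x)
}

#' Serialize a WA-PLS model to JSON
#'
#' Writes a plain-text JSON structure holding everything needed to score
#' unseen samples ([read_wapls()] restores it).
#'
#' @param tf a [fit_wapls()] model.
#' @param path output file path.
#' @export
write_wapls <- function(tf, path) {
  stopifnot(inherits(tf, "wapls"))
  obj <- list(
    format = "pollenclim-wapls", version = 1L,
    variable = tf$variable, n_components = tf$n_components,
    sqrt_transform = tf$sqrt_transform,
    taxa = tf$taxa, dropped_taxa = tf$dropped_taxa,
    taxon_scores = lapply(seq_len(tf$n_components), function(a)
      as.numeric(tf$taxon_scores[, a])),
    transforms = lapply(tf$transforms, function(t)
      list(ortho = as.numeric(t$ortho), mean = t$mean, sd = t$sd)),
    beta = as.numeric(tf$beta), rmse_app = tf$rmse_app)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a WA-PLS model written by [write_wapls()]
#' @param path JSON file path.
#' @return a `wapls` object (training summaries beyond the apparent RMSE
#'   are not stored).
#' @export
read_wapls <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pollenclim-wapls"))
    stop("not a pollenclim WA-PLS model file")
  u <- if (is.matrix(obj$taxon_scores)) t(obj$taxon_scores)
       else do.call(cbind, lapply(obj$taxon_scores, as.numeric))
  dimnames(u) <- list(obj$taxa, NULL)
  transforms <- lapply(seq_len(obj$n_components), function(a) {
    t <- if (is.data.frame(obj$transforms)) as.list(obj$transforms[a, ])
         else obj$transforms[[a]]
    list(ortho = as.numeric(unlist(t$ortho)), mean = as.numeric(t$mean),
         sd = as.numeric(t$sd))
  })
  beta <- as.numeric(obj$beta)
  names(beta) <- c("(Intercept)", paste0("comp", seq_len(obj$n_components)))
  structure(list(variable = obj$variable, n_components = obj$n_components,
                 sqrt_transform = isTRUE(obj$sqrt_transform),
                 taxa = obj$taxa, dropped_taxa = obj$dropped_taxa,
                 taxon_scores = u, transforms = transforms, beta = beta,
                 rmse_app = obj$rmse_app),
            class = "wapls")
}
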