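# Hindcasting: apply one era's transfer function to another era's pollen
# and quantify the systematic bias against that era's observed climate.
# The residual convention throughout is predicted - observed, so a
# positive mean residual is a warm bias.

#' Hindcast a transfer function onto a calibration set
#'
#' Predicts the target set's pollen with a transfer function trained
#' elsewhere and summarizes the residuals against the target's own
#' observed climate.
#'
#' @param tf a [fit_wapls()] model.
#' @param target a [calibration_set()] whose climate table contains the
#'   model's variable (harmonize taxa beforehand if the lists differ).
#' @return an object of class `bias_report` with per-site `observed`,
#'   `predicted`, `residual`, and summary `mean_bias`, `residual_sd`,
#'   `rmse` (degrees C).
#' @export
hindcast <- function(tf, target) {
  stopifnot(inherits(tf, "wapls"), inherits(target, "calibration_set"))
  if (!tf$variable %in% names(target$climate))
    stop("variable absent from target climate: ", tf$variable)
  pred <- predict(tf, target$pollen)
  obs <- target$climate[[tf$variable]]
  resid <- pred - obs
  structure(list(variable = tf$variable,
                 site_id = pm_ids(target$pollen),
                 observed = obs, predicted = unname(pred), residual = resid,
                 mean_bias = mean(resid), residual_sd = stats::sd(resid),
                 rmse = rms(resid)),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("hindcast bias report (", x$variable, "), n = ", length(x$residual),
      " sites\n",
      "  mean bias   ", format(x$mean_bias, digits = 4), " degC\n",
      "  residual sd ", format(x$residual_sd, digits = 4), " degC\n",
      "  RMSE        ", format(x$rmse, digits = 4), " degC\n", sep = "")
  if (!is.null(x$rmsep_boot))
    cat("  reference RMSEP_boot ", format(x$rmsep_boot, digits = 4),
        " degC; bootstrapped improvement ", x$improvement_percent, "%\n",
        sep = "")
  invisible(x)
}

#' Bootstrapped-improvement percentage
#'
#' How much larger (percent) the hindcast error is than the reference
#' set's own bootstrap prediction error:
#' `100 * (rmse_hindcast - rmsep_reference) / rmsep_reference`, rounded to
#' the nearest integer for reporting. Negative when the reference error
#' exceeds the hindcast error.
#'
#' @param rmse_hindcast hindcast RMSE, degrees C (> 0).
#' @param rmsep_reference reference RMSEP (e.g. bootstrap), degrees C (> 0).
#' @return integer percentage.
#' @export
improvement_percent <- function(rmse_hindcast, rmsep_reference) {
  if (rmse_hindcast <= 0 || rmsep_reference <= 0)
    stop("both error inputs must be > 0")
  round(100 * (rmse_hindcast - rmsep_reference) / rmsep_reference)
}

#' Full calibration-set bias experiment
#'
#' The complete hindcasting design: fit a transfer function on the
#' alternative calibration set, hindcast it onto the reference set, and
#' contrast the hindcast error with the reference set's own leave-one-out
#' and bootstrap cross-validation errors.
#'
#' @param cal_ref reference [calibration_set()] (e.g. the pre-settlement
#'   set); hindcast target and cross-validation baseline.
#' @param cal_alt alternative [calibration_set()] (e.g. the disturbed
#'   modern set) on which the transfer function is trained.
#' @param variable climate variable name.
#' @param n_components WA-PLS components (default 2).
#' @param n_boot bootstrap cycles for the reference RMSEP.
#' @param seed integer RNG seed (bootstrap resampling).
#' @return a `bias_report` additionally carrying `loo` and `boot`
#'   `cv_result`s, `rmsep_boot`, and `improvement_percent` (hindcast RMSE
#'   vs reference RMSEP_boot).
#' @export
bias_experiment <- function(cal_ref, cal_alt, variable, n_components = 2,
                            n_boot = 1000, seed = 1) {
  h <- harmonize_taxa(cal_alt$pollen, cal_ref$pollen)
  alt <- calibration_set(h$a, cal_alt$climate, label = cal_alt$label)
  ref <- calibration_set(h$b, cal_ref$climate, label = cal_ref$label)
  tf <- fit_wapls(alt, variable, n_components)
  rep <- hindcast(tf, ref)
  rep$loo <- loo_cross_validate(ref, variable, n_components)
  rep$boot <- bootstrap_rmsep(ref, variable, n_components, n_boot, seed)
  rep$rmsep_boot <- rep$boot$rmsep_boot
  rep$improvement_percent <- improvement_percent(rep$rmse, rep$rmsep_boot)
  rep
}
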