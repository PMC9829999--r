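#' @export
print.bias_fit <- function(x, ...) {
  cat("Logistic hearing-asymmetry bias model",
      if (x$hierarchical) "(hierarchical)" else "(single level)", "\n")
  cat(sprintf("  %d cells, %d participant(s); %d chains x %d iterations\n",
              nrow(x$cells), length(x$participants),
              x$config$chains, x$config$iter))
  key <- if (x$hierarchical)
    c("omega_group", "mu_th", "sigma_lw", "sigma_th") else c("omega", "theta")
  s <- x$summary[x$summary$parameter %in% key, ]
  lab <- c(omega_group = "group omega (dB)", mu_th = "group theta (dB)",
           sigma_lw = "sd log-omega", sigma_th = "sd theta (dB)",
           omega = "omega (dB)", theta = "theta (dB)")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %6.1f  [%.1f, %.1f] 95%%-HDI\n",
                lab[s$parameter[i]], s$mean[i], s$hdi_low[i], s$hdi_high[i]))
  if (any(!is.na(s$rhat)))
    cat(sprintf("  max split-Rhat: %.3f\n", max(x$summary$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior summary table of a bias-model fit
#'
#' @param object a `"bias_fit"` from [fit_bias_model].
#' @param ... unused.
#' @return data.frame with one row per monitored parameter: posterior
#'   `mean`, `hdi_low`, `hdi_high` (95%-HDI), split-Rhat `rhat`, and the
#'   `participant_id` for per-participant parameters.
#' @export
summary.bias_fit <- function(object, ...) object$summary

#' @export
coef.bias_fit <- function(object, ...) {
  s <- object$summary
  stats::setNames(s$mean, s$parameter)
}

# posterior means of the curve parameters for one participant or the group
.curve_params <- function(object, participant = NULL) {
  s <- object$summary
  if (is.null(participant)) {
    if (object$hierarchical)
      c(omega = s$mean[s$parameter == "omega_group"],
        theta = s$mean[s$parameter == "mu_th"])
    else
      c(omega = s$mean[s$parameter == "omega"],
        theta = s$mean[s$parameter == "theta"])
  } else {
    i <- s$participant_id %in% participant & grepl("^omega", s$parameter)
    j <- s$participant_id %in% participant & grepl("^theta", s$parameter)
    if (!any(i)) stop("unknown participant: ", participant)
    c(omega = s$mean[i], theta = s$mean[j])
  }
}

#' Predict implant-side response probability from a fitted model
#'
#' @param object a `"bias_fit"`.
#' @param newdata data.frame with columns `delta_h` and `ha_on` (and
#'   optionally `participant_id` to use participant-level parameters);
#'   default: the fitted cells.
#' @param participant use this participant's posterior means for all rows;
#'   `NULL` (default) uses group-level (hierarchical fit) or the single
#'   participant's parameters.
#' @param ... unused.
#' @return vector of probabilities.
#' @export
predict.bias_fit <- function(object, newdata = NULL, participant = NULL,
                             ...) {
  if (is.null(newdata)) newdata <- object$cells
  if (is.null(participant) && "participant_id" %in% names(newdata) &&
      all(newdata$participant_id %in% object$participants) &&
      object$hierarchical) {
    vapply(seq_len(nrow(newdata)), function(i) {
      pp <- .curve_params(object, newdata$participant_id[i])
      peas_predict(newdata$delta_h[i], pp["omega"], pp["theta"],
                   newdata$ha_on[i])
    }, numeric(1))
  } else {
    pp <- .curve_params(object, participant)
    peas_predict(newdata$delta_h, pp["omega"], pp["theta"], newdata$ha_on)
  }
}

#' @export
fitted.bias_fit <- function(object, ...) predict(object)

#' Pearson residuals of the observed cell proportions
#'
#' `(k/n - p_hat) / sqrt(p_hat (1 - p_hat) / n)` at the posterior-mean
#' predicted probabilities.
#'
#' @param object a `"bias_fit"`.
#' @param ... unused.
#' @return numeric vector, one per cell.
#' @export
residuals.bias_fit <- function(object, ...) {
  p <- predict(object)
  with(object$cells, (k / n - p) / sqrt(p * (1 - p) / n))
}

#' Simulate implant-side response counts from a fitted model
#'
#' Draws binomial response counts for the fitted cells at the
#' posterior-mean predicted probabilities.
#'
#' @param object a `"bias_fit"`.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated `k`, rows matching
#'   the fitted cells.
#' @export
simulate.bias_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object)
  n <- object$cells$n
  out <- as.data.frame(replicate(nsim, rbinom(length(p), n, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot observed bias proportions against the fitted logistic curve
#'
#' Observed `k/n` per cell versus hearing asymmetry, with the group-level
#' (or single-participant) posterior-mean curves for hearing-aid-on and
#' hearing-aid-off conditions.
#'
#' @param x a `"bias_fit"`.
#' @param ... passed to [plot.default].
#' @export
plot.bias_fit <- function(x, ...) {
  cells <- x$cells
  plot(cells$delta_h, cells$k / cells$n,
       pch = ifelse(cells$ha_on, 19, 1),
       xlab = expression(paste(Delta, "H (dB)")),
       ylab = expression(p[EAS]), ylim = c(0, 1), ...)
  dh <- seq(min(cells$delta_h) - 10, max(cells$delta_h) + 10, length.out = 200)
  pp <- .curve_params(x)
  lines(dh, peas_predict(dh, pp["omega"], pp["theta"], ha_on = TRUE), lty = 1)
  lines(dh, peas_predict(dh, pp["omega"], theta = 0, ha_on = FALSE), lty = 2)
  abline(h = 0.5, col = "grey70", lty = 3)
  legend("bottomright", legend = c("HA on", "HA off"), lty = 1:2, bty = "n")
  invisible(x)
}
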