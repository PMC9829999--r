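## File-level pipeline: long-format CSV in, long-format CSV out, with a
## JSON run manifest per stage so completed runs can be re-executed
## deterministically.

#' Read a trial table CSV
#'
#' Expected columns: `participant_id`, `condition`, `band`, `target_az`,
#' `target_el`, `response_az`, `response_el`, `heard`. Validates ranges and
#' the unheard/missing-response contract.
#'
#' @param path CSV file.
#' @param az_range,el_range admissible target ranges (deg).
#' @return validated data.frame.
#' @export
read_trials <- function(path, az_range = c(-80, 80),
                        el_range = c(-45, 60)) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "condition", "band", "target_az", "target_el",
            "response_az", "response_el", "heard")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("trial CSV is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("trial table is empty")
  d$heard <- as.logical(d$heard)
  bad_az <- d$target_az < az_range[1] | d$target_az > az_range[2]
  if (any(bad_az))
    stop(sum(bad_az), " trial(s) have target azimuth outside [",
         az_range[1], ", ", az_range[2], "] deg")
  bad_cond <- !d$condition %in% .conditions
  if (any(bad_cond))
    stop("unknown listening condition(s): ",
         paste(unique(d$condition[bad_cond]), collapse = ", "))
  if (any(!d$heard & !is.na(d$response_az)))
    stop("unheard trials must have missing responses")
  d
}

write_manifest <- function(path, stage, seed, config, inputs = character(),
                           elapsed_s = NA_real_) {
  manifest <- list(
    stage = stage,
    package_version = as.character(packageVersion("easbias")),
    seed = seed,
    config = config,
    inputs = lapply(inputs, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    elapsed_s = elapsed_s,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `audiograms.csv`, `trials.csv`, `asymmetry.csv`, a ground-truth
#' `truth.json` (generative parameters per listener) and a run manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [cohort_config]; `seed` overrides its seed if given.
#' @param seed optional integer seed.
#' @return the generated `"cohort"`, invisibly.
#' @export
run_simulate <- function(out_dir, cfg = cohort_config(), seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg)
  ag_rows <- do.call(rbind, lapply(cohort$listeners, function(l) {
    x <- list(); x[[l$participant_id]] <- list(
      EAS = list(unaided = l$audiograms$eas_unaided,
                 A = l$audiograms$eas_acoustic_aided,
                 E = l$audiograms$eas_electric),
      HA = list(unaided = l$audiograms$ha_unaided,
                A = l$audiograms$ha_aided))
    audiograms_to_df(x)
  }))
  write.csv(ag_rows, file.path(out_dir, "audiograms.csv"),
            row.names = FALSE)
  write.csv(cohort$trials, file.path(out_dir, "trials.csv"),
            row.names = FALSE)
  write.csv(cohort$asymmetry, file.path(out_dir, "asymmetry.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(group = as.list(cohort$group_truth),
         listeners = cohort$truth),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  write_manifest(file.path(out_dir, "manifest_simulate.json"), "simulate",
                 cfg$seed, cfg[setdiff(names(cfg), "seed")],
                 elapsed_s = proc.time()[["elapsed"]] - t0)
  message(sprintf("[simulate] %d listeners, %d trials -> %s",
                  length(cohort$listeners), nrow(cohort$trials), out_dir))
  invisible(cohort)
}

#' Compute hearing asymmetry from an audiogram file
#'
#' For every participant, listening condition and stimulus band, derives
#' the per-ear effective audiogram from the recorded device states, runs
#' the audibility pipeline and writes one asymmetry row. Conditions whose
#' required device states are missing produce an explicit error row
#' (`delta_h = NA`, `note` says what was missing) rather than failing the
#' run.
#'
#' @param audiogram_csv path to a long-format audiogram CSV
#'   (see [read_audiograms]).
#' @param out_csv output path; `NULL` returns the table only.
#' @param conditions,bands design to evaluate.
#' @param level stimulus level in dB(A).
#' @param grid analysis grid (`"third_octave"` or `"fine"`).
#' @param summation_rule `"power"` or `"mean"` (see [audibility]).
#' @return asymmetry data.frame, invisibly when written.
#' @export
run_audibility <- function(audiogram_csv, out_csv = NULL,
                           conditions = .conditions,
                           bands = c("LF", "MF", "MHF", "HF"),
                           level = 65, grid = "third_octave",
                           summation_rule = "power") {
  t0 <- proc.time()[["elapsed"]]
  ags <- read_audiograms(audiogram_csv)
  rows <- list()
  for (pid in names(ags)) {
    sets <- ags[[pid]]
    for (cond in conditions) {
      cond_ags <- tryCatch({
        audiograms <- list(
          ha_unaided = sets$HA$unaided, ha_aided = sets$HA$A,
          eas_unaided = sets$EAS$unaided,
          eas_acoustic_aided = sets$EAS$A,
          eas_electric = sets$EAS$E)
        ca <- condition_audiograms(audiograms, cond)
        if (is.null(ca$eas) || is.null(ca$ha))
          stop("missing device state for condition ", cond)
        ca
      }, error = function(e) e)
      for (b in bands) {
        if (inherits(cond_ags, "error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = pid, condition = cond, band = b,
            delta_h = NA_real_, audibility_eas = NA_real_,
            audibility_ha = NA_real_, inaudible_both = NA,
            ha_on = ha_on_condition(cond),
            note = conditionMessage(cond_ags), stringsAsFactors = FALSE)
          next
        }
        stim <- stimulus_spec(b, overall_level = level)
        h <- stimulus_asymmetry(stim, cond_ags$eas, cond_ags$ha,
                                grid = grid,
                                summation_rule = summation_rule)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, condition = cond, band = b,
          delta_h = h$delta_h, audibility_eas = h$audibility_eas,
          audibility_ha = h$audibility_ha,
          inaudible_both = h$inaudible_both,
          ha_on = ha_on_condition(cond), note = "",
          stringsAsFactors = FALSE)
        message(sprintf(
          "[audibility] %s %s %s: EAS %.1f dB, HA %.1f dB, dH %+.1f dB",
          pid, cond, b, h$audibility_eas, h$audibility_ha, h$delta_h))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    write.csv(out, out_csv, row.names = FALSE)
    write_manifest(paste0(tools::file_path_sans_ext(out_csv),
                          "_manifest.json"),
                   "audibility", NA,
                   list(conditions = conditions, bands = bands,
                        level = level, grid = grid,
                        summation_rule = summation_rule),
                   inputs = audiogram_csv,
                   elapsed_s = proc.time()[["elapsed"]] - t0)
    return(invisible(out))
  }
  out
}

#' Behavioural summary statistics per cell
#'
#' Computes p_EAS and the RMS localization error with percentile bootstrap
#' confidence intervals for every participant x condition x band cell of a
#' trial table.
#'
#' @param trial_csv trial CSV path or a trial data.frame.
#' @param out_csv optional output path.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with `peas`, `peas_lo`, `peas_hi`, `erms`,
#'   `erms_lo`, `erms_hi`, `n_valid` per cell.
#' @export
run_metrics <- function(trial_csv, out_csv = NULL, n_boot = 1000,
                        seed = 1) {
  trials <- if (is.data.frame(trial_csv)) trial_csv
            else read_trials(trial_csv)
  set.seed(as.integer(seed))
  key <- interaction(trials$participant_id, trials$condition, trials$band,
                     drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    v <- d[d$heard & !is.na(d$response_az), , drop = FALSE]
    base <- data.frame(participant_id = d$participant_id[1],
                       condition = d$condition[1], band = d$band[1],
                       n_valid = nrow(v), stringsAsFactors = FALSE)
    if (nrow(v) < 2 || n_boot < 1) {
      cbind(base, peas = peas(d), peas_lo = NA, peas_hi = NA,
            erms = rms_error(d), erms_lo = NA, erms_hi = NA)
    } else {
      bp <- bootstrap_ci(v, statistic = peas, n_boot = n_boot)
      be <- bootstrap_ci(v, statistic = rms_error, n_boot = n_boot)
      cbind(base, peas = bp$estimate, peas_lo = bp$lo, peas_hi = bp$hi,
            erms = be$estimate, erms_lo = be$lo, erms_hi = be$hi)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) {
    write.csv(out, out_csv, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Fit the bias model from trial and asymmetry files
#'
#' Joins a trial table with a hearing-asymmetry table into observation
#' cells, fits the hierarchical logistic bias model, and (optionally)
#' writes the posterior summary, the raw draws (long CSV) and the data for
#' a bias-vs-asymmetry figure: observed cell proportions with binomial
#' confidence intervals plus posterior-mean fitted curves.
#'
#' @param trial_csv trial CSV path or data.frame.
#' @param asymmetry_csv asymmetry CSV path or data.frame
#'   (from [run_audibility]).
#' @param out_prefix if non-NULL, writes `<prefix>_posterior.csv`,
#'   `<prefix>_draws.csv`, `<prefix>_curve.csv` and a manifest.
#' @param seed integer seed.
#' @param ... passed to [fit_bias_model] (chains, iter, priors, ...).
#' @return the `"bias_fit"` object, invisibly when written.
#' @export
run_fit <- function(trial_csv, asymmetry_csv, out_prefix = NULL, seed = 1,
                    ...) {
  t0 <- proc.time()[["elapsed"]]
  trials <- if (is.data.frame(trial_csv)) trial_csv
            else read_trials(trial_csv)
  asym <- if (is.data.frame(asymmetry_csv)) asymmetry_csv
          else read.csv(asymmetry_csv, stringsAsFactors = FALSE)
  cells <- cells_from_trials(trials, asym)
  if (nrow(cells) == 0L) stop("no fittable cells after joining inputs")
  fit <- fit_bias_model(cells, seed = seed, ...)
  message(sprintf("[fit] %d cells, %d participants; max split-Rhat %.3f",
                  nrow(cells), length(fit$participants),
                  max(fit$summary$rhat, na.rm = TRUE)))
  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
    write.csv(fit$summary, paste0(out_prefix, "_posterior.csv"),
              row.names = FALSE)
    draws <- as.data.frame(do.call(rbind, lapply(fit$draws, as.matrix)))
    draws$chain <- rep(seq_along(fit$draws),
                       each = nrow(as.matrix(fit$draws[[1]])))
    write.csv(draws, paste0(out_prefix, "_draws.csv"), row.names = FALSE)
    # figure data: observed proportions with exact binomial CIs + curves
    ci <- t(mapply(function(k, n) {
      b <- stats::binom.test(round(k), n)$conf.int
      c(lo = b[1], hi = b[2])
    }, fit$cells$k, fit$cells$n))
    obs <- cbind(fit$cells, p_hat = fit$cells$k / fit$cells$n, ci,
                 p_fit = predict(fit))
    write.csv(obs, paste0(out_prefix, "_curve.csv"), row.names = FALSE)
    write_manifest(paste0(out_prefix, "_manifest.json"), "fit", seed,
                   fit$config,
                   inputs = c(if (!is.data.frame(trial_csv)) trial_csv,
                              if (!is.data.frame(asymmetry_csv))
                                asymmetry_csv),
                   elapsed_s = proc.time()[["elapsed"]] - t0)
    return(invisible(fit))
  }
  fit
}
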