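## The logistic bias-vs-asymmetry model and its hierarchical Bayesian fit.
##
## p_EAS(delta_H) = (1 + exp(-(2 ln 9 / omega) (delta_H - theta_eff)))^-1
##
## omega (dB) is the width: the delta_H range over which p_EAS rises from
## 0.1 to 0.9. theta (dB) is the hearing-aid preference: the delta_H at
## which responses are balanced when the hearing aid is on; theta_eff = 0
## for hearing-aid-off conditions.

#' Predicted implant-side response probability
#'
#' Evaluates the logistic bias model. With `ha_on = FALSE` the curve passes
#' through (0, 0.5); with `ha_on = TRUE` it is shifted so that p = 0.5 at
#' `delta_h = theta`. By the width definition, p = 0.9 at
#' `theta_eff + omega/2` and p = 0.1 at `theta_eff - omega/2`.
#'
#' @param delta_h hearing asymmetry in dB (vectorized).
#' @param omega width parameter in dB, `> 0`.
#' @param theta hearing-aid preference in dB (default 0).
#' @param ha_on logical: is the hearing aid on? `theta` only applies when
#'   `TRUE`. Vectorized over trials/cells.
#' @return probability of an implant-side response, strictly increasing in
#'   `delta_h`.
#' @examples
#' peas_predict(0, omega = 40)                    # 0.5
#' peas_predict(20, omega = 40)                   # 0.9
#' peas_predict(15, omega = 40, theta = 15, ha_on = TRUE)  # 0.5
#' @export
peas_predict <- function(delta_h, omega, theta = 0, ha_on = FALSE) {
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("omega must be positive and finite")
  theta_eff <- ifelse(ha_on, theta, 0)
  1 / (1 + exp(-(2 * log(9) / omega) * (delta_h - theta_eff)))
}

#' Binomial log-likelihood of an observation cell
#'
#' A cell is one participant x condition x band: `k` implant-side responses
#' out of `n` valid trials at hearing asymmetry `delta_h`. The observation
#' model is binomial at the model-predicted probability, clamped away from
#' 0 and 1 for numerical safety.
#'
#' @param cell list or one-row data.frame with `delta_h`, `k`, `n`, `ha_on`.
#' @param omega,theta model parameters.
#' @return log-probability of the cell.
#' @export
cell_log_likelihood <- function(cell, omega, theta = 0) {
  p <- peas_predict(cell$delta_h, omega, theta, cell$ha_on)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dbinom(cell$k, cell$n, p, log = TRUE)
}

# total log-likelihood over a cell table (vectorized over cells)
cells_log_likelihood <- function(cells, omega, theta = 0) {
  sum(cell_log_likelihood(cells, omega, theta))
}

.default_priors <- function() {
  list(mu_log_omega_mean = log(40), mu_log_omega_sd = 1,
       sigma_log_omega_sd = 1,
       mu_theta_mean = 0, mu_theta_sd = 30,
       sigma_theta_sd = 20)
}

.validate_cells <- function(cells) {
  need <- c("delta_h", "k", "n", "ha_on")
  if (!all(need %in% names(cells)))
    stop("cells must have columns: ", paste(need, collapse = ", "))
  if (!"participant_id" %in% names(cells))
    cells$participant_id <- "P1"
  stopifnot(all(cells$k >= 0), all(cells$k <= cells$n), all(cells$n >= 1))
  cells
}

.jags_hier <- "
model {
  for (j in 1:Ncell) {
    eta[j] <- (2 * log(9) / omega[pid[j]]) * (dh[j] - ha[j] * theta[pid[j]])
    k[j] ~ dbin(ilogit(eta[j]), n[j])
  }
  for (i in 1:Npart) {
    lw[i] ~ dnorm(mu_lw, tau_lw)
    omega[i] <- exp(lw[i])
    theta[i] ~ dnorm(mu_th, tau_th)
  }
  mu_lw ~ dnorm(p_mu_lw_mean, 1 / pow(p_mu_lw_sd, 2))
  sigma_lw ~ dnorm(0, 1 / pow(p_sig_lw_sd, 2)) T(0,)
  tau_lw <- 1 / pow(sigma_lw, 2)
  mu_th ~ dnorm(p_mu_th_mean, 1 / pow(p_mu_th_sd, 2))
  sigma_th ~ dnorm(0, 1 / pow(p_sig_th_sd, 2)) T(0,)
  tau_th <- 1 / pow(sigma_th, 2)
  omega_group <- exp(mu_lw)
}
"

.jags_single <- "
model {
  for (j in 1:Ncell) {
    eta[j] <- (2 * log(9) / omega) * (dh[j] - ha[j] * theta)
    k[j] ~ dbin(ilogit(eta[j]), n[j])
  }
  lw ~ dnorm(p_mu_lw_mean, 1 / pow(p_mu_lw_sd, 2))
  omega <- exp(lw)
  theta ~ dnorm(p_mu_th_mean, 1 / pow(p_mu_th_sd, 2))
}
"

#' Fit the hierarchical logistic bias model by MCMC
#'
#' Fits implant-side response counts as binomial draws whose probability
#' follows the logistic bias model, with per-participant parameters
#' `omega_i` (log-normal across participants) and `theta_i` (normal across
#' participants) and group-level location/scale hyperparameters, all
#' sampled simultaneously with JAGS. With a single participant (or
#' `hierarchical = FALSE`) a two-parameter non-hierarchical model with
#' fixed weakly-informative priors is fitted instead, which is exactly the
#' model checked against the dense grid-posterior oracle
#' ([grid_posterior]).
#'
#' Cells where the stimulus was inaudible in both ears carry no behavioural
#' response and must be excluded before fitting (see
#' [cells_from_trials]).
#'
#' @param cells data.frame with columns `participant_id`, `delta_h` (dB),
#'   `k` (implant-side responses), `n` (valid trials), `ha_on` (logical);
#'   optionally `condition`, `band`.
#' @param hierarchical force the hierarchical (TRUE) or single-level
#'   (FALSE) model; default chooses by the number of participants.
#' @param chains,adapt,warmup,iter MCMC configuration: number of chains,
#'   adaptation steps, burn-in and kept iterations per chain.
#' @param thin thinning interval.
#' @param seed integer; chain RNGs are seeded deterministically from it.
#' @param priors named list overriding elements of the default prior
#'   configuration (`mu_log_omega_mean`, `mu_log_omega_sd`,
#'   `sigma_log_omega_sd`, `mu_theta_mean`, `mu_theta_sd`,
#'   `sigma_theta_sd`).
#' @param quiet suppress JAGS progress output.
#' @return object of class `"bias_fit"` with posterior draws
#'   (`coda::mcmc.list`), a summary table (posterior mean, 95%-HDI and
#'   split-Rhat per parameter), the cell table, and the configuration.
#'   A warning is raised if any split-Rhat exceeds 1.05.
#' @export
fit_bias_model <- function(cells, hierarchical = NULL,
                           chains = 4, adapt = 500, warmup = 2000,
                           iter = 2000, thin = 1, seed = 1,
                           priors = list(), quiet = TRUE) {
  cells <- .validate_cells(cells)
  pr <- utils::modifyList(.default_priors(), priors)
  pids <- unique(cells$participant_id)
  if (is.null(hierarchical)) hierarchical <- length(pids) > 1L
  if (hierarchical && length(pids) < 1L) stop("no participants")

  data <- list(Ncell = nrow(cells), dh = cells$delta_h,
               ha = as.numeric(cells$ha_on), k = cells$k, n = cells$n,
               p_mu_lw_mean = pr$mu_log_omega_mean,
               p_mu_lw_sd = pr$mu_log_omega_sd,
               p_mu_th_mean = pr$mu_theta_mean,
               p_mu_th_sd = pr$mu_theta_sd)
  if (hierarchical) {
    data$pid <- match(cells$participant_id, pids)
    data$Npart <- length(pids)
    data$p_sig_lw_sd <- pr$sigma_log_omega_sd
    data$p_sig_th_sd <- pr$sigma_theta_sd
    monitor <- c("omega", "theta", "mu_lw", "sigma_lw", "mu_th", "sigma_th",
                 "omega_group")
    model_str <- .jags_hier
  } else {
    monitor <- c("omega", "theta")
    model_str <- .jags_single
  }

  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) %% 1000000L) * 1000L + ch))

  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = data,
                            inits = inits, n.chains = chains,
                            n.adapt = adapt, quiet = quiet)
    update(jm, warmup, progress.bar = "none")
    rjags::coda.samples(jm, monitor, n.iter = iter, thin = thin,
                        progress.bar = "none")
  }
  draws <- if (quiet) suppressWarnings(run()) else run()

  summ <- summarize_posterior(draws)
  if (hierarchical) {
    is_pp <- grepl("^(omega|theta)\\[\\d+\\]$", summ$parameter)
    summ$participant_id <- NA_character_
    summ$participant_id[is_pp] <- pids[as.integer(
      sub("^(omega|theta)\\[(\\d+)\\]$", "\\2", summ$parameter[is_pp]))]
  } else {
    summ$participant_id <- ifelse(summ$parameter %in% c("omega", "theta"),
                                  pids[1], NA)
  }
  bad <- summ$parameter[!is.na(summ$rhat) & summ$rhat > 1.05]
  if (length(bad))
    warning("possible non-convergence (split-Rhat > 1.05) for: ",
            paste(bad, collapse = ", "))

  structure(list(draws = draws, summary = summ, cells = cells,
                 participants = pids, hierarchical = hierarchical,
                 priors = pr, seed = seed,
                 config = list(chains = chains, adapt = adapt,
                               warmup = warmup, iter = iter, thin = thin)),
            class = "bias_fit")
}

# split-half potential scale reduction factor for one parameter
# (chains x iterations matrix, each column one chain)
rhat_split <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  splits <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w == 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# posterior mean, 95%-HDI and split-Rhat for every monitored parameter
summarize_posterior <- function(draws, mass = 0.95) {
  stopifnot(inherits(draws, "mcmc.list") || is.matrix(draws))
  if (inherits(draws, "mcmc.list")) {
    pars <- colnames(draws[[1]])
    per_chain <- lapply(draws, as.matrix)
  } else {
    pars <- colnames(draws)
    per_chain <- list(draws)
  }
  rows <- lapply(pars, function(p) {
    chains_mat <- sapply(per_chain, function(m) m[, p])
    x <- as.vector(chains_mat)
    h <- hdi(x, mass = mass)
    data.frame(parameter = p, mean = mean(x),
               hdi_low = h[1], hdi_high = h[2],
               rhat = rhat_split(as.matrix(chains_mat)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Highest-density interval of a posterior sample
#'
#' The shortest contiguous interval containing the requested posterior
#' mass, found by a sorted-sample sweep.
#'
#' @param samples numeric vector of posterior draws (>= 100 recommended).
#' @param mass probability mass in (0, 1), default 0.95.
#' @return numeric length-2 `c(lo, hi)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  s <- sort(samples[is.finite(samples)])
  n <- length(s)
  if (n < 2) return(c(s[1], s[1]))
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[(m + 1):n] - s[1:(n - m)]
  i <- which.min(widths)
  c(s[i], s[i + m])
}

#' Dense grid posterior for the single-participant model
#'
#' Brute-force evaluation of the two-parameter posterior (log-width,
#' preference) on a dense rectangular grid, under exactly the priors of the
#' single-level model in [fit_bias_model]. Serves as an independent oracle
#' for the MCMC fit: posterior means of `omega` and `theta` computed by
#' numerical integration over the grid.
#'
#' @param cells cell table for one participant (see [fit_bias_model]).
#' @param n_grid grid points per dimension (default 500).
#' @param log_omega_range,theta_range grid extents; defaults cover the
#'   priors' effective support.
#' @param priors prior overrides as in [fit_bias_model].
#' @return list with `omega_mean`, `theta_mean`, grid vectors and the
#'   posterior probability matrix.
#' @export
grid_posterior <- function(cells, n_grid = 500,
                           log_omega_range = NULL, theta_range = NULL,
                           priors = list()) {
  cells <- .validate_cells(cells)
  if (length(unique(cells$participant_id)) != 1L)
    stop("grid posterior is defined for a single participant")
  pr <- utils::modifyList(.default_priors(), priors)
  if (is.null(log_omega_range))
    log_omega_range <- pr$mu_log_omega_mean + c(-4, 4) * pr$mu_log_omega_sd
  if (is.null(theta_range))
    theta_range <- pr$mu_theta_mean + c(-4, 4) * pr$mu_theta_sd
  lw <- seq(log_omega_range[1], log_omega_range[2], length.out = n_grid)
  th <- seq(theta_range[1], theta_range[2], length.out = n_grid)
  lp <- matrix(0, n_grid, n_grid)        # rows: lw, cols: th
  slope <- outer(2 * log(9) / exp(lw), rep(1, n_grid))
  th_mat <- outer(rep(1, n_grid), th)
  for (j in seq_len(nrow(cells))) {
    eta <- slope * (cells$delta_h[j] - th_mat * as.numeric(cells$ha_on[j]))
    p <- 1 / (1 + exp(-eta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    lp <- lp + dbinom(cells$k[j], cells$n[j], p, log = TRUE)
  }
  lp <- lp + outer(dnorm(lw, pr$mu_log_omega_mean, pr$mu_log_omega_sd,
                         log = TRUE),
                   dnorm(th, pr$mu_theta_mean, pr$mu_theta_sd, log = TRUE),
                   "+")
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  list(omega_mean = sum(rowSums(post) * exp(lw)),
       theta_mean = sum(colSums(post) * th),
       log_omega = lw, theta = th, posterior = post)
}
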