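#' Posterior predictive replication of the observed log abundances
#'
#' For every retained draw, simulates replicated log observations around the
#' draw's latent states under the observation model (including the inflated
#' polar-cod variance in the anomaly year) and summarises the replicate
#' envelope per year and species.
#'
#' @param draws a `gbs_draws` object from [sample_posterior()].
#' @param data the [fish_data()] table the model was fitted to.
#' @param seed RNG seed for the replicate noise.
#' @return list with `yrep` (draws x years x 3 array of replicated log
#'   observations), `summary` (data.frame: year, species, median and 2.5/97.5
#'   percentiles of the replicates, observed log value) and `coverage`
#'   (fraction of observed values inside the central 95% envelope).
#' @export
posterior_predictive <- function(draws, data, seed = 1L) {
  inp <- gbs_model_inputs(data, draws$priors %||% prior_config())
  S <- nrow(draws$params)
  set.seed(derive_seed(seed, 97L))
  sd_arr <- array(NA_real_, c(S, inp$T, 3))
  s_obs <- sqrt(draws$params[, paste0("r_obs_", gbs_species)]) *
    draws$params[, paste0("sigma_proc_", gbs_species)]
  for (i in 1:3) sd_arr[, , i] <- s_obs[, i]
  if (inp$i95 > 0)
    sd_arr[, inp$i95, 3] <- sqrt(s_obs[, 3]^2 + draws$params[, "sigma_pcod_1995"]^2)
  yrep <- draws$states + array(rnorm(length(sd_arr)), dim(sd_arr)) * sd_arr
  qs <- apply(yrep, c(2, 3), quantile, probs = c(0.5, 0.025, 0.975))
  summary <- data.frame(
    year = rep(inp$years, 3),
    species = rep(gbs_species, each = inp$T),
    median = as.vector(qs[1, , ]),
    lo = as.vector(qs[2, , ]),
    hi = as.vector(qs[3, , ]),
    observed = as.vector(inp$y))
  obs <- !is.na(summary$observed)
  coverage <- mean(summary$observed[obs] >= summary$lo[obs] &
                     summary$observed[obs] <= summary$hi[obs])
  list(yrep = yrep, summary = summary, coverage = coverage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian R-squared per draw and species
#'
#' Variance-explained measure on the process scale: for each draw, the
#' deterministic one-step predictions of the Gompertz map (using the draw's
#' latent states as regressors) are compared with the draw's process-error
#' variance, `R2 = Var(pred) / (Var(pred) + sigma2_proc)`. Values lie in
#' [0, 1]; 1 means the deterministic map explains all latent variation.
#'
#' @param draws a `gbs_draws` object.
#' @param data the fitted [fish_data()] table.
#' @return draws x 3 matrix of R-squared values (cod, cap, pcod).
#' @export
bayesian_r2 <- function(draws, data) {
  inp <- gbs_model_inputs(data, draws$priors %||% prior_config())
  S <- nrow(draws$params)
  out <- matrix(NA_real_, S, 3, dimnames = list(NULL, gbs_species))
  for (s in seq_len(S)) {
    x <- draws$states[s, , ]
    a <- draws$params[s, gbs_coef_names]
    pred <- x[2:inp$T, , drop = FALSE] - gbs_residuals(x, a, inp)
    vp <- apply(pred, 2, var)
    s2 <- draws$params[s, paste0("sigma_proc_", gbs_species)]^2
    tot <- vp + s2
    if (any(tot <= 0)) stop("bayesian_r2: zero total variance")
    out[s, ] <- vp / tot
  }
  out
}

#' Standard deviations of the non-z-scored explanatory variables
#'
#' Sample SDs of the log abundances and log herring biomass over the modelled
#' window, used by [report_table()] to scale coefficients into effect
#' strengths. Intercepts are scaled by the SD of the response species' log
#' abundance.
#'
#' @param data a [fish_data()] table.
#' @return named vector with elements `cod`, `cap`, `pcod`, `herring`.
#' @export
explanatory_sds <- function(data) {
  validate_fish_data(data)
  c(cod = sd(log(data$cod), na.rm = TRUE),
    cap = sd(log(data$cap), na.rm = TRUE),
    pcod = sd(log(data$pcod), na.rm = TRUE),
    herring = sd(log(data$herring)))
}

#' Posterior summary table with effect strengths
#'
#' Median and 5%/95% posterior quantiles for every model parameter, plus the
#' effect strength of each regression coefficient: the median divided by the
#' SD of its explanatory variable for species log abundances, log herring and
#' (for intercepts) the response log abundance; z-scored covariates (st, ice,
#' F) keep the median unchanged.
#'
#' @param draws a `gbs_draws` object.
#' @param explanatory_sds named vector as returned by [explanatory_sds()];
#'   when `NULL` the effect-strength column is filled only for z-scored
#'   covariates.
#' @return data.frame: `parameter`, `median`, `q5`, `q95`, `effect_strength`.
#' @export
report_table <- function(draws, explanatory_sds = NULL) {
  qs <- t(apply(draws$params, 2, quantile, probs = c(0.5, 0.05, 0.95)))
  out <- data.frame(parameter = rownames(qs), median = qs[, 1],
                    q5 = qs[, 2], q95 = qs[, 3],
                    effect_strength = NA_real_, row.names = NULL)
  for (k in seq_len(nrow(out))) {
    p <- out$parameter[k]
    if (!p %in% gbs_coef_names) next
    parts <- strsplit(sub("^a_", "", p), "_")[[1]]
    response <- parts[1]
    regressor <- parts[2]
    if (regressor %in% c("st", "ice", "F")) {
      out$effect_strength[k] <- effect_strength(out$median[k], is_zscored = TRUE)
    } else if (!is.null(explanatory_sds)) {
      key <- if (regressor == "0") response else regressor
      out$effect_strength[k] <- effect_strength(out$median[k],
                                                explanatory_sds[[key]])
    }
  }
  out
}

#' Sensitivity refits over alternative variance-ratio prior centres
#'
#' Refits the model with the observation/process variance-ratio prior centred
#' at each requested value (the published analysis compares centres 1, 2 and
#' 3) and tabulates the posterior coefficient medians side by side.
#'
#' @param data a [fish_data()] table.
#' @param config a [sampler_config()].
#' @param centers ratio-prior centres to compare.
#' @param priors baseline [prior_config()]; only `ratio_mean` is varied.
#' @return list with `fits` (one `gbs_draws` per centre) and `table`
#'   (data.frame of posterior medians, one column per centre).
#' @export
ratio_prior_sensitivity <- function(data, config = sampler_config(4, 3000, 1500, 5),
                                    centers = c(1, 2, 3),
                                    priors = prior_config()) {
  fits <- lapply(centers, function(ctr) {
    pr <- priors
    pr$ratio_mean <- ctr
    sample_posterior(data, pr, config)
  })
  names(fits) <- paste0("ratio_", centers)
  meds <- vapply(fits, function(f) apply(f$params, 2, median),
                 numeric(ncol(fits[[1]]$params)))
  table <- data.frame(parameter = rownames(meds), meds, row.names = NULL,
                      check.names = FALSE)
  names(table)[-1] <- sprintf("median_ratio_%g", centers)
  list(fits = fits, table = table)
}
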