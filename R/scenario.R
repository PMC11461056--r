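#' Fit the log-linear sea-ice trend
#'
#' Ordinary least squares of `ln(ice)` on calendar year. The residuals are
#' retained for reuse in the scenario construction, so that a counterfactual
#' ice series can keep the observed year-to-year variation pattern.
#'
#' @param climate a data.frame with columns `year` and `ice` (> 0), e.g. a
#'   [fish_data()] table or [climate_series()] output.
#' @return object of class `gbs_ice_trend`: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `r_squared`, `residuals`, `fitted`, `years`, `ln_ice`.
#' @export
fit_ice_trend <- function(climate) {
  year <- climate$year
  ice <- climate$ice
  if (length(year) < 3) stop("fit_ice_trend: need at least 3 years")
  if (length(unique(year)) < 2) stop("fit_ice_trend: degenerate year vector")
  if (any(is.na(ice)) || any(ice <= 0))
    stop("fit_ice_trend: ice must be positive and complete")
  fit <- lm(log(ice) ~ year)
  se <- sqrt(diag(vcov(fit)))
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 r_squared = summary(fit)$r.squared,
                 residuals = unname(fit$residuals),
                 fitted = unname(fit$fitted.values),
                 years = year, ln_ice = log(ice)),
            class = "gbs_ice_trend")
}

#' Scenario specification for the low-sea-ice hindcast
#'
#' @param residual_shrink fraction by which the ice-trend residuals are
#'   reduced before being re-added around the scenario trend line
#'   (`0 <= residual_shrink < 1`; the published scenario uses 0.30).
#' @param n_boot bootstrap replicates for the ice-to-temperature mapping.
#' @param boot_type `"parameter"` draws slope/intercept from normals centred
#'   at the OLS estimates with their SEs; `"residual"` resamples regression
#'   residuals instead.
#' @param split_year last year of the "early" (strongly perturbed) period in
#'   median slope comparisons.
#' @param seed RNG seed for the bootstrap.
#' @return object of class `gbs_scenario_spec`.
#' @export
scenario_spec <- function(residual_shrink = 0.30, n_boot = 100,
                          boot_type = c("parameter", "residual"),
                          split_year = 2005, seed = 1L) {
  if (residual_shrink < 0 || residual_shrink >= 1)
    stop("scenario_spec: residual_shrink must be in [0, 1)")
  if (n_boot < 1) stop("scenario_spec: n_boot must be >= 1")
  structure(list(residual_shrink = residual_shrink, n_boot = as.integer(n_boot),
                 boot_type = match.arg(boot_type),
                 split_year = split_year, seed = as.integer(seed)),
            class = "gbs_scenario_spec")
}

#' Construct the low-sea-ice scenario series
#'
#' Builds a counterfactual ice series with a flattened trend: the new slope is
#' the slope of the line joining the recorded `ln(ice)` in the first year to
#' the original trend's prediction for the last year; the new intercept makes
#' the line pass through the recorded `ln(ice)` of the last year. The original
#' trend residuals, shrunk by `residual_shrink`, are added around the new line
#' to keep the observed variation pattern, and the first year is reset to its
#' recorded value. A warning is issued if, in the strongly perturbed first
#' half of the window, the scenario exceeds the observed series on the log
#' scale (the construction is meant to stay below the high-ice years).
#'
#' @param climate data.frame with `year` and `ice` used to fit `fit`.
#' @param fit a [fit_ice_trend()] object derived from the same series.
#' @param spec a [scenario_spec()].
#' @return data.frame with columns `year` and `ice` (natural scale), with
#'   attributes `new_slope`, `new_intercept` and `ln_ice`.
#' @export
build_scenario_ice <- function(climate, fit, spec = scenario_spec()) {
  years <- fit$years
  if (!identical(as.numeric(years), as.numeric(climate$year)) ||
      max(abs(fit$ln_ice - log(climate$ice))) > 1e-8)
    stop("build_scenario_ice: fit was not derived from this series")
  n <- length(years)
  y0 <- years[1]
  y1 <- years[n]
  if (y1 == y0) stop("build_scenario_ice: end year equals start year")
  pred_end <- fit$intercept + fit$slope * y1
  new_slope <- (pred_end - fit$ln_ice[1]) / (y1 - y0)
  new_intercept <- fit$ln_ice[n] - new_slope * y1
  ln_scen <- new_intercept + new_slope * years +
    (1 - spec$residual_shrink) * fit$residuals
  ln_scen[1] <- fit$ln_ice[1]
  early <- years <= years[1] + (y1 - y0) / 2
  early[c(1, n)] <- FALSE
  if (any(ln_scen[early] > fit$ln_ice[early]))
    warning("build_scenario_ice: scenario exceeds the observed ln(ice) in ",
            sum(ln_scen[early] > fit$ln_ice[early]),
            " strongly perturbed year(s)")
  structure(data.frame(year = years, ice = exp(ln_scen)),
            new_slope = new_slope, new_intercept = new_intercept,
            ln_ice = ln_scen)
}

#' Fit the temperature-on-ice linear relationship
#'
#' OLS of z-scored sea temperature on the z-scored sea-ice index, with
#' coefficient standard errors retained for the scenario bootstrap. In the
#' Barents Sea series the two are strongly anti-correlated (r ~ -0.75).
#'
#' @param climate a [fish_data()] table or any data.frame with `st` and `ice`
#'   columns (z-scoring is applied internally), or [climate_series()] output
#'   with `z_st`/`z_ice` columns.
#' @return object of class `gbs_st_ice`: `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `sigma`, `r_squared`, `residuals`.
#' @export
fit_st_ice <- function(climate) {
  if (all(c("z_st", "z_ice") %in% names(climate))) {
    z_st <- climate$z_st
    z_ice <- climate$z_ice
  } else {
    z_st <- zscore(climate$st)
    z_ice <- zscore(climate$ice)
  }
  if (length(z_st) < 3) stop("fit_st_ice: need at least 3 years")
  fit <- lm(z_st ~ z_ice)
  se <- sqrt(diag(vcov(fit)))
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 slope_se = unname(se[2]), intercept_se = unname(se[1]),
                 sigma = summary(fit)$sigma,
                 r_squared = summary(fit)$r.squared,
                 residuals = unname(fit$residuals)),
            class = "gbs_st_ice")
}

#' Map a scenario ice series to a scenario temperature series
#'
#' Propagates the uncertainty of the temperature-on-ice regression: per
#' bootstrap replicate a slope and intercept are drawn from independent
#' normals centred at the OLS estimates with their standard errors
#' (`boot_type = "parameter"`), or the fitted line is perturbed with resampled
#' regression residuals (`boot_type = "residual"`); temperature is predicted
#' for every year and the per-year median across replicates is returned.
#'
#' @param scenario_ice z-scored scenario ice values (one per year).
#' @param fit a [fit_st_ice()] object.
#' @param n_boot number of bootstrap replicates.
#' @param seed RNG seed (the mapping is deterministic given the seed).
#' @param boot_type see [scenario_spec()].
#' @return z-scored scenario temperature, one value per year.
#' @export
ice_to_st <- function(scenario_ice, fit, n_boot = 100, seed = 1L,
                      boot_type = c("parameter", "residual")) {
  boot_type <- match.arg(boot_type)
  if (n_boot < 1) stop("ice_to_st: n_boot must be >= 1")
  set.seed(derive_seed(seed, 31L))
  n <- length(scenario_ice)
  preds <- matrix(NA_real_, n_boot, n)
  for (b in seq_len(n_boot)) {
    if (boot_type == "parameter") {
      sl <- rnorm(1, fit$slope, fit$slope_se)
      ic <- rnorm(1, fit$intercept, fit$intercept_se)
      preds[b, ] <- ic + sl * scenario_ice
    } else {
      preds[b, ] <- fit$intercept + fit$slope * scenario_ice +
        sample(fit$residuals, n, replace = TRUE)
    }
  }
  apply(preds, 2, median)
}

#' Build the full scenario climate table for the hindcast
#'
#' Convenience wrapper running the whole scenario-construction chain:
#' ice-trend fit, scenario ice, z-scoring with the centring/scaling of the
#' observed series (so model coefficients remain applicable), and the
#' bootstrap ice-to-temperature mapping.
#'
#' @param data the observed [fish_data()] table.
#' @param spec a [scenario_spec()].
#' @return data.frame with `year`, `ice`, `st_z` and `ice_z` (`st_z`/`ice_z`
#'   on the z-score scale of the observed series; no natural-scale `st` is
#'   produced because the mapping is fitted on the standardized scale).
#' @export
build_scenario_climate <- function(data, spec = scenario_spec()) {
  validate_fish_data(data)
  trend <- fit_ice_trend(data)
  scen_ice <- build_scenario_ice(data, trend, spec)
  z_obs <- zscore(data$ice)
  ice_z <- (scen_ice$ice - attr(z_obs, "center")) / attr(z_obs, "scale")
  st_fit <- fit_st_ice(data)
  st_z <- ice_to_st(ice_z, st_fit, n_boot = spec$n_boot, seed = spec$seed,
                    boot_type = spec$boot_type)
  data.frame(year = data$year, ice = scen_ice$ice, ice_z = ice_z, st_z = st_z)
}

#' Extract per-draw process errors from fitted draws
#'
#' Reconstructs the structural process errors implied by each draw's latent
#' states and coefficients: `eps_t = x_t - gompertz_step(x_{t-1}, ...)`, so
#' the reconstruction identity holds exactly by definition. These are the
#' errors reinjected by [hindcast()].
#'
#' @param draws a `gbs_draws` object (latent states included).
#' @param data the fitted [fish_data()] table.
#' @return draws x (T-1) x 3 array of process errors.
#' @export
extract_process_errors <- function(draws, data) {
  if (is.null(draws$states)) stop("extract_process_errors: draws carry no latent states")
  inp <- gbs_model_inputs(data, draws$priors %||% prior_config())
  S <- nrow(draws$params)
  eps <- array(NA_real_, c(S, inp$T - 1, 3),
               dimnames = list(NULL, inp$years[-1], gbs_species))
  for (s in seq_len(S))
    eps[s, , ] <- gbs_residuals(draws$states[s, , ], draws$params[s, gbs_coef_names], inp)
  eps
}

#' Stationarity filter over posterior draws
#'
#' Classifies each draw by the spectral radius of its implied lag-1
#' transition matrix (see [transition_matrix()]): a draw is kept when all
#' eigenvalues lie strictly inside the unit circle, so its deterministic
#' dynamics cannot diverge under constant covariates.
#'
#' @param draws a `gbs_draws` object, or a matrix of coefficient draws with
#'   (at least) the 21 coefficient columns.
#' @return logical vector, `TRUE` = stationary (kept).
#' @export
stationarity_filter <- function(draws) {
  params <- if (inherits(draws, "gbs_draws")) draws$params else as.matrix(draws)
  apply(params, 1, function(v) {
    B <- transition_matrix(v[gbs_coef_names])
    max(Mod(eigen(B, only.values = TRUE)$values)) < 1
  })
}

#' Hindcast re-simulation under a covariate scenario
#'
#' Implements the process-error-reinjection hindcast: for every retained draw,
#' the three-species trajectory is re-simulated forward from the draw's
#' first-year latent state using the draw's own coefficients and extracted
#' process errors, but with the scenario climate covariates in place of the
#' observed ones (herring and fishing series stay at their observed values).
#' Within each year the cod equation is evaluated first and the newly
#' simulated cod value feeds the capelin and polar-cod equations, exactly as
#' in the fitted model. With `scenario = NULL` (identity scenario) every
#' draw's original latent trajectory is reproduced.
#'
#' Non-stationary draws (see [stationarity_filter()]) are excluded from the
#' summaries; their trajectories are still returned.
#'
#' @param draws a `gbs_draws` object.
#' @param data the fitted [fish_data()] table.
#' @param scenario output of [build_scenario_climate()] (columns `year`,
#'   `ice_z`, `st_z`), or `NULL` for the identity scenario.
#' @param eps process errors to reinject; defaults to
#'   [extract_process_errors()] of the same draws.
#' @return object of class `gbs_hindcast`: `scenario` and `baseline`
#'   (draws x T x 3 arrays of log abundances), `stationary` (mask),
#'   `summary` (per year/species medians and 2.5/97.5 percentiles of both
#'   runs over the stationary draws), `years`.
#' @export
hindcast <- function(draws, data, scenario = NULL, eps = NULL) {
  inp <- gbs_model_inputs(data, draws$priors %||% prior_config())
  S <- nrow(draws$params)
  T <- inp$T
  ## difference between the supplied process errors and the draws' own
  ## extracted errors; zero when the draws' errors are reinjected unchanged
  de <- array(0, c(S, T - 1, 3))
  if (!is.null(eps)) {
    if (!identical(as.integer(dim(eps)), as.integer(c(S, T - 1, 3))))
      stop("hindcast: eps has wrong dimensions")
    de <- eps - extract_process_errors(draws, data)
  }
  zST <- inp$zST
  zIce <- inp$zIce
  if (!is.null(scenario)) {
    if (!all(c("st_z", "ice_z") %in% names(scenario)))
      stop("hindcast: scenario must have st_z and ice_z columns")
    if (length(scenario$ice_z) != T)
      stop("hindcast: scenario covariates must cover the full year range (",
           T, " years)")
    zST <- scenario$st_z
    zIce <- scenario$ice_z
  }

  a <- draws$params[, gbs_coef_names, drop = FALSE]
  traj <- array(NA_real_, c(S, T, 3), dimnames = dimnames(draws$states))
  traj[, 1, ] <- draws$states[, 1, ]
  ## linear predictors of the three equations, vectorised across draws; the
  ## scenario trajectory is computed as baseline + (scenario predictor -
  ## baseline predictor), which is algebraically the reinjection recursion
  ## x_t = pred + eps_t but reproduces the baseline bit-exactly under the
  ## identity scenario, even for explosive (non-stationary) draws
  pred_cod <- function(x1, x2, x3, st_lag)
    a[, "a_cod_cod"] * x1 + a[, "a_cod_cap"] * x2 + a[, "a_cod_pcod"] * x3 +
      a[, "a_cod_st"] * st_lag
  pred_cap <- function(x2, x3, cod_t, st_lag)
    a[, "a_cap_cap"] * x2 + a[, "a_cap_pcod"] * x3 + a[, "a_cap_cod"] * cod_t +
      a[, "a_cap_st"] * st_lag
  pred_pcod <- function(x2, x3, cod_t, ice_t)
    a[, "a_pcod_pcod"] * x3 + a[, "a_pcod_cap"] * x2 + a[, "a_pcod_cod"] * cod_t +
      a[, "a_pcod_ice"] * ice_t
  ## (intercepts, herring and fishing terms are identical in both runs and
  ## cancel from the difference)
  for (t in 2:T) {
    b1 <- draws$states[, t - 1, 1]; b2 <- draws$states[, t - 1, 2]
    b3 <- draws$states[, t - 1, 3]
    s1 <- traj[, t - 1, 1]; s2 <- traj[, t - 1, 2]; s3 <- traj[, t - 1, 3]
    cod <- draws$states[, t, 1] + de[, t - 1, 1] +
      (pred_cod(s1, s2, s3, zST[t - 1]) -
         pred_cod(b1, b2, b3, inp$zST[t - 1]))
    cap <- draws$states[, t, 2] + de[, t - 1, 2] +
      (pred_cap(s2, s3, cod, zST[t - 1]) -
         pred_cap(b2, b3, draws$states[, t, 1], inp$zST[t - 1]))
    pcod <- draws$states[, t, 3] + de[, t - 1, 3] +
      (pred_pcod(s2, s3, cod, zIce[t]) -
         pred_pcod(b2, b3, draws$states[, t, 1], inp$zIce[t]))
    traj[, t, 1] <- cod; traj[, t, 2] <- cap; traj[, t, 3] <- pcod
  }

  mask <- stationarity_filter(draws)
  summarise <- function(arr, run) {
    qs <- apply(arr[mask, , , drop = FALSE], c(2, 3), quantile,
                probs = c(0.5, 0.025, 0.975))
    data.frame(run = run, year = rep(inp$years, 3),
               species = rep(gbs_species, each = T),
               median = as.vector(qs[1, , ]), lo = as.vector(qs[2, , ]),
               hi = as.vector(qs[3, , ]))
  }
  structure(list(scenario = traj, baseline = draws$states, stationary = mask,
                 years = inp$years,
                 summary = rbind(summarise(draws$states, "baseline"),
                                 summarise(traj, "scenario"))),
            class = "gbs_hindcast")
}

#' Through-origin slope comparison of scenario vs baseline medians
#'
#' For each species, regresses the per-year scenario medians on the baseline
#' medians through the origin, separately for the years up to `split_year`
#' (when the scenario perturbs the covariates most) and after it, and reports
#' both slopes and their difference (early minus late). A slope of 1 means
#' the scenario leaves the medians unchanged.
#'
#' @param baseline,scenario T x 3 matrices of per-year median abundances
#'   (same years, natural or log scale), or a `gbs_hindcast` object passed as
#'   `baseline` (then `scenario` is ignored and medians of exponentiated
#'   trajectories over stationary draws are used).
#' @param years calendar years of the rows.
#' @param split_year last year of the early period.
#' @return data.frame: `species`, `slope_early`, `slope_late`, `slope_diff`.
#' @export
compare_medians <- function(baseline, scenario = NULL, years = NULL,
                            split_year = 2005) {
  if (inherits(baseline, "gbs_hindcast")) {
    hc <- baseline
    years <- hc$years
    keep <- hc$stationary
    baseline <- apply(exp(hc$baseline[keep, , , drop = FALSE]), c(2, 3), median)
    scenario <- apply(exp(hc$scenario[keep, , , drop = FALSE]), c(2, 3), median)
  }
  baseline <- as.matrix(baseline)
  scenario <- as.matrix(scenario)
  if (is.null(years)) stop("compare_medians: years must be supplied")
  if (nrow(baseline) != length(years) || !identical(dim(baseline), dim(scenario)))
    stop("compare_medians: baseline and scenario must cover the same years")
  early <- years <= split_year
  if (!any(early) || all(early)) stop("compare_medians: empty period")
  slope0 <- function(x, y) sum(x * y) / sum(x * x)
  out <- data.frame(species = gbs_species, slope_early = NA_real_,
                    slope_late = NA_real_, slope_diff = NA_real_)
  for (i in 1:3) {
    se <- slope0(baseline[early, i], scenario[early, i])
    sl <- slope0(baseline[!early, i], scenario[!early, i])
    out[i, 2:4] <- c(se, sl, se - sl)
  }
  out
}
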