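#' Joint log density of the state-space model
#'
#' Sum of (i) the multivariate-normal transition densities of the latent log
#' abundances around the deterministic Gompertz map, (ii) the initial-state
#' prior densities, (iii) the independent normal observation densities of the
#' log survey estimates around the latent states (the polar-cod observation
#' in the anomaly year uses variance `sigma2_obs_pcod + sigma_pcod_1995^2`;
#' missing observations contribute nothing), and (iv) the prior densities of
#' the parameters. This is the target density of [sample_posterior()] up to
#' the constant of the correlation-matrix prior.
#'
#' @param params a [model_params()] object.
#' @param states T x 3 matrix of latent log abundances (cod, cap, pcod).
#' @param data a [fish_data()] table with T rows.
#' @param priors a [prior_config()].
#' @return scalar log density.
#' @export
joint_log_density <- function(params, states, data, priors = prior_config()) {
  validate_model_params(params)
  inp <- gbs_model_inputs(data, priors)
  states <- as.matrix(states)
  if (nrow(states) != inp$T || ncol(states) != 3)
    stop("joint_log_density: states must be a ", inp$T, " x 3 matrix")
  if (any(!is.finite(states))) stop("joint_log_density: non-finite states")

  Sigma <- sigma_proc_matrix(params)
  U <- tryCatch(chol(Sigma),
                error = function(e) stop("joint_log_density: Sigma_proc is not positive definite"))
  logdet <- 2 * sum(log(diag(U)))

  ## (i) process transitions
  E <- gbs_residuals(states, params$a, inp)
  W <- backsolve(U, t(E), transpose = TRUE)  # U' W = E'
  lp <- -0.5 * nrow(E) * (3 * log(2 * pi) + logdet) - 0.5 * sum(W * W)

  ## (ii) initial states
  lp <- lp + sum(dnorm(states[1, ], inp$x0mean, inp$x0sd, log = TRUE))

  ## (iii) observations
  s_obs <- sigma_obs(params)
  sd_mat <- matrix(s_obs, inp$T, 3, byrow = TRUE)
  if (inp$i95 > 0)
    sd_mat[inp$i95, 3] <- sqrt(s_obs[3]^2 + params$sigma_pcod_1995^2)
  ok <- !is.na(inp$y)
  lp <- lp + sum(dnorm(inp$y[ok], states[ok], sd_mat[ok], log = TRUE))

  ## (iv) priors
  lp + gbs_log_prior(params, priors)
}

#' Effect strength of a posterior coefficient
#'
#' Scales a coefficient's posterior median by the standard deviation of its
#' explanatory variable, making effects comparable across regressors measured
#' on different scales. Covariates that already enter the model z-scored
#' (sea temperature, sea ice, fishing) are returned unchanged.
#'
#' @param coef_median posterior median of the coefficient.
#' @param explanatory_sd standard deviation of the explanatory variable
#'   (ignored when `is_zscored`).
#' @param is_zscored was the explanatory variable z-scored before fitting?
#' @return `coef_median / explanatory_sd`, or `coef_median` when `is_zscored`.
#' @export
effect_strength <- function(coef_median, explanatory_sd = NULL,
                            is_zscored = FALSE) {
  if (is_zscored) return(coef_median)
  if (is.null(explanatory_sd) || !is.finite(explanatory_sd) ||
      explanatory_sd <= 0)
    stop("effect_strength: explanatory_sd must be a positive number")
  coef_median / explanatory_sd
}
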