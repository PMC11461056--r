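#' Prior and observation-model configuration
#'
#' Weakly informative defaults: Normal(0, `a_sd`) on all regression
#' coefficients, half-Normal(0, `sigma_sd`) on the process-error SDs and on
#' the extra anomaly-year observation SD, a uniform (LKJ shape 1) prior over
#' valid 3x3 correlation matrices, and an informative Normal(`ratio_mean`,
#' `ratio_sd`) prior, truncated at 0, on the observation/process variance
#' ratio of each species (`sigma2_obs_i = r_obs_i * sigma2_proc_i`). The
#' initial latent state of each species has an independent normal prior
#' centred at its first log observation with SD `x0_sd`.
#'
#' `anomaly_year` designates the survey year whose polar-cod observation
#' carries an extra error term (the unrealistically low 1995 estimate in the
#' Barents Sea series); set to `NULL` for none.
#'
#' @param a_sd prior SD of the regression coefficients.
#' @param sigma_sd scale of the half-normal priors on SD parameters.
#' @param ratio_mean,ratio_sd centre and SD of the truncated-normal
#'   variance-ratio prior (sensitivity runs use centres 1 and 3).
#' @param x0_sd prior SD of the initial log-abundance states.
#' @param anomaly_year calendar year of the inflated polar-cod observation
#'   error, or `NULL`.
#' @return object of class `gbs_priors`.
#' @export
prior_config <- function(a_sd = 5, sigma_sd = 2, ratio_mean = 2,
                         ratio_sd = 0.5, x0_sd = 5, anomaly_year = 1995) {
  stopifnot(a_sd > 0, sigma_sd > 0, ratio_sd > 0, ratio_mean > 0, x0_sd > 0)
  structure(list(a_sd = a_sd, sigma_sd = sigma_sd, ratio_mean = ratio_mean,
                 ratio_sd = ratio_sd, x0_sd = x0_sd,
                 anomaly_year = if (is.null(anomaly_year)) NULL
                                else as.integer(anomaly_year)),
            class = "gbs_priors")
}

## joint log prior density of a parameter set (normalized, so that oracle
## implementations can match it exactly); the correlation-matrix prior is
## uniform over the positive-definite region (LKJ shape 1), contributing a
## constant that is omitted
gbs_log_prior <- function(params, priors) {
  lp <- sum(dnorm(params$a, 0, priors$a_sd, log = TRUE))
  lp <- lp + sum(log(2) + dnorm(params$sigma_proc, 0, priors$sigma_sd, log = TRUE))
  lp <- lp + sum(dnorm(params$r_obs, priors$ratio_mean, priors$ratio_sd, log = TRUE) -
                   pnorm(priors$ratio_mean / priors$ratio_sd, log.p = TRUE))
  if (!is.null(priors$anomaly_year))  # otherwise the extra SD is not a parameter
    lp <- lp + log(2) + dnorm(params$sigma_pcod_1995, 0, priors$sigma_sd, log = TRUE)
  lp
}

#' Draw from the observation/process variance-ratio prior
#'
#' Samples the truncated-at-zero normal prior placed on the ratio of the
#' observation-error variance to the process-error variance. With the default
#' centre 2 and SD 0.5 the truncation point lies 4 SDs below the centre, so
#' the prior mean exceeds the centre by only ~7e-5.
#'
#' @param n number of draws.
#' @param priors a [prior_config()].
#' @return numeric vector of positive ratio draws.
#' @export
sample_ratio_prior <- function(n, priors = prior_config()) {
  out <- numeric(0)
  while (length(out) < n) {
    z <- rnorm(n - length(out), priors$ratio_mean, priors$ratio_sd)
    out <- c(out, z[z > 0])
  }
  out
}
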