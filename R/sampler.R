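#' MCMC sampler configuration
#'
#' Defaults follow the full analysis protocol: four independent chains of
#' 30000 iterations each, the first 20000 discarded as burn-in, and thinning
#' by 10, retaining `4 * (30000 - 20000) / 10 = 4000` draws. Scaled-down
#' settings (e.g. `sampler_config(4, 3000, 1500, 5)`) are appropriate for
#' simulation studies and tests.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain (< `n_iter`).
#' @param thin thinning factor; `(n_iter - n_burnin)` must be divisible by it.
#' @param seed master seed; per-chain seeds are derived deterministically.
#' @return object of class `gbs_sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_iter = 30000, n_burnin = 20000,
                           thin = 10, seed = 1L) {
  if (n_chains < 1) stop("sampler_config: n_chains must be >= 1")
  if (n_burnin >= n_iter) stop("sampler_config: n_burnin must be < n_iter")
  if (thin < 1) stop("sampler_config: thin must be >= 1")
  if ((n_iter - n_burnin) %% thin != 0)
    stop("sampler_config: (n_iter - n_burnin) must be divisible by thin")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "gbs_sampler_config")
}

#' Number of retained posterior draws implied by a sampler configuration
#'
#' @param config a [sampler_config()].
#' @return `n_chains * (n_iter - n_burnin) / thin`.
#' @export
n_retained <- function(config) {
  with(config, as.integer(n_chains * (n_iter - n_burnin) / thin))
}

#' Sample the joint posterior of the three-species model
#'
#' Runs the blocked Gibbs sampler: an exact generalised-least-squares draw of
#' all 21 regression coefficients given the latent states, a forward-filter
#' backward-sample draw of the full latent log-abundance trajectory given the
#' parameters, and univariate slice updates for the process-error SDs,
#' variance ratios, process-error correlations and the anomaly-year
#' observation SD. Chains are initialised at per-equation least-squares
#' estimates on the (interpolated) observed series, jittered independently
#' per chain.
#'
#' @param data a [fish_data()] table (at least 4 years).
#' @param priors a [prior_config()].
#' @param config a [sampler_config()].
#' @param rhat_bound convergence bound: a warning is issued (and recorded in
#'   the diagnostics) if any parameter's split-Rhat exceeds it.
#' @return object of class `gbs_draws`: retained draws with chain/iteration
#'   labels. Components: `params` (draws x 31 named matrix), `states`
#'   (draws x T x 3 array of latent log abundances), `chain`, `iteration`,
#'   `years`, `scaling` (covariate centring/scaling), `priors`, `config` and
#'   `diagnostics` (split-Rhat per parameter, retained-draw count,
#'   convergence flag).
#' @export
sample_posterior <- function(data, priors = prior_config(),
                             config = sampler_config(), rhat_bound = 1.05) {
  inp <- gbs_model_inputs(data, priors)
  if (inp$T < 4) stop("sample_posterior: need at least 4 years of data")
  keep_each <- (config$n_iter - config$n_burnin) %/% config$thin
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$seed, ch))
    init <- gbs_chain_init(inp, priors)
    res <- .gbs_chain_cpp(inp$y, inp$lnH, inp$zST, inp$zIce, inp$zF, inp$i95,
                          inp$x0mean, inp$x0sd,
                          priors$a_sd, priors$sigma_sd, priors$ratio_mean,
                          priors$ratio_sd,
                          config$n_iter, config$n_burnin, config$thin,
                          init$a, init$sigma, init$r, init$b, init$s95, init$x)
    chains[[ch]] <- res
  }
  params <- do.call(rbind, lapply(chains, `[[`, "params"))
  colnames(params) <- gbs_param_names
  states <- array(NA_real_, c(nrow(params), inp$T, 3),
                  dimnames = list(NULL, inp$years, gbs_species))
  for (ch in seq_len(config$n_chains)) {
    rows <- (ch - 1) * keep_each + seq_len(keep_each)
    states[rows, , ] <- aperm(chains[[ch]]$states, c(3, 1, 2))
  }
  draws <- structure(list(
    params = params, states = states,
    chain = rep(seq_len(config$n_chains), each = keep_each),
    iteration = as.integer(unlist(lapply(chains, `[[`, "iter"))),
    years = inp$years, scaling = inp$scaling, anomaly_index = inp$i95,
    priors = priors, config = config), class = "gbs_draws")
  draws$diagnostics <- gbs_diagnostics(draws, rhat_bound)
  if (!draws$diagnostics$converged)
    warning(sprintf("sample_posterior: max split-Rhat %.4f exceeds bound %.3f (%s)",
                    draws$diagnostics$max_rhat, rhat_bound,
                    draws$diagnostics$worst_param))
  draws
}

## initial values: per-equation OLS on the linearly interpolated log series,
## with independent jitter so chains start overdispersed
gbs_chain_init <- function(inp, priors) {
  y0 <- inp$y
  for (i in 1:3)
    y0[, i] <- approx(seq_len(inp$T), y0[, i], xout = seq_len(inp$T), rule = 2)$y
  x <- y0 + matrix(rnorm(3 * inp$T, 0, 0.05), inp$T, 3)
  Z <- gbs_designs(x, inp)
  a <- numeric(21)
  sig <- numeric(3)
  for (i in 1:3) {
    fit <- lm.fit(Z[[i]], x[2:inp$T, i])
    a[(i - 1) * 7 + 1:7] <- fit$coefficients + rnorm(7, 0, 0.3)
    sig[i] <- max(sd(fit$residuals), 0.05) * exp(rnorm(1, 0, 0.3))
  }
  list(a = a, sigma = sig,
       r = pmax(rnorm(3, priors$ratio_mean, priors$ratio_sd), 0.2),
       b = runif(3, 0.35, 0.65),
       s95 = abs(rnorm(1, 0.5, 0.2)), x = x)
}

#' @export
print.gbs_draws <- function(x, ...) {
  cat("gbs_draws:", nrow(x$params), "retained draws (",
      max(x$chain), "chains ), years",
      min(x$years), "-", max(x$years), "\n")
  if (!is.null(x$diagnostics$max_rhat))
    cat("max split-Rhat:", format(x$diagnostics$max_rhat, digits = 4),
        if (isTRUE(x$diagnostics$converged)) "(converged)"
        else "(NOT converged)", "\n")
  invisible(x)
}

#' Extract the retained parameter draws as a matrix
#'
#' @param x a `gbs_draws` object.
#' @param ... unused.
#' @return draws x parameters numeric matrix.
#' @export
as.matrix.gbs_draws <- function(x, ...) x$params

#' Latent log-abundance draws
#'
#' @param draws a `gbs_draws` object.
#' @return draws x years x 3 array of latent log abundances.
#' @export
latent_states <- function(draws) draws$states

#' Write posterior draws as a tidy CSV
#'
#' One row per draw and parameter (`chain`, `iteration`, `name`, `value`),
#' including the latent states as `x[<year>,<species>]` rows.
#'
#' @param draws a `gbs_draws` object.
#' @param path output CSV path.
#' @param provenance optional named list written as `# key: value` headers.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path, provenance = NULL) {
  S <- nrow(draws$params)
  xn <- as.vector(outer(draws$years, gbs_species,
                        function(y, s) sprintf("x[%d,%s]", y, s)))
  st <- matrix(draws$states, nrow = S)
  long <- data.frame(
    chain = rep(draws$chain, times = ncol(draws$params) + length(xn)),
    iteration = rep(draws$iteration, times = ncol(draws$params) + length(xn)),
    name = rep(c(colnames(draws$params), xn), each = S),
    value = c(draws$params, st))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ",
                      vapply(provenance, format, "")), con)
  write.csv(long, con, row.names = FALSE)  # names contain commas: keep quotes
  invisible(path)
}

#' Read posterior draws from a tidy CSV
#'
#' Inverse of [write_draws_csv()]. The sampler configuration, priors and
#' covariate scaling are not stored in the CSV; where needed they must be
#' supplied to downstream functions via the original data table.
#'
#' @param path CSV path written by [write_draws_csv()].
#' @return object of class `gbs_draws` (without `priors`/`config`).
#' @export
read_draws_csv <- function(path) {
  long <- read.csv(path, comment.char = "#")
  nms <- unique(long$name)
  S <- sum(long$name == nms[1])
  wide <- matrix(long$value, nrow = S, dimnames = list(NULL, nms))
  pn <- intersect(gbs_param_names, nms)
  xn <- grep("^x\\[", nms, value = TRUE)
  info <- do.call(rbind, regmatches(xn, regexec("^x\\[(-?\\d+),(\\w+)\\]$", xn)))
  years <- sort(unique(as.integer(info[, 2])))
  states <- array(NA_real_, c(S, length(years), 3),
                  dimnames = list(NULL, years, gbs_species))
  for (k in seq_along(xn))
    states[, as.character(info[k, 2]), info[k, 3]] <- wide[, xn[k]]
  structure(list(params = wide[, pn, drop = FALSE], states = states,
                 chain = long$chain[long$name == nms[1]],
                 iteration = long$iteration[long$name == nms[1]],
                 years = years), class = "gbs_draws")
}
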