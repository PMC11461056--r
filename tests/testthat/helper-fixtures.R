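## shared fixtures and small fitted objects, built once per test run

.gbs_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .gbs_cache)) assign(key, force(expr), .gbs_cache)
  get(key, .gbs_cache)
}

tiny_fixture <- function() memo("tiny", make_fixture("tiny8"))

default32_fixture <- function() memo("default32", make_fixture("default32"))

## quick posterior fit on the tiny fixture (no anomaly year in its window)
tiny_fit <- function() memo("tiny_fit", {
  fx <- tiny_fixture()
  suppressWarnings(sample_posterior(
    fx$data, prior_config(anomaly_year = NULL),
    sampler_config(n_chains = 2, n_iter = 800, n_burnin = 400, thin = 4,
                   seed = 42), rhat_bound = Inf))
})

## a fabricated draws object with known parameter rows, for tests that need
## exact control over every draw
fake_draws <- function(param_rows, states, years,
                       priors = prior_config(anomaly_year = NULL)) {
  stopifnot(is.matrix(param_rows),
            identical(colnames(param_rows), gompertzbs:::gbs_param_names))
  structure(list(params = param_rows, states = states,
                 chain = rep(1L, nrow(param_rows)),
                 iteration = seq_len(nrow(param_rows)),
                 years = years, priors = priors,
                 diagnostics = list()), class = "gbs_draws")
}

## flatten a gbs_params object into a named draw row
params_to_row <- function(p) {
  setNames(c(p$a, p$sigma_proc, p$r_obs,
             p$R_proc[1, 2], p$R_proc[2, 3], p$R_proc[1, 3],
             p$sigma_pcod_1995),
           gompertzbs:::gbs_param_names)
}

## small fully specified fish_data table for hand computations
toy_data <- function(T = 4, seed = 7, start_year = 1990) {
  set.seed(seed)
  fish_data(year = start_year + seq_len(T) - 1,
            cod = exp(rnorm(T, 6, 0.3)), cap = exp(rnorm(T, 4, 0.4)),
            pcod = exp(rnorm(T, 5, 0.3)), herring = exp(rnorm(T, 1.6, 0.2)),
            st = rnorm(T, 4, 0.5), ice = exp(rnorm(T, 0.5, 0.4)),
            f_cod = runif(T, 0.3, 0.7), f_cap = runif(T, 0.05, 0.4),
            f_pcod = runif(T, 0.01, 0.1))
}
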