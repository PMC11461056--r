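test_that("process-error reconstruction satisfies the defining identity", {
  dr <- tiny_fit()
  fx <- tiny_fixture()
  eps <- extract_process_errors(dr, fx$data)
  inp <- gompertzbs:::gbs_model_inputs(fx$data, dr$priors)
  T <- inp$T
  set.seed(41)
  for (s in sample(nrow(dr$params), 20)) {
    a <- dr$params[s, gompertzbs:::gbs_coef_names]
    x <- dr$states[s, , ]
    for (t in 2:T) {
      mu <- oracle_step(a, x[t - 1, ], x[t, 1], inp$lnH[t - 1], inp$lnH[t],
                        inp$zST[t - 1], inp$zIce[t], inp$zF[t - 1, ])
      expect_equal(unname(x[t, ] - mu), unname(eps[s, t - 1, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("the generator's drawn errors are recovered exactly from its output", {
  fx <- default32_fixture()
  row <- params_to_row(fx$truth$params)
  dr <- fake_draws(matrix(row, 1, dimnames = list(NULL, names(row))),
                   array(fx$truth$latent, c(1, nrow(fx$data), 3)),
                   fx$data$year)
  eps <- extract_process_errors(dr, fx$data)
  expect_equal(unname(eps[1, , ]), unname(fx$truth$eps), tolerance = 1e-10)
})

test_that("identity scenario reproduces every draw's latent trajectory", {
  dr <- tiny_fit()
  fx <- tiny_fixture()
  hc <- hindcast(dr, fx$data)   # scenario = NULL: observed covariates
  expect_lt(max(abs(hc$scenario - hc$baseline)), 1e-10)
  ## also when the scenario table equals the observed covariates exactly
  scen <- data.frame(year = fx$data$year,
                     ice_z = as.numeric(zscore(fx$data$ice)),
                     st_z = as.numeric(zscore(fx$data$st)))
  hc2 <- hindcast(dr, fx$data, scen)
  expect_lt(max(abs(hc2$scenario - hc2$baseline)), 1e-10)
})

test_that("a single hand-computable draw is re-simulated correctly (T = 3)", {
  d <- toy_data(T = 3, seed = 43)
  p <- model_params(a_cod_0 = 0.5, a_cod_cod = 0.5, a_cod_st = 0.3,
                    a_cap_0 = 1, a_cap_cap = 0.4, a_cap_cod = -0.5,
                    a_cap_st = 0.2,
                    a_pcod_0 = 0.8, a_pcod_pcod = 0.3, a_pcod_cod = 0.1,
                    a_pcod_ice = 0.4)
  row <- params_to_row(p)
  x0 <- c(1, 2, 3)
  eps <- array(c(0.1, -0.2, 0.05, 0.3, -0.1, 0.2), c(1, 2, 3))
  states <- array(0, c(1, 3, 3)); states[1, 1, ] <- x0
  dr <- fake_draws(matrix(row, 1, dimnames = list(NULL, names(row))),
                   states, d$year)
  scen <- data.frame(year = d$year, ice_z = c(0.5, -0.5, 1),
                     st_z = c(0.2, 0.4, -0.3))
  hc <- hindcast(dr, d, scen, eps = eps)
  ## forward simulation by hand
  x <- matrix(NA, 3, 3); x[1, ] <- x0
  for (t in 2:3) {
    cod <- 0.5 + 0.5 * x[t - 1, 1] + 0.3 * scen$st_z[t - 1] + eps[1, t - 1, 1]
    cap <- 1 + 0.4 * x[t - 1, 2] - 0.5 * cod + 0.2 * scen$st_z[t - 1] +
      eps[1, t - 1, 2]
    pcod <- 0.8 + 0.3 * x[t - 1, 3] + 0.1 * cod + 0.4 * scen$ice_z[t] +
      eps[1, t - 1, 3]
    x[t, ] <- c(cod, cap, pcod)
  }
  expect_equal(unname(hc$scenario[1, , ]), x, tolerance = 1e-12)
})

test_that("raising scenario temperature raises capelin in the first perturbed year", {
  dr <- tiny_fit()
  fx <- tiny_fixture()
  ## force a positive capelin temperature effect in every draw and shut the
  ## indirect route through cod so the one-step monotonicity is exact
  dr2 <- dr
  dr2$params[, "a_cap_st"] <- abs(dr$params[, "a_cap_st"]) + 0.1
  dr2$params[, "a_cod_st"] <- 0
  scen <- data.frame(year = fx$data$year,
                     ice_z = as.numeric(zscore(fx$data$ice)),
                     st_z = as.numeric(zscore(fx$data$st)))
  base <- hindcast(dr2, fx$data, scen)
  scen_hi <- scen
  scen_hi$st_z[3] <- scen_hi$st_z[3] + 1   # perturbs year-4 responses first
  pert <- hindcast(dr2, fx$data, scen_hi)
  expect_true(all(pert$scenario[, 4, 2] > base$scenario[, 4, 2]))
  ## years before the perturbation are untouched
  expect_equal(pert$scenario[, 1:3, ], base$scenario[, 1:3, ])
})

test_that("hindcast validates scenario coverage and masks non-stationary draws", {
  dr <- tiny_fit()
  fx <- tiny_fixture()
  bad <- data.frame(year = fx$data$year[-1],
                    ice_z = rnorm(7), st_z = rnorm(7))
  expect_error(hindcast(dr, fx$data, bad), "full year range")
  hc <- hindcast(dr, fx$data)
  expect_equal(length(hc$stationary), nrow(dr$params))
  expect_identical(hc$stationary, stationarity_filter(dr))
  expect_true(all(c("run", "year", "species", "median", "lo", "hi") %in%
                    names(hc$summary)))
})

test_that("a reduced-ice scenario with positive ice effect lowers polar cod", {
  ## full-pipeline directional check on synthetic data: the generating system
  ## has a_pcod_ice > 0, so fitting the model and re-simulating under
  ## uniformly reduced ice (and correspondingly raised temperature through
  ## the fitted ice-temperature linkage) should pull the polar-cod medians
  ## below the baseline medians in most perturbed years
  fx <- default32_fixture()
  dr <- suppressWarnings(sample_posterior(
    fx$data, prior_config(),
    sampler_config(2, 2500, 500, 4, seed = 11), rhat_bound = Inf))
  st_fit <- fit_st_ice(fx$data)
  ice_z <- as.numeric(zscore(fx$data$ice)) - 1        # one SD less ice
  scen <- data.frame(year = fx$data$year, ice_z = ice_z,
                     st_z = ice_to_st(ice_z, st_fit, n_boot = 100, seed = 2))
  expect_true(all(scen$st_z > ice_to_st(ice_z + 1, st_fit, 100, 2)))  # warmer
  hc <- hindcast(dr, fx$data, scen)
  keep <- hc$stationary
  perturbed <- 2:length(hc$years)
  base_med <- apply(hc$baseline[keep, perturbed, 3], 2, median)
  scen_med <- apply(hc$scenario[keep, perturbed, 3], 2, median)
  expect_gt(mean(scen_med < base_med), 0.5)
})
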