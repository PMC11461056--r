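test_that("replicated observations collapse onto the latent states as obs SD -> 0", {
  fx <- tiny_fixture()
  p <- default_generating_params(sigma_proc = rep(1e-2, 3), r_obs = rep(1e-12, 3))
  row <- params_to_row(p)
  states <- array(rep(log(as.matrix(fx$data[c("cod", "cap", "pcod")])), each = 2),
                  c(2, nrow(fx$data), 3))
  dr <- fake_draws(rbind(row, row), states, fx$data$year)
  pp <- posterior_predictive(dr, fx$data, seed = 1)
  expect_lt(max(abs(pp$yrep - states)), 1e-5)
  expect_lt(max(abs(pp$summary$hi - pp$summary$lo)), 1e-5)
})

test_that("envelope widths increase monotonically with the variance ratio", {
  fx <- tiny_fixture()
  states <- array(rep(log(as.matrix(fx$data[c("cod", "cap", "pcod")])), each = 50),
                  c(50, nrow(fx$data), 3))
  width <- vapply(c(0.5, 2, 8), function(r) {
    p <- default_generating_params(r_obs = rep(r, 3))
    rows <- matrix(rep(params_to_row(p), each = 50), 50,
                   dimnames = list(NULL, gompertzbs:::gbs_param_names))
    pp <- posterior_predictive(fake_draws(rows, states, fx$data$year),
                               fx$data, seed = 2)
    mean(pp$summary$hi - pp$summary$lo)
  }, 0)
  expect_true(all(diff(width) > 0))
})

test_that("posterior predictive envelope covers observations at the nominal rate", {
  ## with draws at the generating truth, ~95% of observations fall inside the
  ## central 95% envelope; averaged over years/species/replicates
  fx <- default32_fixture()
  p <- fx$truth$params
  rows <- matrix(rep(params_to_row(p), each = 200), 200,
                 dimnames = list(NULL, gompertzbs:::gbs_param_names))
  states <- array(rep(fx$truth$latent, each = 200), c(200, nrow(fx$data), 3))
  cov <- vapply(1:8, function(k) {
    posterior_predictive(fake_draws(rows, states, fx$data$year), fx$data,
                         seed = 100 + k)$coverage
  }, 0)
  expect_gt(mean(cov), 0.90)
  expect_lte(mean(cov), 1.0)
})

test_that("Bayesian R2 equals the hand-computed variance ratio and its limits", {
  fx <- tiny_fixture()
  T <- nrow(fx$data)
  p <- fx$truth$params
  row <- params_to_row(p)
  states <- array(fx$truth$latent, c(1, T, 3))
  dr <- fake_draws(matrix(row, 1, dimnames = list(NULL, names(row))),
                   states, fx$data$year)
  r2 <- bayesian_r2(dr, fx$data)
  expect_true(all(r2 >= 0 & r2 <= 1))
  ## oracle: fitted deterministic predictions are latent minus process errors
  pred <- fx$truth$latent[2:T, ] - fx$truth$eps
  for (i in 1:3) {
    expected <- var(pred[, i]) / (var(pred[, i]) + p$sigma_proc[i]^2)
    expect_equal(unname(r2[1, i]), expected, tolerance = 1e-10)
  }
  ## constant predictions give R2 = 0; vanishing process error gives R2 -> 1
  p0 <- model_params(sigma_proc = c(0.2, 0.2, 0.2))  # all coefficients zero
  st0 <- array(0.5, c(1, T, 3))
  dr0 <- fake_draws(matrix(params_to_row(p0), 1,
                           dimnames = list(NULL, names(row))),
                    st0, fx$data$year)
  expect_equal(unname(bayesian_r2(dr0, fx$data)[1, ]), c(0, 0, 0))
  p1 <- p; p1$sigma_proc <- rep(1e-9, 3)
  dr1 <- fake_draws(matrix(params_to_row(p1), 1,
                           dimnames = list(NULL, names(row))),
                    states, fx$data$year)
  expect_true(all(bayesian_r2(dr1, fx$data) > 0.999999))
})

test_that("report table quantiles match a direct quantile oracle", {
  set.seed(21)
  fx <- tiny_fixture()
  dr <- tiny_fit()
  ## constant draws: median = q5 = q95 = c
  rows <- matrix(rep(params_to_row(default_generating_params()), each = 3), 3,
                 dimnames = list(NULL, gompertzbs:::gbs_param_names))
  tbl_const <- report_table(fake_draws(rows, array(0, c(3, 8, 3)), fx$data$year))
  expect_equal(tbl_const$median, tbl_const$q5)
  expect_equal(tbl_const$median, tbl_const$q95)

  ## N(0.61, 0.2) draws on one coefficient
  rows2 <- matrix(rep(params_to_row(default_generating_params()), each = 4000),
                  4000, dimnames = list(NULL, gompertzbs:::gbs_param_names))
  rows2[, "a_cod_cod"] <- rnorm(4000, 0.61, 0.2)
  tbl <- report_table(fake_draws(rows2, array(0, c(4000, 8, 3)), fx$data$year))
  row <- tbl[tbl$parameter == "a_cod_cod", ]
  expect_lt(abs(row$median - 0.61), 0.02)
  expect_lt(abs(row$q5 - (0.61 - qnorm(0.95) * 0.2)), 0.03)
  expect_lt(abs(row$q95 - (0.61 + qnorm(0.95) * 0.2)), 0.03)
  ## oracle on the real fit: quantile() per column
  tbl_fit <- report_table(dr, explanatory_sds(fx$data))
  for (pn in c("a_cap_cod", "sigma_proc_cod", "rho_cod_cap")) {
    expect_equal(tbl_fit$median[tbl_fit$parameter == pn],
                 unname(quantile(dr$params[, pn], 0.5)), tolerance = 1e-12)
    expect_equal(tbl_fit$q5[tbl_fit$parameter == pn],
                 unname(quantile(dr$params[, pn], 0.05)), tolerance = 1e-12)
  }
})

test_that("effect strengths in the table follow the z-scoring rule", {
  fx <- tiny_fixture()
  dr <- tiny_fit()
  sds <- explanatory_sds(fx$data)
  tbl <- report_table(dr, sds)
  med <- function(pn) tbl$median[tbl$parameter == pn]
  eff <- function(pn) tbl$effect_strength[tbl$parameter == pn]
  ## z-scored covariates: effect strength equals the median exactly
  for (pn in c("a_cod_st", "a_cap_F", "a_pcod_ice"))
    expect_equal(eff(pn), med(pn))
  ## species and herring terms: median / explanatory SD
  expect_equal(eff("a_cod_cap"), med("a_cod_cap") / sds[["cap"]])
  expect_equal(eff("a_cap_herring"), med("a_cap_herring") / sds[["herring"]])
  ## intercepts: scaled by the response species' log-abundance SD
  expect_equal(eff("a_pcod_0"), med("a_pcod_0") / sds[["pcod"]])
  ## non-coefficient rows carry no effect strength
  expect_true(is.na(tbl$effect_strength[tbl$parameter == "sigma_proc_cod"]))
})
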