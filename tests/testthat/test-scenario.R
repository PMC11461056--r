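test_that("ice trend recovers a noiseless log-linear series exactly", {
  years <- 1986:2017
  ice <- exp(128.3733 - 0.0642 * years)
  fit <- suppressWarnings(fit_ice_trend(data.frame(year = years, ice = ice)))
  expect_equal(fit$slope, -0.0642, tolerance = 1e-9)
  expect_equal(fit$intercept, 128.3733, tolerance = 1e-6)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(fit$fitted + fit$residuals, log(ice), tolerance = 1e-12)
})

test_that("ice trend is an OLS fit: slope recovery and permutation invariance", {
  set.seed(31)
  years <- 1990:2019
  res <- rnorm(30, 0, 0.3)
  ice <- exp(60 - 0.03 * years + res)
  d <- data.frame(year = years, ice = ice)
  fit <- fit_ice_trend(d)
  ## oracle: closed-form simple-regression slope
  slope_oracle <- sum((years - mean(years)) * (log(ice) - mean(log(ice)))) /
    sum((years - mean(years))^2)
  expect_equal(fit$slope, slope_oracle, tolerance = 1e-12)
  expect_lt(abs(fit$slope - (-0.03)), 2 * fit$slope_se)
  expect_lt(abs(sum(fit$residuals)), 1e-10)
  perm <- sample(30)
  fit2 <- fit_ice_trend(d[perm, ])
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$r_squared, fit$r_squared)
  expect_error(fit_ice_trend(data.frame(year = c(1, 1, 1), ice = c(1, 2, 3))),
               "degenerate")
})

test_that("scenario ice construction matches a step-by-step hand computation", {
  years <- 2000:2009
  res <- c(0.05, -0.12, 0.20, 0.03, -0.25, 0.10, 0.08, -0.06, 0.15, -0.18)
  res <- res - mean(res) - (years - mean(years)) *
    sum((years - mean(years)) * res) / sum((years - mean(years))^2)
  ln_ice <- 41 - 0.02 * years + res   # residuals orthogonal to the trend
  d <- data.frame(year = years, ice = exp(ln_ice))
  fit <- fit_ice_trend(d)
  expect_equal(fit$residuals, res, tolerance = 1e-10)
  scen <- build_scenario_ice(d, fit, scenario_spec(residual_shrink = 0.30))
  ## hand computation of the construction
  pred_end <- fit$intercept + fit$slope * 2009
  new_slope <- (pred_end - ln_ice[1]) / (2009 - 2000)
  new_int <- ln_ice[10] - new_slope * 2009
  expected <- new_int + new_slope * years + 0.7 * res
  expected[1] <- ln_ice[1]
  expect_equal(log(scen$ice), expected, tolerance = 1e-10)
  expect_equal(attr(scen, "new_slope"), new_slope, tolerance = 1e-12)
  ## the new line passes through the recorded end value (up to its residual)
  expect_equal(new_int + new_slope * 2009, ln_ice[10], tolerance = 1e-12)
})

test_that("identity configuration reproduces the original series exactly", {
  ## an exactly log-linear series: the anchors already lie on the trend line,
  ## so the new line coincides with the old one and the scenario is the
  ## original series; with a negative slope the output is monotone decreasing
  years <- 2000:2009
  ln_ice <- 5 - 0.01 * years
  d <- data.frame(year = years, ice = exp(ln_ice))
  fit <- suppressWarnings(fit_ice_trend(d))   # noiseless: exact fit
  scen <- build_scenario_ice(d, fit, scenario_spec(residual_shrink = 0))
  expect_equal(log(scen$ice), ln_ice, tolerance = 1e-10)
  expect_equal(attr(scen, "new_slope"), fit$slope, tolerance = 1e-10)
  expect_true(all(diff(scen$ice) < 0))
})

test_that("residual shrinkage scales scenario dispersion by exactly 1 - s", {
  set.seed(33)
  years <- 1986:2017
  ice <- exp(61 - 0.03 * years + rnorm(32, 0, 0.25))
  d <- data.frame(year = years, ice = ice)
  fit <- fit_ice_trend(d)
  for (s in c(0.30, 0.5, 0.9)) {
    scen <- suppressWarnings(build_scenario_ice(d, fit, scenario_spec(residual_shrink = s)))
    new_line <- attr(scen, "new_intercept") + attr(scen, "new_slope") * years
    scen_res <- log(scen$ice) - new_line
    ratio <- sd(scen_res[-1]) / sd(fit$residuals[-1])   # start year is anchored
    expect_equal(ratio, 1 - s, tolerance = 1e-10)
  }
})

test_that("temperature-on-ice fit returns exact coefficients and SE scaling", {
  years <- 1986:2015
  z_ice <- as.numeric(zscore(sin(years / 3) + years * 0.001))
  z_st <- 0.05 - 0.75 * z_ice
  fit <- suppressWarnings(fit_st_ice(data.frame(z_st = z_st, z_ice = z_ice)))
  expect_equal(fit$slope, -0.75, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.05, tolerance = 1e-10)
  expect_lt(fit$slope_se, 1e-8)
  ## doubling residuals doubles coefficient SEs
  set.seed(35)
  e <- rnorm(30, 0, 0.3); e <- e - mean(e) - z_ice * sum(z_ice * e) / sum(z_ice^2)
  f1 <- fit_st_ice(data.frame(z_st = z_st + e, z_ice = z_ice))
  f2 <- fit_st_ice(data.frame(z_st = z_st + 2 * e, z_ice = z_ice))
  expect_equal(f2$slope_se, 2 * f1$slope_se, tolerance = 1e-8)
  expect_equal(f2$intercept_se, 2 * f1$intercept_se, tolerance = 1e-8)
})

test_that("a synthetic anti-correlated climate pair yields a negative slope", {
  set.seed(36)
  n <- 200
  z_ice <- rnorm(n)
  z_st <- -0.75 * z_ice + rnorm(n, 0, 0.66)   # correlation ~ -0.75
  fit <- fit_st_ice(data.frame(z_st = z_st, z_ice = z_ice))
  expect_lt(fit$slope, 0)
  expect_lt(abs(fit$slope - (-0.75)), 3 * fit$slope_se)
})

test_that("the ice-to-temperature bootstrap collapses and converges correctly", {
  fit <- structure(list(slope = -0.75, intercept = 0.05, slope_se = 0,
                        intercept_se = 0, sigma = 0.3,
                        residuals = rnorm(30, 0, 0.3)), class = "gbs_st_ice")
  ice <- seq(-2, 2, length.out = 11)
  ## zero SEs: output is the deterministic line for any n_boot
  for (nb in c(1, 7, 100))
    expect_equal(ice_to_st(ice, fit, n_boot = nb, seed = 2),
                 0.05 - 0.75 * ice, tolerance = 1e-12)
  ## reproducible under a fixed seed
  fit$slope_se <- 0.12; fit$intercept_se <- 0.11
  a <- ice_to_st(ice, fit, n_boot = 1, seed = 5)
  expect_identical(a, ice_to_st(ice, fit, n_boot = 1, seed = 5))
  expect_false(identical(a, ice_to_st(ice, fit, n_boot = 1, seed = 6)))
  ## medians converge to the deterministic line as n_boot grows
  big <- ice_to_st(ice, fit, n_boot = 20000, seed = 7)
  expect_lt(max(abs(big - (0.05 - 0.75 * ice))), 0.02)
  ## residual-resampling mode also runs and converges to the line
  bigr <- ice_to_st(ice, fit, n_boot = 20000, seed = 8, boot_type = "residual")
  expect_lt(max(abs(bigr - (0.05 - 0.75 * ice))), 0.05)
})

test_that("stationarity filter classifies canonical cases", {
  rows <- rbind(
    params_to_row(model_params(a_cod_cod = 0.5, a_cap_cap = 0.5, a_pcod_pcod = 0.5)),
    params_to_row(model_params(a_cod_cod = 1.2)),
    params_to_row(default_generating_params()))
  expect_equal(unname(stationarity_filter(rows)), c(TRUE, FALSE, TRUE))
})

test_that("spectral-radius classification agrees with a long-simulation oracle", {
  set.seed(38)
  n_draws <- 200
  rows <- matrix(NA_real_, n_draws, 31,
                 dimnames = list(NULL, gompertzbs:::gbs_param_names))
  for (k in seq_len(n_draws)) {
    a <- setNames(numeric(21), gompertzbs:::gbs_coef_names)
    a[c("a_cod_cod", "a_cap_cap", "a_pcod_pcod")] <- runif(3, 0.2, 1.25)
    a[c("a_cod_cap", "a_cod_pcod", "a_cap_pcod", "a_pcod_cap")] <- rnorm(4, 0, 0.3)
    a[c("a_cap_cod", "a_pcod_cod")] <- rnorm(2, 0, 0.4)
    rows[k, ] <- params_to_row(model_params(a = a))
  }
  keep <- stationarity_filter(rows)
  radius <- apply(rows, 1, function(v) {
    B <- transition_matrix(v[gompertzbs:::gbs_coef_names])
    max(Mod(eigen(B, only.values = TRUE)$values))
  })
  ## oracle: iterate the deterministic map 1e4 steps from a fixed start under
  ## constant covariates and test boundedness (vectorised across draws)
  B11 <- rows[, "a_cod_cod"]; B12 <- rows[, "a_cod_cap"]; B13 <- rows[, "a_cod_pcod"]
  g2 <- rows[, "a_cap_cod"]; g3 <- rows[, "a_pcod_cod"]
  A22 <- rows[, "a_cap_cap"]; A23 <- rows[, "a_cap_pcod"]
  A32 <- rows[, "a_pcod_cap"]; A33 <- rows[, "a_pcod_pcod"]
  x1 <- rep(1, n_draws); x2 <- rep(1, n_draws); x3 <- rep(1, n_draws)
  diverged <- rep(FALSE, n_draws)
  for (t in 1:10000) {
    n1 <- B11 * x1 + B12 * x2 + B13 * x3
    n2 <- A22 * x2 + A23 * x3 + g2 * n1
    n3 <- A32 * x2 + A33 * x3 + g3 * n1
    x1 <- n1; x2 <- n2; x3 <- n3
    if (t %% 500 == 0) {   # flag divergence, park diverged draws at 0
      mag <- pmax(abs(x1), abs(x2), abs(x3))
      cap <- !is.finite(mag) | mag > 1e100
      diverged <- diverged | cap
      x1[cap] <- 0; x2[cap] <- 0; x3[cap] <- 0
    }
  }
  bounded <- !diverged & pmax(abs(x1), abs(x2), abs(x3)) < 1e50
  away <- radius < 0.99 | radius > 1.01
  expect_gt(sum(away), 150)  # the draw design straddles the boundary
  expect_equal(keep[away], bounded[away])
})

test_that("through-origin slope comparison matches its closed form", {
  years <- 1996:2015
  set.seed(39)
  base <- matrix(runif(60, 1, 10), 20, 3)
  ## identity: slopes 1, difference 0
  cmp <- compare_medians(base, base, years, split_year = 2005)
  expect_equal(cmp$slope_early, rep(1, 3))
  expect_equal(cmp$slope_late, rep(1, 3))
  expect_equal(cmp$slope_diff, rep(0, 3))
  ## doubling before the split: slopes 2 and 1, difference 1
  scen <- base
  scen[years <= 2005, ] <- 2 * base[years <= 2005, ]
  cmp2 <- compare_medians(base, scen, years, split_year = 2005)
  expect_equal(cmp2$slope_early, rep(2, 3))
  expect_equal(cmp2$slope_late, rep(1, 3))
  expect_equal(cmp2$slope_diff, rep(1, 3))
  ## random series: slope equals sum(xy)/sum(x^2)
  scen3 <- base + matrix(rnorm(60), 20, 3)
  cmp3 <- compare_medians(base, scen3, years, split_year = 2005)
  e <- years <= 2005
  for (i in 1:3) {
    expect_equal(cmp3$slope_early[i],
                 sum(base[e, i] * scen3[e, i]) / sum(base[e, i]^2))
    expect_equal(cmp3$slope_late[i],
                 sum(base[!e, i] * scen3[!e, i]) / sum(base[!e, i]^2))
  }
  expect_error(compare_medians(base, scen3, years, split_year = 2020),
               "empty period")
})
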