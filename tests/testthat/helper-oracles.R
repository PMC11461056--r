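## independent reference implementations used as oracles; deliberately coded
## with different numerics than the package (eigen decompositions, explicit
## loops, longhand linear combinations)

## multivariate normal log density via eigen decomposition
mvn_logpdf <- function(x, mu, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  if (min(e$values) <= 0) stop("oracle: covariance not positive definite")
  z <- t(e$vectors) %*% (x - mu)
  -0.5 * (length(x) * log(2 * pi) + sum(log(e$values)) + sum(z^2 / e$values))
}

## longhand linear predictors of the three structural equations at year t
## (index into vectors of the full window); covariates on the model scale
oracle_step <- function(a, x_prev, cod_t, lnH_lag, lnH_t, zST_lag, zIce_t, zF_lag) {
  c(a["a_cod_0"] + a["a_cod_cod"] * x_prev[1] + a["a_cod_cap"] * x_prev[2] +
      a["a_cod_pcod"] * x_prev[3] + a["a_cod_herring"] * lnH_lag +
      a["a_cod_st"] * zST_lag + a["a_cod_F"] * zF_lag[1],
    a["a_cap_0"] + a["a_cap_cap"] * x_prev[2] + a["a_cap_pcod"] * x_prev[3] +
      a["a_cap_cod"] * cod_t + a["a_cap_herring"] * lnH_t +
      a["a_cap_st"] * zST_lag + a["a_cap_F"] * zF_lag[2],
    a["a_pcod_0"] + a["a_pcod_pcod"] * x_prev[3] + a["a_pcod_cap"] * x_prev[2] +
      a["a_pcod_cod"] * cod_t + a["a_pcod_herring"] * lnH_t +
      a["a_pcod_ice"] * zIce_t + a["a_pcod_F"] * zF_lag[3])
}

## brute-force joint log density: explicit loops over years and species
oracle_joint_log_density <- function(params, states, data, priors) {
  T <- nrow(data)
  zs <- function(v) (v - mean(v)) / sd(v)
  lnH <- log(data$herring)
  zST <- zs(data$st); zIce <- zs(data$ice)
  zF <- cbind(zs(data$f_cod), zs(data$f_cap), zs(data$f_pcod))
  Sigma <- diag(params$sigma_proc) %*% params$R_proc %*% diag(params$sigma_proc)
  lp <- 0
  for (t in 2:T) {
    mu <- oracle_step(params$a, states[t - 1, ], states[t, 1],
                      lnH[t - 1], lnH[t], zST[t - 1], zIce[t], zF[t - 1, ])
    lp <- lp + mvn_logpdf(states[t, ], mu, Sigma)
  }
  y <- log(as.matrix(data[c("cod", "cap", "pcod")]))
  for (i in 1:3) {
    x0m <- y[which(!is.na(y[, i]))[1], i]
    lp <- lp + dnorm(states[1, i], x0m, priors$x0_sd, log = TRUE)
  }
  sobs <- sqrt(params$r_obs) * params$sigma_proc
  for (t in 1:T) for (i in 1:3) {
    if (is.na(y[t, i])) next
    s <- sobs[i]
    if (i == 3 && !is.null(priors$anomaly_year) &&
        data$year[t] == priors$anomaly_year)
      s <- sqrt(s^2 + params$sigma_pcod_1995^2)
    lp <- lp + dnorm(y[t, i], states[t, i], s, log = TRUE)
  }
  for (k in seq_along(params$a))
    lp <- lp + dnorm(params$a[k], 0, priors$a_sd, log = TRUE)
  for (i in 1:3) {
    lp <- lp + log(2) + dnorm(params$sigma_proc[i], 0, priors$sigma_sd, log = TRUE)
    lp <- lp + dnorm(params$r_obs[i], priors$ratio_mean, priors$ratio_sd, log = TRUE) -
      pnorm(priors$ratio_mean / priors$ratio_sd, log.p = TRUE)
  }
  if (!is.null(priors$anomaly_year))
    lp <- lp + log(2) + dnorm(params$sigma_pcod_1995, 0, priors$sigma_sd, log = TRUE)
  as.numeric(lp)
}

## independent split-Rhat: textbook formula, straightforward loops
oracle_split_rhat <- function(chains) {
  n <- nrow(chains)
  if (n %% 2 == 1) chains <- chains[-1, , drop = FALSE]
  h <- nrow(chains) / 2
  halves <- list()
  for (j in seq_len(ncol(chains))) {
    halves[[length(halves) + 1]] <- chains[1:h, j]
    halves[[length(halves) + 1]] <- chains[(h + 1):(2 * h), j]
  }
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- h / (m - 1) * sum((means - mean(means))^2)
  max(1, sqrt(((h - 1) / h * W + B / h) / W))   # floored like the package
}

## exact Gaussian smoother by joint-normal conditioning (for FFBS checks):
## returns the posterior mean and covariance of vec-by-year states given y
oracle_smoother <- function(a, Sigma, r_obs, s95, y, lnH, zST, zIce, zF,
                            i95, x0mean, x0sd) {
  T <- nrow(y)
  s <- list(cod = a[1:7], cap = a[8:14], pcod = a[15:21])
  A_lag <- rbind(c(s$cod[2], s$cod[3], s$cod[4]),
                 c(0, s$cap[2], s$cap[3]),
                 c(0, s$pcod[3], s$pcod[2]))
  Gam <- matrix(0, 3, 3); Gam[2, 1] <- s$cap[4]; Gam[3, 1] <- s$pcod[4]
  L <- diag(3) + Gam
  B <- L %*% A_lag
  Q <- L %*% Sigma %*% t(L)
  d <- matrix(0, T, 3)
  for (t in 2:T) {
    d[t, 1] <- s$cod[1] + s$cod[5] * lnH[t - 1] + s$cod[6] * zST[t - 1] + s$cod[7] * zF[t - 1, 1]
    d[t, 2] <- s$cap[1] + s$cap[5] * lnH[t] + s$cap[6] * zST[t - 1] + s$cap[7] * zF[t - 1, 2]
    d[t, 3] <- s$pcod[1] + s$pcod[5] * lnH[t] + s$pcod[6] * zIce[t] + s$pcod[7] * zF[t - 1, 3]
  }
  cc <- t(L %*% t(d))
  ## joint prior of the stacked states (3T)
  mu <- numeric(3 * T)
  mu[1:3] <- x0mean
  for (t in 2:T) mu[(t - 1) * 3 + 1:3] <- cc[t, ] + B %*% mu[(t - 2) * 3 + 1:3]
  P <- matrix(0, 3 * T, 3 * T)
  P[1:3, 1:3] <- diag(x0sd^2, 3)
  for (t in 2:T) {
    it <- (t - 1) * 3 + 1:3; ip <- (t - 2) * 3 + 1:3
    P[it, it] <- B %*% P[ip, ip] %*% t(B) + Q
    for (ss in 1:(t - 1)) {
      is_ <- (ss - 1) * 3 + 1:3
      P[is_, it] <- P[is_, ip] %*% t(B)
      P[it, is_] <- t(P[is_, it])
    }
  }
  ## condition on the observed cells
  obs <- which(!is.na(t(y)))  # index into stacked (species fastest) vector
  Rv <- rep(r_obs * diag(Sigma), T)
  if (i95 > 0) Rv[(i95 - 1) * 3 + 3] <- Rv[(i95 - 1) * 3 + 3] + s95^2
  yv <- as.numeric(t(y))
  Syy <- P[obs, obs, drop = FALSE] + diag(Rv[obs], length(obs))
  K <- P[, obs, drop = FALSE] %*% solve(Syy)
  list(mean = mu + as.numeric(K %*% (yv[obs] - mu[obs])),
       cov = P - K %*% P[obs, , drop = FALSE])
}
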