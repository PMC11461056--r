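#' Deterministic Gompertz map for one transition year
#'
#' Evaluates the expected log abundances at year `t` (the linear predictors of
#' the three structural equations, without process error). The cod component
#' uses only year `t-1` regressors. Because the cod and herring surveys and
#' the winter sea-ice index at year `t` fall between the capelin/polar-cod
#' surveys of years `t-1` and `t`, the capelin and polar-cod components use
#' current-year cod log abundance (`cod_t`), current-year herring and (for
#' polar cod) current-year ice, with sea temperature and fishing lagged.
#'
#' @param x_prev length-3 vector of log abundances at year `t-1` (cod, cap, pcod).
#' @param cod_t log cod abundance at year `t` (used by the capelin and
#'   polar-cod components; ignored by the cod component).
#' @param herring_lag,herring_t log herring biomass at years `t-1` and `t`.
#' @param st_lag z-scored sea temperature at year `t-1`.
#' @param ice_t z-scored sea-ice index at year `t`.
#' @param F_lag length-3 vector of z-scored fishing mortalities at year `t-1`
#'   (cod, cap, pcod).
#' @param params a [model_params()] object (only the coefficients are used).
#' @return length-3 named vector of expected log abundances (cod, cap, pcod).
#' @export
gompertz_step <- function(x_prev, cod_t, herring_lag, herring_t, st_lag,
                          ice_t, F_lag, params) {
  inputs <- c(x_prev, cod_t, herring_lag, herring_t, st_lag, ice_t, F_lag)
  if (length(x_prev) != 3 || length(F_lag) != 3)
    stop("gompertz_step: x_prev and F_lag must have length 3")
  if (any(!is.finite(inputs))) stop("gompertz_step: non-finite input")
  s <- split_coefs(params$a)
  c(cod = s$cod[1] + s$cod[2] * x_prev[1] + s$cod[3] * x_prev[2] +
      s$cod[4] * x_prev[3] + s$cod[5] * herring_lag + s$cod[6] * st_lag +
      s$cod[7] * F_lag[1],
    cap = s$cap[1] + s$cap[2] * x_prev[2] + s$cap[3] * x_prev[3] +
      s$cap[4] * cod_t + s$cap[5] * herring_t + s$cap[6] * st_lag +
      s$cap[7] * F_lag[2],
    pcod = s$pcod[1] + s$pcod[2] * x_prev[3] + s$pcod[3] * x_prev[2] +
      s$pcod[4] * cod_t + s$pcod[5] * herring_t + s$pcod[6] * ice_t +
      s$pcod[7] * F_lag[3])
}

## Prepare model inputs from a fish_data table: log observations, log herring,
## z-scored covariates (over the modelled window), anomaly-year index and the
## initial-state prior mean (first non-missing log observation per species).
## `scaling` carries the centre/scale of every z-scored covariate so scenario
## series can be mapped onto the identical scale.
gbs_model_inputs <- function(data, priors = prior_config()) {
  validate_fish_data(data)
  T <- nrow(data)
  if (T < 2) stop("need at least 2 years of data")
  y <- log(as.matrix(data[gbs_species]))
  dimnames(y) <- list(data$year, gbs_species)
  zST <- zscore(data$st)
  zIce <- zscore(data$ice)
  zF <- cbind(zscore(data$f_cod), zscore(data$f_cap), zscore(data$f_pcod))
  scaling <- list(
    st = c(center = attr(zST, "center"), scale = attr(zST, "scale")),
    ice = c(center = attr(zIce, "center"), scale = attr(zIce, "scale")))
  i95 <- if (is.null(priors$anomaly_year)) 0L else
    match(priors$anomaly_year, data$year, nomatch = 0L)
  x0mean <- apply(y, 2, function(col) col[which(!is.na(col))[1]])
  if (any(is.na(x0mean)))
    stop("each species needs at least one observed abundance")
  list(T = T, years = data$year, y = y, lnH = log(data$herring),
       zST = as.numeric(zST), zIce = as.numeric(zIce),
       zF = unname(zF), i95 = i95, x0mean = unname(x0mean),
       x0sd = priors$x0_sd, scaling = scaling)
}

## Design matrices of the three structural equations given latent states x
## (T x 3). Row t-1 of each matrix holds the regressors of the year-t response.
gbs_designs <- function(x, inp) {
  T <- inp$T
  i1 <- 1:(T - 1)
  i2 <- 2:T
  list(cbind(1, x[i1, 1], x[i1, 2], x[i1, 3], inp$lnH[i1], inp$zST[i1], inp$zF[i1, 1]),
       cbind(1, x[i1, 2], x[i1, 3], x[i2, 1], inp$lnH[i2], inp$zST[i1], inp$zF[i1, 2]),
       cbind(1, x[i1, 3], x[i1, 2], x[i2, 1], inp$lnH[i2], inp$zIce[i2], inp$zF[i1, 3]))
}

## Structural process errors implied by states x and coefficients a:
## eps_t = x_t - Z_t a, one row per transition year (2..T).
gbs_residuals <- function(x, a, inp) {
  Z <- gbs_designs(x, inp)
  s <- split_coefs(a)
  E <- x[2:inp$T, , drop = FALSE] -
    cbind(Z[[1]] %*% s$cod, Z[[2]] %*% s$cap, Z[[3]] %*% s$pcod)
  dimnames(E) <- list(inp$years[-1], gbs_species)
  E
}
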