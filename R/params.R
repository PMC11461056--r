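#' Model parameters for the three-species Gompertz state-space model
#'
#' Collects every parameter of the joint model: the 21 regression
#' coefficients (per species: intercept, own-density dependence, the two
#' interspecific terms, herring, climate and fishing effects), the
#' process-error standard deviations and correlation matrix, the
#' observation/process variance ratios, and the extra observation standard
#' deviation for the anomalous polar-cod survey year.
#'
#' Coefficients are passed by name (see `gompertzbs:::gbs_coef_names`), e.g.
#' `a_cod_cod` is the cod density-dependence term and `a_cap_cod` the effect
#' of current-year cod on capelin. Unspecified coefficients default to 0.
#' The observation variances are tied to the process variances through
#' `sigma2_obs_i = r_obs_i * sigma2_proc_i`.
#'
#' @param ... named coefficients, or a single named numeric vector `a`
#'   covering some or all of the 21 coefficients.
#' @param sigma_proc length-3 vector of process-error SDs (cod, cap, pcod), > 0.
#' @param R_proc 3x3 process-error correlation matrix (symmetric, unit
#'   diagonal, positive definite).
#' @param r_obs length-3 vector of observation/process variance ratios, > 0.
#' @param sigma_pcod_1995 extra observation SD added (in quadrature) to the
#'   polar-cod observation in the designated anomaly year, >= 0.
#' @return object of class `gbs_params`.
#' @export
#' @examples
#' p <- model_params(a_cod_0 = 1, a_cap_0 = 2, a_pcod_0 = 3)
#' gompertz_step(c(0, 0, 0), cod_t = 1, herring_lag = 0, herring_t = 0,
#'               st_lag = 0, ice_t = 0, F_lag = c(0, 0, 0), params = p)
model_params <- function(..., sigma_proc = c(0.15, 0.15, 0.15),
                         R_proc = diag(3), r_obs = c(2, 2, 2),
                         sigma_pcod_1995 = 0) {
  dots <- list(...)
  a <- setNames(numeric(21), gbs_coef_names)
  if (length(dots) == 1 && is.null(names(dots)) && !is.null(names(dots[[1]])))
    dots <- as.list(dots[[1]])
  if (length(dots) == 1 && identical(names(dots), "a")) dots <- as.list(dots$a)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("model_params: coefficients must be named")
    unknown <- setdiff(names(dots), gbs_coef_names)
    if (length(unknown))
      stop("model_params: unknown coefficient(s): ",
           paste(unknown, collapse = ", "))
    a[names(dots)] <- unlist(dots)
  }
  p <- structure(list(a = a, sigma_proc = as.numeric(sigma_proc),
                      R_proc = unname(as.matrix(R_proc)),
                      r_obs = as.numeric(r_obs),
                      sigma_pcod_1995 = as.numeric(sigma_pcod_1995)),
                 class = "gbs_params")
  validate_model_params(p)
  p
}

#' Validate model parameters
#'
#' @param p a [model_params()] object.
#' @return `p`, invisibly; errors on any invariant breach (non-positive SDs
#'   or ratios, non-symmetric / non-unit-diagonal / non-positive-definite
#'   correlation matrix).
#' @export
validate_model_params <- function(p) {
  if (!all(is.finite(p$a)) || length(p$a) != 21)
    stop("model_params: coefficient vector must be 21 finite values")
  if (length(p$sigma_proc) != 3 || any(!is.finite(p$sigma_proc)) ||
      any(p$sigma_proc <= 0))
    stop("model_params: sigma_proc must be 3 positive values")
  if (length(p$r_obs) != 3 || any(!is.finite(p$r_obs)) || any(p$r_obs <= 0))
    stop("model_params: r_obs must be 3 positive values")
  R <- p$R_proc
  if (!is.matrix(R) || any(dim(R) != 3) || max(abs(R - t(R))) > 1e-10 ||
      max(abs(diag(R) - 1)) > 1e-10)
    stop("model_params: R_proc must be a symmetric 3x3 matrix with unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("model_params: R_proc is not positive definite")
  if (!is.finite(p$sigma_pcod_1995) || p$sigma_pcod_1995 < 0)
    stop("model_params: sigma_pcod_1995 must be >= 0")
  invisible(p)
}

#' Process-error covariance implied by the parameters
#'
#' `Sigma_proc = diag(sigma_proc) %*% R_proc %*% diag(sigma_proc)`.
#'
#' @param p a [model_params()] object.
#' @return 3x3 covariance matrix.
#' @export
sigma_proc_matrix <- function(p) {
  diag(p$sigma_proc) %*% p$R_proc %*% diag(p$sigma_proc)
}

#' Observation-error standard deviations implied by the ratio tie
#'
#' @param p a [model_params()] object.
#' @return length-3 vector `sqrt(r_obs) * sigma_proc`.
#' @export
sigma_obs <- function(p) sqrt(p$r_obs) * p$sigma_proc

## coefficient blocks as a named list (cod, cap, pcod), 7 each
split_coefs <- function(a) {
  list(cod = unname(a[1:7]), cap = unname(a[8:14]), pcod = unname(a[15:21]))
}

## structural pieces of the system:
## x_t = d_t + A_lag x_{t-1} + Gam x_t + eps_t, reduced via L = (I + Gam)
## (Gam is strictly lower triangular in the cod column, so Gam^2 = 0)
struct_matrices <- function(a) {
  s <- split_coefs(a)
  A_lag <- rbind(c(s$cod[2], s$cod[3], s$cod[4]),
                 c(0,        s$cap[2], s$cap[3]),
                 c(0,        s$pcod[3], s$pcod[2]))
  Gam <- matrix(0, 3, 3)
  Gam[2, 1] <- s$cap[4]
  Gam[3, 1] <- s$pcod[4]
  L <- diag(3) + Gam
  list(A_lag = A_lag, Gam = Gam, L = L)
}

#' Implied lag-1 (VAR) transition matrix
#'
#' Substitutes the contemporaneous current-year cod term into the capelin and
#' polar-cod equations, giving the reduced-form matrix `B` with
#' `x_t = const_t + B x_{t-1} + noise`. Row cod is
#' `(a_cod_cod, a_cod_cap, a_cod_pcod)`; row capelin is
#' `(a_cap_cod * a_cod_cod, a_cap_cap + a_cap_cod * a_cod_cap,
#' a_cap_pcod + a_cap_cod * a_cod_pcod)`; row polar cod analogously.
#'
#' @param a either a [model_params()] object or a (partially) named
#'   coefficient vector.
#' @return 3x3 transition matrix with rows/columns ordered (cod, cap, pcod).
#' @seealso [stationarity_filter()]
#' @export
transition_matrix <- function(a) {
  if (inherits(a, "gbs_params")) a <- a$a
  if (!is.null(names(a))) {
    v <- setNames(numeric(21), gbs_coef_names)
    v[intersect(names(a), gbs_coef_names)] <- a[intersect(names(a), gbs_coef_names)]
    a <- v
  }
  m <- struct_matrices(a)
  B <- m$L %*% m$A_lag
  dimnames(B) <- list(gbs_species, gbs_species)
  B
}

## rebuild a gbs_params object from one row of a posterior parameter matrix
params_from_draw <- function(v) {
  rho <- c(v["rho_cod_cap"], v["rho_cap_pcod"], v["rho_cod_pcod"])
  R <- matrix(c(1, rho[1], rho[3],
                rho[1], 1, rho[2],
                rho[3], rho[2], 1), 3, 3)
  structure(list(a = setNames(as.numeric(v[gbs_coef_names]), gbs_coef_names),
                 sigma_proc = as.numeric(v[paste0("sigma_proc_", gbs_species)]),
                 R_proc = R,
                 r_obs = as.numeric(v[paste0("r_obs_", gbs_species)]),
                 sigma_pcod_1995 = as.numeric(v["sigma_pcod_1995"])),
            class = "gbs_params")
}

#' Generating parameters used as synthetic-data defaults
#'
#' Coefficient values chosen near the published posterior medians for the
#' Barents Sea system (documented as inspiration for realistic dynamics, not
#' as ground truth), with moderate process-error SDs, variance ratios of 2
#' and mildly positive process-error correlations. The implied lag-1
#' transition matrix is stationary.
#'
#' @param sigma_proc,R_proc,r_obs,sigma_pcod_1995 overrides, see [model_params()].
#' @return a [model_params()] object.
#' @export
default_generating_params <- function(sigma_proc = c(0.15, 0.15, 0.15),
                                      R_proc = matrix(c(1, .3, .3,
                                                        .3, 1, .3,
                                                        .3, .3, 1), 3, 3),
                                      r_obs = c(2, 2, 2),
                                      sigma_pcod_1995 = 1) {
  a <- c(0.14, 0.61, 0.10, 0.37, 0.02, -0.07, -0.28,
         3.40, 0.66, 0.34, -0.51, -0.33, 0.20, -0.27,
         2.52, 0.45, 0.01, 0.07, 0.17, 0.26, 0.18)
  model_params(a = setNames(a, gbs_coef_names), sigma_proc = sigma_proc,
               R_proc = R_proc, r_obs = r_obs,
               sigma_pcod_1995 = sigma_pcod_1995)
}
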