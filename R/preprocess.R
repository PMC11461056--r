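#' Standardize a series to zero mean and unit standard deviation
#'
#' Centres and scales a numeric series using the sample standard deviation
#' (denominator `n - 1`) over the supplied window. Environmental covariates
#' (sea temperature, sea-ice index) and fishing mortality enter the Gompertz
#' model z-scored so their coefficients are directly comparable.
#'
#' @param x numeric vector, length at least 2, with positive variance.
#'   Missing values are ignored when computing the centre and scale and
#'   propagated in the output.
#' @return numeric vector of standardized values with attributes `center`
#'   and `scale` holding the mean and standard deviation for inverse mapping.
#' @seealso [inv_zscore()]
#' @export
#' @examples
#' z <- zscore(c(1, 2, 3))   # -1, 0, 1
#' inv_zscore(z)
zscore <- function(x) {
  if (!is.numeric(x)) stop("zscore: input must be numeric")
  ok <- !is.na(x)
  if (sum(ok) < 2) stop("zscore: need at least 2 non-missing values")
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (!is.finite(s) || s <= 0)
    stop("zscore: degenerate input, series has zero variance")
  structure((x - m) / s, center = m, scale = s)
}

#' Invert a z-score transformation
#'
#' @param z standardized vector as returned by [zscore()], or any numeric
#'   vector if `center` and `scale` are given explicitly.
#' @param center,scale mean and standard deviation used in the forward
#'   transform; defaults to the attributes stored by [zscore()].
#' @return numeric vector on the original scale.
#' @export
inv_zscore <- function(z, center = attr(z, "center"), scale = attr(z, "scale")) {
  if (is.null(center) || is.null(scale))
    stop("inv_zscore: center/scale not supplied and not present as attributes")
  as.numeric(z) * scale + center
}

#' Fishing mortality proxy from landings and biomass
#'
#' Instantaneous-rate approximation `-ln(1 - landings/biomass)` used to
#' construct a fishing mortality index for stocks where only catch and stock
#' size are reported (capelin and polar cod).
#'
#' @param landings landed mass, same units as `biomass`, `0 <= landings < biomass`.
#' @param biomass stock biomass, strictly positive.
#' @return non-negative mortality index, monotone increasing in `landings`.
#' @export
#' @examples
#' fishing_proxy(50, 100)   # -log(0.5)
fishing_proxy <- function(landings, biomass) {
  if (length(landings) != length(biomass))
    stop("fishing_proxy: landings and biomass must have the same length")
  if (any(!is.finite(landings) | !is.finite(biomass)))
    stop("fishing_proxy: non-finite input")
  if (any(biomass <= 0)) stop("fishing_proxy: biomass must be > 0")
  if (any(landings < 0)) stop("fishing_proxy: landings must be >= 0")
  if (any(landings >= biomass))
    stop("fishing_proxy: landings must be strictly less than biomass")
  -log(1 - landings / biomass)
}
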