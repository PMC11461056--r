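#' Split-Rhat convergence diagnostic for one scalar parameter
#'
#' Classic Gelman-Rubin potential scale reduction factor computed on split
#' chains: each chain is cut in half (the first draw is dropped when the
#' length is odd), the between- and within-half-chain variances are combined
#' as `var_hat = (n - 1)/n * W + B/n`, and `Rhat = sqrt(var_hat / W)`. Values
#' near 1 indicate convergence. `type = "rank"` applies the rank-normalised
#' variant (split-Rhat of the normal scores of the pooled ranks, and of the
#' folded draws; the maximum of the two is returned).
#'
#' @param x draws: a matrix with one column per chain, or a numeric vector
#'   with `chain` supplied.
#' @param chain optional chain labels when `x` is a vector.
#' @param type `"classic"` (default) or `"rank"`.
#' @return scalar Rhat (floored at 1: values below 1 arise only from sampling
#'   noise of the variance ratio and carry no convergence information). If
#'   every within-chain
#'   variance is zero the draws are degenerate and `Inf` is returned as a
#'   non-convergence sentinel (or 1 if all chains are identical constants).
#' @export
split_rhat <- function(x, chain = NULL, type = c("classic", "rank")) {
  type <- match.arg(type)
  if (!is.null(chain)) {
    x <- split(as.numeric(x), chain)
    n <- min(lengths(x))
    x <- vapply(x, function(v) v[seq_len(n)], numeric(n))
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("split_rhat: need at least 2 chains")
  if (nrow(x) < 4) stop("split_rhat: need at least 4 draws per chain")
  if (type == "rank") {
    z <- matrix(qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4)), nrow(x))
    folded <- abs(x - median(x))
    zf <- matrix(qnorm((rank(folded) - 3 / 8) / (length(folded) + 1 / 4)), nrow(x))
    return(max(gbs_rhat_basic(z), gbs_rhat_basic(zf)))
  }
  gbs_rhat_basic(x)
}

gbs_rhat_basic <- function(x) {
  n <- nrow(x)
  if (n %% 2 == 1) x <- x[-1, , drop = FALSE]
  h <- nrow(x) / 2
  halves <- cbind(x[seq_len(h), , drop = FALSE], x[h + seq_len(h), , drop = FALSE])
  W <- mean(apply(halves, 2, var))
  B <- h * var(colMeans(halves))
  if (!is.finite(W) || W == 0) {
    if (is.finite(B) && B == 0) return(1)   # identical constant chains
    return(Inf)                             # stuck chains: non-convergent
  }
  ## the variance-ratio estimator can dip below 1 by sampling noise; values
  ## below 1 carry no convergence information, so the diagnostic is floored
  max(1, sqrt((h - 1) / h + B / (W * h)))
}

## split-Rhat for every parameter column and latent-state cell of a draws
## object; returns a named vector
gbs_rhat_all <- function(draws, type = "classic", include_states = TRUE) {
  keep_each <- nrow(draws$params) / max(draws$chain)
  to_mat <- function(v) matrix(v, ncol = max(draws$chain))
  r <- vapply(colnames(draws$params),
              function(p) split_rhat(to_mat(draws$params[, p]), type = type),
              0)
  if (include_states && !is.null(draws$states)) {
    st <- matrix(draws$states, nrow = nrow(draws$params))
    colnames(st) <- as.vector(outer(draws$years, gbs_species,
                                    function(y, s) sprintf("x[%d,%s]", y, s)))
    rs <- vapply(colnames(st), function(p) split_rhat(to_mat(st[, p]), type = type), 0)
    r <- c(r, rs)
  }
  r
}

gbs_diagnostics <- function(draws, rhat_bound = 1.05) {
  single <- max(draws$chain) < 2
  rh <- if (single) NULL else gbs_rhat_all(draws)
  max_rhat <- if (single) NA_real_ else max(rh)
  list(rhat = rh, max_rhat = max_rhat,
       worst_param = if (single) NA_character_ else names(rh)[which.max(rh)],
       rhat_bound = rhat_bound,
       converged = single || max_rhat <= rhat_bound,
       n_retained = nrow(draws$params),
       n_chains = max(draws$chain),
       n_divergent = 0L)
}

#' Convergence diagnostics report
#'
#' Summarises split-Rhat per parameter (and latent state), the retained-draw
#' count and the convergence flag; optionally writes the report as JSON.
#'
#' @param draws a `gbs_draws` object (>= 2 chains for Rhat).
#' @param path optional path of a JSON report to write.
#' @param rhat_bound convergence bound used for the `converged` flag.
#' @param provenance optional named list embedded in the JSON report.
#' @return the diagnostics list, invisibly when `path` is given.
#' @export
diagnose_draws <- function(draws, path = NULL, rhat_bound = 1.05,
                           provenance = NULL) {
  d <- gbs_diagnostics(draws, rhat_bound)
  if (!is.null(path)) {
    out <- list(max_rhat = d$max_rhat, worst_param = d$worst_param,
                rhat_bound = d$rhat_bound, converged = d$converged,
                n_retained = d$n_retained, n_chains = d$n_chains,
                n_divergent = d$n_divergent,
                rhat = as.list(d$rhat))
    if (!is.null(provenance)) out$provenance <- provenance
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(d))
  }
  d
}
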