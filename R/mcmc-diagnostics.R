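# MCMC convergence diagnostics: rank-normalized split-Rhat and bulk
# effective sample size, computed on post-warmup draws only.

.rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

.split_chains <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) stop("need at least 4 draws per chain to split")
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[seq.int(n - half + 1, n), , drop = FALSE])
}

#' Rank-normalized split-Rhat
#'
#' Potential-scale-reduction diagnostic computed on rank-normalized draws
#' after splitting each chain in half, so that both poor mixing and
#' non-stationarity within chains inflate the statistic. Values near 1
#' indicate convergence; values above ~1.05 indicate trouble.
#'
#' @param draws Matrix of post-warmup draws, iterations x chains
#'   (>= 2 chains).
#' @return Split-Rhat, or `NA` (with a warning) when the draws are constant
#'   so the diagnostic is undefined.
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("split-Rhat requires at least 2 chains")
  sp <- .split_chains(draws)
  if (stats::var(as.vector(sp)) == 0) {
    warning("constant draws: split-Rhat undefined")
    return(NA_real_)
  }
  z <- matrix(.rank_normalize(as.vector(sp)), nrow(sp), ncol(sp))
  n <- nrow(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  b <- n * stats::var(means)
  w <- mean(vars)
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Bulk effective sample size
#'
#' Effective number of independent draws, computed on rank-normalized split
#' chains with Geyer's initial-monotone-positive-sequence truncation of the
#' autocorrelation sum.
#'
#' @param draws Matrix of post-warmup draws, iterations x chains.
#' @return Estimated bulk ESS (capped at the total number of draws times
#'   `log10` growth allowance), or `NA` for constant draws.
#' @export
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  sp <- .split_chains(draws)
  if (stats::var(as.vector(sp)) == 0) return(NA_real_)
  z <- matrix(.rank_normalize(as.vector(sp)), nrow(sp), ncol(sp))
  n <- nrow(z)
  m <- ncol(z)
  vars <- apply(z, 2, stats::var)
  w <- mean(vars)
  var_plus <- (n - 1) / n * w + n * stats::var(colMeans(z)) / n
  # chain-averaged autocovariances
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(z[, j], lag.max = n - 1, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov) / var_plus
  # Geyer: sum over pairs while pair sums are positive and non-increasing
  max_pairs <- floor((length(rho) - 1) / 2)
  tau <- rho[1]
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  max(m * n / max(tau, 1e-12), 1)
}

#' Convergence diagnostics table for a growth fit
#'
#' @param fit A `"growth_fit"` object (needs >= 2 chains).
#' @return Data frame with split-Rhat and bulk ESS per group x parameter.
#' @export
growth_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$settings$chains < 2)
    stop("convergence diagnostics require at least 2 chains")
  fit$diagnostics
}
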