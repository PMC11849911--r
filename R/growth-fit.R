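#' Default priors for the distributional Gompertz growth model
#'
#' Median-parameterized lognormal priors for the mean-model parameters
#' (`A`, `B`, `C`) and the variance sub-model parameters (`subA`, `subB`,
#' `subC`), plus a Gamma prior (shape, rate) on the Student-t degrees of
#' freedom, truncated at `nu >= 1`. A parameter with prior center `m` and
#' scale `s` has prior `LogNormal(log(m), s)`, so `m` is the prior median on
#' the natural scale.
#'
#' @param centers Named numeric vector of prior medians.
#' @param scale Lognormal sdlog shared by all six parameters.
#' @param df_shape,df_rate Gamma prior on the degrees of freedom.
#' @return A list of class `"growth_priors"`.
#' @examples
#' growth_priors()
#' @export
growth_priors <- function(centers = c(A = 130, B = 15, C = 0.25,
                                      subA = 20, subB = 10, subC = 3),
                          scale = 0.25, df_shape = 2, df_rate = 0.1) {
  stopifnot(all(centers > 0), scale > 0, df_shape > 0, df_rate > 0,
            setequal(names(centers), c("A", "B", "C", "subA", "subB", "subC")))
  structure(list(centers = centers[c("A", "B", "C", "subA", "subB", "subC")],
                 scale = scale, df_shape = df_shape, df_rate = df_rate),
            class = "growth_priors")
}

#' Draw from the growth-model priors
#'
#' Direct Monte Carlo draws from the joint prior (all parameters independent;
#' degrees of freedom rejection-sampled to respect the `nu >= 1` truncation).
#' Useful for prior predictive checks: sample medians should sit at the prior
#' centers up to Monte Carlo error.
#'
#' @param priors A [growth_priors()] object.
#' @param n Number of draws.
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `A,B,C,subA,subB,subC,nu`.
#' @export
sample_growth_prior <- function(priors = growth_priors(), n = 10000, seed = 1) {
  stopifnot(inherits(priors, "growth_priors"), n >= 1)
  set.seed(seed)
  out <- as.data.frame(lapply(priors$centers, function(m)
    stats::rlnorm(n, meanlog = log(m), sdlog = priors$scale)))
  nu <- stats::rgamma(2 * n, shape = priors$df_shape, rate = priors$df_rate)
  nu <- nu[nu >= 1]
  while (length(nu) < n) {
    extra <- stats::rgamma(n, shape = priors$df_shape, rate = priors$df_rate)
    nu <- c(nu, extra[extra >= 1])
  }
  out$nu <- nu[seq_len(n)]
  out
}

# --- anchor-point parameterization -----------------------------------------
# The posterior in (A, B, C, subA, subB, subC) is an extremely anisotropic
# curved ridge (early observations pin the mean curve to many digits), which
# random-walk samplers cannot traverse. We therefore sample in an
# expected-value parameterization: the log mean area and log residual sd at
# three equally spaced anchor days (t1, t1 + dt, t1 + 2 dt). Both maps have
# closed-form inverses; priors stay on the natural parameters and the change
# of variables enters through a numerical log-Jacobian.

# log mu(t) = log A - exp(-C (t - B)) at the three anchors -> (A, B, C).
# Equal spacing gives log A = (u2^2 - u1 u3) / (2 u2 - u1 - u3).
.mean_from_anchors <- function(u, t1, dt) {
  den <- 2 * u[2] - u[1] - u[3]
  if (!is.finite(den) || den <= 0 || u[1] >= u[2] || u[2] >= u[3]) return(NULL)
  logA <- (u[2]^2 - u[1] * u[3]) / den
  d <- logA - u
  if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
  C <- log(d[1] / d[2]) / dt
  if (!is.finite(C) || C <= 0) return(NULL)
  B <- t1 + log(d[1]) / C
  if (!is.finite(B) || B <= 0) return(NULL)
  c(A = exp(logA), B = B, C = C)
}

.anchors_from_mean <- function(A, B, C, t1, dt) {
  t <- t1 + dt * (0:2)
  log(A) - exp(-C * (t - B))
}

# Variance block sampled as (log sd(ta), log sd(tb), log subA); subB and
# subC recovered via expm1, which stays exact when sd(t) is already close
# to its asymptote.
.var_from_anchors <- function(v, ta, tb) {
  r <- v[3] - v[1:2]
  if (any(!is.finite(r)) || any(r <= 0)) return(NULL)
  q <- expm1(r)
  if (q[1] <= q[2] || q[2] <= 0) return(NULL)
  subC <- (log(q[1]) - log(q[2])) / (tb - ta)
  if (!is.finite(subC) || subC <= 0) return(NULL)
  subB <- ta + log(q[1]) / subC
  if (!is.finite(subB) || subB <= 0) return(NULL)
  c(subA = exp(v[3]), subB = subB, subC = subC)
}

.anchors_from_var <- function(subA, subB, subC, ta, tb) {
  c(log(subA) - log1p(exp(-subC * (c(ta, tb) - subB))), log(subA))
}

# log |det d(log params)/d(anchors)| by central differences (the map is a
# few scalar ops, so this costs nothing next to the likelihood).
.log_det_jac <- function(fun, x, eps = 1e-6) {
  J <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    hi <- x; lo <- x
    hi[j] <- hi[j] + eps; lo[j] <- lo[j] - eps
    fh <- fun(hi); fl <- fun(lo)
    if (is.null(fh) || is.null(fl)) return(NULL)
    J[, j] <- (log(fh) - log(fl)) / (2 * eps)
  }
  d <- det(J)
  if (!is.finite(d) || d == 0) return(NULL)
  log(abs(d))
}

# Log posterior in sampling coordinates
# theta = (u1, u2, u3, log sd(ta), log sd(tb), log subA, log(nu - 1)).
# The truncation constant of the nu prior is dropped (constant in theta).
.growth_log_post <- function(theta, day, area, priors, t1, dt, ta, tb) {
  if (any(!is.finite(theta))) return(-Inf)
  p_mean <- .mean_from_anchors(theta[1:3], t1, dt)
  p_var <- .var_from_anchors(theta[4:6], ta, tb)
  if (is.null(p_mean) || is.null(p_var)) return(-Inf)
  nu <- 1 + exp(theta[7])
  if (!is.finite(nu)) return(-Inf)
  lj_mean <- .log_det_jac(function(u) .mean_from_anchors(u, t1, dt), theta[1:3])
  lj_var <- .log_det_jac(function(v) .var_from_anchors(v, ta, tb), theta[4:6])
  if (is.null(lj_mean) || is.null(lj_var)) return(-Inf)
  logp <- c(log(p_mean), log(p_var))
  lp <- sum(stats::dnorm(logp, mean = log(priors$centers),
                         sd = priors$scale, log = TRUE)) +
    lj_mean + lj_var +
    stats::dgamma(nu, shape = priors$df_shape, rate = priors$df_rate,
                  log = TRUE) + theta[7]
  if (!is.finite(lp)) return(-Inf)
  if (length(day)) {
    mu <- p_mean[1] * exp(-exp(-p_mean[3] * (day - p_mean[2])))
    sd <- p_var[1] / (1 + exp(-p_var[3] * (day - p_var[2])))
    if (any(sd <= 0) || any(!is.finite(mu))) return(-Inf)
    ll <- sum(stats::dt((area - mu) / sd, df = nu, log = TRUE) - log(sd))
    if (!is.finite(ll)) return(-Inf)
    lp <- lp + ll
  }
  lp
}

# Posterior mode and Laplace covariance on the unconstrained scale, used to
# initialize the chains and the proposal covariance.
.growth_map <- function(log_post, init) {
  neg <- function(th) { v <- -log_post(th); if (!is.finite(v)) 1e300 else v }
  ctl <- list(maxit = 5000, reltol = 1e-12)
  opt <- stats::optim(init, neg, method = "Nelder-Mead", control = ctl)
  opt <- stats::optim(opt$par, neg, method = "Nelder-Mead", control = ctl)
  sigma <- tryCatch({
    h <- stats::optimHess(opt$par, neg)
    ev <- eigen((h + t(h)) / 2, symmetric = TRUE)
    lam <- pmax(ev$values, max(ev$values) * 1e-10)
    ev$vectors %*% diag(1 / lam) %*% t(ev$vectors)
  }, error = function(e) NULL)
  if (is.null(sigma) || any(!is.finite(sigma)) || any(diag(sigma) <= 0))
    sigma <- diag(1e-4, length(init))
  list(par = opt$par, sigma = (sigma + t(sigma)) / 2)
}

# Univariate stepping-out slice update along direction v from theta.
.slice_dir <- function(log_post, theta, lp, v, max_step = 30) {
  y <- lp + log(stats::runif(1))
  lo <- -stats::runif(1); hi <- lo + 1
  k <- max_step
  while (k > 0 && log_post(theta + lo * v) > y) { lo <- lo - 1; k <- k - 1 }
  k <- max_step
  while (k > 0 && log_post(theta + hi * v) > y) { hi <- hi + 1; k <- k - 1 }
  repeat {
    s <- stats::runif(1, lo, hi)
    lp_new <- log_post(theta + s * v)
    if (lp_new > y) return(list(theta = theta + s * v, lp = lp_new))
    if (s < 0) lo <- s else hi <- s
  }
}

# One chain of the composite kernel: adaptive random-walk Metropolis with a
# slice-sampling sweep along the current proposal directions every
# `slice_every` iterations. The slice sweeps guarantee movement when the
# random walk stalls in stiff regions; Haario-style covariance adaptation
# and Robbins-Monro global scaling continue with diminishing weights, which
# preserves ergodicity.
.am_chain <- function(log_post, init, warmup, iter_keep, cov0 = NULL,
                      slice_every = 20) {
  d <- length(init)
  theta <- init
  lp <- log_post(theta)
  if (!is.finite(lp)) stop("initial value has zero posterior density")
  log_scale <- log(2.38 / sqrt(d))
  run_mean <- theta
  run_cov <- if (is.null(cov0)) diag(0.04, d) else cov0
  chol_prop <- chol(run_cov + diag(1e-10, d))
  kept <- matrix(NA_real_, iter_keep, d)
  n_total <- warmup + iter_keep
  for (i in seq_len(n_total)) {
    prop <- theta + exp(log_scale) * drop(stats::rnorm(d) %*% chol_prop)
    lp_prop <- log_post(prop)
    acc <- is.finite(lp_prop) && log(stats::runif(1)) < (lp_prop - lp)
    if (acc) { theta <- prop; lp <- lp_prop }
    if (i %% slice_every == 0) {
      for (j in seq_len(d)) {
        r <- .slice_dir(log_post, theta, lp, 2.5 * chol_prop[j, ])
        theta <- r$theta; lp <- r$lp
      }
    }
    w <- 1 / (i + 10)
    delta <- theta - run_mean
    run_mean <- run_mean + w * delta
    run_cov <- (1 - w) * run_cov + w * tcrossprod(delta)
    log_scale <- log_scale + 3 / (i + 20)^0.7 * ((if (acc) 1 else 0) - 0.25)
    if (i %% 25 == 0 && i >= 50)
      chol_prop <- tryCatch(chol(run_cov + diag(1e-10, d)),
                            error = function(e) chol_prop)
    if (i > warmup) kept[i - warmup, ] <- theta
  }
  kept
}

#' Fit the distributional Gompertz growth model by MCMC
#'
#' Fits, for each accession x treatment group, the Bayesian growth model
#' with Student-t likelihood
#' `area ~ t(nu, gompertz_mean(day; A, B, C), variance_profile(day; subA, subB, subC))`,
#' lognormal priors on all six parameters and a truncated Gamma prior on
#' `nu`, using adaptive random-walk Metropolis on the log-parameter scale.
#' Groups are fit independently (the joint posterior factorizes across
#' groups under independent priors).
#'
#' @param data Data frame with columns `plant_id`, `accession`, `treatment`
#'   (`"WW"`/`"WL"`), `day`, `area_cm2`.
#' @param priors A [growth_priors()] object.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param warmup,draws Warmup iterations (discarded, used for adaptation) and
#'   post-warmup draws kept per chain.
#' @param seed Integer RNG seed; the full fit is reproducible from it.
#' @return An object of class `"growth_fit"`: a list with `draws` (named list
#'   of groups, each an `draws x chains x 7` array on the natural scale),
#'   `diagnostics` (split-Rhat / bulk ESS per group x parameter),
#'   `converged` (FALSE if any split-Rhat exceeds 1.05), `groups`, `priors`
#'   and the MCMC settings.
#' @seealso [test_hypothesis()], [growth_diagnostics()], [posterior_predictive()]
#' @export
fit_growth_model <- function(data, priors = growth_priors(), chains = 2,
                             warmup = 1000, draws = 1000, seed = 1) {
  req <- c("plant_id", "accession", "treatment", "day", "area_cm2")
  stopifnot(is.data.frame(data), all(req %in% names(data)),
            chains >= 1, warmup >= 0, draws >= 1)
  data <- data[stats::complete.cases(data[req]), req]
  if (!nrow(data)) stop("no usable growth observations")
  grp <- interaction(data$accession, data$treatment, sep = ":", drop = TRUE)
  for (g in levels(grp)) {
    sub <- data[grp == g, ]
    if (length(unique(sub$plant_id)) < 2)
      stop("group ", g, " has fewer than 2 plants")
    if (length(unique(sub$day)) < 6)
      stop("group ", g, " has fewer than 6 distinct days")
  }
  par_names <- c("A", "B", "C", "subA", "subB", "subC", "nu")
  cen <- priors$centers
  set.seed(seed)
  draws_list <- list()
  for (g in levels(grp)) {
    sub <- data[grp == g, ]
    # anchors at ~15% into the observation window and equally on to the end:
    # early enough to sit in the well-identified rising phase, late enough to
    # avoid the numerically flat pre-growth region
    t1 <- min(sub$day) + 0.15 * diff(range(sub$day))
    dt <- (max(sub$day) - t1) / 2
    ta <- t1; tb <- t1 + dt / 2
    lp_fun <- function(theta)
      .growth_log_post(theta, sub$day, sub$area_cm2, priors, t1, dt, ta, tb)
    init0 <- c(.anchors_from_mean(cen["A"], cen["B"], cen["C"], t1, dt),
               .anchors_from_var(cen["subA"], cen["subB"], cen["subC"], ta, tb),
               log(pmax(priors$df_shape / priors$df_rate - 1, 1)))
    map <- .growth_map(lp_fun, init0)
    jitter_sd <- pmin(2 * sqrt(diag(map$sigma)), 0.2)
    arr <- array(NA_real_, c(draws, chains, 7),
                 dimnames = list(NULL, NULL, par_names))
    for (ch in seq_len(chains)) {
      init <- map$par + stats::rnorm(7, 0, jitter_sd)
      tries <- 0
      while (!is.finite(lp_fun(init)) && tries < 20) {
        init <- map$par + stats::rnorm(7, 0, jitter_sd / 2)
        tries <- tries + 1
      }
      kept <- .am_chain(lp_fun, init, warmup, draws, cov0 = map$sigma)
      for (i in seq_len(draws)) {
        arr[i, ch, 1:3] <- .mean_from_anchors(kept[i, 1:3], t1, dt)
        arr[i, ch, 4:6] <- .var_from_anchors(kept[i, 4:6], ta, tb)
      }
      arr[, ch, 7] <- 1 + exp(kept[, 7])
    }
    draws_list[[g]] <- arr
  }
  diag_df <- do.call(rbind, lapply(names(draws_list), function(g) {
    arr <- draws_list[[g]]
    data.frame(group = g, parameter = par_names,
               rhat = vapply(par_names, function(p)
                 split_rhat(arr[, , p, drop = FALSE][, , 1]), 0),
               ess_bulk = vapply(par_names, function(p)
                 ess_bulk(arr[, , p, drop = FALSE][, , 1]), 0),
               row.names = NULL)
  }))
  structure(list(draws = draws_list, diagnostics = diag_df,
                 converged = all(is.na(diag_df$rhat) | diag_df$rhat <= 1.05),
                 groups = levels(grp), priors = priors,
                 settings = list(chains = chains, warmup = warmup,
                                 draws = draws, seed = seed)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Distributional Gompertz growth fit\n")
  cat("  groups:", paste(x$groups, collapse = ", "), "\n")
  cat(sprintf("  chains: %d, kept draws/chain: %d, max split-Rhat: %.4f\n",
              x$settings$chains, x$settings$draws,
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  if (!x$converged) cat("  WARNING: some split-Rhat > 1.05 (non-converged)\n")
  invisible(x)
}

#' Summarize posterior draws of a growth fit
#'
#' @param object A `"growth_fit"` object.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return Data frame: group, parameter, median, quantiles, Rhat, ESS.
#' @export
summary.growth_fit <- function(object, probs = c(0.025, 0.975), ...) {
  rows <- lapply(object$groups, function(g) {
    arr <- object$draws[[g]]
    do.call(rbind, lapply(dimnames(arr)[[3]], function(p) {
      x <- as.vector(arr[, , p])
      q <- stats::quantile(x, probs)
      data.frame(group = g, parameter = p, median = stats::median(x),
                 t(as.matrix(q)), check.names = FALSE, row.names = NULL)
    }))
  })
  out <- do.call(rbind, rows)
  merge(out, object$diagnostics, by = c("group", "parameter"), sort = FALSE)
}

.pooled_param <- function(fit, group, param) {
  arr <- fit$draws[[group]]
  if (is.null(arr)) stop("group not in fit: ", group)
  as.vector(arr[, , param])
}

#' Posterior hypothesis test on growth parameters
#'
#' Evaluates, for one accession, whether a growth parameter is at least
#' `margin` (as a fraction) larger under well-watered (WW) than under
#' water-limited (WL) conditions. The posterior probability is the fraction
#' of draws with `(theta_WW - theta_WL)/theta_WL > margin`; the effect size
#' is the posterior median of `100 * (theta_WW - theta_WL)/theta_WL`.
#' Hypothesis ids: `asymptote_50` (`A`, margin 0.5), `inflection_5` (`B`,
#' margin 0.05), `rate_5` (`C`, margin 0.05).
#'
#' @param fit A `"growth_fit"` containing both `<accession>:WW` and
#'   `<accession>:WL` groups.
#' @param accession Accession name.
#' @param id Hypothesis id.
#' @param margin Optional margin override (fraction).
#' @param support_threshold Posterior probability needed to declare support.
#' @return List with `hypothesis`, `accession`, `probability`, `effect_size`
#'   (posterior median percent difference), `supported`.
#' @export
test_hypothesis <- function(fit, accession,
                            id = c("asymptote_50", "inflection_5", "rate_5"),
                            margin = NULL, support_threshold = 0.95) {
  id <- match.arg(id)
  spec <- switch(id,
                 asymptote_50 = list(param = "A", margin = 0.5),
                 inflection_5 = list(param = "B", margin = 0.05),
                 rate_5       = list(param = "C", margin = 0.05))
  if (!is.null(margin)) spec$margin <- margin
  ww <- .pooled_param(fit, paste0(accession, ":WW"), spec$param)
  wl <- .pooled_param(fit, paste0(accession, ":WL"), spec$param)
  rel <- (ww - wl) / wl
  prob <- mean(rel > spec$margin)
  list(hypothesis = id, accession = accession, parameter = spec$param,
       margin = spec$margin, probability = prob,
       effect_size = stats::median(100 * rel),
       supported = prob >= support_threshold)
}

#' Posterior predictive quantile ribbons
#'
#' Simulates observations from the fitted Student-t observation model at
#' parameter values drawn from the posterior, and returns per-day quantiles
#' of the simulated observations for one group.
#'
#' @param fit A `"growth_fit"`.
#' @param group Group label (`"<accession>:<treatment>"`).
#' @param days Numeric vector of days at which to evaluate.
#' @param probs Quantile levels of the ribbon.
#' @param seed RNG seed for the predictive simulation.
#' @return Data frame: day, one column per quantile level.
#' @export
posterior_predictive <- function(fit, group, days,
                                 probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                                 seed = 1) {
  arr <- fit$draws[[group]]
  if (is.null(arr)) stop("group not in fit: ", group)
  flat <- apply(arr, 3, as.vector)  # draws*chains x 7
  set.seed(seed)
  out <- lapply(days, function(d) {
    mu <- gompertz_mean(d, flat[, "A"], flat[, "B"], flat[, "C"])
    sd <- variance_profile(d, flat[, "subA"], flat[, "subB"], flat[, "subC"])
    y <- mu + sd * stats::rt(nrow(flat), df = flat[, "nu"])
    stats::quantile(y, probs)
  })
  data.frame(day = days, do.call(rbind, out), check.names = FALSE,
             row.names = NULL)
}
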