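#' Gompertz mean growth curve
#'
#' Expected plant area at time `t` under the Gompertz parameterization in
#' which `B` is literally the inflection time in days:
#' \deqn{\mu(t) = A \exp(-\exp(-C (t - B)))}
#' The curve is strictly increasing in `t`, equals `A/e` at `t = B`, and
#' approaches the asymptote `A` as `t` grows.
#'
#' @param t Numeric vector of times (days since treatment start).
#' @param A Asymptote (cm^2), `> 0`.
#' @param B Inflection time (days), `> 0`.
#' @param C Growth rate (per day), `> 0`.
#' @return Numeric vector of expected areas (cm^2).
#' @examples
#' gompertz_mean(15, A = 130, B = 15, C = 0.25) # = 130/e
#' @export
gompertz_mean <- function(t, A, B, C) {
  stopifnot(is.numeric(t), A > 0, B > 0, C > 0)
  A * exp(-exp(-C * (t - B)))
}

#' Logistic variance profile
#'
#' Residual standard deviation of plant area as a function of time, modelled
#' as a logistic rise towards an asymptote:
#' \deqn{\sigma(t) = subA / (1 + \exp(-subC (t - subB)))}
#' so that variability grows as plants grow. Equals `subA/2` at `t = subB`
#' and approaches `subA` for large `t`.
#'
#' @param t Numeric vector of times (days).
#' @param subA Asymptotic standard deviation (cm^2), `> 0`.
#' @param subB Inflection time of the variance rise (days), `> 0`.
#' @param subC Rate of the variance rise (per day), `> 0`.
#' @return Numeric vector of standard deviations (cm^2).
#' @examples
#' variance_profile(10, subA = 20, subB = 10, subC = 3) # = 10
#' @export
variance_profile <- function(t, subA, subB, subC) {
  stopifnot(is.numeric(t), subA > 0, subB > 0, subC > 0)
  subA / (1 + exp(-subC * (t - subB)))
}
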