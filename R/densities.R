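## Pure model mathematics: link functions and the three conditional
## densities (emotion increment, degradation increment, observation), plus
## the impact-count pmf. No sampling, no I/O.

sigmoid <- function(x) stats::plogis(x)

#' Drift of the emotional state over one inter-visit interval
#'
#' The mean change of the emotional state M over an interval of length
#' \code{dt} is \code{c_mu * tanh(w_delta_pos * delta_pos + w_delta_neg *
#' delta_neg + w_z'z + w_d * d_prev + w_0) * dt}: a bounded, saturating
#' function of the cumulative emotional impacts, the covariates, and the
#' degradation level at the start of the interval. Its absolute value never
#' exceeds \code{c_mu * dt}.
#'
#' @param params A [pe_params()] object.
#' @param delta_neg,delta_pos Non-negative cumulative negative/positive
#'   impact over the interval.
#' @param z Covariate vector at the start of the interval; length must match
#'   \code{params$w_z}.
#' @param d_prev Non-negative degradation level at the start of the interval.
#' @param dt Positive interval length.
#' @return The drift (a single number).
#' @examples
#' p <- pe_setting(1)$params
#' drift_mu(p, delta_neg = 0, delta_pos = 2, d_prev = 4, dt = 1) # 3*tanh(0.4)
#' @export
drift_mu <- function(params, delta_neg = 0, delta_pos = 0, z = numeric(0),
                     d_prev = 0, dt = 1) {
  if (!all(dt > 0)) stop("dt must be strictly positive")
  if (length(z) != length(params$w_z))
    stop("covariate length mismatch: z has length ", length(z),
         " but w_z has length ", length(params$w_z))
  zterm <- if (length(z)) sum(params$w_z * z) else 0
  x <- params$w_delta_pos * delta_pos + params$w_delta_neg * delta_neg +
    zterm + params$w_d * d_prev + params$w_0
  params$c_mu * tanh(x) * dt
}

#' Shape of the gamma degradation increment
#'
#' The degradation increment over an interval of length \code{dt} is gamma
#' distributed with shape \code{c_ga * sigmoid(m_prev) * dt} and rate
#' \code{beta}: a higher emotional state at the start of the interval
#' accelerates degradation, with the logistic link keeping the shape in
#' \code{(0, c_ga * dt)}.
#'
#' @inheritParams drift_mu
#' @param m_prev Emotional state at the start of the interval.
#' @return The gamma shape (single positive number; 0 only in the degenerate
#'   \code{c_ga = 0} mode).
#' @examples
#' gamma_shape(pe_setting(1)$params, m_prev = 0, dt = 1) # 10 * 1/2 = 5
#' @export
gamma_shape <- function(params, m_prev, dt = 1) {
  if (!all(dt > 0)) stop("dt must be strictly positive")
  params$c_ga * sigmoid(m_prev) * dt
}

#' Log-density of an emotional-state increment
#'
#' Normal log-density of \code{dm} with mean [drift_mu()] and standard
#' deviation \code{sigma * sqrt(dt)}.
#'
#' @inheritParams drift_mu
#' @param dm Observed increment of the emotional state.
#' @return Log-density (single number).
#' @export
logpdf_emotion_increment <- function(params, dm, delta_neg = 0, delta_pos = 0,
                                     z = numeric(0), d_prev = 0, dt = 1) {
  if (!all(dt > 0)) stop("dt must be strictly positive")
  mu <- drift_mu(params, delta_neg, delta_pos, z, d_prev, dt)
  stats::dnorm(dm, mean = mu, sd = params$sigma * sqrt(dt), log = TRUE)
}

#' Log-density of a degradation increment
#'
#' Gamma log-density of \code{dd} with shape [gamma_shape()] and rate
#' \code{beta}. Negative increments are outside the support and return
#' \code{-Inf} (degradation is irreversible). The degenerate \code{c_ga = 0}
#' mode has no density and is rejected.
#'
#' @inheritParams gamma_shape
#' @param dd Observed degradation increment.
#' @return Log-density; \code{-Inf} for \code{dd < 0}.
#' @export
logpdf_degradation_increment <- function(params, dd, m_prev, dt = 1) {
  if (!all(dt > 0)) stop("dt must be strictly positive")
  if (params$c_ga == 0)
    stop("degenerate mode c_ga = 0: degradation increment has no density")
  shape <- gamma_shape(params, m_prev, dt)
  out <- rep(-Inf, length(dd))
  ok <- dd >= 0
  out[ok] <- stats::dgamma(dd[ok], shape = rep(shape, length.out = length(dd))[ok],
                           rate = params$beta, log = TRUE)
  if (length(dd) == 1L) out[[1L]] else out
}

#' Log-density of an observed score
#'
#' Normal log-density of the score \code{y} given the latent state: mean
#' \code{h_0 + h_d * d + h_m * m}, standard deviation \code{sigma_eps}.
#'
#' @inheritParams drift_mu
#' @param y Observed score.
#' @param d Non-negative degradation level at the observation time.
#' @param m Emotional state at the observation time.
#' @return Log-density.
#' @export
logpdf_observation <- function(params, y, d, m) {
  stats::dnorm(y, mean = params$h_0 + params$h_d * d + params$h_m * m,
               sd = params$sigma_eps, log = TRUE)
}

#' Log-probability of an impact count
#'
#' The number of emotional impacts in an interval of length \code{dt} follows
#' a Poisson distribution with mean \code{k * dt}.
#'
#' @param k Positive event rate.
#' @param n Non-negative integer count.
#' @param dt Positive interval length.
#' @return Log-probability.
#' @export
logpmf_impact_count <- function(k, n, dt = 1) {
  if (!all(dt > 0)) stop("dt must be strictly positive")
  if (any(!is.finite(n)) || any(n < 0) || any(n != as.integer(n)))
    stop("n must be a non-negative integer")
  stats::dpois(n, lambda = k * dt, log = TRUE)
}
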