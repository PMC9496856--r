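#' Model parameters for the coupled degradation-emotion process
#'
#' Bundles every generative coefficient of the model: the compound-Poisson
#' emotional-impact processes (rates \code{k_pos}, \code{k_neg}; exponential
#' mark rates \code{lambda_pos}, \code{lambda_neg}), the Wiener emotional
#' state (drift coefficients \code{w_delta_pos}, \code{w_delta_neg},
#' \code{w_z}, \code{w_d}, \code{w_0}; drift amplitude \code{c_mu};
#' diffusion \code{sigma}), the gamma degradation process (shape amplitude
#' \code{c_ga}, rate \code{beta}), and the linear-Gaussian observation model
#' (\code{h_0}, \code{h_d}, \code{h_m}, noise sd \code{sigma_eps}).
#'
#' @param k_pos,k_neg Positive rates of the positive/negative impact Poisson
#'   processes (events per unit time).
#' @param lambda_pos,lambda_neg Positive exponential rates of the impact
#'   intensities (marks), so a single impact has mean size \code{1/lambda}.
#' @param w_delta_pos,w_delta_neg Drift regression coefficients on the
#'   cumulative positive/negative impacts over an inter-visit interval.
#' @param w_z Numeric vector of covariate coefficients (length 0 if the model
#'   carries no covariates).
#' @param w_d Drift coefficient on the previous degradation level.
#' @param w_0 Drift intercept.
#' @param c_mu Positive drift amplitude: the per-unit-time mean change of the
#'   emotional state is bounded in \code{[-c_mu, c_mu]}.
#' @param sigma Positive Wiener diffusion coefficient (per square-root time).
#' @param c_ga Non-negative gamma shape amplitude per unit time. \code{c_ga =
#'   0} is a degenerate mode in which the degradation increment is identically
#'   zero; density evaluation rejects it but simulation supports it.
#' @param beta Positive rate parameter of the gamma degradation increments.
#' @param h_0 Observation intercept (score units; the score of a subject with
#'   zero degradation and neutral emotion).
#' @param h_d,h_m Loadings of the degradation level and emotional state on
#'   the observed score.
#' @param sigma_eps Positive observation noise standard deviation (score
#'   units).
#' @param allow_degenerate If \code{TRUE}, permit zero values for the impact
#'   rates, \code{sigma} and \code{sigma_eps} (noise-off modes used in exact
#'   degeneracy checks); the default enforces strict positivity.
#' @return An object of class \code{"pe_params"} (a validated named list).
#' @examples
#' p <- pe_params(c_ga = 10, beta = 10)
#' p$c_ga
#' @seealso [pe_setting()] for the five standard synthetic presets.
#' @export
pe_params <- function(k_pos = 5, k_neg = 4, lambda_pos = 3, lambda_neg = 3,
                      w_delta_pos = 0.1, w_delta_neg = -0.1,
                      w_z = numeric(0), w_d = 0.05, w_0 = 0,
                      c_mu = 3, sigma = 0.5, c_ga = 10, beta = 10,
                      h_0 = 30, h_d = -1, h_m = -0.5, sigma_eps = 1,
                      allow_degenerate = FALSE) {
  p <- list(k_pos = k_pos, k_neg = k_neg,
            lambda_pos = lambda_pos, lambda_neg = lambda_neg,
            w_delta_pos = w_delta_pos, w_delta_neg = w_delta_neg,
            w_z = as.numeric(w_z), w_d = w_d, w_0 = w_0,
            c_mu = c_mu, sigma = sigma, c_ga = c_ga, beta = beta,
            h_0 = h_0, h_d = h_d, h_m = h_m, sigma_eps = sigma_eps)
  scalars <- setdiff(names(p), "w_z")
  for (nm in scalars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  relaxed <- if (allow_degenerate) c("k_pos", "k_neg", "sigma", "sigma_eps")
             else character(0)
  for (nm in c("k_pos", "k_neg", "lambda_pos", "lambda_neg",
               "c_mu", "sigma", "beta", "sigma_eps")) {
    lim_ok <- if (nm %in% relaxed) p[[nm]] >= 0 else p[[nm]] > 0
    if (!lim_ok) stop("parameter '", nm, "' must be strictly positive")
  }
  if (p$c_ga < 0) stop("parameter 'c_ga' must be non-negative")
  if (length(p$w_z) && any(!is.finite(p$w_z)))
    stop("parameter 'w_z' must be finite")
  structure(p, class = "pe_params")
}

#' @export
print.pe_params <- function(x, ...) {
  cat("Coupled degradation-emotion model parameters\n")
  cat(sprintf("  impacts:      k+ = %g, k- = %g, lambda+ = %g, lambda- = %g\n",
              x$k_pos, x$k_neg, x$lambda_pos, x$lambda_neg))
  cat(sprintf("  drift:        w_delta = (%g, %g), w_d = %g, w_0 = %g, c_mu = %g\n",
              x$w_delta_pos, x$w_delta_neg, x$w_d, x$w_0, x$c_mu))
  if (length(x$w_z))
    cat(sprintf("  covariates:   w_z = (%s)\n", paste(x$w_z, collapse = ", ")))
  cat(sprintf("  diffusion:    sigma = %g\n", x$sigma))
  cat(sprintf("  degradation:  c_ga = %g, beta = %g\n", x$c_ga, x$beta))
  cat(sprintf("  observation:  h_0 = %g, h_d = %g, h_m = %g, sigma_eps = %g\n",
              x$h_0, x$h_d, x$h_m, x$sigma_eps))
  invisible(x)
}

#' Standard synthetic parameter settings
#'
#' The five benchmark settings used in the synthetic study. All share the
#' observation model (h_0 = 30, h_d = -1, h_m = -0.5, sigma_eps = 1), drift
#' (w_delta = 0.1/-0.1, w_d = 0.05, w_0 = 0, c_mu = 3, sigma = 0.5) and
#' gamma rate beta = 10, and differ in:
#' \describe{
#'   \item{1}{k+/k- = 5/4, c_ga = 10 (fast degradation).}
#'   \item{2}{k+/k- = 5/4, c_ga = 5 (slower degradation).}
#'   \item{3}{k+/k- = 5/3, c_ga = 5 (positive impacts dominate).}
#'   \item{4}{k+/k- = 3/5, c_ga = 5 (negative impacts dominate).}
#'   \item{5}{c_ga = 5 with a regime switch: k+/k- = 3/5 for intervals ending
#'     at or before the 10th visit after baseline, 5/3 afterwards
#'     (fluctuating emotional environment).}
#' }
#'
#' @param setting_id Integer in 1..5.
#' @return A list of class \code{"pe_setting"} with elements
#'   \code{setting_id}, \code{params}, \code{n_sequences} (20),
#'   \code{n_obs} (21), \code{dt} (1) and, for setting 5 only,
#'   \code{regime_switch = list(switch_index, params_after)} where
#'   \code{switch_index} counts intervals since baseline.
#' @examples
#' pe_setting(1)$params$c_ga  # 10
#' @export
pe_setting <- function(setting_id) {
  if (length(setting_id) != 1L || is.na(setting_id) ||
      setting_id != as.integer(setting_id) || !(setting_id %in% 1:5))
    stop("unknown setting_id: must be an integer in 1..5")
  setting_id <- as.integer(setting_id)
  base <- list(k_pos = 5, k_neg = 4, c_ga = 10)
  base <- switch(setting_id,
                 list(k_pos = 5, k_neg = 4, c_ga = 10),
                 list(k_pos = 5, k_neg = 4, c_ga = 5),
                 list(k_pos = 5, k_neg = 3, c_ga = 5),
                 list(k_pos = 3, k_neg = 5, c_ga = 5),
                 list(k_pos = 3, k_neg = 5, c_ga = 5))
  params <- pe_params(k_pos = base$k_pos, k_neg = base$k_neg, c_ga = base$c_ga)
  out <- list(setting_id = setting_id, params = params,
              n_sequences = 20L, n_obs = 21L, dt = 1)
  if (setting_id == 5L) {
    after <- params
    after$k_pos <- 5
    after$k_neg <- 3
    out$regime_switch <- list(switch_index = 10L, params_after = after)
  }
  class(out) <- "pe_setting"
  out
}

#' @export
print.pe_setting <- function(x, ...) {
  cat(sprintf("Synthetic setting %d: %d sequences x %d observations, dt = %g\n",
              x$setting_id, x$n_sequences, x$n_obs, x$dt))
  print(x$params)
  if (!is.null(x$regime_switch))
    cat(sprintf("  regime switch after interval %d: k+ = %g, k- = %g\n",
                x$regime_switch$switch_index,
                x$regime_switch$params_after$k_pos,
                x$regime_switch$params_after$k_neg))
  invisible(x)
}
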