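#' Joint log-density of data, latent paths and impacts
#'
#' Evaluates the complete-data log-density of a dataset under given
#' parameters: the sum, over subjects and intervals, of the emotion-increment
#' density, the degradation-increment density and the observation density,
#' plus the baseline observation term, plus (optionally) the compound-Poisson
#' impact terms -- the Poisson count probability and the gamma density of the
#' summed exponential marks given the count. Any negative degradation
#' increment puts the path outside the gamma support and yields \code{-Inf}.
#'
#' Every trajectory must carry its latent paths (and impact records when
#' \code{include_impacts = TRUE}).
#'
#' @param params A [pe_params()] object.
#' @param data A [pe_data()] object with latent paths attached.
#' @param include_impacts Add the impact count/mark terms (used when the
#'   impacts are modelled rather than conditioned on).
#' @param init Baseline latent state assumed at each subject's first visit;
#'   defaults to the trajectory's own stored latent baseline.
#' @return A single number (possibly \code{-Inf}).
#' @export
pe_joint_logdensity <- function(params, data, include_impacts = TRUE,
                                init = NULL) {
  stopifnot(inherits(params, "pe_params"), inherits(data, "pe_data"))
  total <- 0
  for (tr in data$trajectories) {
    if (is.null(tr$latent))
      stop("trajectory ", tr$subject_id, " carries no latent paths")
    d <- tr$latent$d; m <- tr$latent$m
    n1 <- length(tr$times)
    if (length(d) != n1 || length(m) != n1)
      stop("latent paths misaligned with the time grid for subject ", tr$subject_id)
    imp <- tr$impacts
    if (is.null(imp)) {
      if (include_impacts)
        stop("trajectory ", tr$subject_id, " carries no impact records")
      imp <- data.frame(n_neg = integer(n1 - 1L), n_pos = integer(n1 - 1L),
                        delta_neg = numeric(n1 - 1L), delta_pos = numeric(n1 - 1L))
    }
    total <- total + logpdf_observation(params, tr$y[1L], d[1L], m[1L])
    for (j in seq_len(n1 - 1L)) {
      dt <- tr$times[j + 1L] - tr$times[j]
      zrow <- if (is.null(tr$z)) numeric(0) else tr$z[j, ]
      dd <- d[j + 1L] - d[j]
      if (dd < 0) return(-Inf)
      total <- total +
        logpdf_emotion_increment(params, m[j + 1L] - m[j],
                                 delta_neg = imp$delta_neg[j],
                                 delta_pos = imp$delta_pos[j],
                                 z = zrow, d_prev = d[j], dt = dt) +
        logpdf_degradation_increment(params, dd, m_prev = m[j], dt = dt) +
        logpdf_observation(params, tr$y[j + 1L], d[j + 1L], m[j + 1L])
      if (include_impacts) {
        total <- total +
          logpmf_impact_count(params$k_neg, imp$n_neg[j], dt) +
          logpmf_impact_count(params$k_pos, imp$n_pos[j], dt)
        if (imp$n_neg[j] > 0)
          total <- total + stats::dgamma(imp$delta_neg[j], shape = imp$n_neg[j],
                                         rate = params$lambda_neg, log = TRUE)
        if (imp$n_pos[j] > 0)
          total <- total + stats::dgamma(imp$delta_pos[j], shape = imp$n_pos[j],
                                         rate = params$lambda_pos, log = TRUE)
      }
      if (!is.finite(total)) return(-Inf)
    }
  }
  total
}
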