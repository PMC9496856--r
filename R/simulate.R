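## Generative simulator: compound-Poisson emotional impacts, Wiener emotional
## state with bounded tanh drift, gamma degradation with emotion-linked
## shape, and the Gaussian score observation. One RNG substream per
## trajectory (L'Ecuyer-CMRG) so enlarging a dataset never perturbs the
## trajectories already generated.

#' Sample the emotional impacts of one interval
#'
#' Draws the number of impacts from a Poisson distribution with mean
#' \code{k * dt} and their total intensity as the sum of that many
#' independent exponential marks with rate \code{lam}. The total is zero
#' exactly when the count is zero.
#'
#' @param k Non-negative impact rate (0 is the empty-process limit).
#' @param lam Positive exponential rate of a single impact's intensity.
#' @param dt Positive interval length.
#' @return A list with elements \code{count} and \code{total}.
#' @examples
#' set.seed(1); sample_impacts(5, 3, 1)
#' @export
sample_impacts <- function(k, lam, dt = 1) {
  if (!is.finite(k) || !is.finite(lam) || !is.finite(dt))
    stop("k, lam and dt must be finite")
  if (k < 0 || lam <= 0 || dt <= 0)
    stop("require k >= 0, lam > 0, dt > 0")
  count <- if (k == 0) 0L else stats::rpois(1L, k * dt)
  total <- if (count > 0L) sum(stats::rexp(count, rate = lam)) else 0
  list(count = count, total = total)
}

.interval_params <- function(params, regime_switch, interval) {
  if (!is.null(regime_switch) && interval > regime_switch$switch_index)
    regime_switch$params_after
  else params
}

#' Simulate one subject trajectory
#'
#' Iterates the model over the intervals of \code{times}: per interval the
#' impacts are sampled first, then the emotional state is updated using the
#' degradation level at the start of the interval, then the degradation is
#' updated using the emotional state at the start of the interval, and
#' finally the score is emitted from the new latent state. The simulated
#' degradation path is non-decreasing by construction.
#'
#' @param params A [pe_params()] object.
#' @param times Strictly increasing visit times (the first is baseline).
#' @param z Optional covariate matrix, one row per visit.
#' @param init Named numeric \code{c(d = , m = )} initial latent state
#'   (defaults to zero: no degradation, neutral emotion).
#' @param subject_id Identifier for the resulting trajectory.
#' @param regime_switch Optional \code{list(switch_index, params_after)}:
#'   intervals after the \code{switch_index}-th use \code{params_after}.
#' @param clip If \code{TRUE}, clamp emitted scores with [clip_score()].
#' @return A [pe_trajectory()] with latent paths and impact records attached.
#' @export
simulate_trajectory <- function(params, times, z = NULL,
                                init = c(d = 0, m = 0), subject_id = "s1",
                                regime_switch = NULL, clip = FALSE) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (init[["d"]] < 0) stop("initial degradation must be non-negative")
  n1 <- length(times)
  if (!is.null(z)) z <- as.matrix(z)
  d <- m <- y <- numeric(n1)
  d[1] <- init[["d"]]; m[1] <- init[["m"]]
  y[1] <- stats::rnorm(1L, params$h_0 + params$h_d * d[1] + params$h_m * m[1],
                       params$sigma_eps)
  imp <- data.frame(n_neg = integer(n1 - 1L), n_pos = integer(n1 - 1L),
                    delta_neg = numeric(n1 - 1L), delta_pos = numeric(n1 - 1L))
  for (j in seq_len(n1 - 1L)) {
    p <- .interval_params(params, regime_switch, j)
    dt <- times[j + 1L] - times[j]
    neg <- sample_impacts(p$k_neg, p$lambda_neg, dt)
    pos <- sample_impacts(p$k_pos, p$lambda_pos, dt)
    imp[j, ] <- list(neg$count, pos$count, neg$total, pos$total)
    zrow <- if (is.null(z)) numeric(0) else z[j, ]
    mu <- drift_mu(p, delta_neg = neg$total, delta_pos = pos$total, z = zrow,
                   d_prev = d[j], dt = dt)
    m[j + 1L] <- m[j] + mu + p$sigma * sqrt(dt) * stats::rnorm(1L)
    shape <- gamma_shape(p, m_prev = m[j], dt = dt)
    dd <- if (shape > 0) stats::rgamma(1L, shape = shape, rate = p$beta) else 0
    d[j + 1L] <- d[j] + dd
    y[j + 1L] <- stats::rnorm(1L, p$h_0 + p$h_d * d[j + 1L] + p$h_m * m[j + 1L],
                              p$sigma_eps)
  }
  if (clip) y <- clip_score(y)
  pe_trajectory(subject_id, times, y, z = z,
                latent = data.frame(d = d, m = m),
                impacts = if (n1 > 1L) imp else NULL)
}

## L'Ecuyer-CMRG substream states derived from a root seed: state i is
## reached by advancing the stream i times, so state i never depends on how
## many later streams are requested
.substream_states <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  suppressWarnings(set.seed(seed, kind = "L'Ecuyer-CMRG"))
  s <- get(".Random.seed", envir = globalenv())
  states <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    states[[i]] <- s
  }
  states
}

## run fn() with the RNG positioned at the given substream state, restoring
## the caller's RNG afterwards
.with_rng_state <- function(state, fn) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  assign(".Random.seed", state, envir = globalenv())
  fn()
}

## convenience: the index-th substream of seed (O(index); use
## .substream_states when many are needed)
.with_substream <- function(seed, index, fn) {
  states <- .substream_states(seed, index)
  .with_rng_state(states[[index]], fn)
}

#' Generate a synthetic dataset
#'
#' Draws a dataset from the generative model, either from one of the five
#' standard settings ([pe_setting()]) or from explicit parameters. Each
#' trajectory uses its own RNG substream derived from \code{seed}, so the
#' same seed reproduces the dataset bit for bit and increasing
#' \code{n_sequences} extends a dataset without changing earlier
#' trajectories.
#'
#' @param setting Integer 1..5 or a [pe_setting()] object; mutually exclusive
#'   with \code{params}.
#' @param params A [pe_params()] object (used when \code{setting} is NULL).
#' @param n_sequences Number of trajectories (default: preset value or 20).
#' @param n_obs Observations per trajectory (default: preset value or 21).
#' @param dt Uniform visit spacing (default: preset value or 1); ignored when
#'   \code{times} is given.
#' @param seed Integer seed (required: no silent nondeterminism).
#' @param times Optional explicit visit-time grid shared by all trajectories.
#' @param z Optional covariate matrix (one row per visit, recycled across
#'   subjects) or a list of per-subject matrices.
#' @param init Initial latent state, as in [simulate_trajectory()].
#' @param clip Clamp scores to the 0-30 instrument range (off by default).
#' @return A [pe_data()] object carrying latent paths and impact records.
#' @examples
#' d <- pe_simulate(setting = 1, n_sequences = 2, seed = 1)
#' d
#' @export
pe_simulate <- function(setting = NULL, params = NULL, n_sequences = NULL,
                        n_obs = NULL, dt = NULL, seed, times = NULL, z = NULL,
                        init = c(d = 0, m = 0), clip = FALSE) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an explicit integer seed is required")
  preset <- NULL
  regime_switch <- NULL
  if (!is.null(setting)) {
    preset <- if (inherits(setting, "pe_setting")) setting else pe_setting(setting)
    params <- preset$params
    regime_switch <- preset$regime_switch
    if (is.null(n_sequences)) n_sequences <- preset$n_sequences
    if (is.null(n_obs)) n_obs <- preset$n_obs
    if (is.null(dt)) dt <- preset$dt
  } else if (is.null(params)) {
    stop("either setting or params must be given")
  }
  if (is.null(n_sequences)) n_sequences <- 20L
  if (is.null(n_obs)) n_obs <- 21L
  if (is.null(dt)) dt <- 1
  if (is.null(times)) times <- seq(0, by = dt, length.out = n_obs)
  states <- .substream_states(seed, n_sequences)
  trs <- lapply(seq_len(n_sequences), function(i) {
    zi <- if (is.list(z) && !is.data.frame(z)) z[[i]] else z
    .with_rng_state(states[[i]], function()
      simulate_trajectory(params, times, z = zi, init = init,
                          subject_id = sprintf("s%03d", i),
                          regime_switch = regime_switch, clip = clip))
  })
  pe_data(trs, preset = preset, seed = as.integer(seed))
}
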