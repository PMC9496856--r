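## Sequential one-step-ahead forecasting. The default engine is a particle
## filter over (parameter, latent-state) particles: parameters are drawn
## from a fitted posterior (or from the prior), each particle carries its
## own latent (D, M) state, observations reweight and resample the cloud,
## and a forecast propagates the filtered cloud one interval forward --
## sampling the coming interval's emotional impacts from their
## compound-Poisson law -- and emits predictive score draws. Forecasts never
## condition on data at or after their target time.

## one length-J parameter vector per model parameter (w_z as a J x p matrix)
.particle_params <- function(fit_or_priors, J) {
  if (inherits(fit_or_priors, "pe_fit")) {
    priors <- fit_or_priors$priors
    draws <- pe_posterior_draws(fit_or_priors)
    idx <- sample.int(nrow(draws), J, replace = TRUE)
    draws <- draws[idx, , drop = FALSE]
  } else if (inherits(fit_or_priors, "pe_priors")) {
    priors <- fit_or_priors
    draws <- pe_prior_draws(priors, J)
  } else stop("fit_or_priors must be a pe_fit or pe_priors object")
  pp <- list()
  template <- pe_params()
  cn <- colnames(draws)
  if (is.null(cn)) cn <- character(0)
  for (nm in setdiff(names(template), "w_z")) {
    if (nm %in% cn) pp[[nm]] <- as.numeric(draws[, nm])
    else if (nm %in% names(priors$fixed)) pp[[nm]] <- rep(priors$fixed[[nm]], J)
    else stop("parameter '", nm, "' is neither sampled nor fixed")
  }
  wz_cols <- grep("^w_z\\[", cn, value = TRUE)
  if (length(wz_cols)) pp$w_z <- draws[, wz_cols, drop = FALSE]
  else if ("w_z" %in% names(priors$fixed) && length(priors$fixed$w_z))
    pp$w_z <- matrix(priors$fixed$w_z, J, length(priors$fixed$w_z), byrow = TRUE)
  else pp$w_z <- NULL
  pp
}

## propagate the particle cloud over one interval; imp = observed impact row
## (list with delta_pos, delta_neg) or NULL to sample from the prior
.pf_propagate <- function(pp, D, M, dt, z = numeric(0), imp = NULL) {
  J <- length(D)
  if (is.null(imp)) {
    npos <- stats::rpois(J, pp$k_pos * dt)
    nneg <- stats::rpois(J, pp$k_neg * dt)
    dp <- stats::rgamma(J, shape = npos, rate = pp$lambda_pos)
    dn <- stats::rgamma(J, shape = nneg, rate = pp$lambda_neg)
    dp[npos == 0L] <- 0; dn[nneg == 0L] <- 0
  } else {
    dp <- rep(imp$delta_pos, length.out = J)
    dn <- rep(imp$delta_neg, length.out = J)
  }
  zterm <- if (length(z) && !is.null(pp$w_z)) as.numeric(pp$w_z %*% z) else 0
  mu <- pp$c_mu * tanh(pp$w_delta_pos * dp + pp$w_delta_neg * dn + zterm +
                         pp$w_d * D + pp$w_0) * dt
  Mn <- M + mu + pp$sigma * sqrt(dt) * stats::rnorm(J)
  shape <- pp$c_ga * stats::plogis(M) * dt
  dd <- stats::rgamma(J, shape = shape, rate = pp$beta)
  dd[shape == 0] <- 0
  list(D = D + dd, M = Mn)
}

.pf_obs_logw <- function(pp, y, D, M) {
  mean_y <- pp$h_0 + pp$h_d * D + pp$h_m * M
  lw <- ifelse(pp$sigma_eps > 0,
               stats::dnorm(y, mean_y, pp$sigma_eps, log = TRUE),
               ifelse(abs(y - mean_y) < 1e-9, 0, -Inf))
  lw
}

.systematic_resample <- function(logw, J) {
  mx <- max(logw)
  if (!is.finite(mx)) {
    warning("all particle weights vanished; falling back to uniform weights")
    return(seq_len(J))
  }
  w <- exp(logw - mx)
  cw <- cumsum(w) / sum(w)
  u <- (stats::runif(1) + seq_len(J) - 1) / J
  findInterval(u, cw) + 1L
}

## run the filter along one trajectory, emitting a forecast for t_{i+1}
## whenever i >= i_min (i counts observations after baseline, 0-based); if
## final_target is given, also forecast that time after assimilating all
## observations
.pe_filter <- function(tr, pp, i_min, J, init, final_target = NULL) {
  n1 <- length(tr$times)
  D <- rep(init[["d"]], J); M <- rep(init[["m"]], J)
  logw <- .pf_obs_logw(pp, tr$y[1L], D, M)
  fc <- list(); dr <- list()
  emit <- function(Dc, Mc, ppc, target_time) {
    ydraw <- ppc$h_0 + ppc$h_d * Dc + ppc$h_m * Mc +
      ppc$sigma_eps * stats::rnorm(length(Dc))
    list(row = data.frame(subject_id = tr$subject_id, target_time = target_time,
                          predictive_mean = mean(ydraw),
                          q05 = stats::quantile(ydraw, 0.05, names = FALSE),
                          q95 = stats::quantile(ydraw, 0.95, names = FALSE),
                          stringsAsFactors = FALSE),
         draws = ydraw)
  }
  sub <- function(ppl, idx) {
    out <- lapply(ppl[setdiff(names(ppl), "w_z")], `[`, idx)
    if (!is.null(ppl$w_z)) out$w_z <- ppl$w_z[idx, , drop = FALSE]
    out
  }
  for (v in seq_len(n1 - 1L)) {
    dt <- tr$times[v + 1L] - tr$times[v]
    zrow <- if (is.null(tr$z)) numeric(0) else tr$z[v, ]
    idx <- .systematic_resample(logw, J)
    D <- D[idx]; M <- M[idx]; ppv <- sub(pp, idx)
    if (v - 1L >= i_min) {
      st <- .pf_propagate(ppv, D, M, dt, zrow, imp = NULL)
      e <- emit(st$D, st$M, ppv, tr$times[v + 1L])
      fc[[length(fc) + 1L]] <- e$row
      dr[[length(dr) + 1L]] <- e$draws
    }
    imp <- if (!is.null(tr$impacts))
      list(delta_pos = tr$impacts$delta_pos[v], delta_neg = tr$impacts$delta_neg[v])
    else NULL
    st <- .pf_propagate(ppv, D, M, dt, zrow, imp = imp)
    D <- st$D; M <- st$M; pp <- ppv
    logw <- .pf_obs_logw(pp, tr$y[v + 1L], D, M)
  }
  if (!is.null(final_target)) {
    if (final_target <= tr$times[n1])
      stop("target time must exceed the last observed time")
    dt <- final_target - tr$times[n1]
    idx <- .systematic_resample(logw, J)
    ppv <- sub(pp, idx)
    zrow <- if (is.null(tr$z)) numeric(0) else tr$z[n1, ]
    st <- .pf_propagate(ppv, D[idx], M[idx], dt, zrow, imp = NULL)
    e <- emit(st$D, st$M, ppv, final_target)
    fc[[length(fc) + 1L]] <- e$row
    dr[[length(dr) + 1L]] <- e$draws
  }
  list(forecasts = do.call(rbind, fc), draws = dr)
}

.as_forecasts <- function(rows, draws) {
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "draws") <- do.call(c, draws)
  class(out) <- c("pe_forecasts", "data.frame")
  out
}

#' One-step-ahead forecast for a single subject
#'
#' Assimilates the subject's full history with the particle filter and
#' forecasts the score at \code{target_time}: per particle the latent state
#' is propagated one interval forward (the coming interval's emotional
#' impacts drawn from their compound-Poisson law) and a predictive score is
#' emitted; the predictive mean and the 5-95% interval summarize the draws.
#'
#' @param history A [pe_trajectory()] (at least one observation).
#' @param fit_or_priors A [pe_fit()] (posterior parameters) or [pe_priors()]
#'   (prior parameters) object.
#' @param target_time Forecast time; defaults to extending the last observed
#'   spacing (or \code{+1} for a single observation).
#' @param n_particles Particle count.
#' @param seed Integer seed.
#' @param init Baseline latent state.
#' @return A one-row \code{"pe_forecasts"} data frame (columns
#'   \code{subject_id}, \code{target_time}, \code{predictive_mean},
#'   \code{q05}, \code{q95}) with the predictive draws in
#'   \code{attr(, "draws")}.
#' @export
pe_forecast_next <- function(history, fit_or_priors, target_time = NULL,
                             n_particles = 4000, seed = 1,
                             init = c(d = 0, m = 0)) {
  stopifnot(inherits(history, "pe_trajectory"))
  n1 <- length(history$times)
  if (is.null(target_time))
    target_time <- history$times[n1] +
      if (n1 >= 2L) diff(history$times)[n1 - 1L] else 1
  if (target_time <= history$times[n1])
    stop("target time must exceed the last observed time")
  .with_substream(seed, 1L, function() {
    pp <- .particle_params(fit_or_priors, n_particles)
    res <- .pe_filter(history, pp, i_min = Inf, J = n_particles, init = init,
                      final_target = target_time)
    .as_forecasts(list(res$forecasts), res$draws)
  })
}

#' Sequential one-step-ahead forecasts
#'
#' Walks each trajectory forward in time: for every visit index \code{i}
#' from \code{i_min} on, the model conditions on the observations up to and
#' including \code{t_i} and forecasts the score at \code{t_{i+1}}. Forecasts
#' never condition on data at or after their target time. The default
#' \code{"particle"} method makes one filtering pass per trajectory,
#' reweighting the (parameter, latent-state) cloud as each observation
#' arrives; \code{"refit"} reruns the MCMC on each history prefix (much
#' slower) and then launches the forecast from that fit's smoothed terminal
#' latent state.
#'
#' @param data A [pe_data()] object or a single [pe_trajectory()].
#' @param fit_or_priors A [pe_fit()] or [pe_priors()] object ("refit"
#'   requires priors).
#' @param i_min First forecast origin: number of post-baseline observations
#'   that must have been seen before the first forecast (default 1, so the
#'   first forecast conditions on two observations; 0 forecasts from the
#'   baseline visit alone).
#' @param n_particles Particle count per trajectory.
#' @param seed Integer seed (per-trajectory substreams).
#' @param method \code{"particle"} (default) or \code{"refit"}.
#' @param control [pe_control()] for the per-step refits (refit method only).
#' @param init Baseline latent state.
#' @return A \code{"pe_forecasts"} data frame, one row per forecast, with
#'   predictive draws concatenated in \code{attr(, "draws")}.
#' @export
pe_forecast <- function(data, fit_or_priors, i_min = 1, n_particles = 4000,
                        seed = 1, method = c("particle", "refit"),
                        control = NULL, init = c(d = 0, m = 0)) {
  method <- match.arg(method)
  if (inherits(data, "pe_trajectory")) data <- pe_data(list(data))
  stopifnot(inherits(data, "pe_data"))
  for (tr in data$trajectories)
    if (length(tr$times) < 2L)
      stop("insufficient data: sequential forecasting needs at least 2 observations")
  if (method == "particle") {
    rows <- list(); drl <- list()
    for (s in seq_along(data$trajectories)) {
      tr <- data$trajectories[[s]]
      res <- .with_substream(seed, s, function() {
        pp <- .particle_params(fit_or_priors, n_particles)
        .pe_filter(tr, pp, i_min = i_min, J = n_particles, init = init)
      })
      rows[[s]] <- res$forecasts
      drl[[s]] <- res$draws
    }
    return(.as_forecasts(rows, do.call(c, drl)))
  }
  ## refit: rerun the MCMC on every history prefix
  if (!inherits(fit_or_priors, "pe_priors"))
    stop("method = 'refit' updates from a prior specification; pass pe_priors")
  if (i_min < 1) stop("refit needs i_min >= 1 (a prefix of at least 2 observations)")
  if (is.null(control)) control <- pe_control()
  rows <- list(); drl <- list()
  for (s in seq_along(data$trajectories)) {
    tr <- data$trajectories[[s]]
    n1 <- length(tr$times)
    if (i_min > n1 - 2L) next
    for (i in seq.int(i_min, n1 - 2L)) {
      keep <- seq_len(i + 1L)
      prefix <- pe_trajectory(tr$subject_id, tr$times[keep], tr$y[keep],
                              z = if (!is.null(tr$z)) tr$z[keep, , drop = FALSE],
                              impacts = if (!is.null(tr$impacts))
                                tr$impacts[seq_len(i), , drop = FALSE])
      ctl <- control
      ctl$seed <- control$seed + 1000L * s + i
      fit <- pe_fit(pe_data(list(prefix)), fit_or_priors, ctl, init = init,
                    monitor_latent = TRUE)
      res <- .with_substream(seed, 1000L * s + i, function() {
        draws <- pe_posterior_draws(fit)
        lat <- do.call(rbind, lapply(fit$latent, as.matrix))
        J <- nrow(draws)
        pp <- .particle_params(fit, J)
        Dv <- lat[, sprintf("D[1,%d]", i + 1L)]
        Mv <- lat[, sprintf("M[1,%d]", i + 1L)]
        dt <- tr$times[i + 2L] - tr$times[i + 1L]
        zrow <- if (is.null(tr$z)) numeric(0) else tr$z[i + 1L, ]
        st <- .pf_propagate(pp, Dv, Mv, dt, zrow, imp = NULL)
        ydraw <- pp$h_0 + pp$h_d * st$D + pp$h_m * st$M +
          pp$sigma_eps * stats::rnorm(J)
        list(row = data.frame(subject_id = tr$subject_id,
                              target_time = tr$times[i + 2L],
                              predictive_mean = mean(ydraw),
                              q05 = stats::quantile(ydraw, 0.05, names = FALSE),
                              q95 = stats::quantile(ydraw, 0.95, names = FALSE),
                              stringsAsFactors = FALSE),
             draws = ydraw)
      })
      rows[[length(rows) + 1L]] <- res$row
      drl[[length(drl) + 1L]] <- res$draws
    }
  }
  .as_forecasts(rows, drl)
}

#' @export
print.pe_forecasts <- function(x, digits = 3, ...) {
  cat(sprintf("One-step-ahead forecasts: %d predictions, %d subjects\n",
              nrow(x), length(unique(x$subject_id))))
  print.data.frame(cbind(x[1:2], round(x[3:5], digits)), row.names = FALSE)
  invisible(x)
}

#' Forecasts from a fitted model
#'
#' @param object A [pe_fit()] object.
#' @param newdata A [pe_data()] or [pe_trajectory()] of held-out subjects.
#' @param ... Passed to [pe_forecast()].
#' @return A \code{"pe_forecasts"} data frame.
#' @export
predict.pe_fit <- function(object, newdata, ...) {
  pe_forecast(newdata, object, ...)
}

#' Evaluate forecasts against observed scores
#'
#' Pairs every forecast with the observed score at its (subject, target
#' time) and reports the pooled mean squared error of the predictive means,
#' the per-subject MSEs and their average, and the empirical coverage of the
#' 5-95% intervals.
#'
#' @param forecasts A \code{"pe_forecasts"} data frame.
#' @param data A [pe_data()] holding the realized scores, or \code{NULL} if
#'   \code{truths} is given.
#' @param truths Optional numeric vector of realized scores aligned with the
#'   forecast rows (alternative to \code{data}).
#' @return A list of class \code{"pe_evaluation"}: \code{mse} (pooled),
#'   \code{mse_by_subject}, \code{mse_subject_mean}, \code{coverage_05_95},
#'   \code{n_predictions}.
#' @export
pe_evaluate <- function(forecasts, data = NULL, truths = NULL) {
  stopifnot(inherits(forecasts, "pe_forecasts") || is.data.frame(forecasts))
  if (is.null(truths)) {
    if (is.null(data)) stop("either data or truths must be given")
    stopifnot(inherits(data, "pe_data"))
    ids <- vapply(data$trajectories, `[[`, character(1), "subject_id")
    truths <- vapply(seq_len(nrow(forecasts)), function(r) {
      s <- match(forecasts$subject_id[r], ids)
      if (is.na(s)) stop("pairing error: no subject '", forecasts$subject_id[r],
                         "' in the data")
      tr <- data$trajectories[[s]]
      j <- which(abs(tr$times - forecasts$target_time[r]) < 1e-8)
      if (length(j) != 1L)
        stop("pairing error: subject '", forecasts$subject_id[r],
             "' has no observation at time ", forecasts$target_time[r])
      tr$y[j]
    }, numeric(1))
  } else if (length(truths) != nrow(forecasts)) {
    stop("pairing error: truths length does not match the number of forecasts")
  }
  err2 <- (forecasts$predictive_mean - truths)^2
  by_subj <- tapply(err2, forecasts$subject_id, mean)
  structure(list(mse = mean(err2),
                 mse_by_subject = by_subj,
                 mse_subject_mean = mean(by_subj),
                 coverage_05_95 = mean(truths >= forecasts$q05 &
                                         truths <= forecasts$q95),
                 n_predictions = nrow(forecasts)),
            class = "pe_evaluation")
}

#' @export
print.pe_evaluation <- function(x, digits = 4, ...) {
  cat("Forecast evaluation\n")
  cat(sprintf("  predictions:        %d\n", x$n_predictions))
  cat(sprintf("  pooled MSE:         %.*f\n", digits, x$mse))
  cat(sprintf("  mean subject MSE:   %.*f\n", digits, x$mse_subject_mean))
  cat(sprintf("  5-95%% coverage:     %.*f\n", digits, x$coverage_05_95))
  invisible(x)
}
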