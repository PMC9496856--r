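## Bayesian estimation by MCMC with latent-path augmentation. The latent
## emotional path is parameterized non-centrally (standard-normal
## innovations scaled by sigma) and the degradation increments as unit-rate
## gamma innovations scaled by 1/beta; both decouple the scale parameters
## from the paths and mix far better than the centered forms. The sampler
## behind the model graph is JAGS (Gibbs/slice); everything the graph
## encodes -- the drift, links, densities -- is the package's own model and
## is cross-checked against the pure-R densities in the test suite.

.jags_name <- c(c_mu = "cmu", sigma = "sigma", c_ga = "cga", beta = "beta",
                h_0 = "h0", h_d = "hd", h_m = "hm", sigma_eps = "sigma_eps",
                w_d = "wd", w_0 = "w0", w_delta_pos = "wdp",
                w_delta_neg = "wdn", w_z = "wz")
.r_name <- structure(names(.jags_name), names = .jags_name)

#' MCMC configuration
#'
#' @param n_chains Number of chains (at least 2 whenever R-hat is wanted).
#' @param n_adapt Adaptation iterations (sampler tuning, discarded).
#' @param n_warmup Warm-up (burn-in) iterations, discarded.
#' @param n_samples Retained draws per chain (after thinning).
#' @param thin Thinning interval.
#' @param seed Integer seed; every chain derives its own RNG seed from it.
#' @param quiet Suppress JAGS progress output.
#' @return A list of class \code{"pe_control"}.
#' @export
pe_control <- function(n_chains = 3, n_adapt = 1000, n_warmup = 1000,
                       n_samples = 1000, thin = 1, seed = 1, quiet = TRUE) {
  stopifnot(n_chains >= 1, n_adapt >= 0, n_warmup >= 0, n_samples >= 1,
            thin >= 1, is.finite(seed))
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples), thin = as.integer(thin),
                 seed = as.integer(seed), quiet = isTRUE(quiet)),
            class = "pe_control")
}

.pe_model_string <- function(free, p_cov, has_z) {
  prior_line <- function(nm) {
    jn <- .jags_name[nm]
    trunc <- if (isTRUE(.pe_free_names[nm])) " T(0,)" else ""
    if (nm == "w_z")
      sprintf("  for (q in 1:P) { wz[q] ~ dnorm(pm_wz[q], pp_wz[q]) }")
    else
      sprintf("  %s ~ dnorm(pm_%s, pp_%s)%s", jn, jn, jn, trunc)
  }
  zterm <- if (has_z) " + inprod(wz[1:P], zc[s, i-1, 1:P])" else ""
  paste0(
    "model {\n",
    "  for (s in 1:S) {\n",
    "    M[s,1] <- M1[s]\n",
    "    D[s,1] <- D1[s]\n",
    "    y[s,1] ~ dnorm(h0 + hd*D[s,1] + hm*M[s,1], tau_eps)\n",
    "    for (i in 2:N[s]) {\n",
    "      mu[s,i] <- cmu * tanh(wdp*dpos[s,i] + wdn*dneg[s,i]", zterm,
    " + wd*D[s,i-1] + w0) * dtm[s,i]\n",
    "      e[s,i] ~ dnorm(0, 1)\n",
    "      M[s,i] <- M[s,i-1] + mu[s,i] + sigma * sqrt(dtm[s,i]) * e[s,i]\n",
    "      g[s,i] ~ dgamma(cga * ilogit(M[s,i-1]) * dtm[s,i], 1)\n",
    "      D[s,i] <- D[s,i-1] + g[s,i] / beta\n",
    "      y[s,i] ~ dnorm(h0 + hd*D[s,i] + hm*M[s,i], tau_eps)\n",
    "    }\n",
    "  }\n",
    "  tau_eps <- pow(sigma_eps, -2)\n",
    paste(vapply(free, prior_line, character(1)), collapse = "\n"), "\n",
    "}\n")
}

.jags_inputs <- function(data, priors, init, use_observations) {
  trs <- data$trajectories
  S <- length(trs)
  N <- vapply(trs, function(tr) length(tr$times), integer(1))
  if (any(N < 2L)) stop("every subject needs at least 2 observations for fitting")
  maxN <- max(N)
  p_cov <- if (is.null(trs[[1]]$z)) 0L else ncol(trs[[1]]$z)
  free <- names(priors$free)
  fixed <- priors$fixed

  wdp_zero <- identical(fixed[["w_delta_pos"]], 0) && identical(fixed[["w_delta_neg"]], 0)
  has_imp <- all(vapply(trs, function(tr) !is.null(tr$impacts), logical(1)))
  if (!has_imp && !wdp_zero)
    stop("impacts are not recorded for all subjects; either record them or fix ",
         "w_delta_pos and w_delta_neg to zero")

  mat <- function(fill = NA_real_) matrix(fill, S, maxN)
  y <- mat(); dtm <- mat(); dpos <- mat(0); dneg <- mat(0)
  zc <- if (p_cov > 0L) array(0, c(S, maxN, p_cov)) else NULL
  for (s in seq_len(S)) {
    tr <- trs[[s]]
    y[s, seq_len(N[s])] <- tr$y
    dtm[s, 2:N[s]] <- diff(tr$times)
    if (has_imp) {
      dpos[s, 2:N[s]] <- tr$impacts$delta_pos
      dneg[s, 2:N[s]] <- tr$impacts$delta_neg
    }
    if (p_cov > 0L) zc[s, seq_len(N[s]), ] <- tr$z
  }
  if (!use_observations) y[] <- NA_real_

  jd <- list(S = S, N = N, y = y, dtm = dtm, dpos = dpos, dneg = dneg,
             D1 = rep(init[["d"]], S), M1 = rep(init[["m"]], S))
  if (p_cov > 0L) { jd$zc <- zc; jd$P <- p_cov }

  ## every model parameter must be either free or fixed
  need <- c("c_mu", "sigma", "c_ga", "beta", "h_0", "h_d", "h_m", "sigma_eps",
            "w_d", "w_0", "w_delta_pos", "w_delta_neg")
  if (p_cov > 0L) need <- c(need, "w_z")
  covered <- union(free, names(fixed))
  missing <- setdiff(need, covered)
  if (length(missing))
    stop("parameters neither free nor fixed: ", paste(missing, collapse = ", "))
  if (p_cov == 0L && "w_z" %in% free)
    stop("w_z is free but the data carry no covariates")

  for (nm in setdiff(intersect(need, names(fixed)), "w_z"))
    jd[[.jags_name[nm]]] <- fixed[[nm]]
  if ("w_z" %in% names(fixed) && p_cov > 0L) {
    wz <- fixed[["w_z"]]
    if (length(wz) != p_cov) stop("fixed w_z length must match covariate dimension")
    jd$wz <- wz
  }
  for (nm in free) {
    pr <- priors$free[[nm]]
    if (nm == "w_z" && length(pr[["mean"]]) != p_cov)
      stop("w_z prior length must match covariate dimension")
    jd[[paste0("pm_", .jags_name[nm])]] <- pr[["mean"]]
    jd[[paste0("pp_", .jags_name[nm])]] <- 1 / pr[["sd"]]^2
  }
  list(jd = jd, free = free, p_cov = p_cov, S = S, N = N, maxN = maxN)
}

.jags_inits <- function(inp, priors, control) {
  spread <- if (control$n_chains == 1L) 0 else
    seq(-1, 1, length.out = control$n_chains)
  set.seed(control$seed)
  rng_seeds <- sample.int(.Machine$integer.max - 1L, control$n_chains)
  e0 <- matrix(NA_real_, inp$S, inp$maxN)
  g0 <- matrix(NA_real_, inp$S, inp$maxN)
  for (s in seq_len(inp$S)) {
    e0[s, 2:inp$N[s]] <- 0
    g0[s, 2:inp$N[s]] <- 1
  }
  lapply(seq_len(control$n_chains), function(ch) {
    ini <- list(e = e0, g = g0,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = rng_seeds[ch])
    for (nm in inp$free) {
      pr <- priors$free[[nm]]
      v <- pr[["mean"]] + spread[ch] * pr[["sd"]]
      if (isTRUE(.pe_free_names[nm])) v <- pmax(v, pmax(pr[["sd"]] * 0.1, 1e-3))
      ini[[.jags_name[nm]]] <- v
    }
    ini
  })
}

#' Fit the coupled degradation-emotion model by MCMC
#'
#' Estimates the free parameters (and the latent degradation/emotion paths,
#' by augmentation) from a longitudinal dataset. Per-interval emotional
#' impacts are taken as recorded when every trajectory carries them;
#' otherwise the impact coefficients must be fixed at zero so the
#' compound-Poisson term drops out of the drift. The fit is deterministic
#' given \code{(data, priors, control)}: each chain's RNG seed derives from
#' \code{control$seed}.
#'
#' @param data A [pe_data()] object (every subject needs at least 2 visits).
#' @param priors A [pe_priors()] object covering every model parameter.
#' @param control A [pe_control()] object.
#' @param init Named numeric \code{c(d = , m = )}: the shared initial latent
#'   state at each subject's baseline visit.
#' @param use_observations If \code{FALSE}, the scores are withheld and the
#'   chains target the prior (prior-sampling check).
#' @param monitor_latent If \code{TRUE}, retain posterior draws of the latent
#'   \code{M} and \code{D} paths.
#' @return An object of class \code{"pe_fit"} with components \code{draws}
#'   (a \code{coda::mcmc.list} over free parameters), \code{rhat} (named
#'   split-chain R-hat), \code{summary} (posterior summary table),
#'   \code{latent} (optional \code{mcmc.list} of latent paths), plus the
#'   inputs.
#' @examples
#' \donttest{
#' d <- pe_simulate(setting = 1, n_sequences = 3, n_obs = 8, seed = 1)
#' f <- pe_fit(d, pe_priors_synthetic(),
#'             pe_control(n_adapt = 200, n_warmup = 200, n_samples = 200, seed = 1))
#' summary(f)
#' }
#' @export
pe_fit <- function(data, priors = pe_priors_synthetic(),
                   control = pe_control(), init = c(d = 0, m = 0),
                   use_observations = TRUE, monitor_latent = FALSE) {
  stopifnot(inherits(data, "pe_data"), inherits(priors, "pe_priors"),
            inherits(control, "pe_control"))
  inp <- .jags_inputs(data, priors, init, use_observations)

  if (!length(inp$free)) {
    ## nothing to estimate: the posterior is the point mass at the fixed values
    sc <- priors$fixed[vapply(priors$fixed, length, integer(1)) == 1L]
    draws <- lapply(seq_len(control$n_chains), function(ch)
      coda::mcmc(matrix(unlist(sc), control$n_samples, length(sc), byrow = TRUE,
                        dimnames = list(NULL, names(sc)))))
    fit <- structure(list(draws = coda::as.mcmc.list(draws),
                          rhat = stats::setNames(rep(NA_real_, length(sc)), names(sc)),
                          priors = priors, control = control, data = data,
                          model = NULL, latent = NULL), class = "pe_fit")
    fit$summary <- posterior_summary(fit)
    return(fit)
  }

  monitors <- unname(.jags_name[inp$free])
  if (monitor_latent) monitors <- c(monitors, "M", "D")
  model_str <- .pe_model_string(inp$free, inp$p_cov, has_z = inp$p_cov > 0L)
  inits <- .jags_inits(inp, priors, control)

  run <- function() {
    m <- rjags::jags.model(textConnection(model_str), data = inp$jd,
                           inits = inits, n.chains = control$n_chains,
                           n.adapt = control$n_adapt, quiet = control$quiet)
    if (control$n_warmup > 0)
      stats::update(m, control$n_warmup,
                    progress.bar = if (control$quiet) "none" else "text")
    rjags::coda.samples(m, variable.names = monitors,
                        n.iter = control$n_samples * control$thin,
                        thin = control$thin,
                        progress.bar = if (control$quiet) "none" else "text")
  }
  samples <- tryCatch(run(), error = function(e)
    stop("MCMC initialization or sampling failed: ", conditionMessage(e)))

  par_cols <- unlist(lapply(inp$free, function(nm) {
    jn <- .jags_name[nm]
    if (nm == "w_z") c("wz", paste0("wz[", seq_len(inp$p_cov), "]")) else jn
  }))
  cn <- colnames(samples[[1]])
  keep <- cn %in% par_cols
  rname <- function(x) {
    out <- x
    plain <- x %in% names(.r_name)
    out[plain] <- .r_name[x[plain]]
    out <- sub("^wz\\[", "w_z[", out)
    out[out == "w_z"] <- "w_z[1]"  # JAGS drops the index on length-1 arrays
    out
  }
  draws <- coda::as.mcmc.list(lapply(samples, function(ch) {
    mm <- ch[, keep, drop = FALSE]
    colnames(mm) <- rname(colnames(mm))
    mm
  }))
  latent <- if (monitor_latent)
    coda::as.mcmc.list(lapply(samples, function(ch)
      ch[, grepl("^[MD]\\[", colnames(ch)), drop = FALSE]))
  else NULL

  fit <- structure(list(draws = draws, priors = priors, control = control,
                        data = data, model = model_str, latent = latent),
                   class = "pe_fit")
  fit$rhat <- split_rhat(draws)
  fit$summary <- posterior_summary(fit)
  fit
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Splits each chain in half and compares between- and within-half variances:
#' values near 1 indicate that the chains have mixed; values above about
#' 1.05 indicate they have not. Chains with (numerically) zero within-chain
#' variance are degenerate: the statistic is undefined and \code{NA} is
#' returned with a warning.
#'
#' @param x A \code{coda::mcmc.list}, a matrix (iterations x chains) for a
#'   single parameter, or a 3-d array (iterations x chains x parameters).
#' @return Named numeric vector of R-hat values (single value for a matrix).
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(4000), 2000, 2)
#' split_rhat(m) # close to 1
#' @export
split_rhat <- function(x) {
  one <- function(mat) { # iterations x chains
    n <- floor(nrow(mat) / 2)
    if (n < 2) stop("need at least 4 iterations per chain")
    halves <- cbind(mat[seq_len(n), , drop = FALSE],
                    mat[seq.int(nrow(mat) - n + 1L, nrow(mat)), , drop = FALSE])
    W <- mean(apply(halves, 2, stats::var))
    if (!is.finite(W) || W <= .Machine$double.eps * max(1, mean(halves)^2)) {
      warning("degenerate chains: zero within-chain variance, R-hat undefined")
      return(NA_real_)
    }
    B <- n * stats::var(colMeans(halves))
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  if (inherits(x, "mcmc.list")) {
    pars <- colnames(x[[1]])
    vapply(pars, function(p) one(sapply(x, function(ch) as.numeric(ch[, p]))),
           numeric(1))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    pars <- dimnames(x)[[3]]
    if (is.null(pars)) pars <- as.character(seq_len(dim(x)[3]))
    stats::setNames(vapply(seq_len(dim(x)[3]),
                           function(j) one(x[, , j]), numeric(1)), pars)
  } else {
    one(as.matrix(x))
  }
}

#' Posterior summary table
#'
#' One row per free parameter: posterior mean, sd, 5/50/95% quantiles over
#' the pooled post-warm-up draws, and split-chain R-hat.
#'
#' @param fit A [pe_fit()] object.
#' @return A data frame.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "pe_fit"))
  pooled <- do.call(rbind, lapply(fit$draws, as.matrix))
  rh <- if (!is.null(fit$rhat)) fit$rhat else
    tryCatch(suppressWarnings(split_rhat(fit$draws)),
             error = function(e) stats::setNames(rep(NA_real_, ncol(pooled)),
                                                 colnames(pooled)))
  data.frame(parameter = colnames(pooled),
             mean = colMeans(pooled),
             sd = apply(pooled, 2, stats::sd),
             q05 = apply(pooled, 2, stats::quantile, 0.05),
             q50 = apply(pooled, 2, stats::quantile, 0.50),
             q95 = apply(pooled, 2, stats::quantile, 0.95),
             rhat = unname(rh[colnames(pooled)]),
             row.names = NULL)
}

#' @export
summary.pe_fit <- function(object, ...) posterior_summary(object)

#' @export
coef.pe_fit <- function(object, ...) {
  s <- posterior_summary(object)
  stats::setNames(s$mean, s$parameter)
}

#' @export
print.pe_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Coupled degradation-emotion model fit (%d chains, %d draws/chain)\n",
              length(x$draws), nrow(x$draws[[1]])))
  s <- x$summary
  s[-1] <- lapply(s[-1], round, digits)
  print(s, row.names = FALSE)
  mx <- suppressWarnings(max(x$rhat, na.rm = TRUE))
  if (is.finite(mx))
    cat(sprintf("max split R-hat: %.3f (%s)\n", mx,
                if (mx < 1.05) "chains mixed" else "NOT converged"))
  invisible(x)
}

#' Pooled posterior draws as a matrix
#'
#' @param fit A [pe_fit()] object.
#' @return Matrix of pooled post-warm-up draws, one column per parameter.
#' @export
pe_posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "pe_fit"))
  do.call(rbind, lapply(fit$draws, as.matrix))
}

#' Tidy draws table
#'
#' @param fit A [pe_fit()] object.
#' @return Data frame with columns chain, iteration, parameter, value.
#' @export
pe_draws_table <- function(fit) {
  stopifnot(inherits(fit, "pe_fit"))
  out <- lapply(seq_along(fit$draws), function(ch) {
    m <- as.matrix(fit$draws[[ch]])
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate datasets from a fitted model
#'
#' Draws datasets from the generative model at the posterior-mean parameter
#' values (free parameters) combined with the fit's fixed values.
#'
#' @param object A [pe_fit()] object.
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_sequences,n_obs,dt Passed to [pe_simulate()].
#' @param ... Unused.
#' @return A list of [pe_data()] objects (a single object when
#'   \code{nsim = 1}).
#' @export
simulate.pe_fit <- function(object, nsim = 1, seed = 1, n_sequences = 10,
                            n_obs = 21, dt = 1, ...) {
  est <- coef(object)
  est <- est[!grepl("^w_z\\[", names(est))]
  args <- c(as.list(est), object$priors$fixed)
  args <- args[names(args) %in% names(formals(pe_params))]
  params <- do.call(pe_params, args)
  out <- lapply(seq_len(nsim), function(i)
    pe_simulate(params = params, n_sequences = n_sequences, n_obs = n_obs,
                dt = dt, seed = seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}
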