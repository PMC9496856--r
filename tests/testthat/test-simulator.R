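test_that("compound-Poisson impacts have the right moments and degenerate limits", {
  set.seed(501)
  expect_identical(sample_impacts(0, 3, 1), list(count = 0L, total = 0))
  n <- 100000
  draws <- vapply(seq_len(n), function(i) {
    s <- sample_impacts(5, 3, 1)
    c(s$count, s$total)
  }, numeric(2))
  counts <- draws[1, ]; totals <- draws[2, ]
  ## total = 0 iff count = 0
  expect_true(all((totals == 0) == (counts == 0)))
  ## E total = k/lam, Var total = 2k/lam^2 (exponential marks)
  se_mean <- sqrt(10 / 9 / n)
  expect_lt(abs(mean(totals) - 5 / 3), 4 * se_mean)
  expect_lt(abs(var(totals) - 10 / 9), 0.05)
  ## doubling dt doubles the mean count
  set.seed(502)
  c2 <- vapply(seq_len(20000), function(i) sample_impacts(5, 3, 2)$count,
               numeric(1))
  expect_lt(abs(mean(c2) - 10), 4 * sqrt(10 / 20000))
  expect_error(sample_impacts(Inf, 3, 1), "finite")
  expect_error(sample_impacts(5, 0, 1), "lam > 0")
})

test_that("the all-noise-off model freezes the latent state and the score", {
  p <- degenerate_params()
  set.seed(503)
  tr <- simulate_trajectory(p, 0:10, init = c(d = 2, m = -1))
  expect_equal(tr$latent$d, rep(2, 11))
  expect_equal(tr$latent$m, rep(-1, 11))
  expect_equal(tr$y, rep(30 - 2 + 0.5, 11))
  expect_true(all(tr$impacts$n_pos == 0) && all(tr$impacts$delta_neg == 0))
})

test_that("simulated degradation paths are monotone in every setting", {
  for (sid in 1:5) {
    d <- pe_simulate(setting = sid, n_sequences = 3, seed = 600 + sid)
    for (tr in d$trajectories) {
      expect_true(all(diff(tr$latent$d) >= 0))
      expect_true(all(tr$latent$d >= 0))
    }
  }
})

test_that("datasets are reproducible and substream-stable under growth", {
  a <- pe_simulate(setting = 1, n_sequences = 4, n_obs = 6, seed = 99)
  b <- pe_simulate(setting = 1, n_sequences = 4, n_obs = 6, seed = 99)
  expect_identical(a$trajectories, b$trajectories)
  big <- pe_simulate(setting = 1, n_sequences = 7, n_obs = 6, seed = 99)
  expect_identical(a$trajectories, big$trajectories[1:4])
  c2 <- pe_simulate(setting = 1, n_sequences = 4, n_obs = 6, seed = 100)
  expect_false(identical(a$trajectories[[1]]$y, c2$trajectories[[1]]$y))
})

test_that("one-interval transition moments match the model densities", {
  ## 4000 independent single-interval transitions from (d, m) = (0, 0)
  d <- pe_simulate(setting = 1, n_sequences = 4000, n_obs = 2, seed = 77)
  p <- pe_setting(1)$params
  dm <- vapply(d$trajectories, function(tr) diff(tr$latent$m), numeric(1))
  dd <- vapply(d$trajectories, function(tr) diff(tr$latent$d), numeric(1))
  drift <- vapply(d$trajectories, function(tr)
    drift_mu(p, tr$impacts$delta_neg[1], tr$impacts$delta_pos[1],
             d_prev = 0, dt = 1), numeric(1))
  resid <- dm - drift
  expect_lt(abs(mean(resid)), 4 * p$sigma / sqrt(4000))
  expect_lt(abs(sd(resid) - p$sigma), 0.02)
  ## Delta D ~ Gamma(c_ga/2, beta) at m_prev = 0: mean alpha/beta, var alpha/beta^2
  alpha <- gamma_shape(p, 0, 1)
  expect_lt(abs(mean(dd) - alpha / p$beta), 4 * sqrt(alpha / p$beta^2 / 4000))
  expect_lt(abs(var(dd) - alpha / p$beta^2), 0.01)
})

test_that("impact-rate asymmetry orders the settings as designed", {
  ## setting 3 (k+ = 5 > k- = 3): positive impacts dominate
  d3 <- pe_simulate(setting = 3, n_sequences = 200, seed = 31)
  tot <- function(d, col) mean(vapply(d$trajectories,
                                      function(tr) sum(tr$impacts[[col]]),
                                      numeric(1)))
  expect_gt(tot(d3, "delta_pos"), tot(d3, "delta_neg"))
  ## setting 4 reverses the rates and slows degradation
  d4 <- pe_simulate(setting = 4, n_sequences = 200, seed = 31)
  termD <- function(d) mean(vapply(d$trajectories,
                                   function(tr) tr$latent$d[length(tr$times)],
                                   numeric(1)))
  expect_lt(termD(d4), termD(d3))
  ## larger c_ga (setting 1 vs 2) degrades faster and scores fall further
  d1 <- pe_simulate(setting = 1, n_sequences = 200, seed = 32)
  d2 <- pe_simulate(setting = 2, n_sequences = 200, seed = 32)
  expect_gt(termD(d1), termD(d2))
  termY <- function(d) mean(vapply(d$trajectories,
                                   function(tr) tr$y[length(tr$times)],
                                   numeric(1)))
  expect_lt(termY(d1), termY(d2))
})

test_that("the setting-5 regime switch flips the dominant impact rate at the tenth interval", {
  s5 <- pe_setting(5)
  expect_equal(s5$regime_switch$switch_index, 10L)
  expect_equal(s5$params$k_pos, 3)
  expect_equal(s5$regime_switch$params_after$k_pos, 5)
  d5 <- pe_simulate(setting = 5, n_sequences = 300, seed = 55)
  npos_first <- mean(vapply(d5$trajectories,
                            function(tr) sum(tr$impacts$n_pos[1:10]), numeric(1)))
  npos_last <- mean(vapply(d5$trajectories,
                           function(tr) sum(tr$impacts$n_pos[11:20]), numeric(1)))
  ## 10 intervals at rate 3 vs 10 at rate 5
  expect_lt(abs(npos_first - 30), 4 * sqrt(30 / 300))
  expect_lt(abs(npos_last - 50), 4 * sqrt(50 / 300))
  expect_error(pe_setting(6), "unknown setting_id")
  expect_error(pe_simulate(setting = 1, n_sequences = 2), "seed")
})

test_that("score clamping clips to the instrument range only when asked", {
  expect_equal(clip_score(31.2), 30)
  expect_equal(clip_score(15), 15)
  expect_equal(clip_score(-2), 0)
  expect_error(clip_score(1, lo = 2, hi = 1), "lo must be below hi")
  dcl <- pe_simulate(setting = 1, n_sequences = 5, seed = 9, clip = TRUE)
  for (tr in dcl$trajectories) expect_true(all(tr$y >= 0 & tr$y <= 30))
})
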