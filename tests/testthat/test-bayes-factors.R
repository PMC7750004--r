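# conjugate Normal mean model helpers: y ~ N(mu, 1), mu ~ N(0, s0)
conj_log_post <- function(y, s0) {
  function(mu) {
    sum(dnorm(y, mu[1], 1, log = TRUE)) + dnorm(mu[1], 0, s0, log = TRUE)
  }
}
conj_draws <- function(y, s0, n = 2000, seed = 1) {
  post_var <- 1 / (length(y) + 1 / s0^2)
  post_mean <- sum(y) * post_var
  entroread:::with_seed(seed,
    matrix(rnorm(n, post_mean, sqrt(post_var)), ncol = 1))
}

test_that("the analytic conjugate oracle is itself correct", {
  expect_equal(analytic_normal_bf(numeric(0), 1, 1)$bf10, 1)
  # specific small dataset, cross-checked by numeric integration
  y <- c(0.2, -0.1, 0.3)
  oracle <- analytic_normal_bf(y, 1, 1)
  quad <- integrate(function(mu) {
    vapply(mu, function(m) {
      exp(sum(dnorm(y, m, 1, log = TRUE)) + dnorm(m, 0, 1, log = TRUE))
    }, 0)
  }, -8, 8, rel.tol = 1e-10)$value
  expect_equal(oracle$logml1, log(quad), tolerance = 1e-7)
  expect_equal(oracle$logml0, sum(dnorm(y, 0, 1, log = TRUE)))
  # null-centred data favour the null
  set.seed(61)
  y0 <- rnorm(200)
  y0 <- y0 - mean(y0)
  expect_lt(analytic_normal_bf(y0, 1, 1)$bf10, 1)
})

test_that("bridge sampling matches the conjugate closed form", {
  set.seed(62)
  y <- rnorm(50, 0.3, 1)
  oracle <- analytic_normal_bf(y, 1, 1)
  bs <- bridge_sampler(conj_draws(y, 1, seed = 63), conj_log_post(y, 1),
                       seed = 64)
  expect_lt(abs(bs$logml - oracle$logml1), 3 * bs$error)
  expect_gt(bs$error, 0)
  expect_true(bs$converged)
})

test_that("identical marginal likelihoods give BF10 = 1, labelled inconclusive", {
  ml <- structure(list(logml = -12.3, error = 0.01), class = "logml")
  bf <- bayes_factor_ratio(ml, ml)
  expect_equal(bf$bf10, 1)
  expect_equal(bf$label, "inconclusive")
})

test_that("evidence labels follow the 3.0 / 0.3 thresholds and grades", {
  expect_equal(bf_evidence_label(1), "inconclusive")
  expect_equal(bf_evidence_label(2.9), "inconclusive")
  expect_equal(bf_evidence_label(3.5), "moderate evidence for effect")
  expect_equal(bf_evidence_label(15), "strong evidence for effect")
  expect_equal(bf_evidence_label(40), "very strong evidence for effect")
  expect_equal(bf_evidence_label(200), "extreme evidence for effect")
  expect_equal(bf_evidence_label(0.25), "moderate evidence for null")
  expect_equal(bf_evidence_label(0.005), "extreme evidence for null")
  expect_error(bf_evidence_label(-1), "positive")
})

test_that("widening the slope prior on null data lowers BF10", {
  set.seed(65)
  y <- rnorm(120)
  y <- y - mean(y)   # exactly null-centred
  widths <- c(0.1, 0.5, 1.0)
  # analytic: exact monotone decrease
  bfs_exact <- vapply(widths, function(s0) analytic_normal_bf(y, 1, s0)$bf10, 0)
  expect_true(all(diff(bfs_exact) < 0))
  # bridge estimates reproduce the same ordering
  logml0 <- sum(dnorm(y, 0, 1, log = TRUE))
  bfs_bridge <- vapply(seq_along(widths), function(i) {
    s0 <- widths[i]
    bs <- bridge_sampler(conj_draws(y, s0, seed = 70 + i),
                         conj_log_post(y, s0), seed = 80 + i)
    exp(bs$logml - logml0)
  }, 0)
  expect_true(all(diff(bfs_bridge) < 0))
  expect_equal(log(bfs_bridge), log(bfs_exact), tolerance = 0.05)
})

test_that("bridge estimates are transitive across prior widths", {
  set.seed(66)
  y <- rnorm(60, 0.1)
  ml <- lapply(c(0.1, 0.5, 1.0), function(s0) {
    bridge_sampler(conj_draws(y, s0, seed = round(s0 * 100)),
                   conj_log_post(y, s0), seed = round(s0 * 7))
  })
  bf_ac <- ml[[1]]$logml - ml[[3]]$logml
  bf_ab_bc <- (ml[[1]]$logml - ml[[2]]$logml) +
    (ml[[2]]$logml - ml[[3]]$logml)
  err <- sqrt(sum(vapply(ml, function(m) m$error^2, 0)))
  expect_lt(abs(bf_ac - bf_ab_bc), 3 * err + 1e-12)
  # and both agree with the analytic difference
  exact <- analytic_normal_bf(y, 1, 0.1)$logml1 -
    analytic_normal_bf(y, 1, 1)$logml1
  expect_lt(abs(bf_ac - exact), 3 * err + 0.02)
})

test_that("mismatched data fingerprints are refused", {
  a <- structure(list(logml = -1, error = 0.01, fingerprint = "x"),
                 class = "logml")
  b <- structure(list(logml = -2, error = 0.01, fingerprint = "y"),
                 class = "logml")
  expect_error(bayes_factor_ratio(a, b), "different data")
})

test_that("flagged fits are refused by the marginal-likelihood estimator", {
  des <- experiment_design(8, 8, n_fillers = 0, seed = 1)
  spr <- generate_spr_trials(des, generative_params("reciprocal_speed"),
                             p_sub100 = 0, seed = 2)
  fit <- suppressWarnings(
    fit_reading_model(spr, "categorical", prior_spec("reciprocal_speed"),
                      chains = 2, warmup = 100, iter = 150, seed = 3))
  fit$flagged <- TRUE
  expect_error(estimate_log_marginal_likelihood(fit), "flagged")
})

test_that("a planted effect yields decisive hierarchical Bayes factors", {
  des <- experiment_design(24, 12, n_fillers = 0, seed = 3)
  spr <- generate_spr_trials(des, generative_params(
    "reciprocal_speed", beta = c(set_size = 0.4)), p_sub100 = 0, seed = 11)
  full <- fit_reading_model(spr, "categorical", prior_spec("reciprocal_speed"),
                            chains = 4, warmup = 600, iter = 800, seed = 6)
  red <- fit_reading_model(spr, "categorical", prior_spec("reciprocal_speed"),
                           drop_predictor = "set_size",
                           chains = 4, warmup = 600, iter = 800, seed = 6)
  expect_false(full$flagged)
  expect_false(red$flagged)
  # the reduced model keeps the dropped predictor's random slopes
  expect_false("b_set_size" %in% red$summary$parameter)
  expect_true("sd_item__set_size" %in% red$summary$parameter)

  mlf <- estimate_log_marginal_likelihood(full, seed = 7)
  mlr <- estimate_log_marginal_likelihood(red, seed = 8)
  bf <- bayes_factor_ratio(mlf, mlr)
  expect_gt(bf$bf10, 3)

  # self-consistency: re-estimation with a new seed agrees within error
  mlf2 <- estimate_log_marginal_likelihood(full, seed = 99)
  expect_lt(abs(mlf$logml - mlf2$logml),
            3 * sqrt(mlf$error^2 + mlf2$error^2))
})
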