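test_that("effect contrast codes are centred and multiply correctly", {
  cc <- contrast_codes(c("small", "large", "small", "large"),
                       c("short", "short", "long", "long"))
  expect_equal(cc$c_set_size, c(-0.5, 0.5, -0.5, 0.5))
  expect_equal(cc$c_distance, c(-0.5, -0.5, 0.5, 0.5))
  expect_equal(cc$c_interaction, cc$c_set_size * cc$c_distance)
  expect_equal(sum(cc$c_set_size), 0)
  expect_error(contrast_codes("tiny", "short"), "small/large")
})

test_that("Box-Cox selection identifies the generating transform", {
  set.seed(21)
  # reciprocal-scale data: 1000/y is approximately Normal
  y_rec <- 1000 / rnorm(3000, 2.5, 0.3)
  y_rec <- y_rec[y_rec > 0]
  l_rec <- select_boxcox_lambda(y_rec)
  expect_gte(l_rec$lambda, -1.3)
  expect_lte(l_rec$lambda, -0.7)
  # lognormal data
  l_log <- select_boxcox_lambda(rlnorm(2000, 5.7, 0.4))
  expect_lte(abs(l_log$lambda), 0.3)
  # already-Normal data (the low coefficient of variation leaves the
  # profile shallow, so a large sample is needed to pin lambda down)
  l_id <- select_boxcox_lambda(rnorm(50000, 300, 10))
  expect_gte(l_id$lambda, 0.7)
  expect_lte(l_id$lambda, 1.3)
  expect_error(select_boxcox_lambda(c(-1, 2)), "positive")
})

test_that("Box-Cox profile agrees with a direct likelihood computation", {
  set.seed(3)
  y <- rlnorm(200, 5, 0.5)
  prof <- select_boxcox_lambda(y)$profile
  # independent profile: -n/2 log(sigma_hat^2) + (lambda - 1) sum(log y)
  own <- vapply(prof$lambda, function(l) {
    z <- if (abs(l) < 1e-12) log(y) else (y^l - 1) / l
    -length(y) / 2 * log(mean((z - mean(z))^2)) + (l - 1) * sum(log(y))
  }, 0)
  expect_equal(prof$lambda[which.max(prof$loglik)],
               prof$lambda[which.max(own)])
})

test_that("prior-predictive arithmetic reproduces the documented bounds", {
  log_b <- prior_predictive_bounds(prior_spec("log_ms"))
  expect_equal(log_b$response_interval, c(110, 812))
  rec_b <- prior_predictive_bounds(prior_spec("reciprocal_speed"))
  expect_equal(rec_b$response_interval, c(2, 4))
  expect_equal(rec_b$effect_slowdown, 1)
  expect_equal(rec_b$effect_speedup, 1)
  degen <- prior_predictive_bounds(prior_spec("log_ms"), k_sd = 0)
  expect_equal(degen$response_interval, c(299, 299))
})

test_that("slice machinery matches the conjugate Normal closed form", {
  set.seed(31)
  y <- rnorm(40, 0.4, 1)
  s0 <- 0.7
  log_post <- function(mu) {
    sum(dnorm(y, mu, 1, log = TRUE)) + dnorm(mu, 0, s0, log = TRUE)
  }
  ch <- entroread:::fit_mh(log_post, init = 0, par_names = "mu",
                           chains = 2, warmup = 300, iter = 700, seed = 7)
  draws <- unlist(ch)
  post_prec <- length(y) + 1 / s0^2
  post_mean <- sum(y) / post_prec
  mc_se <- sd(draws) / sqrt(400)   # generous effective-n allowance
  expect_lt(abs(mean(draws) - post_mean), 4 * mc_se)
  expect_lt(abs(sd(draws) - sqrt(1 / post_prec)), 0.02)
})

test_that("hierarchical fit recovers planted effects and logs exclusions", {
  des <- experiment_design(20, 12, n_fillers = 0, seed = 2)
  par <- generative_params("reciprocal_speed",
                           beta = c(set_size = 0.3, distance = -0.15))
  spr <- generate_spr_trials(des, par, p_sub100 = 0.02, seed = 13)
  fit <- suppressWarnings(
    fit_reading_model(spr, "categorical", prior_spec("reciprocal_speed"),
                      chains = 2, warmup = 400, iter = 600, seed = 3))
  s <- fit$summary
  get <- function(p) s[s$parameter == p, ]
  # signs recovered and truths inside the 95% interval
  expect_gt(get("b_set_size")$mean, 0)
  expect_lt(get("b_distance")$mean, 0)
  expect_true(get("b_Intercept")$ci_low < 2.5 &
                get("b_Intercept")$ci_high > 2.5)
  # sub-100 ms exclusions logged
  expect_equal(sum(fit$exclusions$n), round(0.02 * nrow(spr)))
  # every reported parameter carries diagnostics
  expect_true(all(is.finite(s$rhat)))
  expect_true(all(s$ci_low <= s$mean & s$mean <= s$ci_high))
})

test_that("swapping contrast signs flips the slope posterior", {
  des <- experiment_design(16, 8, n_fillers = 0, seed = 4)
  spr <- generate_spr_trials(des, generative_params(
    "reciprocal_speed", beta = c(set_size = 0.25)), p_sub100 = 0, seed = 5)
  fit1 <- suppressWarnings(
    fit_reading_model(spr, "categorical", prior_spec("reciprocal_speed"),
                      chains = 2, warmup = 300, iter = 500, seed = 6))
  swapped <- spr
  swapped$set_size <- ifelse(spr$set_size == "small", "large", "small")
  fit2 <- suppressWarnings(
    fit_reading_model(swapped, "categorical", prior_spec("reciprocal_speed"),
                      chains = 2, warmup = 300, iter = 500, seed = 6))
  b1 <- fit1$summary$mean[fit1$summary$parameter == "b_set_size"]
  b2 <- fit2$summary$mean[fit2$summary$parameter == "b_set_size"]
  expect_lt(abs(b1 + b2), 0.05)
})

test_that("entropy models support the continuous predictor structure", {
  des <- experiment_design(16, 8, n_fillers = 0, seed = 7)
  spr <- generate_spr_trials(des, generative_params(
    "reciprocal_speed", beta = c(entropy = -0.3)), p_sub100 = 0, seed = 8)
  fit <- suppressWarnings(
    fit_reading_model(spr, "entropy", prior_spec("reciprocal_speed"),
                      chains = 2, warmup = 300, iter = 500, seed = 9))
  expect_true("b_entropy" %in% fit$summary$parameter)
  expect_lt(fit$summary$mean[fit$summary$parameter == "b_entropy"], 0)
})

test_that("degenerate designs are refused, never fitted silently", {
  one <- data.frame(participant = 1, item = 1, set_size = "small",
                    distance = "short", rt_ms = 400)
  expect_error(fit_reading_model(one, "categorical",
                                 prior_spec("reciprocal_speed")),
               "degenerate")
})

test_that("the ZOIB density behaves like its components", {
  # alpha = 0 reduces to a pure Beta: density at 0.5 is Beta(2,2)
  expect_equal(dzoib(0.5, 0, 0.5, 0.5, 4), dbeta(0.5, 2, 2))
  expect_equal(dbeta(0.5, 2, 2), 1.5)
  # boundary masses
  expect_equal(dzoib(0, 0.2, 0.4, 0.5, 4), 0.2 * 0.6)
  expect_equal(dzoib(1, 0.2, 0.4, 0.5, 4), 0.2 * 0.4)
})

test_that("ZOIB and hurdle densities integrate to one", {
  total_zoib <- dzoib(0, 0.2, 0.5, 0.6, 4) + dzoib(1, 0.2, 0.5, 0.6, 4) +
    integrate(function(x) dzoib(x, 0.2, 0.5, 0.6, 4), 0, 1,
              rel.tol = 1e-9)$value
  expect_equal(total_zoib, 1, tolerance = 1e-6)
  total_hl <- dhurdle_lognormal(0, 0.15, 0.2, 0.5) +
    integrate(function(x) dhurdle_lognormal(x, 0.15, 0.2, 0.5), 0, Inf,
              rel.tol = 1e-9)$value
  expect_equal(total_hl, 1, tolerance = 1e-6)
})

test_that("the ZOIB fit recovers known mixture parameters", {
  set.seed(41)
  n <- 600
  comp <- runif(n)
  v <- ifelse(comp < 0.1, 0, ifelse(comp < 0.2, 1, rbeta(n, 0.6 * 5, 0.4 * 5)))
  fit <- fit_zoib_cloze(v, chains = 2, warmup = 300, iter = 500, seed = 42)
  s <- fit$summary
  inside <- function(p, truth) {
    row <- s[s$parameter == p, ]
    row$ci_low <= truth & truth <= row$ci_high
  }
  # recovery is checked against the realized mixture proportions of
  # this sample (the credible interval targets the data, not the
  # asymptotic truth)
  alpha_real <- mean(v %in% c(0, 1))
  gamma_real <- sum(v == 1) / sum(v %in% c(0, 1))
  expect_true(inside("alpha", alpha_real))
  expect_true(inside("gamma1", gamma_real))
  expect_true(inside("b_Intercept", qlogis(0.6)))
  expect_lt(abs(s$mean[s$parameter == "gamma1"] - gamma_real), 0.1)
})

test_that("the hurdle fit handles zeros, recovery, and the tight slope prior", {
  set.seed(43)
  n <- 400
  z <- runif(n) < 0.1
  v <- ifelse(z, 0, rlnorm(n, 0.1, 0.4))
  dat <- data.frame(set_size = rep(c("small", "large"), n / 2),
                    distance = rep(c("short", "long"), each = n / 2))
  fit <- fit_hurdle_entropy(v, dat, chains = 2, warmup = 300, iter = 500,
                            seed = 44)
  s <- fit$summary
  th <- s[s$parameter == "theta", ]
  expect_true(th$ci_low <= 0.1 & 0.1 <= th$ci_high)
  # the Normal(0, 0.01) prior shrinks slopes essentially to zero
  expect_lt(abs(s$mean[s$parameter == "b_set_size"]), 0.03)
  # all-zero input: theta posterior concentrates near 1
  fit0 <- fit_hurdle_entropy(rep(0, 50), chains = 2, warmup = 200,
                             iter = 300, seed = 45)
  expect_gt(fit0$summary$mean[fit0$summary$parameter == "theta"], 0.9)
})

test_that("value-range validation guards the cloze models", {
  expect_error(fit_zoib_cloze(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fit_hurdle_entropy(c(1, -0.1)), "non-negative")
})
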