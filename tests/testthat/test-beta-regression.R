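test_that("simulate_beta_data has the right moments and determinism", {
  d0 <- simulate_beta_data(-2, 0, 30, 4000, seed = 1)
  expect_equal(mean(d0$y), plogis(-2),
               tolerance = 3 * sd(d0$y) / sqrt(4000) / plogis(-2))
  # variance shrinks as 1 / (1 + phi)
  dbig <- simulate_beta_data(-2, 3, 5000, 500, seed = 2)
  mu <- plogis(-2 + 3 * dbig$x)
  expect_lt(max(abs(dbig$y - mu)), 0.05)
  expect_identical(simulate_beta_data(-3, 5, 30, 50, seed = 9),
                   simulate_beta_data(-3, 5, 30, 50, seed = 9))
  expect_error(simulate_beta_data(0, 0, -1, 10), "phi")
  expect_error(simulate_beta_data(0, 0, 1, 0), "n must")
})

test_that("input contracts of fit_beta_regression are enforced", {
  d <- simulate_beta_data(-2, 1, 30, 20, seed = 3)
  d$y[1] <- 0
  expect_error(fit_beta_regression(d, y ~ x), "strictly in")
  d2 <- simulate_beta_data(-2, 1, 30, 5, seed = 3)
  expect_error(fit_beta_regression(d2, y ~ x), "at least 10")
  expect_error(fit_beta_regression(d, y ~ x + z), "one covariate")
})

test_that("null data yields a slope CI covering zero and ~0.5 tails", {
  d <- simulate_beta_data(-2.5, 0, 40, 200, seed = 21)
  fit <- fit_beta_regression(d, y ~ x, seed = 7)
  s <- fit$summary[fit$summary$parameter == "slope", ]
  expect_lt(s$ci_lower, 0); expect_gt(s$ci_upper, 0)
  expect_gt(fit$tail[["p_le_0"]], 0.1)
  expect_lt(fit$tail[["p_le_0"]], 0.9)
  expect_true(fit$converged)
  expect_equal(nrow(fit$draws), 8000)
})

test_that("posterior concentrates on the generating parameters", {
  d <- simulate_beta_data(-3.72, 6.92, 30, 148, seed = 31)
  fit <- fit_beta_regression(d, y ~ x, seed = 8)
  s <- fit$summary
  expect_lt(abs(s$mean[s$parameter == "intercept"] + 3.72),
            3 * s$sd[s$parameter == "intercept"])
  expect_lt(abs(s$mean[s$parameter == "slope"] - 6.92),
            3 * s$sd[s$parameter == "slope"])
  expect_true(all(s$ci_lower <= s$mean & s$mean <= s$ci_upper))
  expect_true(all(s$rhat < 1.05))
})

test_that("posterior mean approaches the ML estimate at large n", {
  d <- simulate_beta_data(-3.72, 6.92, 30, 2000, seed = 5)
  # independent ML oracle: direct likelihood maximization
  nll <- function(th) {
    mu <- plogis(th[1] + th[2] * d$x); phi <- exp(th[3])
    -sum(dbeta(d$y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  ml <- optim(c(-3, 5, 3), nll, method = "BFGS")
  fit <- fit_beta_regression(d, y ~ x, seed = 12)
  s <- fit$summary
  expect_lt(abs(s$mean[s$parameter == "slope"] - ml$par[2]), 0.1)
  expect_lt(abs(s$mean[s$parameter == "intercept"] - ml$par[1]), 0.05)
  # second independent route: glmmTMB beta family point estimates
  tmb <- glmmTMB::glmmTMB(y ~ x, family = glmmTMB::beta_family(),
                          data = d)
  co <- glmmTMB::fixef(tmb)$cond
  expect_lt(abs(s$mean[s$parameter == "slope"] - co[["x"]]), 0.15)
})

test_that("credible intervals cover the truth at a reasonable rate", {
  hits <- vapply(1:12, function(s) {
    d <- simulate_beta_data(-3.72, 6.92, 30, 148, seed = 5000 + s)
    fit <- fit_beta_regression(d, y ~ x, seed = s, chains = 2,
                               iter = 1000, warmup = 1000)
    su <- fit$summary[fit$summary$parameter == "slope", ]
    su$ci_lower <= 6.92 && 6.92 <= su$ci_upper
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("posterior_tail_fraction counts draws as printed", {
  d <- simulate_beta_data(-3.72, 6.92, 30, 148, seed = 31)
  fit <- fit_beta_regression(d, y ~ x, seed = 8)
  frac <- posterior_tail_fraction(fit, "le")
  expect_equal(as.numeric(frac), 0)          # strong positive slope
  expect_equal(attr(frac, "n_draws"), 8000)
  expect_equal(as.numeric(posterior_tail_fraction(fit, "ge")), 1)
  # crafted draw sets: symmetry and the 1-of-8000 case
  fit2 <- fit
  fit2$draws[, "slope"] <- c(seq(-1, -1e-6, length.out = 4000),
                             seq(1e-6, 1, length.out = 4000))
  expect_equal(as.numeric(posterior_tail_fraction(fit2, "le")), 0.5)
  fit2$draws[, "slope"] <- c(-1e-9, seq(1e-6, 1, length.out = 7999))
  expect_equal(as.numeric(posterior_tail_fraction(fit2, "le")), 1 / 8000)
  expect_equal(as.numeric(posterior_tail_fraction(fit2, "le")), 0.000125)
})
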