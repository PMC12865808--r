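# Bayesian inference: conjugate agreement, diagnostics, Bayes factors,
# sequential stopping, ANOVA behavior.

test_that("posterior matches the conjugate closed form with known sigma", {
  set.seed(3)
  n <- 100
  x <- rnorm(n)
  sigma <- 0.5
  y <- 0.8 * x + rnorm(n, 0, sigma)
  dat <- data.frame(y = y, x = x)
  pr <- ds_priors(intercept_mean = 0, intercept_sd = 10, beta_sd = 1,
                  sigma_fixed = sigma)
  fit <- fit_hierarchical(y ~ x, dat, priors = pr, seed = 2)
  expect_true(fit$converged)

  X <- cbind(1, x)
  S0inv <- diag(c(1 / 100, 1))
  V <- solve(crossprod(X) / sigma^2 + S0inv)
  m <- drop(V %*% crossprod(X, y) / sigma^2)
  for (j in 1:2) {
    row <- fit$summary[j, ]
    mcse <- row$sd / sqrt(row$ess)
    expect_lt(abs(row$mean - m[j]), 3 * mcse + 1e-8)
    expect_equal(row$sd, sqrt(V[j, j]), tolerance = 0.1)
  }
})

test_that("likelihood invariance: shifting the response moves only the
           intercept", {
  set.seed(8)
  n <- 80
  dat <- data.frame(x = rnorm(n))
  dat$y <- 0.5 * dat$x + rnorm(n, 0, 0.3)
  pr <- ds_priors(intercept_mean = 0, intercept_sd = 50, beta_sd = 5)
  f1 <- fit_hierarchical(y ~ x, dat, priors = pr, seed = 3)
  dat2 <- dat
  dat2$y <- dat$y + 10
  f2 <- fit_hierarchical(y ~ x, dat2, priors = pr, seed = 3)
  b1 <- f1$summary[f1$summary$parameter == "x", ]
  b2 <- f2$summary[f2$summary$parameter == "x", ]
  expect_lt(abs(b1$mean - b2$mean), 3 * (b1$sd / sqrt(b1$ess) +
                                           b2$sd / sqrt(b2$ess)) + 0.01)
  i1 <- f1$summary[f1$summary$parameter == "(Intercept)", "mean"]
  i2 <- f2$summary[f2$summary$parameter == "(Intercept)", "mean"]
  expect_equal(i2 - i1, 10, tolerance = 0.1)
})

test_that("random-intercept variance is recovered and shrinks when absent", {
  set.seed(4)
  G <- 60
  dat <- data.frame(g = factor(rep(seq_len(G), each = 2)))
  u <- rnorm(G, 0, 0.5)
  dat$y <- 1 + u[as.integer(dat$g)] + rnorm(nrow(dat), 0, 0.2)
  fit <- fit_hierarchical(y ~ 1 + (1 | g), dat,
                          priors = ds_priors(beta_sd = 5), seed = 5)
  tau_row <- fit$summary[fit$summary$parameter == "sd_u", ]
  expect_gt(tau_row$q97.5, 0.3)
  expect_lt(tau_row$q2.5, 0.7)

  dat0 <- dat
  set.seed(6)
  dat0$y <- 1 + rnorm(nrow(dat0), 0, 0.2) # no group effect
  fit0 <- fit_hierarchical(y ~ 1 + (1 | g), dat0,
                           priors = ds_priors(beta_sd = 5), seed = 5)
  expect_lt(fit0$summary[fit0$summary$parameter == "sd_u", "q97.5"], 0.25)
})

test_that("rank-normalized split R-hat separates mixed from unmixed chains", {
  set.seed(1)
  good <- matrix(rnorm(4000), 1000, 4)
  expect_lt(rhat(good), 1.01)
  split_chains <- cbind(rnorm(1000, 0), rnorm(1000, 5))
  expect_gt(rhat(split_chains), 1.5)
  # constant chains: not applicable
  expect_true(is.na(rhat(matrix(1, 100, 2))))
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("prior and posterior predictive checks behave as designed", {
  set.seed(9)
  dat <- data.frame(y = rnorm(60, 0.3, 0.05))
  pp <- prior_predictive(y ~ 1, dat,
                         priors = ds_priors(intercept_mean = 0.3,
                                            intercept_sd = 0.1,
                                            sigma_sd = 0.01),
                         n_draws = 10000, seed = 2)
  expect_equal(mean(pp$rep_means), 0.3, tolerance = 0.02)
  # degenerate zero-variance priors collapse on the prior mean
  pp0 <- prior_predictive(y ~ 1, dat,
                          priors = ds_priors(intercept_mean = 0.3,
                                             intercept_sd = 1e-12,
                                             sigma_sd = 1e-12),
                          n_draws = 50, seed = 2)
  expect_equal(unname(range(pp0$rep_means)), c(0.3, 0.3), tolerance = 1e-9)
  expect_identical(pp0$rep_means,
                   prior_predictive(y ~ 1, dat,
                                    priors = ds_priors(intercept_mean = 0.3,
                                                       intercept_sd = 1e-12,
                                                       sigma_sd = 1e-12),
                                    n_draws = 50, seed = 2)$rep_means)

  fit <- fit_hierarchical(y ~ 1, dat, priors = ds_priors(beta_sd = 5),
                          chains = 2, iterations = 500, warmup = 300, seed = 3)
  post <- posterior_predictive(fit, seed = 4)
  expect_gt(post$percentile, 0.05)
  expect_lt(post$percentile, 0.95)
  expect_identical(post$rep_means, posterior_predictive(fit, seed = 4)$rep_means)
  # grossly shifted data against the same fitted draws
  fit_shift <- fit
  fit_shift$y <- fit$y + 1
  post_s <- posterior_predictive(fit_shift, seed = 4)
  expect_true(post_s$percentile > 0.99 || post_s$percentile < 0.01)
})

test_that("Bayes factors: identity, analytic Savage-Dickey agreement,
           reciprocity", {
  set.seed(13)
  n <- 60
  x <- rnorm(n)
  sigma <- 1
  y <- 0.25 * x + rnorm(n, 0, sigma)
  dat <- data.frame(y = y, x = x)
  pr <- ds_priors(intercept_mean = 0, intercept_sd = 10, beta_sd = 1,
                  sigma_fixed = sigma)

  expect_equal(bayes_factor(y ~ x, y ~ x, dat, priors = pr)$bf10, 1)

  # analytic conjugate posterior for the slope
  X <- cbind(1, x)
  S0inv <- diag(c(1 / 100, 1))
  V <- solve(crossprod(X) / sigma^2 + S0inv)
  m <- drop(V %*% crossprod(X, y) / sigma^2)
  bf_true <- dnorm(0, 0, 1) / dnorm(0, m[2], sqrt(V[2, 2]))

  bf_sd <- bayes_factor(y ~ x, y ~ 1, dat, priors = pr,
                        method = "savage_dickey", seed = 7)
  expect_lt(abs(bf_sd$bf10 - bf_true), 3 * bf_sd$mc_error + 0.05 * bf_true)

  bf_m <- bayes_factor(y ~ x, y ~ 1, dat, priors = pr, method = "marginal")
  expect_equal(bf_m$bf10, bf_true, tolerance = 1e-6)

  # reciprocity with free sigma and a random intercept
  dat$g <- factor(rep(1:20, 3))
  pr2 <- ds_priors(beta_sd = 1)
  b1 <- bayes_factor(y ~ x + (1 | g), y ~ 1 + (1 | g), dat, priors = pr2,
                     method = "marginal")
  b2 <- bayes_factor(y ~ 1 + (1 | g), y ~ x + (1 | g), dat, priors = pr2,
                     method = "marginal")
  expect_equal(b1$bf10 * b2$bf10, 1, tolerance = 1e-8)

  expect_error(bayes_factor(y ~ x, y ~ 1 + x + g, dat, priors = pr,
                            method = "savage_dickey"), "nested")
})

test_that("sequential monitoring applies the stopping thresholds", {
  traj <- c(1, 1.4, 2.2, 3.1, 2.8, 5.6, 9)
  res <- sequential_monitor(trajectory = traj)
  expect_equal(res$decision, "support-full")
  expect_equal(res$stop_at, 6)
  expect_equal(sequential_monitor(trajectory = c(1, 0.6, 0.1))$decision,
               "support-null")
  expect_equal(sequential_monitor(trajectory = rep(1, 10))$decision,
               "resources exhausted")

  # data-driven: strong effect stops early with support for the full model
  set.seed(5)
  n <- 80
  dat <- data.frame(x = rnorm(n), cell = rep(c("a", "b"), n / 2))
  dat$y <- 1 * dat$x + rnorm(n, 0, 0.3)
  res2 <- sequential_monitor(y ~ x, y ~ 1, data = dat,
                             start_n_per_condition = 10,
                             priors = ds_priors(beta_sd = 1), step = 5)
  expect_equal(res2$decision, "support-full")
  expect_lte(res2$stop_at, n)
  expect_true(all(res2$trajectory$bf10[seq_len(nrow(res2$trajectory) - 1)] <= 5))
})

test_that("Bayesian ANOVA: null covers zero, shifts are detected, labels
           flip signs", {
  set.seed(10)
  n_cell <- 24
  dat <- expand.grid(rep = seq_len(n_cell), f1 = c("lo", "hi"),
                     f2 = c("no", "yes"))
  dat$y <- rnorm(nrow(dat), 50, 5)
  dat$f1 <- factor(dat$f1, levels = c("lo", "hi"))
  fit0 <- bayesian_anova(dat, "y", c("f1", "f2"), chains = 2,
                         iterations = 500, warmup = 300, seed = 2)
  s0 <- fit0$summary
  eff_names <- setdiff(s0$parameter, c("(Intercept)", "sigma"))
  for (p in eff_names) {
    e99 <- eti(fit0$draws[, p], 0.99)
    expect_lt(e99[["lower"]], 0)
    expect_gt(e99[["upper"]], 0)
  }

  dat$y2 <- dat$y + ifelse(dat$f1 == "hi", 50, 0)
  fit1 <- bayesian_anova(dat, "y2", c("f1", "f2"), chains = 2,
                         iterations = 500, warmup = 300, seed = 2)
  r1 <- fit1$summary[fit1$summary$parameter == "f11", ]
  expect_true(r1$q2.5 > 0 | r1$q97.5 < 0)

  dat$f1r <- factor(dat$f1, levels = c("hi", "lo"))
  fit2 <- bayesian_anova(dat, "y2", c("f1r", "f2"), chains = 2,
                         iterations = 500, warmup = 300, seed = 2)
  r2 <- fit2$summary[fit2$summary$parameter == "f1r1", ]
  expect_equal(r1$mean, -r2$mean, tolerance = 3)
})
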