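test_that("Wald ratios follow hand arithmetic and unit covariance", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.02)
  expect_equal(wr$theta, 0.5)
  expect_equal(wr$se, 0.2)
  wr2 <- wald_ratio(0.1, 0.01, 0.05, 0.02, order = "second")
  expect_equal(wr2$se, sqrt(0.02^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  # null numerator
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.03)$theta, 0)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.03)$se, 0.03 / 0.2)
  # scaling exposure by c scales theta by 1/c
  expect_equal(wald_ratio(0.2, 0.02, 0.05, 0.02)$theta,
               wald_ratio(0.1, 0.01, 0.05, 0.02)$theta / 2)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "undefined")
})

test_that("IVW equals the closed-form weighted mean and zero-intercept WLS", {
  iv <- make_iv(beta_x = c(1, 1, 1), se_x = 0.01,
                beta_y = c(0.2, 0.4, 0.6), se_y = 0.1)
  fit <- mr_ivw(iv, model = "fixed")
  expect_equal(fit$beta, 0.4)
  expect_equal(fit$se, 0.1 / sqrt(3))
  # degenerate homogeneity: all ratios equal -> Q = 0
  ivh <- make_iv(c(0.1, 0.2, 0.4), 0.01, c(0.05, 0.10, 0.20), c(0.01, 0.02, 0.04))
  expect_equal(mr_ivw(ivh)$extras$Q, 0)
  expect_equal(mr_ivw(ivh)$beta, 0.5)

  for (s in 1:15) {
    iv <- random_iv(20, seed = s)
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = iv,
              weights = 1 / iv$se_outcome^2)
    expect_equal(mr_ivw(iv)$beta, unname(coef(wls)), tolerance = 1e-10)
  }
  expect_error(mr_ivw(make_iv(0.1, 0.01, 0.1, 0.1)), "at least 2")
})

test_that("fixed-effect IVW matches an independent meta-analysis oracle", {
  iv <- random_iv(25, seed = 99)
  wr <- wald_ratio(iv$beta_exposure, iv$se_exposure,
                   iv$beta_outcome, iv$se_outcome)
  rma <- metafor::rma(yi = wr$theta, sei = wr$se, method = "FE")
  fit <- mr_ivw(iv, model = "fixed")
  expect_equal(fit$beta, as.numeric(rma$beta), tolerance = 1e-8)
  expect_equal(fit$se, as.numeric(rma$se), tolerance = 1e-8)
})

test_that("MR-Egger reproduces with-intercept WLS and its orientation rule", {
  for (s in 1:10) {
    iv <- random_iv(15, seed = 100 + s)
    fit <- mr_egger(iv)
    sgn <- sign(iv$beta_exposure)
    wls <- lm(I(sgn * beta_outcome) ~ I(sgn * beta_exposure), data = iv,
              weights = 1 / iv$se_outcome^2)
    expect_equal(fit$beta, unname(coef(wls)[2]), tolerance = 1e-10)
    expect_equal(fit$extras$egger_intercept, unname(coef(wls)[1]),
                 tolerance = 1e-10)
    # flipping arbitrary rows must not change the fit
    flip <- seq_len(nrow(iv)) %% 2 == 0
    iv2 <- iv
    iv2$beta_exposure[flip] <- -iv2$beta_exposure[flip]
    iv2$beta_outcome[flip] <- -iv2$beta_outcome[flip]
    expect_equal(mr_egger(iv2)$beta, fit$beta, tolerance = 1e-12)
  }
  # exact zero-intercept data with identical SEs: Egger slope = IVW slope
  bx <- c(0.05, 0.1, 0.15, 0.2)
  iv0 <- make_iv(bx, 0.001, 0.3 * bx, 0.02)
  eg0 <- mr_egger(iv0)
  expect_equal(eg0$beta, mr_ivw(iv0)$beta, tolerance = 1e-9)
  expect_equal(eg0$extras$egger_intercept, 0, tolerance = 1e-12)
  expect_error(mr_egger(make_iv(c(0.1, 0.2), 0.01, c(0.1, 0.2), 0.01)),
               "at least 3")
})

test_that("the weighted median interpolates cumulative weights correctly", {
  # equal weights, odd J -> ordinary median
  iv <- make_iv(rep(1, 5), 0.01, c(0.3, 0.1, 0.5, 0.2, 0.4), rep(0.1, 5))
  fit <- mr_weighted_median(iv, n_boot = 200, seed = 1)
  expect_equal(fit$beta, 0.3)
  # hand cumulative-weight walk: theta (0.1, 0.2, 0.9), weights (1, 1, 2)
  # normalized s = (0.125, 0.375, 0.750); interpolate at 0.5
  theta <- c(0.1, 0.2, 0.9)
  w <- c(1, 1, 2)
  hand <- 0.2 + (0.9 - 0.2) * (0.5 - 0.375) / (0.750 - 0.375)
  iv2 <- make_iv(rep(1, 3), 0.001, theta, 1 / sqrt(w))
  fit2 <- mr_weighted_median(iv2, n_boot = 200, seed = 2)
  expect_equal(fit2$beta, hand)
  expect_equal(fit2$beta, brute_weighted_median(theta, w))
  # property: matches the brute-force walk on random instances
  for (s in 1:10) {
    set.seed(s)
    th <- rnorm(11); ww <- runif(11, 0.5, 3)
    ivr <- make_iv(rep(1, 11), 0.001, th, 1 / sqrt(ww))
    expect_equal(mr_weighted_median(ivr, n_boot = 100, seed = s)$beta,
                 brute_weighted_median(th, ww))
  }
  # bootstrap is seeded and reproducible
  iv3 <- random_iv(12, seed = 3)
  a <- mr_weighted_median(iv3, n_boot = 300, seed = 7)
  b <- mr_weighted_median(iv3, n_boot = 300, seed = 7)
  expect_identical(a$se, b$se)
  expect_warning(mr_weighted_median(iv3, n_boot = 50, seed = 1), "n_boot")
})

test_that("maximum likelihood matches a profile-grid oracle and the IVW limit", {
  iv <- make_iv(c(0.08, 0.12, 0.10), c(0.01, 0.015, 0.012),
                c(0.030, 0.020, 0.028), c(0.012, 0.011, 0.013))
  fit <- mr_max_likelihood(iv)
  # brute-force profile-likelihood grid
  grid <- seq(-1, 1, by = 1e-4)
  ll <- vapply(grid, function(th) {
    -0.5 * sum((iv$beta_outcome - th * iv$beta_exposure)^2 /
                 (iv$se_outcome^2 + th^2 * iv$se_exposure^2))
  }, numeric(1))
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-4)
  # se_x -> 0: estimate collapses to IVW
  iv0 <- iv
  iv0$se_exposure <- 1e-8
  expect_equal(mr_max_likelihood(iv0)$beta, mr_ivw(iv0, model = "fixed")$beta,
               tolerance = 1e-6)
})

test_that("maximum likelihood recovers a simulated causal effect", {
  est <- vapply(1:100, function(r) {
    tr <- sim_truth(seed = 6000 + r, n_snps = 50, n_snps_mediator = 0,
                    theta_xm = numeric(0), theta_my = numeric(0),
                    theta_xy_direct = 0.3)
    sim <- simulate_two_sample(tr)
    iv <- harmonize(select_instruments(sim$exposure), sim$outcome)
    mr_max_likelihood(iv)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("RAPS with no overdispersion and squared loss equals maximum likelihood", {
  for (s in 1:8) {
    iv <- random_iv(15, seed = 300 + s)
    expect_equal(mr_raps(iv)$beta, mr_max_likelihood(iv)$beta,
                 tolerance = 1e-6)
  }
})

test_that("RAPS overdispersion responds to balanced pleiotropy", {
  # pleiotropy variance must be resolvable against the outcome sampling
  # noise, so the outcome GWAS is a common-disease-scale sample here
  hits <- vapply(1:60, function(r) {
    tr <- sim_truth(seed = 8000 + r, n_snps = 60, n_snps_mediator = 0,
                    theta_xm = numeric(0), theta_my = numeric(0),
                    theta_xy_direct = 0.2, prop_invalid = 1,
                    pleiotropy_mean = 0, pleiotropy_sd = 0.01,
                    n_outcome = 50000)
    sim <- simulate_two_sample(tr)
    iv <- harmonize(select_instruments(sim$exposure), sim$outcome)
    mr_raps(iv, overdispersion = TRUE)$extras$tau2 > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Huber-loss RAPS resists a single gross outlier", {
  truth <- 0.2
  bx <- rep(c(0.08, 0.10, 0.12), 4)
  by <- truth * bx
  by[1] <- by[1] + 0.5  # gross contamination
  iv <- make_iv(bx, 0.002, by, 0.01)
  rob <- mr_raps(iv, loss = "huber")
  naive <- mr_raps(iv, loss = "squared")
  # the robust SE is the common yardstick: a gross outlier inflates the
  # squared-loss sandwich SE along with its own bias, masking itself
  expect_lt(abs(rob$beta - truth), 2 * rob$se)
  expect_gt(abs(naive$beta - truth), 2 * rob$se)
  expect_lt(abs(rob$beta - truth), abs(naive$beta - truth) / 5)
})

test_that("estimators are sign-equivariant and scale like ratios", {
  iv <- random_iv(14, seed = 55)
  flip <- iv
  flip$beta_exposure <- -flip$beta_exposure
  flip$beta_outcome <- -flip$beta_outcome
  scaled <- iv
  scaled$beta_exposure <- 2 * scaled$beta_exposure
  scaled$se_exposure <- 2 * scaled$se_exposure
  fits <- list(
    ivw = mr_ivw, egger = mr_egger, ml = mr_max_likelihood,
    med = function(x) mr_weighted_median(x, n_boot = 100, seed = 4),
    raps = function(x) mr_raps(x)
  )
  for (f in fits) {
    expect_equal(f(flip)$beta, f(iv)$beta, tolerance = 1e-8)
    expect_equal(f(scaled)$beta, f(iv)$beta / 2, tolerance = 1e-6)
  }
})

test_that("results expose a consistent odds-ratio scale and p-values", {
  iv <- random_iv(10, seed = 66)
  for (fit in list(mr_ivw(iv), mr_egger(iv),
                   mr_weighted_median(iv, n_boot = 100, seed = 5),
                   mr_max_likelihood(iv), mr_raps(iv))) {
    expect_true(fit$ci_low < fit$beta && fit$beta < fit$ci_high)
    expect_equal(fit$or, exp(fit$beta), tolerance = 1e-12)
    expect_equal(fit$or_ci_low, exp(fit$ci_low), tolerance = 1e-12)
    ref_p <- if (is.null(fit$df)) 2 * pnorm(-abs(fit$beta / fit$se)) else
      2 * pt(-abs(fit$beta / fit$se), fit$df)
    expect_equal(fit$pval, ref_p, tolerance = 1e-12)
  }
})
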