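test_that("multivariable IVW solves the weighted normal equations exactly", {
  set.seed(17)
  J <- 5
  BX <- cbind(TG = rnorm(J, 0.1, 0.03), IL = rnorm(J, 0.05, 0.02))
  by <- rnorm(J, 0.02, 0.02)
  sy <- runif(J, 0.01, 0.03)
  mvset <- list(beta_exposure = BX, se_exposure = BX * 0 + 0.005,
                beta_outcome = by, se_outcome = sy)
  fit <- mvmr_ivw(mvset)
  W <- diag(1 / sy^2)
  oracle <- solve(t(BX) %*% W %*% BX, t(BX) %*% W %*% by)
  expect_equal(fit$estimates$beta, as.numeric(oracle), tolerance = 1e-10)
  expect_equal(fit$estimates$exposure, c("TG", "IL"))
  expect_equal(fit$n_snps, J)
})

test_that("rank-deficient exposure matrices raise a collinearity error", {
  J <- 6
  BX <- cbind(A = rep(0.1, J), B = rep(0, J))
  mvset <- list(beta_exposure = BX, se_exposure = BX * 0 + 0.01,
                beta_outcome = rnorm(J, 0, 0.01), se_outcome = rep(0.01, J))
  expect_error(mvmr_ivw(mvset), "collinear")
  # perfectly proportional columns too
  set.seed(2)
  x <- rnorm(J, 0.1, 0.02)
  mvset2 <- list(beta_exposure = cbind(A = x, B = 2 * x),
                 se_exposure = cbind(A = rep(0.01, J), B = rep(0.01, J)),
                 beta_outcome = rnorm(J, 0, 0.01), se_outcome = rep(0.01, J))
  expect_error(mvmr_ivw(mvset2), "collinear")
})

test_that("too few instruments for the number of exposures is an error", {
  BX <- cbind(A = c(0.1, 0.2), B = c(0.05, 0.02))
  mvset <- list(beta_exposure = BX, se_exposure = BX * 0 + 0.01,
                beta_outcome = c(0.01, 0.02), se_outcome = c(0.01, 0.01))
  expect_error(mvmr_ivw(mvset), "more instruments")
})

test_that("multivariable fits recover direct rather than total effects", {
  # structural truth: direct exposure effect 0.2, mediator path 0.5 x 0.3;
  # the univariable total is 0.35, the MVMR coefficients are 0.2 and 0.3
  reps <- 60
  est <- t(vapply(seq_len(reps), function(r) {
    # large mediator GWAS so measurement error in the mediator betas does
    # not attenuate its coefficient
    tr <- sim_truth(seed = 14000 + r, n_snps = 60, n_snps_mediator = 30,
                    theta_xm = 0.5, theta_my = 0.3, theta_xy_direct = 0.2,
                    n_mediator = 2e5, n_outcome = 50000)
    sim <- simulate_two_sample(tr)
    mvset <- mvmr_harmonize(list(exposure = sim$exposure,
                                 M1 = sim$mediators$M1), sim$outcome)
    fit <- mvmr_ivw(mvset)
    c(fit$estimates$beta[fit$estimates$exposure == "exposure"],
      fit$estimates$beta[fit$estimates$exposure == "M1"])
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 0.2), 0.02)
  expect_lt(abs(mean(est[, 2]) - 0.3), 0.02)
  expect_gt(abs(mean(est[, 1]) - 0.35), 0.1)  # clearly not the total
})

test_that("mvmr harmonization aligns orientations across traits", {
  tr <- sim_truth(seed = 55, n_snps = 30, n_snps_mediator = 10,
                  n_outcome = 50000)
  sim <- simulate_two_sample(tr)
  flipped_outcome <- sim$outcome
  swap <- seq_len(10)
  tmp <- flipped_outcome$effect_allele[swap]
  flipped_outcome$effect_allele[swap] <- flipped_outcome$other_allele[swap]
  flipped_outcome$other_allele[swap] <- tmp
  flipped_outcome$beta[swap] <- -flipped_outcome$beta[swap]
  flipped_outcome$eaf[swap] <- 1 - flipped_outcome$eaf[swap]
  a <- mvmr_ivw(mvmr_harmonize(list(exposure = sim$exposure,
                                    M1 = sim$mediators$M1), sim$outcome))
  b <- mvmr_ivw(mvmr_harmonize(list(exposure = sim$exposure,
                                    M1 = sim$mediators$M1), flipped_outcome))
  expect_equal(a$estimates$beta, b$estimates$beta, tolerance = 1e-12)
})

test_that("conditional instrument strength is reported per exposure", {
  tr <- sim_truth(seed = 66, n_snps = 50, n_snps_mediator = 25,
                  n_outcome = 50000)
  sim <- simulate_two_sample(tr)
  fit <- mvmr_ivw(mvmr_harmonize(list(exposure = sim$exposure,
                                      M1 = sim$mediators$M1), sim$outcome))
  expect_true(all(is.finite(fit$estimates$conditional_F)))
  expect_gt(fit$estimates$conditional_F[1], 10)
})

test_that("the mediation table satisfies both decomposition identities", {
  tr <- sim_truth(seed = 202, n_outcome = 2e5)
  sim <- simulate_two_sample(tr)
  dec <- two_step_mediation(sim$exposure, sim$mediators, sim$outcome,
                            method = "both")
  tab <- dec$table
  prod_row <- tab[tab$method == "product", ]
  expect_equal(prod_row$indirect, prod_row$beta1 * prod_row$beta2)
  expect_equal(prod_row$proportion_mediated,
               100 * prod_row$indirect / (prod_row$beta3 + prod_row$indirect))
  expect_equal(prod_row$se_indirect,
               sqrt(prod_row$beta1^2 * prod_row$se_beta2^2 +
                      prod_row$beta2^2 * prod_row$se_beta1^2))
  diff_row <- tab[tab$method == "difference", ]
  expect_equal(diff_row$indirect, diff_row$total - diff_row$beta3)
  expect_equal(diff_row$proportion_mediated,
               100 * diff_row$indirect / diff_row$total)
  # single valid mediator at large n: the two definitions agree closely
  expect_lt(abs(prod_row$proportion_mediated - diff_row$proportion_mediated), 5)
})

test_that("the mediated proportion is invariant to mediator rescaling", {
  tr <- sim_truth(seed = 303)
  sim <- simulate_two_sample(tr)
  rescaled <- sim$mediators
  rescaled$M1$beta <- 10 * rescaled$M1$beta
  rescaled$M1$se <- 10 * rescaled$M1$se
  a <- two_step_mediation(sim$exposure, sim$mediators, sim$outcome)
  b <- two_step_mediation(sim$exposure, rescaled, sim$outcome)
  expect_equal(a$table$proportion_mediated, b$table$proportion_mediated,
               tolerance = 1e-8)
  expect_equal(b$table$beta1, 10 * a$table$beta1, tolerance = 1e-8)
  expect_equal(b$table$beta2, a$table$beta2 / 10, tolerance = 1e-8)
})

test_that("no mediator-outcome path means a near-zero mediated proportion", {
  props <- vapply(1:30, function(r) {
    tr <- sim_truth(seed = 15000 + r, theta_my = 0, n_outcome = 2e5)
    sim <- simulate_two_sample(tr)
    dec <- two_step_mediation(sim$exposure, sim$mediators, sim$outcome)
    dec$table$proportion_mediated
  }, numeric(1))
  expect_lt(abs(median(props)), 3)
})

test_that("a purely indirect effect yields a mediated proportion near 100%", {
  props <- vapply(1:30, function(r) {
    tr <- sim_truth(seed = 16000 + r, theta_xy_direct = 0, theta_xm = 0.3,
                    theta_my = 0.4, n_mediator = 2e5, n_outcome = 2e5)
    sim <- simulate_two_sample(tr)
    dec <- two_step_mediation(sim$exposure, sim$mediators, sim$outcome)
    dec$table$proportion_mediated
  }, numeric(1))
  expect_lt(abs(median(props) - 100), 10)
})

test_that("opposite-sign indirect and total effects raise the inconsistency flag", {
  row <- mrmediation:::.mediation_row("M", beta1 = 0.2, se1 = 0.01,
                                      beta2 = -0.3, se2 = 0.02,
                                      beta3 = 0.25, se3 = 0.02,
                                      total = 0.19, se_total = 0.02,
                                      method = "product")
  expect_true(row$inconsistent)
  expect_lt(row$proportion_mediated, 0)
  row2 <- mrmediation:::.mediation_row("M", beta1 = 0.2, se1 = 0.01,
                                       beta2 = 0.3, se2 = 0.02,
                                       beta3 = 0.25, se3 = 0.02,
                                       total = 0.31, se_total = 0.02,
                                       method = "difference")
  expect_false(row2$inconsistent)
})

test_that("joint adjustment for two mediators uses the all-mediator fit", {
  tr <- sim_truth(seed = 404, theta_xm = c(0.10, 0.12), theta_my = c(0.25, 0.2),
                  n_snps_mediator = 20, n_outcome = 2e5)
  sim <- simulate_two_sample(tr)
  dec <- two_step_mediation(sim$exposure, sim$mediators, sim$outcome,
                            method = "product")
  tab <- dec$table
  expect_equal(nrow(tab), 3)  # two pairwise rows + one joint row
  joint <- tab[tab$mediator == "M1+M2", ]
  expect_equal(joint$beta3,
               dec$mvmr_joint$estimates$beta[
                 dec$mvmr_joint$estimates$exposure == ".exposure"])
  est <- dec$mvmr_joint$estimates
  ind <- sum(vapply(c("M1", "M2"), function(nm) {
    dec$step1[[nm]]$beta * est$beta[est$exposure == nm]
  }, numeric(1)))
  expect_equal(joint$indirect, ind)
  expect_equal(joint$proportion_mediated, 100 * ind / (joint$beta3 + ind))
})
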