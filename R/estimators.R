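# Univariable two-sample MR estimators on a harmonized instrument set.
#
# All estimators consume the Wald-ratio parameterisation: per SNP j the
# ratio theta_j = beta_outcome_j / beta_exposure_j estimates the causal
# effect, with first-order SE se_outcome_j / |beta_exposure_j|. IVW is the
# inverse-variance-weighted mean of the ratios, algebraically the slope of
# the zero-intercept weighted regression of outcome on exposure betas.

#' Construct an MR result object
#'
#' @param method Method label.
#' @param beta,se Causal log-effect estimate and standard error.
#' @param n_snps Number of instruments used.
#' @param df Degrees of freedom for a t reference distribution; `NULL`
#'   (default) uses the normal reference.
#' @param extras Named list of method-specific extras.
#' @return A list of class `"mr_result"` with the estimate, its 95% CI and
#'   p-value on the log scale, and the exponentiated (odds-ratio) scale.
#' @export
mr_result <- function(method, beta, se, n_snps, df = NULL, extras = list()) {
  if (is.null(df)) {
    crit <- .qnorm975
    pval <- .p_from_z(beta / se)
  } else {
    crit <- stats::qt(0.975, df)
    pval <- 2 * stats::pt(-abs(beta / se), df)
  }
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pval = pval,
    or = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    n_snps = as.integer(n_snps), df = df, extras = extras
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$or, x$or_ci_low, x$or_ci_high,
              x$pval, x$n_snps))
  if (!is.null(x$extras$egger_intercept)) {
    cat(sprintf("  Egger intercept = %.4f (SE %.4f), p = %.3g\n",
                x$extras$egger_intercept, x$extras$egger_intercept_se,
                x$extras$egger_intercept_pval))
  }
  if (!is.null(x$extras$tau2)) {
    cat(sprintf("  overdispersion tau^2 = %.3g\n", x$extras$tau2))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             n_snps = x$n_snps, stringsAsFactors = FALSE)
}

#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate `theta = beta_y / beta_x` with first-order SE
#' `se_y / |beta_x|`, or the second-order SE
#' `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)` which additionally
#' propagates the exposure-side sampling error.
#'
#' @param beta_x,se_x Exposure effect and SE (vectorised).
#' @param beta_y,se_y Outcome effect and SE.
#' @param order `"first"` (default) or `"second"` order SE.
#' @return data.frame with columns `theta`, `se`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y,
                       order = c("first", "second")) {
  order <- match.arg(order)
  if (any(beta_x == 0)) {
    stop("Wald ratio undefined: zero exposure effect for ",
         sum(beta_x == 0), " variant(s)")
  }
  theta <- beta_y / beta_x
  se <- if (order == "first") {
    se_y / abs(beta_x)
  } else {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  }
  data.frame(theta = theta, se = se)
}

.iv_columns <- function(iv) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(iv))
  if (length(miss) > 0) {
    stop("instrument set lacks column(s): ", paste(miss, collapse = ", "))
  }
  iv
}

#' Inverse-variance-weighted MR estimate
#'
#' Meta-analyses the per-SNP Wald ratios with first-order inverse-variance
#' weights `w_j = se(theta_j)^-2`. The point estimate equals the slope of
#' the zero-intercept weighted least-squares regression of outcome betas on
#' exposure betas with weights `se_outcome^-2`. Under the multiplicative
#' random-effects model (default) the fixed-effect SE `(sum w_j)^(-1/2)` is
#' inflated by `max(1, sqrt(Q/(J-1)))` where Q is Cochran's heterogeneity
#' statistic; inference uses the normal reference.
#'
#' @param iv Harmonized instrument set (>= 2 SNPs).
#' @param model `"random"` (multiplicative random effects; default) or
#'   `"fixed"`.
#' @param se_order Wald-ratio SE order passed to [wald_ratio()].
#' @return An [mr_result()] with extras `Q`, `Q_df`, `Q_pval`, `model`.
#' @export
mr_ivw <- function(iv, model = c("random", "fixed"),
                   se_order = c("first", "second")) {
  model <- match.arg(model); se_order <- match.arg(se_order)
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 2) stop("IVW requires at least 2 instruments, got ", J)
  wr <- wald_ratio(iv$beta_exposure, iv$se_exposure,
                   iv$beta_outcome, iv$se_outcome, order = se_order)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$theta) / sum(w)
  Q <- sum(w * (wr$theta - beta)^2)
  se_fixed <- 1 / sqrt(sum(w))
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / (J - 1))) else se_fixed
  mr_result("IVW", beta, se, J,
            extras = list(Q = Q, Q_df = J - 1,
                          Q_pval = stats::pchisq(Q, J - 1, lower.tail = FALSE),
                          model = model))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept and weights `se_outcome^-2`, after orienting all exposure
#' effects to be non-negative (sign-flipping both betas of negative rows).
#' The slope is the pleiotropy-adjusted causal estimate; the intercept
#' estimates the average directional pleiotropic effect. Standard errors
#' use multiplicative residual inflation floored at 1 and a t reference on
#' J - 2 degrees of freedom.
#'
#' @param iv Harmonized instrument set (>= 3 SNPs).
#' @return An [mr_result()] with intercept extras (`egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_ci_low/high`,
#'   `egger_intercept_pval`).
#' @export
mr_egger <- function(iv) {
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 3) stop("MR-Egger requires at least 3 instruments, got ", J)
  s <- sign(iv$beta_exposure)
  s[s == 0] <- 1
  bx <- iv$beta_exposure * s
  by <- iv$beta_outcome * s
  w <- 1 / iv$se_outcome^2
  X <- cbind(`(Intercept)` = 1, bx = bx)
  fit <- stats::lm.wfit(x = X, y = by, w = w)
  rss <- sum(w * fit$residuals^2)
  sigma <- sqrt(rss / (J - 2))
  infl <- max(1, sigma)
  xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  se_base <- sqrt(diag(xtwx_inv))           # unit-residual-variance SEs
  slope <- fit$coefficients["bx"]
  slope_se <- se_base[2] * infl
  icpt <- fit$coefficients["(Intercept)"]
  icpt_se <- se_base[1] * infl
  tcrit <- stats::qt(0.975, J - 2)
  mr_result("MR-Egger", unname(slope), unname(slope_se), J, df = J - 2,
            extras = list(
              egger_intercept = unname(icpt),
              egger_intercept_se = unname(icpt_se),
              egger_intercept_ci_low = unname(icpt - tcrit * icpt_se),
              egger_intercept_ci_high = unname(icpt + tcrit * icpt_se),
              egger_intercept_pval = unname(2 * stats::pt(-abs(icpt / icpt_se),
                                                          J - 2))))
}

# interpolated weighted median of theta with weights w
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  J <- length(theta)
  if (0.5 >= s[J]) return(theta[J])
  hi <- which(s >= 0.5)[1]
  lo <- hi - 1
  theta[lo] + (theta[hi] - theta[lo]) * (0.5 - s[lo]) / (s[hi] - s[lo])
}

#' Weighted-median MR estimate
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance-weighted
#' median: the value at normalized cumulative weight 0.5, linearly
#' interpolated between the bracketing order statistics. Consistent when
#' at least half the total weight comes from valid instruments. The SE is
#' a parametric bootstrap: ratios are resampled as
#' `theta_j* ~ Normal(theta_j, se(theta_j)^2)` and the SD of the resampled
#' medians is reported.
#'
#' @param iv Harmonized instrument set (>= 3 SNPs).
#' @param n_boot Bootstrap replicates for the SE (default 1000; fewer than
#'   100 triggers a warning).
#' @param seed Integer seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return An [mr_result()].
#' @export
mr_weighted_median <- function(iv, n_boot = 1000, seed) {
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 3) stop("weighted median requires at least 3 instruments, got ", J)
  if (missing(seed)) stop("seed is required for the bootstrap SE")
  if (n_boot < 100) {
    warning("n_boot < 100 gives an unstable bootstrap SE")
  }
  wr <- wald_ratio(iv$beta_exposure, iv$se_exposure,
                   iv$beta_outcome, iv$se_outcome)
  w <- 1 / wr$se^2
  est <- .weighted_median(wr$theta, w)
  boot <- .with_seed(seed, {
    draws <- matrix(stats::rnorm(n_boot * J, mean = rep(wr$theta, each = n_boot),
                                 sd = rep(wr$se, each = n_boot)),
                    nrow = n_boot)
    apply(draws, 1, .weighted_median, w = w)
  })
  se <- stats::sd(boot)
  mr_result("weighted-median", est, se, J,
            extras = list(n_boot = n_boot, seed = seed))
}

# profile log-likelihood in theta (gamma_j profiled out analytically)
.ml_profile_loglik <- function(theta, bx, by, sx2, sy2) {
  -0.5 * sum((by - theta * bx)^2 / (sy2 + theta^2 * sx2))
}

#' Maximum-likelihood MR estimate
#'
#' Jointly models the observed exposure and outcome betas as
#' `beta_x_j ~ N(gamma_j, se_x_j^2)`, `beta_y_j ~ N(theta gamma_j, se_y_j^2)`
#' and maximizes the likelihood over `(theta, gamma_1..gamma_J)`. The
#' per-SNP nuisance strengths are profiled out analytically, leaving a
#' one-dimensional profile likelihood in `theta` which is maximized
#' numerically from the IVW starting value (objective tolerance 1e-10).
#' The SE comes from the observed information (numerical curvature of the
#' profile log-likelihood at the maximum).
#'
#' @param iv Harmonized instrument set (>= 2 SNPs).
#' @return An [mr_result()] with extra `loglik`.
#' @export
mr_max_likelihood <- function(iv) {
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 2) stop("maximum likelihood requires at least 2 instruments, got ", J)
  bx <- iv$beta_exposure; by <- iv$beta_outcome
  sx2 <- iv$se_exposure^2; sy2 <- iv$se_outcome^2
  start <- mr_ivw(iv, model = "fixed")$beta
  width <- max(1, 20 * abs(start), 20 * mr_ivw(iv, model = "fixed")$se)
  obj <- function(th) -.ml_profile_loglik(th, bx, by, sx2, sy2)
  for (attempt in 1:8) {
    opt <- stats::optimize(obj, interval = c(start - width, start + width),
                           tol = 1e-10)
    interior <- opt$minimum > start - width + 1e-6 * width &&
      opt$minimum < start + width - 1e-6 * width
    if (interior) break
    width <- width * 4
  }
  if (!interior) {
    stop("maximum-likelihood estimate did not converge inside the expanded ",
         "bracket [", start - width, ", ", start + width, "]")
  }
  theta <- opt$minimum
  # observed information from the analytic profile score, differentiated
  # numerically at a step scaled to the estimate's sampling uncertainty
  grad <- function(th) {
    r <- by - th * bx
    v <- sy2 + th^2 * sx2
    sum(r * bx / v + r^2 * th * sx2 / v^2)
  }
  se_scale <- mr_ivw(iv, model = "fixed")$se
  info <- NA_real_
  h <- max(1e-6, 0.05 * se_scale, 1e-4 * abs(theta))
  for (attempt in 1:6) {
    info <- -(grad(theta + h) - grad(theta - h)) / (2 * h)
    if (is.finite(info) && info > 0) break
    h <- h * 10
  }
  if (!is.finite(info) || info <= 0) {
    stop("observed information not positive at the maximum-likelihood estimate")
  }
  se <- 1 / sqrt(info)
  mr_result("maximum-likelihood", theta, se, J,
            extras = list(loglik = -opt$objective))
}

# E[psi(Z) Z] for standard normal Z, used in the overdispersion moment
# equation: 1 for squared loss, a closed form for Huber.
.psi_delta <- function(loss, k) {
  if (loss == "squared") return(1)
  # E[psi(Z) Z] = E[Z^2 1{|Z|<k}] + k E[|Z| 1{|Z|>=k}]
  p_in <- stats::pnorm(k) - stats::pnorm(-k)
  e_in <- p_in - 2 * k * stats::dnorm(k)   # E[Z^2 1{|Z|<k}]
  e_out <- 2 * k * stats::dnorm(k)         # k E[|Z| 1{|Z|>=k}]
  e_in + e_out
}

#' Robust adjusted profile score (RAPS) MR estimate
#'
#' Solves the adjusted profile estimating equation
#' `sum_j psi(t_j) * d t_j / d theta = 0` where
#' `t_j = (beta_y_j - theta beta_x_j) / sqrt(se_y_j^2 + theta^2 se_x_j^2 + tau^2)`
#' and `psi` is the identity (squared loss) or the Huber score with
#' constant 1.345. With `overdispersion = TRUE` the pleiotropy variance
#' `tau^2` is solved jointly from its moment equation (mean standardized
#' residual energy equal to its standard-normal expectation), floored at 0.
#' The SE is the sandwich estimate; the root is bracketed around the IVW
#' estimate with geometric expansion.
#'
#' With `tau^2 = 0` and squared loss the estimating equation is exactly the
#' profile-likelihood score, so the estimate coincides with
#' [mr_max_likelihood()].
#'
#' @param iv Harmonized instrument set (>= 3 SNPs).
#' @param loss `"squared"` (default) or `"huber"`.
#' @param overdispersion Estimate `tau^2` jointly (default `FALSE`).
#' @param k_huber Huber constant (default 1.345).
#' @return An [mr_result()] with extra `tau2`.
#' @export
mr_raps <- function(iv, loss = c("squared", "huber"), overdispersion = FALSE,
                    k_huber = 1.345) {
  loss <- match.arg(loss)
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 3) stop("RAPS requires at least 3 instruments, got ", J)
  bx <- iv$beta_exposure; by <- iv$beta_outcome
  sx2 <- iv$se_exposure^2; sy2 <- iv$se_outcome^2
  psi <- if (loss == "squared") {
    function(t) t
  } else {
    function(t) pmax(pmin(t, k_huber), -k_huber)
  }
  delta <- .psi_delta(loss, k_huber)

  t_of <- function(theta, tau2) {
    (by - theta * bx) / sqrt(sy2 + theta^2 * sx2 + tau2)
  }
  # score in theta: sum psi(t_j) * (-d t_j / d theta)
  score <- function(theta, tau2) {
    v <- sy2 + theta^2 * sx2 + tau2
    t <- (by - theta * bx) / sqrt(v)
    sum(psi(t) * (bx / sqrt(v) + t * theta * sx2 / v))
  }
  solve_theta <- function(tau2, start, start_se) {
    lo <- start - 3 * start_se; hi <- start + 3 * start_se
    for (attempt in 1:60) {
      flo <- score(lo, tau2); fhi <- score(hi, tau2)
      if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
        return(stats::uniroot(score, c(lo, hi), tau2 = tau2,
                              tol = 1e-12)$root)
      }
      mid <- (lo + hi) / 2; half <- (hi - lo)
      lo <- mid - half; hi <- mid + half
    }
    stop("RAPS estimating equation has no root in the expanded bracket ",
         "around the IVW estimate (", format(start), ")")
  }
  solve_tau2 <- function(theta) {
    g <- function(tau2) sum(psi(t_of(theta, tau2)) * t_of(theta, tau2) - delta)
    if (g(0) <= 0) return(0)
    hi <- stats::var(by - theta * bx) + max(sy2)
    for (attempt in 1:60) {
      if (g(hi) <= 0) break
      hi <- hi * 4
    }
    stats::uniroot(g, c(0, hi), tol = 1e-14)$root
  }

  ivw <- mr_ivw(iv, model = "fixed")
  theta <- ivw$beta; tau2 <- 0
  if (overdispersion) {
    for (iter in 1:100) {
      theta_new <- solve_theta(tau2, ivw$beta, ivw$se)
      tau2_new <- solve_tau2(theta_new)
      done <- abs(theta_new - theta) < 1e-10 && abs(tau2_new - tau2) < 1e-12
      theta <- theta_new; tau2 <- tau2_new
      if (done) break
    }
  } else {
    theta <- solve_theta(0, ivw$beta, ivw$se)
  }

  # sandwich SE: A = d score / d theta, B = sum of squared score terms
  v <- sy2 + theta^2 * sx2 + tau2
  t <- (by - theta * bx) / sqrt(v)
  terms <- psi(t) * (bx / sqrt(v) + t * theta * sx2 / v)
  h <- max(1e-7, abs(theta) * 1e-6)
  A <- (score(theta + h, tau2) - score(theta - h, tau2)) / (2 * h)
  B <- sum(terms^2)
  se <- sqrt(B) / abs(A)
  mr_result("RAPS", theta, se, J,
            extras = list(tau2 = tau2, loss = loss,
                          overdispersion = overdispersion))
}

#' Run all univariable MR estimators on one instrument set
#'
#' Convenience wrapper returning IVW, MR-Egger, weighted-median,
#' maximum-likelihood and RAPS results as a single table.
#'
#' @param iv Harmonized instrument set.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Seed for the bootstrap.
#' @param ivw_model IVW model passed to [mr_ivw()].
#' @return data.frame with one row per method.
#' @export
mr_all_methods <- function(iv, n_boot = 1000, seed, ivw_model = "random") {
  res <- list(
    mr_ivw(iv, model = ivw_model),
    mr_egger(iv),
    mr_weighted_median(iv, n_boot = n_boot, seed = seed),
    mr_max_likelihood(iv),
    mr_raps(iv, overdispersion = TRUE)
  )
  tab <- do.call(rbind, lapply(res, as.data.frame))
  tab$egger_intercept <- NA_real_
  tab$egger_intercept[tab$method == "MR-Egger"] <- res[[2]]$extras$egger_intercept
  tab$egger_intercept_pval <- NA_real_
  tab$egger_intercept_pval[tab$method == "MR-Egger"] <-
    res[[2]]$extras$egger_intercept_pval
  tab
}
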