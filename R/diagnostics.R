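# Heterogeneity, pleiotropy, influence and outlier diagnostics.

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_j w_j (theta_j - theta_IVW)^2` over the per-SNP Wald ratios
#' with first-order inverse-variance weights, referred to a chi-square on
#' J - 1 degrees of freedom. Also reports `I^2 = max(0, (Q - df)/Q)`.
#'
#' @param iv Harmonized instrument set (>= 2 SNPs).
#' @return A list of class `"heterogeneity_report"` with `Q`, `df`, `pval`,
#'   `i_squared`.
#' @export
cochran_q <- function(iv) {
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 2) stop("Cochran's Q requires at least 2 instruments, got ", J)
  wr <- wald_ratio(iv$beta_exposure, iv$se_exposure,
                   iv$beta_outcome, iv$se_outcome)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$theta) / sum(w)
  Q <- sum(w * (wr$theta - beta)^2)
  df <- J - 1
  structure(list(
    method = "IVW", Q = Q, df = df,
    pval = stats::pchisq(Q, df, lower.tail = FALSE),
    i_squared = max(0, (Q - df) / Q)
  ), class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g, I^2 = %.1f%%\n",
              x$Q, x$df, x$pval, 100 * x$i_squared))
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("Egger intercept = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_ci_low,
                x$egger_intercept_ci_high, x$egger_intercept_pval))
  }
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Extracts the intercept of the MR-Egger fit: its estimate, SE, 95% CI
#' and t-based p-value on J - 2 df. A nonzero intercept indicates average
#' directional pleiotropy; significance is conventionally declared at
#' p < 0.05.
#'
#' @param iv Harmonized instrument set (>= 3 SNPs).
#' @return A `"heterogeneity_report"` list with the intercept fields and a
#'   `significant` flag.
#' @export
egger_intercept_test <- function(iv) {
  fit <- mr_egger(iv)
  e <- fit$extras
  structure(list(
    method = "MR-Egger",
    egger_intercept = e$egger_intercept,
    egger_intercept_se = e$egger_intercept_se,
    egger_intercept_ci_low = e$egger_intercept_ci_low,
    egger_intercept_ci_high = e$egger_intercept_ci_high,
    egger_intercept_pval = e$egger_intercept_pval,
    significant = e$egger_intercept_pval < 0.05,
    df = fit$n_snps - 2
  ), class = "heterogeneity_report")
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Recomputes the IVW estimate J times, omitting each instrument in turn,
#' plus the all-SNP row. Flags instruments whose removal moves the
#' estimate across zero or the p-value across 0.05.
#'
#' @param iv Harmonized instrument set (>= 3 SNPs).
#' @param model IVW model.
#' @return data.frame with J + 1 rows (`snp = "All"` last) and columns
#'   `snp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `crosses_null`,
#'   `p_crosses_0.05`.
#' @export
leave_one_out <- function(iv, model = "random") {
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 3) stop("leave-one-out requires at least 3 instruments, got ", J)
  all_fit <- mr_ivw(iv, model = model)
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(iv[-j, , drop = FALSE], model = model)
    data.frame(snp = iv$snp[j], beta = fit$beta, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high, pval = fit$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$crosses_null <- sign(out$beta) != sign(all_fit$beta)
  out$p_crosses_0.05 <- (out$pval < 0.05) != (all_fit$pval < 0.05)
  out <- rbind(out, data.frame(snp = "All", beta = all_fit$beta,
                               se = all_fit$se, ci_low = all_fit$ci_low,
                               ci_high = all_fit$ci_high, pval = all_fit$pval,
                               crosses_null = FALSE, p_crosses_0.05 = FALSE,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# leave-one-out IVW slopes from sufficient statistics, O(J)
.loo_slopes <- function(bx, by, sy2) {
  wv <- bx^2 / sy2
  th <- by / bx
  num <- sum(wv * th); den <- sum(wv)
  (num - wv * th) / (den - wv)
}

#' MR-PRESSO global test, outlier detection and corrected estimate
#'
#' Tests whether residual heterogeneity exceeds what the per-SNP sampling
#' errors predict, flags the responsible instruments, and re-estimates the
#' causal effect without them. The observed global residual sum of squares
#' is `RSS = sum_j (beta_y_j - theta_(-j) beta_x_j)^2 / se_y_j^2` using
#' leave-one-out IVW slopes `theta_(-j)` (so an outlier cannot mask
#' itself). Its null distribution is simulated parametrically: in each of
#' `n_sim` replicates, `beta_x_j* ~ N(beta_x_j, se_x_j^2)` and
#' `beta_y_j* ~ N(theta_(-j) beta_x_j, se_y_j^2)`, and the RSS is recomputed
#' with the replicate's own leave-one-out slopes. The global p-value is the
#' fraction of simulated RSS at or above the observed one; per-SNP p-values
#' compare each observed term with its simulated counterparts and are
#' Bonferroni-adjusted. Outliers are SNPs with adjusted p below
#' `outlier_alpha`; the corrected estimate is IVW on the non-flagged set.
#' When outliers are found, a distortion test compares the raw-minus-
#' corrected slope change against the distribution obtained by removing
#' equally many randomly chosen non-outlier SNPs.
#'
#' @param iv Harmonized instrument set (>= 4 SNPs).
#' @param n_sim Number of parametric simulations (>= 1000; default 5000).
#' @param outlier_alpha Family-level significance threshold for outlier
#'   flagging (applied after Bonferroni adjustment); default 0.05.
#' @param seed Integer seed (mandatory; the report is a pure function of
#'   its inputs).
#' @param model IVW model for the raw and corrected estimates.
#' @return A list of class `"presso_report"`: `global_rss_observed`,
#'   `global_pval`, `global_pval_label` (`"<1/n_sim"` when no simulated RSS
#'   reached the observed one), `outlier_pvals` (named, adjusted),
#'   `outlier_ids`, `raw_estimate`, `corrected_estimate`,
#'   `distortion_pval`, `n_sim`, `seed`.
#' @export
mr_presso <- function(iv, n_sim = 5000, outlier_alpha = 0.05, seed,
                      model = "random") {
  iv <- .iv_columns(iv)
  J <- nrow(iv)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments, got ", J)
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  if (missing(seed)) stop("seed is required")
  bx <- iv$beta_exposure; by <- iv$beta_outcome
  sx <- iv$se_exposure; sy <- iv$se_outcome
  sy2 <- sy^2

  loo <- .loo_slopes(bx, by, sy2)
  terms_obs <- (by - loo * bx)^2 / sy2
  rss_obs <- sum(terms_obs)

  sim <- .with_seed(seed, {
    BX <- matrix(stats::rnorm(n_sim * J, mean = rep(bx, each = n_sim),
                              sd = rep(sx, each = n_sim)), nrow = n_sim)
    BY <- matrix(stats::rnorm(n_sim * J, mean = rep(loo * bx, each = n_sim),
                              sd = rep(sy, each = n_sim)), nrow = n_sim)
    SY2 <- matrix(sy2, n_sim, J, byrow = TRUE)
    WV <- BX^2 / SY2
    TH <- BY / BX
    num <- rowSums(WV * TH); den <- rowSums(WV)
    LOO <- (num - WV * TH) / (den - WV)
    TERMS <- (BY - LOO * BX)^2 / SY2
    list(terms = TERMS, rss = rowSums(TERMS))
  })

  n_ge <- sum(sim$rss >= rss_obs)
  global_pval <- if (n_ge == 0) 1 / n_sim else n_ge / n_sim
  global_label <- if (n_ge == 0) paste0("<", format(1 / n_sim)) else
    format(global_pval)

  # raw simulation fractions decide flagging (a zero count is evidence at
  # resolution 1/n_sim, not a p of exactly 1/n_sim); reported values are
  # floored so no p-value prints as 0
  p_snp_raw <- colMeans(sweep(sim$terms, 2, terms_obs, ">="))
  outliers <- iv$snp[pmin(1, p_snp_raw * J) < outlier_alpha]
  p_adj <- pmin(1, pmax(p_snp_raw, 1 / n_sim) * J)
  names(p_adj) <- iv$snp

  raw <- mr_ivw(iv, model = model)
  keep <- !(iv$snp %in% outliers)
  corrected <- if (sum(keep) >= 2) mr_ivw(iv[keep, , drop = FALSE],
                                          model = model) else NULL

  distortion_pval <- NA_real_
  if (length(outliers) > 0 && !is.null(corrected) &&
      sum(keep) > length(outliers)) {
    d_obs <- raw$beta - corrected$beta
    nonout <- which(keep)
    d_null <- .with_seed(seed + 1L, {
      vapply(seq_len(min(n_sim, 2000L)), function(i) {
        drop_idx <- sample(nonout, length(outliers))
        sub <- mr_ivw(iv[-drop_idx, , drop = FALSE], model = model)
        raw$beta - sub$beta
      }, numeric(1))
    })
    distortion_pval <- mean(abs(d_null) >= abs(d_obs))
    if (distortion_pval == 0) distortion_pval <- 1 / length(d_null)
  }

  structure(list(
    global_rss_observed = rss_obs,
    global_pval = global_pval,
    global_pval_label = global_label,
    outlier_pvals = p_adj,
    outlier_ids = outliers,
    raw_estimate = raw,
    corrected_estimate = corrected,
    distortion_pval = distortion_pval,
    n_sim = n_sim, outlier_alpha = outlier_alpha, seed = seed
  ), class = "presso_report")
}

#' @export
print.presso_report <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.3f, global p = %s (%d sims)\n",
              x$global_rss_observed, x$global_pval_label, x$n_sim))
  cat("Outliers:", if (length(x$outlier_ids) == 0) "none" else
    paste(x$outlier_ids, collapse = ", "), "\n")
  cat("Raw:      "); print(x$raw_estimate)
  if (!is.null(x$corrected_estimate)) {
    cat("Corrected:"); print(x$corrected_estimate)
  }
  if (!is.na(x$distortion_pval)) {
    cat(sprintf("Distortion test p = %.3g\n", x$distortion_pval))
  }
  invisible(x)
}

#' Coordinate tables for scatter, forest and funnel plots
#'
#' Produces tidy coordinate tables for the three standard MR diagnostic
#' displays, consumable by any plotting layer: the scatter of outcome vs
#' exposure betas with one fitted line per method (IVW and ratio-based
#' lines pass through the origin; MR-Egger carries its intercept), the
#' per-SNP Wald-ratio forest with one summary row per method, and the
#' funnel of ratio estimates against their precisions with one vertical
#' reference line per method.
#'
#' @param iv Harmonized instrument set.
#' @param results data.frame of method results (as from
#'   [mr_all_methods()]), or a single [mr_result()].
#' @return A list with data.frames `scatter`, `scatter_lines`, `forest`,
#'   `funnel`, `funnel_lines`.
#' @export
plot_data <- function(iv, results) {
  iv <- .iv_columns(iv)
  if (inherits(results, "mr_result")) results <- as.data.frame(results)
  stopifnot(is.data.frame(results), nrow(results) > 0)
  wr <- wald_ratio(iv$beta_exposure, iv$se_exposure,
                   iv$beta_outcome, iv$se_outcome)
  scatter <- data.frame(
    snp = iv$snp, beta_exposure = iv$beta_exposure,
    se_exposure = iv$se_exposure, beta_outcome = iv$beta_outcome,
    se_outcome = iv$se_outcome, stringsAsFactors = FALSE
  )
  intercepts <- vapply(seq_len(nrow(results)), function(i) {
    if (results$method[i] == "MR-Egger" &&
        "egger_intercept" %in% names(results) &&
        !is.na(results$egger_intercept[i]))
      results$egger_intercept[i] else 0
  }, numeric(1))
  scatter_lines <- data.frame(method = results$method,
                              slope = results$beta,
                              intercept = intercepts,
                              stringsAsFactors = FALSE)
  forest <- rbind(
    data.frame(label = iv$snp, type = "snp", beta = wr$theta,
               ci_low = wr$theta - .qnorm975 * wr$se,
               ci_high = wr$theta + .qnorm975 * wr$se,
               stringsAsFactors = FALSE),
    data.frame(label = results$method, type = "summary", beta = results$beta,
               ci_low = results$ci_low, ci_high = results$ci_high,
               stringsAsFactors = FALSE)
  )
  funnel <- data.frame(snp = iv$snp, theta = wr$theta,
                       precision = 1 / wr$se, stringsAsFactors = FALSE)
  funnel_lines <- data.frame(method = results$method, theta = results$beta,
                             stringsAsFactors = FALSE)
  list(scatter = scatter, scatter_lines = scatter_lines, forest = forest,
       funnel = funnel, funnel_lines = funnel_lines)
}
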