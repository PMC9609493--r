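# Multivariable MR (direct effects) and the two-step mediation
# decomposition: exposure -> mediator(s) -> binary outcome.

#' Assemble a harmonized multivariable MR dataset
#'
#' Selects instruments for each exposure trait from its own summary
#' statistics, takes the union of the selected variants, requires every
#' union variant to be present in all exposure datasets and in the outcome
#' (missing variants are dropped and counted), and aligns every trait's
#' effect to a single reference orientation (the first exposure's alleles)
#' using the same allele logic as [harmonize()].
#'
#' @param exposures Named list of summary-statistics data.frames (order
#'   matters: the first is the reference orientation).
#' @param outcome Outcome summary statistics.
#' @param p_threshold,maf_min,exclude,ld,positions,window_kb,r2_limit
#'   Instrument-selection settings applied per trait, see
#'   [select_instruments()].
#' @param palindrome_eaf_band,drop_palindromic_ambiguous Harmonization
#'   settings, see [harmonize()].
#' @return A list of class `"mvmr_set"`: `snp` (IDs), `beta_exposure` and
#'   `se_exposure` (J x K matrices, one column per exposure),
#'   `beta_outcome`, `se_outcome`, `counts` (dropped-variant ledger),
#'   `instruments` (per-trait selected IDs).
#' @export
mvmr_harmonize <- function(exposures, outcome, p_threshold = 5e-8,
                           maf_min = 0.01, exclude = character(0),
                           ld = NULL, positions = NULL, window_kb = 10000,
                           r2_limit = 0.001,
                           palindrome_eaf_band = c(0.42, 0.58),
                           drop_palindromic_ambiguous = TRUE) {
  stopifnot(is.list(exposures), length(exposures) >= 1,
            !is.null(names(exposures)), all(nzchar(names(exposures))))
  sel <- lapply(exposures, select_instruments, p_threshold = p_threshold,
                maf_min = maf_min, exclude = exclude, ld = ld,
                positions = positions, window_kb = window_kb,
                r2_limit = r2_limit)
  union_ids <- sort(unique(unlist(lapply(sel, `[[`, "snp"))))

  counts <- c(union = length(union_ids))
  ref <- exposures[[1]]
  present <- union_ids %in% ref$snp
  for (e in exposures[-1]) present <- present & union_ids %in% e$snp
  present <- present & union_ids %in% outcome$snp
  counts["missing_in_some_trait"] <- sum(!present)
  ids <- union_ids[present]

  ref_rows <- ref[match(ids, ref$snp), , drop = FALSE]
  K <- length(exposures)
  J <- length(ids)
  BX <- matrix(NA_real_, J, K, dimnames = list(ids, names(exposures)))
  SX <- BX
  dropped <- logical(J)

  align_trait <- function(trait) {
    rows <- trait[match(ids, trait$snp), , drop = FALSE]
    beta <- rep(NA_real_, J)
    for (i in seq_len(J)) {
      al <- .align_alleles(ref_rows$effect_allele[i], ref_rows$other_allele[i],
                           rows$effect_allele[i], rows$other_allele[i],
                           ref_rows$eaf[i], rows$eaf[i],
                           band = palindrome_eaf_band,
                           drop_ambiguous = drop_palindromic_ambiguous)
      if (al$status != "ok") { dropped[i] <<- TRUE; next }
      beta[i] <- if (al$flip) -rows$beta[i] else rows$beta[i]
    }
    list(beta = beta, se = rows$se)
  }

  for (k in seq_len(K)) {
    a <- align_trait(exposures[[k]])
    BX[, k] <- a$beta; SX[, k] <- a$se
  }
  ao <- align_trait(outcome)
  by <- ao$beta; sy <- ao$se

  counts["unalignable"] <- sum(dropped)
  keep <- !dropped
  structure(list(
    snp = ids[keep],
    beta_exposure = BX[keep, , drop = FALSE],
    se_exposure = SX[keep, , drop = FALSE],
    beta_outcome = by[keep], se_outcome = sy[keep],
    counts = counts,
    instruments = lapply(sel, `[[`, "snp")
  ), class = "mvmr_set")
}

#' Multivariable IVW regression for direct effects
#'
#' Weighted least squares of the outcome betas on the matrix of exposure
#' betas with no intercept and weights `se_outcome^-2`. Each coefficient is
#' the direct effect of that exposure on the outcome holding the other
#' exposures fixed. Coefficient SEs use multiplicative overdispersion
#' scaling floored at 1 (as in univariable IVW) with a normal reference.
#' A conditional instrument-strength diagnostic is reported per exposure:
#' the weighted residual of that exposure's betas regressed on the others,
#' standardized by its SEs and averaged over variants (an F-like
#' statistic; values well above 10 indicate conditionally strong
#' instruments).
#'
#' @param mvset An `"mvmr_set"` from [mvmr_harmonize()], or a list with
#'   elements `beta_exposure` (J x K matrix with column names),
#'   `se_exposure`, `beta_outcome`, `se_outcome`, optional `snp`.
#' @return A list of class `"mvmr_result"` with a per-exposure data.frame
#'   `estimates` (`exposure`, `beta`, `se`, `ci_low`, `ci_high`, `pval`,
#'   `or`, `or_ci_low`, `or_ci_high`, `conditional_F`), `n_snps`, `Q`.
#' @export
mvmr_ivw <- function(mvset) {
  BX <- as.matrix(mvset$beta_exposure)
  SX <- as.matrix(mvset$se_exposure)
  by <- mvset$beta_outcome
  sy <- mvset$se_outcome
  K <- ncol(BX)
  if (is.null(colnames(BX))) colnames(BX) <- paste0("X", seq_len(K))
  ok <- stats::complete.cases(BX) & !is.na(by) & !is.na(sy)
  BX <- BX[ok, , drop = FALSE]; SX <- SX[ok, , drop = FALSE]
  by <- by[ok]; sy <- sy[ok]
  J <- nrow(BX)
  if (J < K + 1) {
    stop("multivariable IVW needs more instruments (", J,
         ") than exposures + 1 (", K + 1, ")")
  }
  w <- 1 / sy^2
  Xw <- BX * sqrt(w)
  qr_x <- qr(Xw)
  if (qr_x$rank < K) {
    cm <- suppressWarnings(stats::cor(BX))
    diag(cm) <- 0
    cm[!is.finite(cm)] <- 1  # a constant (e.g. all-zero) column is degenerate
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    stop("exposure-beta matrix is rank deficient; collinear pair: ",
         colnames(BX)[worst[1]], " and ", colnames(BX)[worst[2]])
  }
  fit <- stats::lm.wfit(x = BX, y = by, w = w)
  coef <- fit$coefficients
  XtWX_inv <- chol2inv(qr.R(qr_x))
  rss <- sum(w * fit$residuals^2)
  sigma2 <- rss / (J - K)
  infl <- max(1, sqrt(sigma2))
  se <- sqrt(diag(XtWX_inv)) * infl

  cond_F <- vapply(seq_len(K), function(k) {
    if (K == 1) {
      r <- BX[, 1]
    } else {
      f <- stats::lm.wfit(x = BX[, -k, drop = FALSE], y = BX[, k], w = w)
      r <- f$residuals
    }
    mean(r^2 / SX[, k]^2)
  }, numeric(1))

  z <- coef / se
  crit <- .qnorm975
  est <- data.frame(
    exposure = colnames(BX), beta = unname(coef), se = unname(se),
    ci_low = unname(coef - crit * se), ci_high = unname(coef + crit * se),
    pval = unname(.p_from_z(z)),
    or = unname(exp(coef)), or_ci_low = unname(exp(coef - crit * se)),
    or_ci_high = unname(exp(coef + crit * se)),
    conditional_F = cond_F, stringsAsFactors = FALSE
  )
  structure(list(estimates = est, n_snps = J, Q = rss, Q_df = J - K,
                 Q_pval = stats::pchisq(rss, J - K, lower.tail = FALSE)),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat("Multivariable IVW on", x$n_snps, "instruments\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

.mediation_row <- function(label, beta1, se1, beta2, se2, beta3, se3,
                           total, se_total, method) {
  indirect <- beta1 * beta2
  se_ind <- sqrt(beta1^2 * se2^2 + beta2^2 * se1^2)
  if (method == "product") {
    denom <- beta3 + indirect
    e_pct <- 100 * indirect / denom
    e_lo <- 100 * (indirect - .qnorm975 * se_ind) / denom
    e_hi <- 100 * (indirect + .qnorm975 * se_ind) / denom
    inconsistent <- sign(indirect) != sign(denom)
  } else {
    indirect <- total - beta3
    se_ind <- sqrt(se_total^2 + se3^2)  # ignores cov(total, direct)
    e_pct <- 100 * indirect / total
    e_lo <- 100 * (indirect - .qnorm975 * se_ind) / total
    e_hi <- 100 * (indirect + .qnorm975 * se_ind) / total
    inconsistent <- sign(indirect) != sign(total)
  }
  data.frame(mediator = label, method = method,
             beta1 = beta1, se_beta1 = se1,
             beta2 = beta2, se_beta2 = se2,
             beta3 = beta3, se_beta3 = se3,
             total = total, se_total = se_total,
             indirect = indirect, se_indirect = se_ind,
             indirect_ci_low = indirect - .qnorm975 * se_ind,
             indirect_ci_high = indirect + .qnorm975 * se_ind,
             proportion_mediated = e_pct,
             proportion_ci_low = min(e_lo, e_hi),
             proportion_ci_high = max(e_lo, e_hi),
             inconsistent = inconsistent,
             stringsAsFactors = FALSE)
}

#' Two-step MR mediation decomposition
#'
#' Decomposes the total exposure-outcome effect into direct and
#' mediator-carried components. Step 1 estimates `beta1_k`, the effect of
#' the exposure on mediator k, by univariable IVW using the exposure's
#' instruments. Step 2 estimates `beta2_k`, the effect of mediator k on
#' the outcome adjusted for the exposure, as the mediator coefficient of
#' the multivariable IVW fit of exposure + mediator k on the outcome; the
#' exposure coefficient of the same fit is that row's direct effect
#' `beta3`. With several mediators a joint row is added whose `beta2`
#' coefficients and `beta3` come from the all-mediator multivariable fit.
#' The total effect is univariable IVW of exposure on outcome.
#'
#' The mediated (indirect) effect is `beta1 x beta2` with delta-method SE
#' `sqrt(beta1^2 se(beta2)^2 + beta2^2 se(beta1)^2)` (product method), or
#' `total - beta3` (difference method). The proportion mediated is
#' `100 * sum_k beta1 beta2_k / (beta3 + sum_k beta1 beta2_k)` for the
#' product method and `100 * (total - beta3) / total` for the difference
#' method; its CI propagates the indirect-effect CI against the fixed
#' denominator and is approximate. When the indirect and total effects
#' have opposite signs the row is flagged `inconsistent` rather than
#' reported as a bare negative percentage.
#'
#' @param exposure Exposure summary statistics.
#' @param mediators Named list of mediator summary statistics.
#' @param outcome Outcome summary statistics.
#' @param method `"product"` (default), `"difference"`, or `"both"`.
#' @param ivw_model IVW model for the univariable fits.
#' @param p_threshold,maf_min,exclude Instrument-selection settings.
#' @param palindrome_eaf_band,drop_palindromic_ambiguous Harmonization
#'   settings.
#' @return A list of class `"mediation_decomposition"` with `table` (one
#'   row per mediator per method, plus joint rows when there are several
#'   mediators), `total` (the univariable total-effect [mr_result()]), and
#'   `mvmr_joint` (the all-mediator [mvmr_ivw()] fit).
#' @export
two_step_mediation <- function(exposure, mediators, outcome,
                               method = c("product", "difference", "both"),
                               ivw_model = "random",
                               p_threshold = 5e-8, maf_min = 0.01,
                               exclude = character(0),
                               palindrome_eaf_band = c(0.42, 0.58),
                               drop_palindromic_ambiguous = TRUE) {
  method <- match.arg(method)
  methods <- if (method == "both") c("product", "difference") else method
  stopifnot(is.list(mediators), length(mediators) >= 1,
            !is.null(names(mediators)), all(nzchar(names(mediators))))
  K <- length(mediators)

  sel_exp <- select_instruments(exposure, p_threshold = p_threshold,
                                maf_min = maf_min, exclude = exclude)

  # total effect: exposure -> outcome
  iv_xy <- harmonize(sel_exp, outcome,
                     palindrome_eaf_band = palindrome_eaf_band,
                     drop_palindromic_ambiguous = drop_palindromic_ambiguous)
  total_fit <- mr_ivw(iv_xy, model = ivw_model)

  # step 1: exposure -> mediator k with the exposure's instruments
  step1 <- lapply(mediators, function(med) {
    iv <- harmonize(sel_exp, med,
                    palindrome_eaf_band = palindrome_eaf_band,
                    drop_palindromic_ambiguous = drop_palindromic_ambiguous)
    mr_ivw(iv, model = ivw_model)
  })

  # step 2: pairwise MVMR exposure + mediator k -> outcome
  pairwise <- lapply(names(mediators), function(nm) {
    mvset <- mvmr_harmonize(
      stats::setNames(list(exposure, mediators[[nm]]), c(".exposure", nm)),
      outcome, p_threshold = p_threshold, maf_min = maf_min,
      exclude = exclude, palindrome_eaf_band = palindrome_eaf_band,
      drop_palindromic_ambiguous = drop_palindromic_ambiguous)
    mvmr_ivw(mvset)
  })
  names(pairwise) <- names(mediators)

  rows <- list()
  for (m in methods) {
    for (nm in names(mediators)) {
      est <- pairwise[[nm]]$estimates
      b2 <- est[est$exposure == nm, ]
      b3 <- est[est$exposure == ".exposure", ]
      rows[[length(rows) + 1L]] <- cbind(
        .mediation_row(nm, step1[[nm]]$beta, step1[[nm]]$se,
                       b2$beta, b2$se, b3$beta, b3$se,
                       total_fit$beta, total_fit$se, m),
        n_snps = pairwise[[nm]]$n_snps)
    }
  }

  mvmr_joint <- NULL
  if (K > 1) {
    mvset <- mvmr_harmonize(
      c(stats::setNames(list(exposure), ".exposure"), mediators), outcome,
      p_threshold = p_threshold, maf_min = maf_min, exclude = exclude,
      palindrome_eaf_band = palindrome_eaf_band,
      drop_palindromic_ambiguous = drop_palindromic_ambiguous)
    mvmr_joint <- mvmr_ivw(mvset)
    est <- mvmr_joint$estimates
    b3 <- est[est$exposure == ".exposure", ]
    ind_sum <- 0; var_sum <- 0
    for (nm in names(mediators)) {
      b2 <- est[est$exposure == nm, ]
      b1 <- step1[[nm]]
      ind_sum <- ind_sum + b1$beta * b2$beta
      var_sum <- var_sum + b1$beta^2 * b2$se^2 + b2$beta^2 * b1$se^2
    }
    se_ind <- sqrt(var_sum)
    joint_label <- paste(names(mediators), collapse = "+")
    for (m in methods) {
      if (m == "product") {
        denom <- b3$beta + ind_sum
        e_pct <- 100 * ind_sum / denom
        e_lo <- 100 * (ind_sum - .qnorm975 * se_ind) / denom
        e_hi <- 100 * (ind_sum + .qnorm975 * se_ind) / denom
        ind <- ind_sum; se_i <- se_ind
        inconsistent <- sign(ind_sum) != sign(denom)
      } else {
        ind <- total_fit$beta - b3$beta
        se_i <- sqrt(total_fit$se^2 + b3$se^2)
        e_pct <- 100 * ind / total_fit$beta
        e_lo <- 100 * (ind - .qnorm975 * se_i) / total_fit$beta
        e_hi <- 100 * (ind + .qnorm975 * se_i) / total_fit$beta
        inconsistent <- sign(ind) != sign(total_fit$beta)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mediator = joint_label, method = m,
        beta1 = NA_real_, se_beta1 = NA_real_,
        beta2 = NA_real_, se_beta2 = NA_real_,
        beta3 = b3$beta, se_beta3 = b3$se,
        total = total_fit$beta, se_total = total_fit$se,
        indirect = ind, se_indirect = se_i,
        indirect_ci_low = ind - .qnorm975 * se_i,
        indirect_ci_high = ind + .qnorm975 * se_i,
        proportion_mediated = e_pct,
        proportion_ci_low = min(e_lo, e_hi),
        proportion_ci_high = max(e_lo, e_hi),
        inconsistent = inconsistent,
        n_snps = mvmr_joint$n_snps,
        stringsAsFactors = FALSE)
    }
  }

  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, total = total_fit, step1 = step1,
                 pairwise = pairwise, mvmr_joint = mvmr_joint),
            class = "mediation_decomposition")
}

#' @export
print.mediation_decomposition <- function(x, ...) {
  cat("Two-step MR mediation decomposition\n")
  cat(sprintf("Total effect: beta = %.4f (SE %.4f), OR = %.3f\n",
              x$total$beta, x$total$se, x$total$or))
  cols <- c("mediator", "method", "indirect", "beta3",
            "proportion_mediated", "inconsistent", "n_snps")
  print(x$table[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}
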