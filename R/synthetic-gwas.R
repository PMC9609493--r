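# Synthetic two-sample GWAS summary statistics under a known structural
# model: exposure X -> mediators M_k -> binary outcome Y (log-odds scale),
# plus a direct X -> Y path and optional per-SNP horizontal pleiotropy.
#
# Effects are generated directly on the summary scale. Per trait t with
# sample size n_t, the standard error of an observed per-allele effect at
# minor allele frequency f is se = (2 f (1 - f) n_t)^(-1/2); for a binary
# outcome n_t should be the effective sample size 4 / (1/cases + 1/controls).

.NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                  "G", "A", "C", "A", "G", "T", "C", "T"),
                                ncol = 2, byrow = TRUE)

#' Ground-truth parameters for the synthetic GWAS generator
#'
#' Bundles every structural and nuisance parameter of the generator, so that
#' simulated data are a pure function of this object (including its seed).
#' The implied total exposure-outcome effect is
#' `theta_xy_direct + sum(theta_xm * theta_my)` by construction.
#'
#' Defaults mirror the study conditions of a UK-Biobank-scale lipid exposure
#' (n = 441,016), SCALLOP-scale cytokine mediator (n = 21,758) and a rare
#' binary liver-disease outcome from FinnGen (894 cases / 217,898 controls,
#' effective n = 3,561), with true effects beta1 = 0.10 (exposure on
#' mediator), beta2 = 0.25 (mediator on outcome log-odds) and a direct
#' exposure effect beta3 = 0.17, i.e. a mediated proportion of
#' 0.025 / 0.195 = 12.8%.
#'
#' @param n_snps Number of exposure instruments (>= 3).
#' @param theta_xm Numeric vector: true effect of the exposure on each
#'   mediator, per unit exposure. Length = number of mediators.
#' @param theta_my Numeric vector, same length: true direct effect of each
#'   mediator on the outcome log-odds.
#' @param theta_xy_direct True direct exposure-outcome effect (log-odds).
#' @param n_snps_mediator Number of additional SNPs per mediator that act as
#'   that mediator's own instruments (direct SNP-mediator effects). These
#'   are required for multivariable MR to be identified: without them every
#'   SNP's mediator effect is proportional to its exposure effect.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the direct
#'   SNP-outcome effects given to the invalid fraction of exposure
#'   instruments (directional pleiotropy when the mean is nonzero).
#' @param prop_invalid Fraction of exposure instruments given pleiotropic
#'   effects, in \[0, 1\].
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes per trait
#'   (effective sample size for binary traits).
#' @param maf_range Interval within (0, 0.5\] from which minor allele
#'   frequencies are drawn uniformly.
#' @param gamma_mean,gamma_sd Distribution of true instrument strengths
#'   (per-allele SNP-exposure effects), Normal(gamma_mean, gamma_sd^2). The
#'   default 0.08 (0.02) gives genome-wide-significant instruments with
#'   mean F far above 10 at the default exposure sample size.
#' @param seed Integer seed; mandatory.
#' @return A list of class `"sim_truth"`.
#' @export
sim_truth <- function(n_snps = 100,
                      theta_xm = 0.10,
                      theta_my = 0.25,
                      theta_xy_direct = 0.17,
                      n_snps_mediator = 20,
                      pleiotropy_mean = 0,
                      pleiotropy_sd = 0,
                      prop_invalid = 0,
                      n_exposure = 441016,
                      n_mediator = 21758,
                      n_outcome = 3561,
                      maf_range = c(0.05, 0.5),
                      gamma_mean = 0.08,
                      gamma_sd = 0.02,
                      seed = 1L) {
  if (length(theta_xm) != length(theta_my)) {
    stop("theta_xm and theta_my must have one entry per mediator")
  }
  if (n_snps < 3) stop("n_snps must be >= 3")
  if (any(c(n_exposure, n_mediator, n_outcome) <= 0)) {
    stop("sample sizes must be positive")
  }
  if (length(maf_range) != 2 || diff(maf_range) < 0 ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    stop("maf_range must be a non-empty interval within (0, 0.5]")
  }
  if (prop_invalid < 0 || prop_invalid > 1) stop("prop_invalid must be in [0, 1]")
  if (is.null(seed) || is.na(seed)) stop("seed is mandatory")
  structure(list(
    n_snps = as.integer(n_snps),
    theta_xm = theta_xm, theta_my = theta_my,
    theta_xy_direct = theta_xy_direct,
    n_snps_mediator = as.integer(n_snps_mediator),
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    prop_invalid = prop_invalid,
    n_exposure = n_exposure, n_mediator = n_mediator, n_outcome = n_outcome,
    maf_range = maf_range,
    gamma_mean = gamma_mean, gamma_sd = gamma_sd,
    seed = as.integer(seed)
  ), class = "sim_truth")
}

#' Total exposure-outcome effect implied by a truth object
#' @param truth A [sim_truth()] object.
#' @return The true total effect `theta_xy_direct + sum(theta_xm * theta_my)`.
#' @export
true_total_effect <- function(truth) {
  truth$theta_xy_direct + sum(truth$theta_xm * truth$theta_my)
}

# Per-trait seeds derived from the master seed so that noise draws for
# exposure, each mediator and the outcome come from independent streams
# (two-sample design) while the whole simulation stays reproducible.
.derived_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009L + stream * 9973) %% 2147483629)
}

.trait_noise <- function(seed, stream, n) {
  .with_seed(.derived_seed(seed, stream), stats::rnorm(n))
}

.as_sumstats <- function(snp, ea, oa, eaf, beta_true, se, n) {
  beta <- beta_true
  z <- beta / se
  data.frame(
    snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se,
    pval = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin),
    n = n, stringsAsFactors = FALSE
  )
}

#' Simulate two-sample GWAS summary statistics with known ground truth
#'
#' Generates one summary-statistics table per trait (exposure, each
#' mediator, outcome) under the structural model encoded in `truth`.
#' Per SNP j: a minor allele frequency is drawn uniformly from
#' `maf_range`; exposure instruments get a true strength
#' gamma_j ~ Normal(gamma_mean, gamma_sd^2); each mediator additionally has
#' `n_snps_mediator` SNPs with direct mediator effects from the same
#' distribution. True mediator effects are `gamma_j * theta_xm[k]` plus the
#' direct SNP-mediator effect; true outcome effects are
#' `gamma_j * theta_xy_direct + sum_k (mediator effect)_k * theta_my[k] +
#' alpha_j`, with alpha_j ~ Normal(pleiotropy_mean, pleiotropy_sd^2) for the
#' invalid fraction of exposure instruments and 0 otherwise. Observed betas
#' add Normal(0, se^2) noise with `se = (2 maf (1-maf) n_trait)^(-1/2)`,
#' using an independent noise stream per trait (non-overlapping samples).
#' P-values come from the observed z-scores.
#'
#' @param truth A [sim_truth()] object.
#' @return A list with elements `exposure` (sumstats data.frame),
#'   `mediators` (named list of sumstats, `M1`, `M2`, ...), `outcome`
#'   (sumstats), `truth` (the input echoed), and `valid` (logical vector
#'   over exposure instruments: FALSE for pleiotropic SNPs).
#' @export
simulate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  K <- length(truth$theta_xm)
  m_extra <- K * truth$n_snps_mediator
  M <- truth$n_snps + m_extra
  set.seed(truth$seed)

  snp <- sprintf("rs%06d", seq_len(M))
  pair <- .NONPALINDROMIC_PAIRS[sample.int(nrow(.NONPALINDROMIC_PAIRS), M,
                                           replace = TRUE), , drop = FALSE]
  ea <- pair[, 1]; oa <- pair[, 2]
  maf <- stats::runif(M, truth$maf_range[1], truth$maf_range[2])

  is_exp <- seq_len(M) <= truth$n_snps
  gamma <- numeric(M)
  gamma[is_exp] <- stats::rnorm(truth$n_snps, truth$gamma_mean, truth$gamma_sd)

  # direct SNP -> mediator instrument strengths
  delta <- matrix(0, M, max(K, 1))
  if (K > 0 && truth$n_snps_mediator > 0) {
    for (k in seq_len(K)) {
      idx <- truth$n_snps + (k - 1L) * truth$n_snps_mediator +
        seq_len(truth$n_snps_mediator)
      delta[idx, k] <- stats::rnorm(truth$n_snps_mediator,
                                    truth$gamma_mean, truth$gamma_sd)
    }
  }

  n_invalid <- round(truth$prop_invalid * truth$n_snps)
  alpha <- numeric(M)
  valid <- rep(TRUE, truth$n_snps)
  if (n_invalid > 0) {
    inv <- sample.int(truth$n_snps, n_invalid)
    valid[inv] <- FALSE
    alpha[inv] <- stats::rnorm(n_invalid, truth$pleiotropy_mean,
                               truth$pleiotropy_sd)
  }

  b_med_true <- matrix(0, M, max(K, 1))
  for (k in seq_len(K)) b_med_true[, k] <- gamma * truth$theta_xm[k] + delta[, k]
  b_y_true <- gamma * truth$theta_xy_direct + alpha
  for (k in seq_len(K)) b_y_true <- b_y_true + b_med_true[, k] * truth$theta_my[k]

  se_for <- function(n) 1 / sqrt(2 * maf * (1 - maf) * n)

  se_x <- se_for(truth$n_exposure)
  exposure <- .as_sumstats(snp, ea, oa, maf,
                           gamma + se_x * .trait_noise(truth$seed, 1L, M),
                           se_x, truth$n_exposure)

  mediators <- list()
  if (K > 0) {
    for (k in seq_len(K)) {
      se_m <- se_for(truth$n_mediator)
      mediators[[paste0("M", k)]] <-
        .as_sumstats(snp, ea, oa, maf,
                     b_med_true[, k] + se_m * .trait_noise(truth$seed, 1L + k, M),
                     se_m, truth$n_mediator)
    }
  }

  se_y <- se_for(truth$n_outcome)
  outcome <- .as_sumstats(snp, ea, oa, maf,
                          b_y_true + se_y * .trait_noise(truth$seed, 100L, M),
                          se_y, truth$n_outcome)

  for (d in c(list(exposure, outcome), mediators)) {
    class(d) <- c("sumstats", "data.frame")
  }
  list(exposure = exposure, mediators = mediators, outcome = outcome,
       truth = truth, valid = valid)
}

#' Shift the outcome effects of k SNPs to create known outliers
#'
#' Adds a fixed offset to the outcome beta of `k` randomly chosen SNPs and
#' returns their IDs, so that outlier-detection power (e.g. of MR-PRESSO)
#' can be scored against ground truth.
#'
#' @param records An outcome summary-statistics data.frame.
#' @param k Number of SNPs to perturb; must be `< nrow(records)`.
#' @param magnitude Offset added to each chosen SNP's beta.
#' @param seed Integer seed for the choice of SNPs.
#' @return A list with `records` (modified table, p-values recomputed) and
#'   `altered` (character vector of perturbed snp IDs).
#' @export
inject_outliers <- function(records, k, magnitude, seed) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (k >= n) stop("k must be smaller than the number of records (", n, ")")
  if (k < 0) stop("k must be non-negative")
  if (k == 0) return(list(records = records, altered = character(0)))
  pick <- .with_seed(seed, sample.int(n, k))
  records$beta[pick] <- records$beta[pick] + magnitude
  z <- records$beta / records$se
  records$pval <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  list(records = records, altered = records$snp[pick])
}
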