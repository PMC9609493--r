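# Shared fixtures built in code.

# Minimal harmonized instrument set from raw vectors.
make_iv <- function(beta_x, se_x, beta_y, se_y,
                    snp = sprintf("rs%03d", seq_along(beta_x))) {
  structure(
    data.frame(snp = snp,
               effect_allele = "A", other_allele = "G", eaf = 0.3,
               beta_exposure = beta_x, se_exposure = se_x,
               pval_exposure = 2 * pnorm(-abs(beta_x / se_x)),
               beta_outcome = beta_y, se_outcome = se_y,
               eaf_outcome = 0.3, palindromic = FALSE, flipped = FALSE,
               stringsAsFactors = FALSE),
    class = c("instrument_set", "data.frame"), harmonized = TRUE)
}

# Random harmonized instrument set for property-style loops.
random_iv <- function(J, seed, theta = 0.3) {
  set.seed(seed)
  bx <- rnorm(J, 0.1, 0.04)
  bx[abs(bx) < 0.01] <- 0.05
  sx <- runif(J, 0.002, 0.01)
  sy <- runif(J, 0.01, 0.05)
  by <- theta * bx + rnorm(J, 0, sy)
  make_iv(bx, sx, by, sy)
}

# Brute-force interpolated weighted median (independent of the package's
# internal implementation).
brute_weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  i <- max(which(s < 0.5))
  theta[i] + (theta[i + 1] - theta[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}
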