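---
title: "Methods: two-step and multivariable MR with mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step and multivariable MR with mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`mrmediation` works entirely on GWAS summary statistics. For each SNP
$j$ and each trait $t$ it consumes a per-allele effect $\hat\beta_{tj}$
and its standard error; binary outcomes are on the log-odds scale. The
structural model behind the mediation machinery is

$$ M_k = \beta_{1k} X + \delta_k G + \epsilon_M, \qquad
   \mathrm{logit}\,P(Y{=}1) = \beta_3 X + \sum_k \beta_{2k} M_k + \alpha G + \epsilon_Y, $$

where $X$ is the exposure, $M_k$ the mediators, $G$ the genotypes,
$\delta_k$ direct SNP–mediator effects and $\alpha$ horizontal
pleiotropy. The total exposure effect decomposes as
$\beta_{\text{tot}} = \beta_3 + \sum_k \beta_{1k}\beta_{2k}$, and the
mediated proportion is
$E\% = \sum_k \beta_{1k}\beta_{2k} \,/\, (\beta_3 + \sum_k \beta_{1k}\beta_{2k})$
(product method) or $(\beta_{\text{tot}} - \beta_3)/\beta_{\text{tot}}$
(difference method). Both are implemented; the product method is the
default because the $E\%$ formula is written in terms of
$\beta_1 \times \beta_2$, and `method = "both"` reports the two side by
side so their (finite-sample) disagreement is inspectable rather than
hidden.

Key assumptions, in the order they bite: instruments are associated with
their exposure (relevance — enforced by the genome-wide $p$ threshold);
independent of confounders (randomization at conception); and affect the
outcome only through the modelled exposures (exclusion restriction —
probed, not guaranteed, by the Egger intercept, Cochran's $Q$, PRESSO
and leave-one-out). MR-Egger additionally needs InSIDE (instrument
strength independent of direct effects). Mediation additionally assumes
the exposure-before-mediator ordering is correct a priori; summary-level
data cannot distinguish mediation from confounding of the
mediator–outcome pair.

# Tunable parameters

| Parameter | Default | Units / scale | Why |
|---|---|---|---|
| `p_threshold` | 5e-8 | association $p$ | conventional genome-wide significance |
| `window_kb`, `r2_limit` | 10,000 kb, 0.001 | clumping window, LD $r^2$ | standard strict-independence clumping |
| `maf_min` | 0.01 | minor allele frequency | rare variants have unstable summary effects |
| `palindrome_eaf_band` | [0.42, 0.58] | allele frequency | inside this band an A/T or C/G SNP's strand cannot be inferred from frequency |
| `drop_palindromic_ambiguous` | TRUE | — | conservative default; keeping flagged records is opt-in |
| IVW `model` | `"random"` | — | multiplicative random effects: heterogeneous instruments are the norm at these instrument counts, and the fixed-effect SE is anti-conservative under heterogeneity |
| Wald-ratio SE | first-order | — | standard practice; the second-order formula is available where exposure-side noise matters |
| `n_boot` (median) | 1000 | bootstrap draws | SD of the bootstrap median stabilises well below the SE itself |
| `n_sim` (PRESSO) | 5000 | null simulations | resolves $p \approx 0.01$ with Monte-Carlo SE $< 0.002$ |
| `outlier_alpha` | 0.05 | family level | applied after Bonferroni over instruments |
| Huber constant | 1.345 | standardized residuals | 95% Gaussian efficiency |

P-values use the normal reference for IVW, weighted median, maximum
likelihood and RAPS, and t(J−2) for both MR-Egger coefficients.

# The synthetic generator

`sim_truth()` / `simulate_two_sample()` generate summary statistics
directly on the summary scale: per SNP a minor allele frequency is drawn
uniformly (default 0.05–0.5), instrument strengths are
$\gamma_j \sim N(0.08, 0.02^2)$ (genome-wide-significant-scale effects,
mean F far above 10 at the default exposure sample size), and each
trait's observed effect adds mean-zero normal noise with
$\mathrm{se} = (2f(1-f)\,n_t)^{-1/2}$ — independent streams per trait,
matching the non-overlapping two-sample design. Defaults mirror
the motivating study conditions: a lipid exposure from a 441,016-sample
biobank GWAS, a cytokine mediator from a 21,758-sample proteomics GWAS,
and a rare binary liver-disease outcome, entered as the effective sample
size $4/(1/894 + 1/217{,}898) \approx 3{,}561$ because the log-odds SE
formula requires effective counts for unbalanced case/control designs.
Default true effects are $\beta_1 = 0.10$, $\beta_2 = 0.25$,
$\beta_3 = 0.17$, i.e. a 12.8% mediated proportion, consistent with a
lipid–cytokine log-OR of about 0.10.

Each mediator also receives `n_snps_mediator` (default 20) SNPs with
*direct* mediator effects drawn from the same strength distribution.
This is a modelling necessity, not a convenience: if every SNP's
mediator effect were proportional to its exposure effect
($\gamma_j \beta_1$), the multivariable design matrix would be collinear
in expectation and direct effects would be unidentified — exactly why
real two-step analyses require mediators with instruments of their own.

What the generator does **not** emulate: LD between instruments (data
are post-clumping by construction; clumping itself is exercised against
user-supplied toy LD matrices), sample overlap, winner's curse in
instrument selection, population stratification, and non-collapsibility
of the odds ratio (outcome effects are generated linearly on the
log-odds scale). Passing tests therefore validate the estimators and
their bookkeeping under the stated summary-level model; they do not
certify behaviour under individual-level complications the model
excludes.

# Numerical choices

- **Clumping** is greedy on ascending $p$ with a lexicographic variant-ID
  tiebreak, so selection is deterministic. Without an LD matrix all
  survivors are independent; without positions the distance window is
  vacuous and only $r^2$ binds.
- **Maximum likelihood** profiles the per-SNP strengths analytically,
  leaving a one-dimensional profile likelihood maximised by golden-section
  search (objective tolerance 1e-10) from the IVW start, with geometric
  bracket expansion and a hard failure if no interior optimum is found.
  The SE differentiates the *analytic* profile score numerically at a
  step scaled to the IVW standard error — naive second differences of
  the log-likelihood cancel catastrophically at these magnitudes.
- **RAPS** solves the profile estimating equation by bracketed
  root-finding around the IVW estimate; with overdispersion the
  $(\theta, \tau^2)$ pair alternates between the score root and the
  moment equation $\sum_j [\psi(t_j)t_j - \delta_\psi] = 0$ with
  $\tau^2$ floored at zero ($\delta_\psi = E[\psi(Z)Z]$ under the
  standard normal). SEs are sandwich estimates. With $\tau^2 = 0$ and
  squared loss the score is exactly the profile-likelihood score, which
  the tests exploit as an equivalence oracle.
- **MR-PRESSO** uses leave-one-out slopes inside the residual sum of
  squares so an outlier cannot mask itself, computes them in $O(J)$ from
  sufficient statistics, and vectorises the whole null simulation.
  Outlier flagging uses the raw simulation counts (a zero count is
  evidence at resolution $1/n_\text{sim}$); reported $p$-values are
  floored at $1/n_\text{sim}$ so nothing prints as exactly zero.
- **Degenerate inputs**: zero exposure betas are a hard error for Wald
  ratios; an exactly collinear exposure matrix names the offending pair;
  an exact-fit Egger regression (zero residual) is handled without
  division by zero because base SEs come from the design matrix, not
  from rescaling by $\hat\sigma$.
- **Reproducibility**: every stochastic routine takes a mandatory seed,
  restores the caller's RNG state, and per-edge pipeline seeds derive
  from the master seed by a counter, so report bundles are bitwise
  reproducible.

# Open design points, resolved

- The fixed-vs-random-effects IVW choice and the Wald-ratio SE order are
  surfaced as arguments with the defaults above.
- Palindromic-SNP handling and the clumping algorithm are not uniquely
  determined by the thresholds alone; the frequency-band rule and greedy
  $p$-ranked clumping are the standard conventions and are configurable.
- The MAF filter applies at selection with missing-frequency variants
  kept and flagged, since frequencies are optional in the exchange
  format.
- For several mediators jointly, $\beta_{2k}$ and $\beta_3$ come from
  the all-mediator multivariable fit (the $k$-sum in the $E\%$ formula
  implies jointly adjusted coefficients); each single-mediator row uses
  its own pairwise fit.
- No uncertainty convention exists for $E\%$ at summary level, so its
  CI propagates the delta-method indirect-effect CI against the fixed
  denominator and is labelled approximate; joint-indirect variance sums
  per-mediator delta terms and ignores their covariance. Opposite-sign
  indirect and total effects set an `inconsistent` flag instead of
  printing a bare negative percentage.

# Validation problem sizes

The test suite validates estimator–oracle equivalence to 1e-10 (IVW,
Egger), 1e-12 (weighted median walk) and 1e-6 (ML vs RAPS); type-I error
and CI coverage over 1000 null replicates at 40 instruments; pleiotropy
robustness over 500 replicates at 360 instruments (the lipid-GWAS
instrument scale, where the Egger intercept has useful power against a
30%-invalid mixture); PRESSO power and specificity over 100 replicate
pairs at 50 instruments and 5000 null simulations; mediation recovery
over 500 replicates at $5\times10^5$ samples per trait; and
multivariable recovery over 300 replicates with a $2\times10^5$-sample
mediator GWAS, large enough that mediator-side measurement error does
not attenuate the adjusted coefficient — at proteomics-scale mediator
GWAS sizes a few percent attenuation is expected and visible.

# Limitations

Proxy-SNP lookup, LD estimation from reference panels, Steiger
filtering, radial MR and mode-based estimators are out of scope. The
confounder screen behind the exclusion list (PhenoScanner / GWAS-catalog
lookups) is a manual step represented by a plain text file. Real-data
instrument counts and effect sizes from the motivating consortium
datasets cannot be re-derived without those downloads; the package's
claims are about the estimators' behaviour under the stated synthetic
conditions.
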