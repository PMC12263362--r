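---
title: "Ancestry-weighted PRS and absolute breast-cancer risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-weighted PRS and absolute breast-cancer risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixprs)
```

# The problem

Polygenic risk scores (PRS) for breast cancer are mostly trained in
European-ancestry cohorts. Applied to an admixed population — such as
Colombian women, where individual genomes mix African, Indigenous American
and European segments in continuously varying proportions — a single-ancestry
score is miscalibrated for most individuals. One pragmatic answer is to keep
a library of ancestry-specific panels and blend them per individual: weight
each panel's standardized score by the fraction of that individual's genome
attributed to the matching reference ancestry. `admixprs` implements that
pipeline end to end, from genotype dosages to an absolute 10-year risk and a
personalised screening age, together with the discrimination and
reclassification statistics used to judge whether adding the PRS to clinical
risk factors (mammographic density, family history) improves prediction.

# Models

## Scoring and combination

A raw PRS is the additive sum $\mathrm{PRS} = \sum_i \beta_i x_i$ over panel
variants, where $x_i \in [0,2]$ is the alternate-allele dosage and $\beta_i$
the log odds ratio of the effect allele. Raw scores are standardized against
the panel's reference distribution, $z = (\mathrm{PRS} - \mu_\mathrm{ref})
/ \sigma_\mathrm{ref}$. The combined score is the admixture-weighted average
$\sum_k q_k z_k$ over the five 1000 Genomes superpopulations
(AFR/AMR/EAS/EUR/SAS). Two choices here were genuinely open:

* **Averaging happens on the z scale, not the raw scale.** Raw scores from
  different panels live on incomparable scales (different variant counts and
  weight magnitudes); a weighted average of raw scores would be dominated by
  whichever panel has the largest weights.
* **The combined value is re-standardized** against the control (or an
  external reference) distribution of the combined score. The weighted
  average of unit-variance components has variance $\sum_k q_k^2 < 1$, so
  without this step "per standard deviation" effect sizes would depend on
  the cohort's admixture distribution. Re-standardization restores a
  per-SD interpretation. Ancestries contributing less than 1% of a genome
  and lacking a panel are renormalized away; above that threshold a missing
  panel is an error rather than a silent gap.

## Admixture estimation

Supervised admixture proportions maximize
$\ell(q)=\sum_i x_i \log p_i(q) + (2-x_i)\log(1-p_i(q))$ with
$p_i(q) = \sum_k q_k f_{ik}$ over the probability simplex, where $f_{ik}$
are reference allele frequencies. The optimizer is the EM-style
multiplicative update on expected ancestry-of-origin allele counts. Because
$\ell$ is a sum of logarithms of affine functions of $q$, it is concave on
the simplex; a single uniform start therefore reaches the global optimum and
random restarts would add cost without changing the answer. Convergence is
declared when the log-likelihood gain drops below $10^{-8}$. Frequencies are
clamped to $[10^{-4}, 1-10^{-4}]$ so no fixed variant can drive the
log-likelihood to $-\infty$. When all reference columns are identical the
likelihood is flat; the estimator returns uniform proportions with a
warning rather than an arbitrary vertex. The discrete "major ancestry" label
is the argmax with a configurable minimum proportion (below it: "admixed");
the threshold rule is a convention, not an estimate. The PCA space is
consumed, never computed: loadings and centering means are an input
artifact, and projection is the centered dot product with missing dosages
imputed at the centering mean.

## Relative and absolute risk

A standardized score maps to a relative risk $RR = \exp(z \cdot
\log\mathrm{OR}_\mathrm{SD})$, and per-panel relative risks are combined as
the admixture-weighted arithmetic mean (a log-scale geometric alternative is
available by flag). Percentile categories $[p_\mathrm{lo}, p_\mathrm{hi})$
of a standard-normal reference carry the truncated-lognormal mean relative
risk
$$RR_k = e^{b^2/2}\,\frac{\Phi(z_\mathrm{hi}-b)-\Phi(z_\mathrm{lo}-b)}
{\Phi(z_\mathrm{hi})-\Phi(z_\mathrm{lo})},\qquad b=\log\mathrm{OR}_\mathrm{SD},$$
the category *mean* rather than $\exp(b\bar z_k)$, because the mean is what
makes the population constraint below interpretable.

Age-specific population incidence $I_\mathrm{pop}(t)$ is recalibrated per
category as $I_k(t) = I_\mathrm{pop}(t)\, RR_k / \sum_j w_j RR_j$, with
$w_k$ the category shares. This multiplicative, incidence-scale reading is
the standard solution to the constraint that the share-weighted category
incidences reproduce the population incidence at every age,
$\sum_k w_k I_k(t) = I_\mathrm{pop}(t)$, which the implementation preserves
to machine precision (it is a property-based test). Whether the adjustment
should act on the hazard or the cumulative-risk scale is not determined by
the constraint alone; the hazard (incidence) scale is the chosen and
documented reading. A recalibrated incidence reaching 1 is treated as model
breakdown and raised as an error naming the age and category, never clipped
silently.

Absolute risk over a horizon accumulates the discrete annual recursion
$$AR(t) = \sum_{u=t_0}^{t_0+T-1} P_\mathrm{ND}(u)\, S(u)\, I(u),$$
with $P_\mathrm{ND}(u)=\prod_{v<u}(1-m(v))$ survival from competing
(other-cause) mortality and $S(u)=\prod_{v<u}(1-I(v))$ survival from breast
cancer, both products over $v \in [t_0, u)$. The first-year term uses
$P_\mathrm{ND}=S=1$ (start-of-interval convention — made explicit because a
sum written "$\sum_0^t$" is ambiguous about its first term). With zero
competing mortality and constant hazard $h$ this collapses to
$1-(1-h)^T$, which the tests verify to $10^{-12}$.

For a continuous score the individual's incidence is
$I_\mathrm{pop}(t)\,RR/E[RR]$ with the analytic normalizer $E[RR] = \sum_k
q_k e^{b_k^2/2}$ over the standard-normal reference, so the
population-average constraint also holds in the continuous limit. The
`rr` argument of `ten_year_risk()` / `risk_equivalent_age()` instead accepts
a relative risk already expressed versus the population average, with no
further normalization: `rr = 1` reproduces the population risk exactly,
which gives the screening-age fixed point below. The 10-year clock starts at
the individual's current age.

## Screening age

The risk-equivalent screening age is the smallest age at which the
individual's 10-year risk reaches the population-average 10-year risk at
the guideline age (50, the mammography starting age in Colombia), linearly
interpolated between integer ages and clamped (with a flag) to the life
table's range when the threshold is never reached. An average-risk
individual maps to exactly 50 by construction. On a unimodal incidence
curve the 10-year risk is itself unimodal, so "smallest age reaching the
threshold" is well defined.

## Discrimination and reclassification

Logistic models are fitted by IRLS (`stats::glm`) with Wald intervals,
matching how such studies report odds ratios; profile-likelihood intervals
are deliberately not offered. Separation and non-convergence are explicit
errors. Unknown covariate levels (density, family history) enter as an
explicit `"unknown"` indicator rather than row deletion, which would
silently change the analysis n. The AUC is tie-corrected Mann–Whitney
concordance — half credit for ties is load-bearing: an ordinal 4-level
predictor like BI-RADS density only reproduces its published AUC under that
convention. Stratum odds ratios use indicator terms against the central
quintile (40–60%) with optional adjusters, defaulting percentile assignment
to the analytic standard-normal scale.

Categorical NRI is computed from the old-stratum × new-stratum movement
matrices separately for cases and controls, with the up/down components
reported alongside their sum; IDI is the change in discrimination slope. In
the pipeline the four risk strata (low `[0,30)`, standard `[30,70)`,
moderate `[70,90)`, high `[90,100]` percentiles; left-closed bins, top bin
closed) are converted to fixed probability cut points — the control
percentiles of the *baseline* model — applied to both models' predicted
probabilities. Re-deriving percentiles under each model separately forces
both control distributions to the nominal 30/40/20/10 shares by
construction, which pins the control component of the NRI near zero; fixed
cut points let controls genuinely move down when the new model separates
better. For `assign_strata()` generally, the percentile reference defaults
to the analytic standard-normal distribution with an empirical
(control-sample, mean-rank) alternative: published stratum shares in this
literature are inconsistent with self-referential control percentiles, so
both conventions are supported and neither is asserted as "the" one.

# The synthetic-data generator

The generator produces the study conditions the pipeline is validated
under; it is first-class, tested code, not a fixture.

* **Reference frequencies**: Balding–Nichols draws — per variant an
  ancestral frequency $p \sim U(0.05, 0.95)$, then per superpopulation
  $f_k \sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ with
  divergence $F = 0.15$ by default, a typical continental-scale
  differentiation; frequencies are clamped to $(0.01, 0.99)$.
* **Cohort**: admixture $q \sim \mathrm{Dirichlet}(\alpha)$ with default
  $\alpha = (0.3, 7.5, 0.1, 2.0, 0.1)$ for (AFR, AMR, EAS, EUR, SAS) —
  mean proportions of about 3/75/1/20/1%, an AMR-dominant,
  European-second profile like the validation cohort's; genotypes
  $x_{ij} \sim \mathrm{Binomial}(2, \sum_k q_k f_{jk})$. Variants are
  independent: no LD and no realistic haplotype structure, so nothing here
  validates LD-aware methods, and passing tests say nothing about panel
  transferability on real LD patterns.
* **Outcome**: $P(\mathrm{case}\mid z, F) = \mathrm{logit}^{-1}(\alpha_0 +
  z\log\mathrm{OR}_\mathrm{SD} + \sum \text{covariate effects})$ with the
  defaults $\mathrm{OR}_\mathrm{SD} = 1.56$ and case fraction 0.255 at
  $n = 1997$, the published study design. The intercept is solved by 1-D
  root finding to $10^{-6}$ on the marginal case rate: at a 25% case
  fraction the rare-disease approximation would misplace it badly.
* **Covariates**: BI-RADS density A–D with population marginals
  (20.3/58.2/19.4/2.1%) taken from the published control distribution, and
  the default density effects (log-odds 0/0.617/1.652/2.413 versus A) are
  the unadjusted log odds ratios implied by the published case/control
  density table; family history has prevalence 12% and odds ratio 2, a
  field-standard figure. Covariate base distributions are case-status
  independent — their marginal association with disease is produced only
  through the outcome model, so any recovered association is attributable
  to the configured effects.
* **Life tables**: Gaussian-in-age incidence peaking at 0.2%/year near age
  65 and Gompertz other-cause mortality (0.3%/year at 50, log-slope
  0.09/year), a stylized Colombian urban region. These put the peak of the
  10-year risk curve near age 60. They are synthetic stand-ins; regional
  registry tables should replace them for any real analysis.
* **Determinism**: every generator routes randomness through one explicit
  seed (fixed offsets per stage) and restores the caller's RNG state;
  identical config + seed is bit-identical output.

# Numerical choices and degenerate inputs

* Harmonization matches panels to genotypes by `(chrom, pos)` (1-based, VCF
  convention throughout); an effect allele equal to the reference allele
  flips the contribution to $\beta(2-x)$; strand-ambiguous (A/T, C/G) rows
  are dropped by default; unmatched rows are reported, never silently
  dropped; zero matches is a hard error. No liftover and no strand
  inference — both are out of scope and error-prone.
* Missing dosages at scoring time are imputed at the expected dosage
  $2\sum_k q_k f_{ik}$ when reference frequencies and admixture proportions
  are available, else at $2f$ from the panel-declared effect-allele
  frequency; an individual with every dosage missing is flagged unreliable
  rather than scored. Imputation counts are reported per individual.
* An all-zero-weight panel (a degenerate but constructible case) stores
  unit reference scale so standardization is defined and returns z = 0.
* `risk_equivalent_age` interpolates linearly between integer ages only at
  the final step; everything else stays on the annual grid.
* The AUC increment's bootstrap (2,000 seeded resamples by default)
  resamples individuals and recomputes both AUCs from stored fitted
  probabilities; it does not refit.

# Problem sizes in the test suite

The suite exercises the statistical properties at sizes chosen to keep a
full run around two minutes while leaving comfortable Monte-Carlo margins:
admixture recovery uses 5,000 variants per individual and a 200-individual
cohort at 2,000 variants for the Dirichlet-mean check; parameter recovery
uses 50 replicate cohorts at the study's n = 1,997; the stratum-OR check
uses one cohort of n = 200,000; reclassification positivity uses 50
replicates at n = 3,000. Tolerances follow the binomial/Dirichlet standard
errors at those sizes (typically 3 SE), and exact algebraic identities
(recalibration constraint, closed-form absolute risk, self-standardization)
are tested at machine precision.

# Known limitations

* Supervised admixture only: reference panels are an input; no unsupervised
  STRUCTURE/ADMIXTURE estimation, no reference-panel construction.
* No LD: scoring assumes pre-pruned or harmonized panels; no LD-aware
  weighting, no imputation beyond mean-dosage fill-in, no genotype QC.
* The absolute-risk model is the discrete competing-risk recursion above;
  no calendar-period effects, no cause-specific hazards beyond the two
  competing processes, and the synthetic life tables are stylized.
* NRI/IDI are the categorical and slope forms; continuous NRI and
  analytic confidence intervals are not implemented (seeded bootstrap only
  for the AUC increment).
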