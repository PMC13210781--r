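---
title: "Methods: treatment-modified Mendelian randomization with metabolite polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: treatment-modified Mendelian randomization with metabolite polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgxe)
```

## The model

`mrgxe` estimates whether the causal effect of a genetically influenced
metabolite on glycaemic control (HbA1c) depends on a binary treatment
(metformin use). The structural equation is

$$ Y = \alpha + \beta_{exposure}\,X + \beta_{G\times E}\,(S \cdot T) +
   \gamma' C + \varepsilon $$

where $X$ is the metabolite level (endogenous: an unobserved confounder
$U$ loads on both $X$ and $Y$), $S$ is the metabolite's polygenic score,
$T \in \{0,1\}$ the treatment indicator, and $C$ the covariates (age,
sex, BMI, leading genotype principal components). The score instruments
the metabolite; the product $S \cdot T$ enters **both** the instrument
set and the structural equation as an included exogenous variable:

$$ Y \sim X + S\!\cdot\!T + C \;\;\big|\;\; S + S\!\cdot\!T + C $$

$\beta_{exposure}$ is the baseline causal effect in the whole cohort;
$\beta_{G\times E}$ is the shift of the genetically driven effect among
the treated. There is deliberately no treatment main-effect term: the
model mirrors the conventional specification for this design, and the
generator's outcome contains none either. A consequence worth knowing is
that any outcome signal that differs between arms and is correlated with
the score's treated-arm values loads on the interaction term; the
leave-one-out analysis (below) is the tool for deciding whether one
variant carries that signal.

Identification rests on the usual instrumental-variable conditions:
relevance (checked by the first-stage F), exclusion (screened per variant
and per score, and probed by leave-one-out), and independence of the
instrument from confounders of the outcome. Treatment is assumed
exogenous — assigned independently of genotype — which is also what the
collider screen tests.

## The estimator

`mr_gxe()` solves the 2SLS normal equations
$\hat\beta = (W' P_Z W)^{-1} W' P_Z y$ with
$W = [1, X, S\!\cdot\!T, C]$ and $Z = [1, S, S\!\cdot\!T, C]$, entirely
through QR decompositions: the instrument projection is `qr.fitted()` on
the QR of $Z$, the solve is the QR of the projected regressors, and the
unscaled covariance comes from the triangular factor. No raw
cross-product matrix is ever inverted. Rank deficiency in either design
is reported with the names of the dependent columns, and an all-treated
or all-untreated cohort is a hard error (the product term degenerates).

The default covariance is the classical 2SLS estimator
$\hat\sigma^2 (W' P_Z W)^{-1}$ with $\hat\sigma^2$ computed from the
*structural* residuals $y - W\hat\beta$ — the observed exposure, not its
first-stage fit; the naive second-stage residual variance is known to be
wrong. A heteroskedasticity-robust HC0 sandwich
is available (`vcov_type = "robust"`). p-values and confidence intervals
use the t distribution on $n-k$ degrees of freedom by default; a standard
normal reference is a switch (`df_type = "normal"`). Rows with any
missing value are dropped and counted (complete-case analysis).

The score and the product term are used on their natural, unaveraged
scale by default. `standardize = TRUE` divides both by the score's
standard deviation, putting $\beta_{G\times E}$ on a per-SD scale that is
comparable across metabolites; the t statistics are unchanged.

## The synthetic cohort generator

No individual-level data ship with the package; the generator supplies
cohorts with precisely the statistical structure the analysis assumes,
with known truth for calibration.

* **Genotypes.** Each variant's ALT-allele frequency is uniform on
  `maf_range` (default 0.05–0.5, the post-QC spectrum). Within a block of
  `ld_block_size` consecutive variants (default 20), each haplotype's
  allele indicators come from thresholding a latent Gaussian that mixes a
  per-haplotype block factor with idiosyncratic noise at correlation
  `ld_rho` (default 0.3); blocks are independent, and are laid out 2 Mb
  apart so different blocks never share a clumping window. This
  block-factor threshold model was chosen because it gives direct,
  controllable dosage correlation for the pruning and clumping stages to
  act on, while remaining trivially reproducible.
* **Phenotypes.** Age is uniform on 20–70 years, sex Bernoulli(0.5), BMI
  normal(28, 5) truncated at 15 — plausible adult-cohort marginals whose
  exact values are immaterial to recovery. A latent standard-normal
  confounder $U$ loads on exposure and outcome with strengths 1.0 and 0.5
  (defaults): enough endogeneity to make OLS visibly biased while keeping
  variances of order one. The exposure adds the causal-variant score
  (weights normal with scale `effect_sd`, default 0.15) and unit noise.
  Treatment is Bernoulli(0.3), independent of genotype by construction —
  0.3 gives both arms adequate size at the default n of 2743. The outcome
  follows the structural model above with defaults
  $\beta_{exposure} = 0.2$, $\beta_{G\times E} = -0.1$.
* **The interaction term in the generator** is score-by-treatment,
  matching the fitted model. An alternate mode
  (`gxe_mode = "exposure"`) generates exposure-by-treatment effect
  modification instead, for robustness exploration only; it is off by
  default.
* **Truth object.** Causal ids, weights, confounder values and true
  coefficients are returned alongside the phenotypes for recovery
  assertions; the analysis pipeline never reads them.
* **Seeding.** A configuration seed makes a cohort bit-reproducible. The
  phenotype stream is offset from the genotype stream by a large odd
  constant (1,000,003) so that replicate studies seeded with consecutive
  integers never reuse a stream across replicates.

What the generator does **not** emulate: population structure or
admixture (principal components on simulated data capture sampling noise,
not ancestry), metabolite correlation networks, dose/duration/adherence
of treatment, genotyping error, or non-Gaussian metabolite distributions.
Passing calibration on these cohorts therefore demonstrates correctness
of the estimator and pipeline logic under the stated model — not
robustness to the full messiness of biobank data.

## Thresholds and their defaults

All thresholds follow the conventions of the workflow this package
implements, and every one is configurable through `pipeline_config()`:

| stage | parameter | default | boundary semantics |
|---|---|---|---|
| variant QC | `maf_min` | 0.05 | removal is strict `<`; MAF exactly 0.05 is kept |
| variant QC | `hwe_min` | 1e-6 | strict `<` removes |
| variant QC | `cr_min` | 0.90 | strict `<` removes |
| PC pruning | `prune_r2` | 0.5 | strict `>` prunes |
| scan | `p_candidate` | 5e-6 | strict `<` selects |
| clumping | `clump_r2` / `clump_window_kb` | 0.001 / 500 | strict `>` discards; window is `<=` |
| pleiotropy screen | `p_pleiotropy` | 0.05 | strict `<` removes |
| instrument strength | `f_min` | 10 | strict `>` retains |
| validity screens | `p_screen` | 0.05 | `<` excludes |

The Hardy–Weinberg test is the one-degree-of-freedom Pearson chi-square
against proportions at the estimated allele frequency — the conventional
large-sample screen; an exact test would differ only at small
minor-allele counts, below the MAF filter anyway. The association scan
adjusts for age, sex, BMI and the leading principal components (the same
covariate set as the causal model, since the scan's own adjustment set is
a free choice); the per-variant pleiotropy screens are covariate-free
marginal regressions, sex being screened with the same linear model for
uniformity. Greedy scans break ties deterministically: pruning keeps the
smaller position of a correlated pair; clumping orders by p-value, then
chromosome, then position.

## The instrument screens, and their one-sample paradox

The literal outcome screen — *exclude a score associated with the
outcome* — contradicts instrument relevance whenever the exposure truly
affects the outcome: the score then associates with the outcome through
the very path being estimated, and with enough power the screen rejects
every good instrument. The conditional variant
(`outcome_screen = "conditional"`) adjusts for the exposure, which
removes that path, but under strong confounding conditioning on the
endogenous exposure itself induces a score–outcome association (the
score and the confounder become dependent given the exposure), so
neither mode is safe under all conditions. The package therefore
implements both, defaults to the literal marginal reading, logs the mode
in every diagnostics table, and offers `screens = "warn"` — diagnostics
are computed and reported, the fit proceeds — for settings where the
screens are known to be conservative. The collider screen (score versus
treatment) and the weak-instrument bound F > 10 have no such ambiguity
and are always meaningful.

## Pattern classification

`classify_pattern()` reduces a fitted pair to a qualitative label at a
stated significance level: interaction non-significant → `none`;
interaction significant with a non-significant baseline →
`conditional_only`; both significant with the same sign →
`strengthened`. For opposite signs the label depends on the direction of
the baseline effect relative to the harmful direction of the outcome
(higher HbA1c is worse): a harmful baseline opposed by the interaction is
`reversed` (treatment turns a deleterious genetic effect toward benefit);
a protective baseline opposed by the interaction is `attenuated`
(treatment erodes a benefit). Comparing the two magnitudes instead would
be tempting but is not meaningful: $\beta_{G\times E}$ is per score unit
and $\beta_{exposure}$ per exposure unit, scales that differ by the
first-stage slope. The direction rule cannot distinguish attenuation from
an overshoot into harm; that distinction would require a common scale and
is deliberately not attempted.

## Leave-one-out sensitivity

`leave_one_out()` rebuilds the score without each variant in turn,
refits, and flags a variant as influential when its removal flips the
sign or the significance of $\beta_{G\times E}$. A single variant with
its own treatment-dependent path to the outcome — horizontal pleiotropy
concentrated in one instrument component — produces exactly this
signature: the spurious interaction survives every removal except that
variant's. Because the model has no treatment main effect, a pleiotropic
signal that mimics a uniform treated-arm shift is partially absorbed by
the interaction term of *any* score containing correlated components;
the planted-variant calibration in the test-suite therefore uses a
mean-balanced (mixed-sign-weight) score, where membership of the
offending variant, not a shared shift, carries the signal.

## Numerical choices

* All least-squares solves use QR with column pivoting; rank checks name
  offending columns.
* A perfect first stage (zero residual) reports `F = Inf` and is
  retained, rather than overflowing.
* Zero-variance dosage makes LD r² undefined: it returns `NA` with a
  warning, and greedy scans treat the pair as uncorrelated.
* Missing dosages: excluded per variant in MAF/HWE/scan computations;
  replaced by the variant's mean dosage in scores and by the column mean
  (zero after centring) in principal components.
* Monomorphic variants get `NA` scan statistics and can never become
  candidates.
* An empty post-QC matrix or an empty screened candidate set is a
  warning-flagged valid state, not an error; the pipeline records it and
  continues.
* Multiplicity adjustment wraps the standard step-up/step-down
  procedures (`none`, `bonferroni`, `benjamini_hochberg`).

## Calibration studies and problem sizes

The test-suite and `scripts/acceptance.R` calibrate the estimator at
sizes chosen to make Monte-Carlo error small relative to the quantities
checked while keeping a full run in the order of a minute: parameter
recovery and interval coverage over 200 replicates of n = 5000 with 100
causal variants and active confounding; test size under the interaction
null over 1000 replicates of n = 2000; oracle equivalence of the solver
against explicit dense projection solves on 50 small instances; greedy
clumping and pruning against literal step-by-step oracles on 100–200
random instances; and planted-pleiotropy detection over 100 replicates
of a 20-variant instrument at n = 1500. The recovery studies instrument
the exposure with the generator's true weights, isolating the estimator's
calibration from scan-selection noise (winner's curse in estimated
weights is a property of the construction stage, tested separately).

## Known limitations

* One-sample, individual-level design only: no summary-statistic
  (two-sample) estimators, no MR-Egger or weighted-median pleiotropy
  models.
* Binary treatment without dose, duration or adherence.
* No sample-level QC (relatedness, heterozygosity) and no sex
  chromosomes; principal components are computed without relatedness
  handling.
* Metabolite preprocessing is a user choice (`transform = "none"`,
  `"log"`, `"inverse_normal"`); the default applies none.
* The weak-instrument regime is diagnosed (F reported, strict F > 10
  gate) but not corrected; at low F the estimator inherits the usual
  finite-sample bias of 2SLS.
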