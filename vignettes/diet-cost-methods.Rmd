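---
title: "Estimating the cost of adherence to the EAT-Lancet diet: methods"
author: "eatcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the cost of adherence to the EAT-Lancet diet: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatcost)
```

## The question and the analysis chain

`eatcost` estimates how daily diet cost changes with adherence to the
EAT-Lancet reference diet, from repeated 24-h dietary recalls linked to
a retail food-price database. The chain has five statistical stages,
each a module of the package:

1. **Pricing** (`build_price_table()`, `apply_yield()`,
   `fill_missing_prices()`, `cost_recalls()`): each food group gets a
   consumer price equal to total dollars sold divided by total
   kilograms sold, pooled over foods and stores. The pooled ratio *is*
   the sales-volume-weighted mean of item prices; an unweighted
   mean-of-prices variant is available behind a flag for sensitivity,
   since both readings of "averaged, weighted for sales volume" occur
   in practice. Purchased prices are converted to edible prices by
   dividing by a yield factor (loss < 1, cooking gain > 1; default 1
   because loss tables are instrument-specific). Unpriced groups are
   filled by an ordered fallback: mean price of priced siblings in the
   same category, then a manual price, then the global pooled price;
   the rule that fired is recorded as provenance. A recall day's cost
   is the price-weighted sum of its amounts.
2. **Index scoring** (`default_eat_i_spec()`, `score_total()`): the
   EAT-Lancet dietary index (EAT-I) has ten components worth 80 points
   in total - six 10-point and four 5-point components (dairy foods,
   red & processed meats, poultry & eggs, fish & plant-based proteins).
   Adequacy components score proportionally up to their target;
   moderation components score fully at or below target and decline
   linearly to an upper cut-off; optional components score fully inside
   a range and decline outside it. All cut-offs live in an editable
   YAML file seeded with the EAT-Lancet 2500-kcal reference targets, so
   users can align the engine with any published scoring table; the
   moderation upper cut-offs and optional outer cut-offs beyond the
   reference ranges are package defaults, not published constants.
   Whether to score nutrient densities (per 2500 kcal) or absolute
   intakes is a flag; density scoring is the default because the
   reference diet is defined for a 2500-kcal day. Population mean
   scores use the population ratio convention - score the weighted
   mean intake vector, not the mean of individual scores - with a
   participant-resampling bootstrap CI.
3. **Plausibility screening** (`classify_plausibility()`): mean
   reported energy intake is compared with the IOM predicted energy
   requirement at a lightly active activity level; the ratio is classed
   under/plausible/over outside a band of
   `sqrt(CV_within^2 / n_recalls + CV_pEER^2 + CV_TEE^2)` percent
   (1 SD by default; 8.2% is used for both the prediction-equation and
   the day-to-day expenditure CV, the latter the commonly used
   biological value). The within-person CV of energy is estimated from
   the recalls by a log-scale one-way variance decomposition - a
   deliberate simplification of a full univariate measurement-error
   fit, documented as such. Classification is diagnostic only; nobody
   is excluded downstream.
4. **Measurement-error correction** (`me_spec()`, `fit_me_model()`,
   `simulate_usual()`): single recall days are noisy; the quantity of
   interest is each person's usual (long-run average) intake and cost.
   Foods for which at least 10% of participants (weighted, inclusive
   threshold) report zero on their first recall are treated as
   episodic and get a two-part model: a probit consumption part with a
   person random effect, and a Box-Cox-transformed amount part with a
   person random effect. Daily variables - including energy and cost,
   always - get the amount part only. All person random effects are
   jointly multivariate normal with unstructured covariance; amount
   errors within a day are multivariate normal; day-level probit and
   amount errors are independent (their dependence is carried by the
   random effects). The model is fitted by Gibbs sampling with data
   augmentation (latent probit values; latent amounts on
   non-consumption days), stratified by sex, with recall-sequence and
   weekend (Friday-Sunday) indicators plus sociodemographics as fixed
   effects. Each Box-Cox lambda is chosen on a grid (default 0, 0.1,
   ..., 1; 0 means log) by the profile likelihood of observed positive
   amounts before the main run.
5. **Spline contrasts** (`spline_contrast()`, `subgroup_contrasts()`):
   usual cost is regressed on the restricted-cubic-spline basis of the
   usual score (knots at the 5th/35th/65th/95th weighted percentiles by
   default; 10th/50th/90th for skewed component distributions; a plain
   linear term for near-constant ones), with usual energy as the only
   optional covariate - cost tracks calories so closely that the
   energy-adjusted contrast is the economically meaningful one. The
   effect size is the fitted cost difference between the 75th and 25th
   percentiles of the score distribution. Confidence intervals come
   from 200 (default) bootstrap resamples of *participants* -
   pseudo-individuals are not independent observations and travel with
   their participant - re-running knot placement, fitting and
   percentile computation each time; the CI is a normal approximation
   on the bootstrap SE (percentile bounds behind a flag). A score whose
   75th and 25th weighted percentiles coincide is reported as skipped
   with a reason rather than fitted - this is what happens to
   components with almost no variation (in the motivating application,
   red and processed meats; in the default synthetic study, dairy).

## Usual-intake simulation and back-transformation

For each participant, `n_pseudo` (default 500) pseudo-individuals are
drawn from the stored posterior of the person random effects, together
with the matching fixed-effect and covariance draws. Each draw maps to
an original-scale usual intake via the second-order Taylor
back-transformation of the Box-Cox mean,

g^-1(t) + (sigma_w^2 / 2) * d2 g^-1 / dt2,

evaluated as a 4/7 weekday + 3/7 weekend mixture with the first-recall
indicator at zero and the remaining sequence indicators averaged over
recalls 2..K (the first recall is treated as the inflated one; averaging
the later recalls cancels their per-recall sampling noise). Episodic
usual intake is consumption probability times the usual
consumption-day amount. Pooled over pseudo-individuals, with weights
`balancing_weight / n_pseudo`, these draws estimate the population
distribution of usual intakes and costs.

Two documented approximations: the Taylor correction (rather than exact
integration) per the model's design, and block fitting for
high-dimensional runs - foods are fitted in blocks (default 6) with
energy and cost included in every block so each food's correlation
with energy and cost is preserved, while cross-block food correlations
are not. One structural caveat worth knowing: because energy and cost
are deterministic positive combinations of the foods, their within-day
errors are genuinely correlated with every food's, and on
non-consumption days the augmented latent amount borrows from that
day's (food-free) energy and cost. With realistically many foods the
effect is diluted; with very few variables it can visibly compress an
expensive episodic food's usual intake. This is a property of the
model class itself, not of the sampler.

## The synthetic study and its ground truth

No suitable recall-price data set is public, so the package ships a
generator whose defaults define a reference synthetic study: 1000
participants (500 at test scale) in 30 region x sex x age strata with
post-stratification balancing weights; 3 recalls over 3 weeks with a
1.06 first-recall inflation and a 1.10 weekend/weekday ratio (Friday
counted as weekend, weekend probability 3/7, multipliers centred so
the long-run mean equals the true usual intake); 15 food groups mapped
to the EAT-I components, roughly half episodic; correlated log-normal
usual intakes driven by a single "healthy, more expensive eater"
factor (vegetables, fruits, fish, nuts load positively and are dear;
free sugars and filler foods load negatively and are cheap; poultry
and eggs are cheap protein loading positively, which is what makes
their in-range component score move opposite to cost); person-level
under/over-reporting of all amounts (20% at x0.75, 15% at x1.25,
echoing commonly observed misreporting splits); and energy balance -
each person's true intake vector is rescaled so true energy equals
their predicted requirement times a log-normal equation-error
deviation (CV 8.2%). Without the energy-balance link the ratio of
reported energy to predicted requirement would carry an arbitrary
person-level offset and misreporting would be unidentifiable from any
sample; with it, the synthetic truth behaves like a population that
eats what it expends. Density-based index scores are invariant to that
whole-diet rescaling.

`oracle_truth()` prices the true usual intakes and scores them, so the
full pipeline can be compared against a known score-cost relationship;
`run_study()` reports both the estimated and the oracle contrasts.

What the generator does *not* emulate: real food lists (181 groups),
intake seasonality, store/region price differentiation, correlated
within-day food noises beyond the shared day multipliers, structural
never-consumers in the fitted model (the generator can create them;
the model absorbs them through the probit random effect), and
covariate-dependent intake distributions. Passing tests therefore
demonstrate internal validity of the machinery under a known truth,
not agreement with any real population.

## Numerical and design choices

* **MCMC defaults**: 5000 iterations, 2500 burn-in, thinning 5, at
  test scale; convergence is monitored by a split-chain potential
  scale reduction factor on the variance components, with a warning
  above 1.2. These lengths are engineering choices - the variance
  components of the model mix quickly at n = 500 - and are
  configurable.
* **Problem sizes in the shipped tests**: measurement-error recovery
  uses n = 500 participants, 3 recalls, one episodic plus two daily
  foods at moderate log-normal variability (sd 0.45 between and
  within, consumption probability 0.7) - conditions chosen so the
  quantities being recovered are identifiable from three recalls and
  the realized sample SD of a heavy-tailed lognormal is itself a
  stable target; the end-to-end study runs at n = 500 with 100
  pseudo-individuals and 50 bootstrap resamples; coverage of the
  bootstrap CI is assessed over 100 replicates of n = 300 against a
  reference contrast computed once from a 60 000-person draw.
* **Weighted percentiles** use a generalisation of type-7
  interpolation (positions `(cumw_i - w_i) / (W - mean(w))`) that
  reduces exactly to `quantile(type = 7)` under equal weights.
* **Imputation**: missing income and education are imputed *once* by
  chained multinomial models (10 cycles), matching the single-dataset
  convention of the motivating design; the resulting CIs do not
  propagate imputation uncertainty, a known understatement that
  multiple imputation would fix at the cost of a different inferential
  pipeline.
* **Degenerate inputs**: zero within-person variance collapses the
  posterior within-variance toward zero and returns person means;
  zero sales dispersion recovers prices exactly; all-identical
  participants give a zero bootstrap SE; amounts of zero are retained
  as episodic non-consumption days.
* **Known limitations**: no survey-design linearized variances (the
  bootstrap substitutes); no never-consumer sub-model; no
  covariate-dependent within-person variance; refitting the
  measurement-error model inside each bootstrap resample is supported
  in principle but off by default for cost, so the CIs condition on
  the fitted error model.

## A small worked run

```{r run, eval = FALSE}
cfg <- study_config(
  cohort = cohort_config(n_participants = 500, seed = 101),
  me_options = list(n_pseudo = 100,
                    mcmc = list(n_iter = 3000, n_burn = 1500, thin = 5)),
  n_boot = 50, seed = 101)
res <- run_study(cfg)
print(res)
res$overall     # P75 - P25 cost contrasts, with and without energy adjustment
res$components  # per-component contrasts (degenerate ones skipped)
res$oracle      # the same contrasts computed on the ground truth
```
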