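# eatcost

Does eating closer to the EAT-Lancet reference diet cost more? `eatcost`
implements the full analysis chain used to answer that question from
repeated 24-h dietary recalls linked to a retail food-price database,
for nutrition epidemiologists who have recall-level intake data and
food-group sales data and want a defensible, reproducible estimate of
the cost of adherence.

The chain:

* **Sales-weighted pricing** — each food group's consumer price is
  `sum(dollars sold) / sum(kg sold)` pooled over foods and stores,
  adjusted to edible weight by yield factors, with an ordered fallback
  hierarchy (category mean → manual price → global mean) for groups the
  price database does not cover. Recall amounts (kg) times prices give a
  daily diet cost per recall.
* **EAT-I scoring** — the EAT-Lancet dietary index: ten components,
  0–80 points, with adequacy (more is better), moderation (less is
  better) and optional (in-range is best) scoring curves declared in an
  editable YAML spec seeded with the EAT-Lancet 2500-kcal reference
  targets. Population means use the NCI population-ratio convention.
* **Plausibility screening** — reported energy vs IOM predicted energy
  requirement (lightly active), classified against the
  `sqrt(CV_wEI²/n + CV_pEER² + CV_TEE²)` band (Huang-style, ±1 SD).
* **Measurement-error correction** — a multivariate two-part
  (probit consumption + Box–Cox amount) mixed model for episodic and
  daily dietary variables, fitted by MCMC with data augmentation,
  stratified by sex; usual intakes and usual costs are simulated as
  pseudo-individuals (regression calibration in the NCI multivariate
  style, re-implemented from the published model class).
* **Spline contrasts** — weighted restricted-cubic-spline regression of
  usual cost on EAT-I (and component) scores; the effect size is
  Δcost between the 75th and 25th score percentiles, with participant-
  resampling bootstrap CIs, with/without energy adjustment, and by
  sociodemographic subgroup.

Because no recall–price data set of this kind is public, the package
ships a synthetic-cohort generator with fully known ground truth (true
usual intakes, true costs, a controllable score–cost relationship), and
the test suite validates every stage — including end-to-end recovery of
the true contrast — against it.

## Worked example

```r
library(eatcost)

cfg <- study_config(
  cohort = cohort_config(n_participants = 500, seed = 101),
  me_options = list(n_pseudo = 100,
                    mcmc = list(n_iter = 3000, n_burn = 1500, thin = 5)),
  n_boot = 50, seed = 101)
res <- run_study(cfg)
print(res)
```

```
Diet-cost study results
  n = 500 participants, 100 pseudo-individuals each
  mean EAT-I (population ratio): 53.4 (95% CI 52.5, 54.3)
  mean energy-adjusted cost: 9.68 $/2500 kcal
  misreporting: 17.9% under, 21.1% over
  P75-P25 cost contrast (not energy-adjusted): 1.35 $/d (95% CI 1.05, 1.64)
  P75-P25 cost contrast (energy-adjusted): 0.96 $/d (95% CI 0.82, 1.11)
```

Reading this: in the synthetic cohort, moving from the 25th to the 75th
percentile of EAT-Lancet adherence is associated with a 0.96 $CAD/d
higher diet cost at fixed energy intake. The oracle contrast computed
directly on the generator's ground truth is available for comparison:

```r
res$oracle
#      score_variable energy_adjusted delta_cost ci_low ci_high
#   eat_i_total_truth           FALSE       1.21   0.65    1.77
#   eat_i_total_truth            TRUE       1.07   0.83    1.31
```

so the estimated contrast (0.96, CI 0.82–1.11) recovers the true
energy-adjusted contrast (1.07) within its bootstrap uncertainty.
Component contrasts (`res$components`) show the expected structure:
positive for vegetables, fruits, fish & plant proteins and free sugars,
negative for the cheap-protein poultry & eggs component
(−1.04 $CAD/d in this run), and a skip with a logged reason for the
near-constant dairy component.

See `vignettes/diet-cost-methods.Rmd` for the model details, the
synthetic study design, and every numerical choice.

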