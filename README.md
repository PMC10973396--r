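# heterotic

Heterotic-group identification and Line × Tester evaluation for hybrid crop
breeding, built for panels that combine continuous agro-morphological traits
with binary SSR-marker and seed-protein band profiles (the running example is
a sunflower CMS/restorer breeding program).

## What it does

**Experiment 1 — find the groups.** A germplasm panel (one row per genotype:
line type CMS/B/R/SFP, nine traits, 0/1 band matrices) is integrated into a
single feature matrix: each trait column is optionally Yeo–Johnson
transformed (λ fitted by maximum likelihood on [−5, 5]) and then min–max
scaled,

> x′ = (x − x_min) / (x_max − x_min) ∈ [0, 1],

so continuous and binary features enter clustering with equal weight. Three
unsupervised algorithms, implemented from scratch, are compared:

- **Ward.D2** agglomeration — Lance–Williams recurrence on squared Euclidean
  distances, heights on the distance scale;
- **Lloyd k-means** with k-means++ initialization and best-of-n restarts;
- **hybrid hkmeans** — one deterministic Lloyd refinement started from the
  centroids of the Ward tree cut at k.

The tree cut at k = 2 gives the major populations (restorer vs CMS/B/SFP
material) and at k = 12 the heterotic groups; cluster purity against the
line types and the adjusted Rand index quantify each algorithm's resolution.
The genotype with the highest seed yield in each group (restricted to R
parents in the restorer population and CMS parents elsewhere) becomes that
group's representative in the crossing block.

**Experiment 2 — prove the groups work.** Representatives are crossed in a
full Line × Tester design (l × t F1s). For every cross and trait the package
computes mid-parent and better-parent heterosis,

> MPH% = 100 (F1 − MP) / MP, MP = (P1 + P2)/2
> BPH% = 100 (F1 − BP) / BP, BP = max(P1, P2),

and Kempthorne-style combining ability from the cross means:
g_i = ȳ_i·· − ȳ···, g_j = ȳ·j· − ȳ···, s_ij = ȳ_ij· − ȳ_i·· − ȳ·j· + ȳ···,
with the randomized-block Line × Tester ANOVA, standard errors
(SE(g_line) = √(MSE/rt), SE(g_tester) = √(MSE/rl), SE(s) = √(MSE/r)) and
t-based stars when replicated plot data supply an error variance.

A synthetic-data module generates panels with planted 2-population × 6-group
structure and trials with known (μ, g, s, σ), so every stage is testable
offline, and a published 12-parent / 36-hybrid sunflower mean table ships as
an embedded fixture.

## Worked example

```r
library(heterotic)

fx <- sunflower_fixture()
ht <- heterosis_table(fx$parents, fx$hybrids, fx$design)
dplyr::arrange(dplyr::filter(ht, trait == "SYP"), dplyr::desc(mph))
#> # A tibble: 36 × 11
#>   cross                   f1    mp    bp   mph   bph
#> 1 RHP-41 × CMS-HAP-111  99.4  42.4  56.8  135.  74.9
#> 2 RHP-71 × CMS-HAP-12   98.9  43.9  57.0  125.  73.4
#> 3 RHP-71 × CMS-HAP-54  103.   46.8  62.8  121.  64.5
```

The top seed-yield cross (RHP-41 × CMS-HAP-111) out-yields its mid-parent by
134.69% and its better parent by 74.93% — strong hybrid vigor between the
restorer and CMS groups. Combining ability from the same means:

```r
sub <- setNames(ht[ht$trait == "SYP", c("line", "tester", "f1")],
                c("line", "tester", "value"))
fit <- combining_ability(sub)
dplyr::arrange(tidy(fit), dplyr::desc(gca))
#> 1 RHP-71     tester 20.4   NA unavailable
#> 2 RHP-41     tester  6.53  NA unavailable
#> 3 CMS-HAP-12 line    6.43  NA unavailable
```

RHP-71 is the strongest general combiner for seed yield; `significance` is
`unavailable` because a means-only table carries no error variance — supply
replicated plot data (`trial_data()` / `generate_lxt_trial()`) to get the
ANOVA and stars. The full workflows are one call each:
`run_grouping(config, out_dir)` and `run_evaluation(config, out_dir)`, driven
by a YAML/JSON config; see `vignette source in vignettes/` for the methods.

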