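---
title: "Heterotic grouping and Line x Tester evaluation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterotic grouping and Line x Tester evaluation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterotic)
```

## The problem

Hybrid breeding in crops with cytoplasmic male sterility (sunflower here)
needs *heterotic groups*: clusters of genotypes such that crosses *between*
groups show strong hybrid vigor while crosses *within* a group do not.
Assembling groups by pedigree is slow; this package instead clusters a
germplasm panel on everything measurable at the line stage — continuous
agro-morphological traits plus binary SSR-marker and seed-protein band
profiles — and then validates the grouping the only way that counts: by
making the crosses and measuring heterosis and combining ability.

The panel model is deliberately simple. A genotype is a row with a line
type (CMS female, B maintainer, R restorer, SFP open-pollinated), nine
trait values (DFI, DFC days; PH, LA, HD, SC in cm/cm²; LP count; HSW, SYP
in g), and presence/absence calls for each scored SSR and protein band.
Validation is strict: unique ids, strictly binary band matrices, no missing
traits (an explicit `impute = "column mean"` switch exists but is off,
because group means published for such panels are complete).

## Feature integration

Traits, SSR bands and protein bands are concatenated into one matrix with
every column in [0, 1]:

1. *(optional, default on)* each trait column is Yeo–Johnson transformed,
   \(\psi(x,\lambda)\), with \(\lambda\) fitted by maximizing the Gaussian
   profile log-likelihood (including the Jacobian term
   \((\lambda-1)\sum \mathrm{sign}(x)\log(|x|+1)\)) over \([-5, 5]\). The
   search is a 101-point grid followed by golden-section refinement inside
   the bracketing interval, which protects against locally flat or
   multimodal profiles; a 10001-point grid oracle in the tests confirms the
   optimum to \(10^{-3}\).
2. each trait column is min–max scaled, \((x - x_{\min})/(x_{\max} -
   x_{\min})\). Binary columns are left untouched — their endpoints are
   already 0 and 1, and power-transforming indicators is meaningless.

Two choices deserve a note:

- **Order of operations.** Yeo–Johnson before min–max. The transform
  symmetrizes skewed traits (plant height, leaf area and yield are
  right-skewed in practice) so that the subsequent range compression is not
  dominated by one long tail; running min–max only is exposed as
  `yeo_johnson = FALSE` and is what the clustering tests use when they need
  an exactly reproducible linear map.
- **Constant columns** map to 0 with a warning rather than being dropped.
  Dropping would silently renumber columns and break the provenance
  bookkeeping (`trait` / `ssr` / `protein` tags kept per column).

No column weighting is applied: with 9 trait and ~54 band columns the band
blocks dominate distances, which matches the intent of integrating
molecular and biochemical evidence rather than letting phenotype alone
drive the grouping.

## Clustering engines

All three algorithms are first-class implementations in this package, not
wrappers, because their agreement and disagreement is the analysis:

- **Ward.D2**: Lance–Williams recurrence on *squared* Euclidean distances,
  \[
  D^2(i\cup j, k) = \frac{(n_i+n_k)D^2(i,k) + (n_j+n_k)D^2(j,k) - n_k D^2(i,j)}{n_i+n_j+n_k},
  \]
  merging the global-minimum pair at each step and recording the height
  \(\sqrt{D^2}\) (distance scale). Ties are broken towards the pair whose
  smallest member indices are lexicographically least — an arbitrary but
  documented and deterministic rule. Tests verify the merge sequence and
  heights against an exhaustive oracle that recomputes the Ward criterion
  \(2\frac{|A||B|}{|A|+|B|}\lVert \bar a - \bar b\rVert^2\) from raw
  coordinates at every step, and against `stats::hclust(method =
  "ward.D2")`.
- **k-means**: Lloyd iterations with k-means++ initialization from a seeded
  generator, best WSS over `n_init` restarts, convergence on unchanged
  labels or 300 iterations. An emptied cluster is re-seeded at the point
  farthest from its assigned center — deterministic given the state.
- **hybrid hkmeans**: cut the Ward tree at k, take per-cluster centroids,
  run a single Lloyd refinement from them. No randomness, and the refined
  WSS can never exceed the WSS of the initializing partition (Lloyd is
  monotone), which the tests assert on every run.

Distances are Euclidean on the integrated [0, 1] matrix — the only metric
under which the Ward criterion is a within-cluster variance. Tree cutting
supports both `k` (undo the k−1 highest merges) and height mode (undo
merges above h); the canonical grouping run uses k-mode (k = 2 major,
k = 12 fine) because dendrogram heights depend on the preprocessing scale
while the group count is the analyst's actual decision. Labels are numbered
by first-leaf order so repeated runs are bit-identical.

Resolution of a clustering is scored two ways: *purity* against the known
line types (how cleanly the algorithm isolates CMS/B/R/SFP material) and
the adjusted Rand index between partitions. In both simulated panels and
the motivating use case, the hierarchical tree has the highest resolution —
k-means at k = 2 recovers the major split but cannot subdivide it, and the
hybrid refinement can shuffle borderline genotypes across group boundaries.

## From groups to crosses

The tree cut at k = 2 and k = 12 yields nested major/sub labels (nesting is
structural for cuts of one tree; the code still verifies it). One
representative per sub-cluster is selected by maximum seed yield (SYP),
with eligibility restricted per major cluster: the restorer-dominated
cluster may only contribute R parents, the other only CMS parents. This
restriction is this package's explicit resolution of an ambiguity — a
sub-cluster's top yielder may be a B or SFP line that cannot enter a
CMS × R crossing block — and it is configurable. Trait ties break to the
lexicographically smaller id (logged in the design docs, asserted in
tests). Representatives then form a full factorial Line × Tester design,
rendered `"TESTER × LINE"`.

## Heterosis

For each cross and trait, with parent means \(P_1, P_2\) and F1 mean
\(F_1\):
\[
\mathrm{MPH} = 100\,\frac{F_1 - (P_1+P_2)/2}{(P_1+P_2)/2},\qquad
\mathrm{BPH} = 100\,\frac{F_1 - \max(P_1,P_2)}{\max(P_1,P_2)}.
\]

**The better parent is the larger mean, regardless of trait polarity.**
For flowering traits a *low* value is agronomically better, yet published
heterobeltiosis tables for such designs reconcile only under the
max-parent convention; the package follows it and leaves agronomic
interpretation (negative BPH is desirable for DFI/DFC/PH) to the analyst.
Consequences: \(\mathrm{BPH} \le \mathrm{MPH}\) whenever parents are
positive, both statistics are symmetric in the parents, and both are
undefined at MP = 0 or BP = 0 (an error, not NA — a zero parent mean in
these traits is a data problem).

Significance uses the standard line-by-tester variances of the contrasts:
\(t_{MP} = (F_1 - MP)/\sqrt{3\,\mathrm{MSE}/2r}\) and
\(t_{BP} = (F_1 - BP)/\sqrt{2\,\mathrm{MSE}/r}\) against the t distribution
on the error df, starred at 0.05 (*) and 0.01 (**). A 10,000-replicate null
simulation in the acceptance suite (true F1 = true MP, known \(\sigma^2\),
r = 3) confirms the type-I error sits in [0.04, 0.06]. With means-only
input there is no error variance; annotation is skipped with a warning
rather than guessed.

Report tables round to 2 decimals; all internal computation keeps full
precision. When recomputing a published heterosis table from its published
means, entries can disagree in the last digit when the source authors
rounded their means for print after computing heterosis from unrounded
values — the concordance check in the tests therefore counts entries within
±0.15 rather than demanding digit equality, and finds ~99% agreement on the
embedded fixture.

## Combining ability

From the l × t table of cross means (averaged over r replications):
\(g_i = \bar y_{i\cdot\cdot} - \bar y_{\cdots}\),
\(g_j = \bar y_{\cdot j\cdot} - \bar y_{\cdots}\),
\(s_{ij} = \bar y_{ij\cdot} - \bar y_{i\cdot\cdot} - \bar y_{\cdot j\cdot} + \bar y_{\cdots}\).
These satisfy, to numerical identity: \(\sum_i g_i = \sum_j g_j = 0\), both
margins of \(s\) are zero, and every cell reconstructs exactly as
\(\bar y_{ij\cdot} = \bar y_{\cdots} + g_i + g_j + s_{ij}\). The
randomized-block ANOVA partitions SS into replications, crosses (further
into lines, testers, line × tester) and error by subtraction, with F tests
against the error mean square; on noiseless data the subtraction can leave
a residue of order machine epsilon, which is clamped at zero. Standard
errors follow \(\sqrt{\mathrm{MSE}/rt}\), \(\sqrt{\mathrm{MSE}/rl}\),
\(\sqrt{\mathrm{MSE}/r}\) with difference SEs \(\sqrt2\) larger. Effects
are estimated from cross means only — no parental or reciprocal entries —
the standard Line × Tester model. When only a mean table exists,
effects are computed and significance is reported as `"unavailable"`;
the package never invents an error variance. The proportional
contributions of lines, testers and their interaction to the crosses SS
are always reported; the Baker-style ratio is deliberately left to the
analyst since it adds no information beyond those proportions.

## What the synthetic generator does and does not emulate

`generate_panel()` plants a two-level structure chosen to mirror the
analysis assumptions: 109 genotypes by default (~28% restorers, the rest
CMS/B/SFP in equal shares), restorers all in major population 1, everything
else in population 2, six sub-clusters per population filled round-robin.
Trait centres are Normal draws at two scales — major populations separated
at \(2\delta\) within-cluster SDs, sub-clusters at \(\delta\) (default
\(\delta = 6\), a separation at which a practitioner would call the groups
visually distinct) — and each of the 40 SSR + 14 protein columns follows a
two-level Bernoulli pattern: one 0/1 pattern per population, flipped per
sub-cluster with probability 0.1, sampled per genotype at frequency
\(0.5 \pm \varepsilon\) (default \(\varepsilon = 0.4\), i.e. 0.1/0.9 —
strongly but not perfectly diagnostic bands). At \(\delta = 0,
\varepsilon = 0\) the generator degenerates to pure noise and clustering
recovers nothing (ARI ≈ 0), which the tests also assert.

Not emulated: trait–trait covariance within clusters (a hook exists but no
published covariance information would anchor it), multi-allelic SSR loci
(one column per marker), linkage, and the field-trial noise structure of
augmented designs. Passing the recovery tests therefore shows the
algorithms work *under the stated structure*, not that any real panel has
that structure.

`generate_lxt_trial()` draws \(y_{ijk} = \mu + g_i + g_j + s_{ij} + b_k +
e_{ijk}\) with Normal block and residual effects; truth objects are
centered on construction so the generating effects are identifiable, and at
\(\sigma = 0\) estimation recovers them exactly.

## Problem sizes and numerical choices

The test and acceptance suites run, as the package's own verification
scale: 50 seeded point sets (n ≤ 8) against the exhaustive Ward oracle;
20 random 3×3×2 trials against a definition-level ANOVA oracle at 1e-9
relative; 500 seeded 6×6×3 trials at \(\sigma = 5\) for unbiasedness
(within 3 Monte-Carlo SEs); 20 panel seeds for 12-group recovery (mean
ARI ≥ 0.9); and 10,000 null replicates for the t-test calibration. Key
numerical decisions: squared-distance clipping at zero in the Euclidean
kernel (floating-point cancellation), deterministic tie-breaks everywhere
(agglomeration pairs, k-means++ via seeded RNG, representative selection by
id), error-SS clamping at zero, and full-precision storage with rounding
only at the reporting layer.

## Known limitations

- Ward height inversions cannot occur for Euclidean input, but non-metric
  user-supplied distance matrices may produce them; heights are reported as
  computed and a decreasing sequence is the caller's signal to distrust
  height-mode cuts.
- The purity score favours many small clusters; it is reported alongside k
  and should be compared at equal k (the run report does).
- Cross ids are plain strings (`"TESTER × LINE"`); reciprocal crosses are
  out of scope, as are diallel and partial-diallel designs.
- With means-only input the ANOVA, stars and SEs are unavailable by
  design; conclusions about significance then require the replicated data.
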