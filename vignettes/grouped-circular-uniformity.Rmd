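---
title: "Testing circular uniformity on grouped angular data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing circular uniformity on grouped angular data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circtb)
```

## The problem

The most common inferential step with a sample of directions
$\phi_1, \dots, \phi_n \in [0, 2\pi)$ is to test the null hypothesis of
circular uniformity: constant density around the circle, no preferred
direction. The classical tests assume the angles are continuously
distributed. Field data almost never are: compasses are read to the nearest
5 or 10 degrees, video tracking is binned, activity times are recorded to
the hour. Grouped data live on a grid of $m$ evenly spaced values
(commonly $m = 36$), and once $n$ approaches or exceeds $m$, exact ties
between observations become frequent.

Ties are poison for tests built on the *spacings*
$$T_i = \begin{cases}\phi_{(i+1)} - \phi_{(i)} & i < n\\
2\pi - \phi_{(n)} + \phi_{(1)} & i = n,\end{cases}$$
the arc lengths between circularly adjacent sorted points
(`circ_spacings()`), because a tie is a spacing of exactly zero — an event
of probability zero under a continuous null, which the test therefore reads
as evidence against uniformity. The practical consequence is an inflated
type-I error rate that grows with $n$: in the package's own simulation
(`type1_experiment()`, $m = 36$, $n = 50$), the standard Rao spacing test
rejects a true uniform null far more than half the time at a nominal 5%
level.

## The tests

`circtb` implements seven statistics (`circ_statistics`):

* **Rayleigh**: the mean resultant length
  $\bar R = |\sum_i e^{i\phi_i}|/n$. Its standard p-value is the
  closed-form series approximation
  $p \approx e^{-S}\bigl[1 + \tfrac{2S - S^2}{4n} -
  \tfrac{24S - 132S^2 + 76S^3 - 9S^4}{288 n^2}\bigr]$ with
  $S = n\bar R^2$, clamped into $(0, 1]$.
* **Kuiper**: $V_n = \sqrt{n}(D^+ + D^-)$ on $u_i = \phi_{(i)}/2\pi$, and
  **Watson**: $U^2 = \sum_i (u_i - \tfrac{2i-1}{2n})^2 -
  n(\bar u - \tfrac12)^2 + \tfrac{1}{12n}$ — the rotation-invariant
  EDF tests, in their classical forms so that published critical-value
  tables apply (`kuiper_pvalue_bounds()`, `watson_pvalue_bounds()` report
  the traditional "p > 0.15"-style range statements).
* **Rao spacing**: $U = \tfrac12 \sum_i |T_i - 2\pi/n|$, and **Gini**:
  $G_n = \tfrac{2}{n(n-1)}\sum_{i<j}\tfrac12|nT_i - nT_j|$, the
  spacing-based pair. $G_n$ is computed through the sorted-spacings
  identity $G_n = \tfrac{1}{n-1}\sum_k (2k - n - 1)\,T_{(k)}$, which is
  algebraically equal to the double sum (the equivalence is tested to
  $10^{-10}$ against a literal double-loop evaluation).
* **Hermans–Rasson**:
  $V = \tfrac1n\sum_i\sum_j\bigl(\bigl||\phi_i-\phi_j| - \pi\bigr| -
  \tfrac{\pi}{2} - 2.895(|\sin(\phi_i-\phi_j)| - \tfrac{2}{\pi})\bigr)$,
  over all pairs including $i = j$.
* **chi-squared**: Pearson $X^2$ on the $m$ bin counts against equal
  expectations $n/m$, df $= m - 1$, no continuity correction; refused for
  $n \le 5$.

All six circular statistics are rotation-invariant and deterministic;
the suite checks both properties and validates each against a brute-force
evaluation of its defining formula.

## Monte-Carlo p-values and the tie-breaking modification

Except for Rayleigh (closed form) and chi-squared, p-values come from
simulation: draw $N_R$ null samples of size $n$, count the number $N_e$
whose statistic equals or exceeds the observed one, and report
$$p = \frac{N_e + 1}{N_R + 1},$$
the standard valid permutation construction ($p \ge 1/(N_R+1)$; ties count
toward $N_e$). The default is $N_R = 10{,}000$.

The **tie-breaking (TB)** variant (`tb_test()`) addresses grouping by
adding a tiny independent von Mises$(0, \kappa)$ perturbation to every
angle — observed and simulated — before the statistic is evaluated, with
wrap-around back into $[0, 2\pi)$. The default $\kappa = 1000$ gives noise
with a circular SD of about $1.8°$, far below a $10°$ grouping resolution,
so ties break while the ordering of distinct grouped values is essentially
never disturbed. $\kappa$ should always be chosen so the noise is much
smaller than the data's rounding granularity.

### The TB null pipeline

A design question with real consequences is what the TB null samples
should look like. Two candidates:

1. continuous uniform, then perturb;
2. continuous uniform, **group to $m$ values**, then perturb.

We implement (2): the null must mirror the pipeline that produced the
observed data, and perturbed-grouped data are *not* distributionally
equivalent to perturbed-continuous data for spacing statistics. Both
options were measured during development: under (1), TB Rao and TB Gini on
grouped uniform data ($m = 36$, $n = 50$) reject at about 10% instead of
5%, while under (2) every TB test holds $5\% \pm 1.5\%$ across
$n \in \{5, \dots, 50\}$ (the acceptance suite re-runs this check). When
no grouping resolution is recorded the TB null assumes $m = 36$, the most
common field resolution; on truly continuous data this makes the TB tests
mildly conservative at large $n$ (they "correct" for bins that are not
there) and near-nominal at small $n$. TB
tests are for grouped data; on continuous data the standard variants are
preferable, and `variant = "auto"` in `circ_uniformity_test()` makes that
switch on the presence of ties or grouping metadata.

### Reproducibility and realization variance

Every stochastic function takes a `seed`; a seeded result is bit-for-bit
reproducible, including $N_e$. One subtlety deserves emphasis: a TB
p-value on tied data is itself a random quantity through the *single*
perturbation of the observed sample, with spread well beyond the binomial
$\sqrt{p(1-p)/N_R}$: two seeded TB runs (or two labs) can legitimately
differ in the second decimal place. Report the seed, $N_R$ and $\kappa$
alongside any TB p-value. The statistics themselves and the closed-form p-values carry no
such variance.

## The worked example

The built-in `pigeon_bearings` (13 homing-pigeon vanishing bearings,
rounded to the nearest 5°, visibly bimodal north/south) exercise every
code path:

```{r}
pigeon_example(n_reps = 10000, seed = 1)
```

The Rayleigh test sees nothing (p = 0.555) because near-antipodal data
have a tiny resultant; the Hermans–Rasson and spacing-based tests detect
the bimodality. The 72-bin chi-squared p-value, 0.046, is deterministic.
With only one tied pair in the data, standard and TB p-values differ
little here.

## The simulation harness

`type1_experiment()` and `power_experiment()` run the full factorial:
(test, variant) × distribution × sample size × grouping. Defaults are
desk-scale — 2,000 datasets and $N_R = 2{,}000$ per cell with sample sizes
$\{5, 10, 15, 25, 50\}$ — chosen so the whole type-I battery runs in
seconds while keeping the binomial SE of a 5% rejection rate at about
0.5 points; both counts are configurable upward (10,000/10,000 reproduces
a full-scale run). Two accelerations matter:

* **Shared nulls.** Within a cell, every dataset has the identical null
  pipeline, so one simulated null distribution of the statistic
  (`null_statistics()`) is computed per cell and reused for all its
  p-values. Rejection-rate estimates are unchanged in expectation
  (verified against per-dataset fresh nulls in the suite);
  `share_null = FALSE` disables the sharing at ~`n_datasets`-fold cost.
* **Vectorized statistics.** All statistic evaluations inside the engine
  run column-wise over matrices of samples; the suite pins the vectorized
  results to the scalar implementations.

Per-cell seeds are derived from the master seed by hashing the cell
coordinates, so any cell can be reproduced in isolation.

### The alternative panel

`study_distributions()` provides the 12 alternatives used for power:
von Mises ($\kappa = 1$), wrapped skew normal (dispersion 1, skewness 30,
via Azzalini's representation wrapped onto the circle), symmetric and
asymmetric bimodal von Mises mixtures ($\kappa = 5$; modes 0°/180° and
0°/120°), symmetric and asymmetric trimodal mixtures ($\kappa = 10$;
0°/120°/240° and 0°/90°/200°), cardioid ($\rho = 0.3$, rejection
sampling), Kato–Jones ($r = 0.7$, $\kappa = 2.3$, as a Möbius transform of
a von Mises draw with $\mu = \nu = 0$), triangular ($\rho = 0.3$, analytic
inverse-CDF), wrapped Cauchy ($\rho = 0.7$), wrapped normal and wrapped
stable (scale 1, index 0.3, skewness 1, Chambers–Mallows–Stuck in the
1-parameterization, wrapped). The wrapped normal's dispersion is not
pinned down by the study design; we set $\sigma = \sqrt{-2\log 0.7}$ so
its resultant length is 0.7, matching the wrapped Cauchy scenario for
comparability. Von Mises draws use the exact Best–Fisher rejection
algorithm. Generators with a closed-form resultant length (von Mises,
wrapped Cauchy, wrapped normal, cardioid, triangular) are calibrated
against it at $n = 10^5$ in the suite; the Kato–Jones and wrapped-stable
generators, whose reference implementations are external, are validated
structurally (support, determinism, mean direction, agreement with an
independently coded CMS formula).

### What the synthetic data do and do not show

The generator panel emulates clean i.i.d. draws from smooth densities,
grouped by exact rounding. Real data additionally carry serial dependence
(consecutive bearings of one animal), heterogeneous rounding (mixed 5° and
10° records), heaping on salient values (0°, 90°, ...) and measurement
error beyond rounding. Passing the type-I and power checks here therefore
demonstrates correctness of the *procedures* under the stated sampling
models, not robustness to those further violations; heaping in particular
is a non-uniformity a TB test will rightly detect.

## Numerical choices and degenerate inputs

* Internal unit is radians on $[0, 2\pi)$; degrees are converted at I/O
  boundaries only. Wrapping uses `%%` with a fold of the exact-$2\pi$
  edge case back to 0.
* Grouping rounds half-up at bin midpoints (15° with $m = 36$ goes to
  20°), with a $10^{-9}$-bin guard so that values that are midpoints in
  exact arithmetic but fall a few ulps short after degree-to-radian
  conversion still round up. The choice is conventional; it affects only
  a measure-zero set of continuous inputs.
* A single angle is a valid sample (`circ_sample`) but has no spacing
  structure: spacing- and EDF-based tests refuse $n < 2$ with a clear
  error. Ties are legal everywhere; zero spacings are exactly what the TB
  machinery exists to handle. The chi-squared test refuses $n \le 5$.
* With 36 bins and $n \le 25$ the chi-squared expected counts drop below
  one and the asymptotic reference distribution makes the test
  conservative (observed type-I ≈ 3%); it does not inflate. This is a
  property of the binned-count test itself, not of the grouping problem.
* The Rayleigh series p-value is clamped into $(0, 1]$; at $\bar R = 1$
  the unclamped value underflows gracefully.
* `findInterval` on the sorted shared null counts strict predecessors, so
  simulated values exactly equal to the observed statistic count toward
  $N_e$, matching the "equal to or greater" rule.

## Known limitations

* TB p-values on heavily tied data carry perturbation-realization
  variance (see above); there is no averaging over perturbations, by
  design — the procedure is the published one.
* Axial (period-$\pi$) data, weighted observations and density/CDF/fitting
  for the generator families are out of scope.
* Table-bound p-values are provided for Kuiper and Watson only, at the
  tabled levels; everything else is Monte-Carlo or closed-form.
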