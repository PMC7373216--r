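# circtb

Tests of circular uniformity that stay honest on grouped angular data.

## The problem

Directional measurements in biology — orientation bearings, vanishing
directions, activity times — are routinely rounded to the nearest 5 or 10
degrees, so the recorded angles live on a grid of *m* evenly spaced values
and contain exact ties. The classical tests of the null hypothesis of
circular uniformity assume continuously distributed angles. For tests
built on the spacings *T<sub>i</sub>* between circularly adjacent sorted
points — Rao's spacing test *U* = ½ Σ |T<sub>i</sub> − 2π/n| and the Gini
spacing test *G<sub>n</sub>* = (2/(n(n−1))) Σ<sub>i&lt;j</sub> ½|nT<sub>i</sub> −
nT<sub>j</sub>| — a tie is a zero spacing, impossible under a continuous
null, and the type-I error rate inflates dramatically as *n* grows (above
50% at *n* = 50 for data rounded to 10°).

`circtb` provides:

* the **Rayleigh** (closed-form series p-value), **Kuiper**, **Watson**,
  **Rao spacing**, **Gini** and **Hermans–Rasson** tests, plus a
  **chi-squared** baseline on bin counts;
* Monte-Carlo p-values *p* = (N<sub>e</sub> + 1)/(N<sub>R</sub> + 1) from
  simulated null samples;
* the **tie-breaking (TB)** variant of each simulated test: tiny von
  Mises(0, κ = 1000) perturbations added to observed and simulated angles
  (null samples grouped to the data's resolution first), which restores
  type-I error control on grouped data at negligible power cost;
* seeded generators for 12 alternative circular distributions and a
  simulation harness measuring type-I error and power across tests,
  variants, sample sizes and grouping resolutions.

## Worked example

Thirteen homing-pigeon vanishing bearings (degrees from North, rounded to
the nearest 5°, clustering near North and South) ship with the package:

```r
library(circtb)
pigeon_example(n_reps = 10000, seed = 1)
```

```
Homing-pigeon vanishing bearings (n = 13), N_R = 10000, kappa = 1000, seed = 1
reference_p: values reported for this dataset in the literature

       test  variant statistic p_value    p_method reference_p
1  rayleigh standard    0.2156 0.55542 closed_form      0.5550
2    kuiper standard    1.4176 0.17158 monte_carlo          NA
3    watson standard    0.1361 0.13479 monte_carlo          NA
4       rao standard    2.8261 0.07719 monte_carlo          NA
5      gini standard    4.0433 0.04120 monte_carlo      0.0440
6        hr standard   10.3241 0.00430 monte_carlo      0.0034
7     chisq standard   92.2308 0.04604 closed_form      0.0460
8    kuiper       tb    1.4543 0.14379 monte_carlo      0.1620
9    watson       tb    0.1325 0.14009 monte_carlo      0.1380
10      rao       tb    2.7754 0.09859 monte_carlo      0.0685
11     gini       tb    4.0834 0.03650 monte_carlo      0.0480
12       hr       tb   10.2008 0.00490 monte_carlo      0.0039
```

The data are bimodal, so the Rayleigh test — blind to symmetric multimodal
structure because the mean resultant length of near-antipodal data is ~0 —
finds nothing (p = 0.555), while the Hermans–Rasson test (p ≈ 0.004) and
the spacing-based tests do. Monte-Carlo and TB p-values match the
reference values up to simulation error; TB p-values additionally vary
with the perturbation draw (the seed is part of the result).

Testing your own data:

```r
x <- read_angles("bearings.txt", units = "degrees")
circ_uniformity_test(x, "rao", variant = "auto", seed = 1)
```

`variant = "auto"` switches to the TB form whenever ties or a grouping
resolution are present. A thin command-line wrapper with `test`, `study`
and `example` subcommands is installed at `inst/cli/circtb`.

Simulation study (type-I error of every test on 10°-grouped data):

```r
res <- type1_experiment(study_config(seed = 1))
subset(res, n == 50 & test %in% c("rao", "rayleigh"))
#>        test  variant distribution  n grouping_m rejection_rate n_datasets seed
#> 53 rayleigh standard      uniform 50         36         0.0565       2000    1
#> 56      rao standard      uniform 50         36         0.8845       2000    1
#> 59 rayleigh       tb      uniform 50         36         0.0370       2000    1
#> 62      rao       tb      uniform 50         36         0.0535       2000    1
```

The standard Rao test rejects a true uniform null 88% of the time at the
nominal 5% level once the data are grouped; its TB version (and the
standard Rayleigh test) sit at 5%.

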