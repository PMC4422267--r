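# spikefill

Differential miRNA expression and grain-filling kinetics in superior and
inferior rice spikelets.

Rice panicles fill their grains unevenly: spikelets on apical primary
branches (*superior*) flower early and fill fast, those on proximal
secondary branches (*inferior*) fill late and slowly, producing lighter,
partially plump grain. Small-RNA sequencing of the two spikelet types at
five grain-filling stages (10, 15, 21, 27, 35 days after flowering; one
library per condition and stage) asks which miRNAs differ between spikelet
classes, which novel-miRNA candidates are credible, and how expression
dynamics relate to the filling kinetics. `spikefill` implements that
analysis as a tested, reusable R pipeline for anyone working with
two-library small-RNA count designs and growth-curve phenotypes.

## What it computes

**Exact two-library count test.** With one library per condition, the test
for a miRNA with `x` tags (superior, total clean reads `N1`) and `y` tags
(inferior, `N2`) is the exact conditional probability

```
p(y|x) = (N2/N1)^y * (x+y)! / (x! y!) * (1 + N2/N1)^-(x+y+1)
```

evaluated in log space, with lower/upper tail p-values and a two-sided
p-value that doubles the smaller tail. For fixed `x` this is the
negative-binomial pmf `NB(x+1, N1/(N1+N2))`; the test suite verifies the
implementation against exact rational arithmetic to better than 1e-10
relative error for all `x, y <= 100`.

**Normalization and filters.** Counts are scaled to TPM by each library's
total clean reads; exact zeros are floored at 0.01 TPM; miRNAs never
strictly above 10 TPM are excluded from differential analysis. A comparison
is *differential* when `|log2(inferior/superior)| > 1` with `0.01 <= p <=
0.05`, *significant* when `p < 0.01`. Cross-stage consistency uses a
two-tailed paired t-test over the five stages.

**Novel miRNA criteria.** A candidate is accepted with evidence **H**
(> 50 TPM somewhere), **F** (detected in at least half the libraries) or
**S** (miRNA* passenger strand observed). The published 13-candidate table
ships as a fixture and is reproduced code-for-code.

**Logistic kinetics.** Grain weight follows `Y(t) = K / (1 + a e^(-bt))`;
`fit_logistic()` estimates `(K, a, b)` by Levenberg–Marquardt least squares,
and derived quantities include the rate curve `V(t) = dY/dt`, its peak
`Vmax = K b / 4` at `t = ln(a)/b`, time-to-completion and a rate-curve
asymmetry index.

**Synthetic generator.** `simulate_counts()` / `simulate_weights()` /
`simulate_targets()` emulate the full study design (negative-binomial
counts, 24-nt-dominant read lengths, logistic weight series, anti-coupled
target genes) with complete ground truth, so every stage is testable
offline.

## Worked example

```r
library(spikefill)

cfg  <- simulation_config(n_mirnas = 300, seed = 7)
sim  <- simulate_counts(cfg)
expr <- apply_floor(tpm_normalize(sim$counts, sim$meta))
kept <- abundance_filter(expr)$kept
de   <- stage_comparison(sim$counts[rownames(kept), ], sim$meta, expr = kept)
summarize_de(de)$per_stage
#>  stage_daf n_tested n_de n_differential n_significant n_higher_superior
#>         10      279   52             15            37                37
#>         15      279   45              6            39                34
#>         21      279   49             22            27                34
#>         27      279   32              9            23                22
#>         35      279   46             19            27                35
```

279 of 300 simulated miRNAs clear the 10-TPM filter; at each stage, roughly
a sixth are called differentially expressed (the `differential` and
`significant` classes together), and most of those sit higher in superior
spikelets (`log2_fc < 0`), as configured in the generator's ground truth.

A single comparison, explicitly — 12 vs. 58 tags in libraries of 153,731
and 176,320 clean reads:

```r
ac_pvalue(12, 58, 153731, 176320)
#>    p_lower      p_upper  p_two_sided
#>  0.9999999 2.315072e-07 4.630143e-07
```

The upper tail is tiny: 58 inferior tags are far more than library sizes
alone explain, so this miRNA would be called significantly higher in
inferior spikelets if its fold change also clears the two-fold gate.

Kinetics of the simulated superior-spikelet weight series:

```r
w   <- simulate_weights(cfg)
fit <- fit_logistic(w$daf[w$condition == "superior"],
                    w$weight[w$condition == "superior"])
fit
#> Logistic grain-filling fit
#>   K = 21.6815 mg, a = 56.3801, b = 0.3191 /day
#>   RSS = 1.37 mg^2 over 9 points, converged: TRUE
kinetics_summary(fit)
#>    t_peak    v_max t_completion mean_rate  asymmetry
#>  12.63677 1.729526     21.86473 0.9247589 0.08484417
```

The fit recovers the generating parameters (K = 22, a = 60, b = 0.32) from
nine noisy points: peak filling at ~12.6 DAF, maximum rate ~1.73 mg/grain/day,
95% filled by ~21.9 DAF.

The whole chain — simulate, normalize, test, summarize, kinetics, profiles,
JSON report — runs as one call:

```r
run_pipeline(pipeline_config(seed = 7), out_dir = "run1")
```

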