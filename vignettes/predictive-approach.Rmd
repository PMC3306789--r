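---
title: "The sequential predictive-interval criterion for differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sequential predictive-interval criterion for differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pade)
```

## The model

Let $x_{igh}$ be the $i$-th log-expression replicate of gene $g$ in condition
$h \in \{c, t\}$, with $n_c$ control and $n_t$ treatment replicates. The unit
of analysis is not the replicate matrix but the per-gene **mean treatment
effect**

$$Y_g = \bar x_{gt} - \bar x_{gc}, \qquad g = 1, \dots, n,$$

computed by `compute_treatment_effects()`. The $Y_g$ are modelled as an
i.i.d. sample from $\mathcal N(\mu, \sigma^2)$ with the conjugate
normal–inverse-gamma prior

$$\mu \mid \sigma^2 \sim \mathcal N(\mu_0, \sigma^2/\lambda), \qquad
  \sigma^2 \sim \mathcal{IG}(\tau/2, \beta/2).$$

Conjugacy gives a closed-form posterior with location
$\mu^* = \frac{n}{n+\lambda}\bar y + \frac{\lambda}{n+\lambda}\mu_0$,
degrees of freedom $\tau^* = \tau + n + 1$ and scale component
$\beta^* = \beta + (n-1)s^2 + \frac{n\lambda(\bar y - \mu_0)^2}{n+\lambda}$
(`posterior_update()`), and the predictive distribution of a new effect is a
location-scale Student-$t$ with variance

$$\mathrm{Var}(Y_{n+1} \mid \mathbf y) =
  \frac{\tau^*}{\tau^*-2}\cdot\frac{\beta^*(n+\lambda+1)}{\tau^*(n+\lambda)}$$

(`predictive_variance()`), defined for $\tau^* > 2$.

Two printed-form choices deserve a note, because the package follows them
deliberately:

* **$\tau^* = \tau + n + 1$.** The textbook conjugate update gives
  $\tau + n$. The extra unit is how the source method states its update, and
  all published calibration numbers were produced under it, so it is the
  default. With $n$ in the hundreds the difference is far below Monte-Carlo
  noise; `df_rule = "conjugate"` switches to the textbook variant for
  sensitivity analysis.
* **Interval half-width $= t_{1-\alpha/2,\tau^*}\sqrt{\mathrm{Var}}$.** The
  credibility interval is stated with the variance under the quantile
  multiplier without an explicit radical. A half-width must carry the units
  of $y$, so the only dimensionally coherent reading takes the square root
  of the predictive variance; `credibility_interval()` implements that
  reading.

## The sequential criterion

`pa_detect()` sorts the effects increasingly, $y_{(1)} < \dots < y_{(n)}$,
and visits them in that order. At step $g$ the **reference set** is every
effect except the current one and except all effects already called
differential. From the reference set it computes the predictive parameters,
forces the location to $\mu^* = 0$ (the posterior location is still reported
for diagnostics), and calls gene $g$ when

$$|y_{(g)}| > t_{1-\alpha/2,\tau^*}\sqrt{\mathrm{Var}(Y_{\text{new}} \mid \text{reference})}.$$

Called effects are removed from all later reference sets. The point of the
exclusion is robustness of the null model: as true positives are identified
and set aside, the reference spread converges to that of the null genes, so
the threshold is not inflated by the very signal it is trying to detect.
This is what gives the criterion its advantage when the treatment changes
the variance of expression (the $\gamma > 1$ regimes below), a situation in
which mean-difference $t$-statistics gain nothing.

Three design points were genuinely open and are resolved as follows:

* **The prior scale $\beta$ is computed once** from the full effect vector
  via `default_beta()` ($\beta = (\tau-2)R^2$ with $R$ the range of
  $\mathbf y$) and held fixed across steps. A prior that shrank as genes
  were called would let the data be used twice; the range rule is defined on
  the observed data as a whole.
* **Processing order.** Increasing numerical order is the stated order and
  the default. The sequential exclusion makes the order material, and an
  `"extremity"` order (decreasing $|y|$) is exposed as an alternative. A
  consequence worth knowing: the default criterion is **not** exactly
  invariant to a sign flip of $\mathbf y$. Each per-step quantity is even in
  the reference set, but negating $\mathbf y$ reverses the processing
  direction — the low tail is tested before any exclusions, the high tail
  after the other tail's calls have shrunk the reference set. The exact
  identity is `pa_detect(-y)` $\equiv$ `pa_detect(y, order = "decreasing")`,
  and the `"extremity"` order is exactly sign-flip invariant. In aggregate
  (rates over replicates) the direction effect is far below Monte-Carlo
  noise.
* **Single pass.** Genes not called at their own step are not revisited
  after later exclusions shrink the threshold; a fixed-point iteration would
  be a different (and more aggressive) procedure.

The implementation keeps running sums over the shrinking reference pool, so
a full pass over $n$ genes costs $O(n)$ posterior evaluations; the test
suite checks it bit-exactly against a from-scratch sequential oracle.

## Baseline tests

For comparison the package ships the three per-gene tests most commonly
applied to this problem, all two-sided at a working level $\alpha$:

* **Welch $t$** (`welch_t_test()`): unequal-variance statistic with
  fractional Welch–Satterthwaite degrees of freedom (no integer rounding).
* **Cyber-t** (`cyber_t_test()`): each condition variance is replaced by
  $\tilde\sigma^2_h = \frac{\nu_0\sigma_0^2 + (n_h-1)s_h^2}{\nu_0+n_h-2}$
  with $\nu_0 = 10 - n_g$ pseudo-observations ($n_g = n_c + n_t$; the
  $k=10$ rule) and prior variance $\sigma_0^2 = \frac{n_g-1}{n_g}s_g^2$, the
  biased variance of the gene's pooled two-condition values. Pooling across
  the condition split means a real mean difference inflates $\sigma_0^2$,
  which is why this per-gene variant is conservative (its null rejection
  rate runs near 0.03 at $\alpha = 0.05$, below the Welch test's 0.04).
  The window-based variant that pools neighbouring genes is out of scope.
  For $n_g \ge 10$ the rule would give $\nu_0 \le 0$; $\nu_0$ is floored at
  zero there, a case outside the benchmark grid.
* **Bayesian $t$** (`bayes_t_test()`): conjugate posterior-$t$ for the mean
  difference with $\nu_0 = n_g$, $\sigma_0^2 = s_g^2$ and
  $\nu_n\sigma_n^2 = \nu_0\sigma_0^2 + (n_c-1)s_c^2 + (n_t-1)s_t^2$,
  $\nu_n = \nu_0 + n_c + n_t - 2$.

## What the simulator emulates

`simulate_dataset()` draws control replicates from
$\mathcal N(\mu_c, \sigma_c^2)$ with defaults $\mu_c = -14$ and
$\sigma_c^2 = 0.8$ — the average observed log-scale mean and variance of the
control arrays of the *E. coli* nylon-membrane experiment the method was
developed on. A deterministic count of genes (exactly the rounded
percentages $p_{\text{over}}$, $p_{\text{under}}$ of $n$; only the subset
membership is random) receives treatment replicates from
$\mathcal N(\mu_c \pm \delta\sigma_c, (\gamma\sigma_c)^2)$: $\delta$ shifts
the mean in control standard deviations ($\sigma_c = \sqrt{0.8} \approx
0.894$; $\delta$ multiplies the s.d., not the variance) and $\gamma$
multiplies the standard deviation. All other genes draw treatment from the
control distribution. The benchmark grid (`scenario_grid()`) crosses
$n_c = n_t \in \{4, 8\}$, splits $(3,2), (7,3), (5,15)$ percent,
$\delta \in \{0, 0.25, \dots, 2\}$ and $\gamma \in \{1,2,3\}$ with $S = 100$
replicates per cell; the differential subset is redrawn each replicate.

The generator is deliberately idealised: Gaussian noise, equal per-gene
variance within a condition, no gene–gene correlation, no
intensity-dependent variance, and balanced replicate counts. A green
benchmark therefore establishes calibration and power **under the stated
model**, not robustness to the mean–variance trends or correlation
structure of real array or sequencing data. Conversely the per-gene
baselines make the same normality assumption, so the comparison is fair.

Seeding: a root seed spawns one congruentially mixed substream per
(scenario, replicate), all below $2^{31}$, so any single table cell — or any
single replicate — can be regenerated in isolation.

## Scoring

`score_calls()` computes, per replicate, the true-positive rate (called
among truly differential), false-positive rate (called among null) and
true-discovery rate (truly differential among called). `run_benchmark()`
runs every method on the *same* dataset within a replicate (a paired
design, shrinking Monte-Carlo variance of method contrasts) and averages
over replicates with Monte-Carlo standard errors. Replicates with zero
discoveries have no defined TDR and are dropped from the TDR mean — they are
rare everywhere on the grid. The FPR and TDR definitions are the standard
confusion-matrix ones; their internal consistency with the published
true-positive rates was checked via the accounting identity
discoveries $=$ TPR$\cdot n_{\text{true}}$ + FPR$\cdot n_{\text{null}}$.

## Numerical choices and degenerate inputs

* Sample variances use the $n-1$ denominator throughout.
* The incremental detector clamps a negative round-off variance at zero
  (reachable only when all reference effects are numerically equal).
* Ties in $y$ are broken by original gene index (stable sort) so runs are
  deterministic; ties are measure-zero under the model.
* `default_beta()` refuses constant effect vectors (range zero: prior scale
  undefined); the detector refuses a reference set smaller than 2 (reachable
  only when nearly every gene is called, e.g. under an absurdly small
  explicit $\beta$).
* Validation errors and numerical/degeneracy errors carry distinct condition
  classes, mapped by the CLI to exit codes 2 and 3.

## Defaults that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | tail probability | working level of all four methods |
| `tau` | 3 | — | smallest integer shape with a finite prior variance mean; weakly informative |
| `mu0` | 0 | log-expression difference | no prior preference for up- or down-regulation |
| `lambda` | $10^{-2}$ | pseudo-observations | prior on $\mu$ worth 1/100 of an observation |
| `beta` | $(\tau-2)R^2$ | squared effect units | prior mean of $\sigma^2$ equals the squared observed range |
| `mu_c`, `sigma2_c` | $-14$, $0.8$ | log-expression | observed control moments of the reference *E. coli* dataset |

## Known limitations

No multiplicity control: $\alpha$ is a per-gene working level, and the
sequential criterion controls nothing like an FDR across $n$ genes —
extending it that way is future work, as is dependence between genes. The
criterion's calls depend (weakly) on the processing direction, as discussed
above. Real-data applications need upstream normalisation and quality
filtering; the package starts from a clean log-expression matrix.
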