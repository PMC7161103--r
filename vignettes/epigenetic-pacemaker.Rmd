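---
title: "Closed-form fitting of the molecular clock and epigenetic pacemaker models"
author: "EpiPacemaker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-form fitting of the molecular clock and epigenetic pacemaker models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpiPacemaker)
```

# The models

A methylation data set is an $n \times m$ matrix $\hat S = [\hat s_{ij}]$ of
observed methylation levels at $n$ CpG sites across $m$ individuals, plus a
chronological age $t_j$ per individual. The **molecular clock (MC)** model
assumes each site methylates (or demethylates) at a constant rate:
$$\hat s_{ij} = s_i^0 + r_i t_j + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, \sigma^2) \text{ i.i.d.},$$
with per-site start state $s_i^0$ (expected level at $t = 0$) and rate $r_i$
(level change per unit time; either sign). The **epigenetic pacemaker
(EPM)** relaxes the clock: all sites of an individual may change their rates
*in concert*, keeping pairwise rate ratios fixed. That is equivalent to
replacing the individual's chronological age with a latent **epigenetic age**
$t_j$ that is estimated jointly with the site parameters. Under the Gaussian
noise model, maximum likelihood for either model is minimization of the
residual sum of squares
$$\mathrm{RSS} = \sum_{i \le n} \sum_{j \le m}
  \left(\hat s_{ij} - (s_i^0 + r_i t_j)\right)^2 .$$

Model assumptions worth keeping in mind: trajectories are linear in
(epigenetic) time, noise is homoscedastic and independent across entries,
and methylation levels are *not* constrained to $[0, 1]$ — the linear model
has no natural bounds, and the estimators do not clip.

# The closed-form site step

For fixed ages the MC problem is ordinary least squares in
$\beta = (r_1 .. r_n, s_1^0 .. s_n^0)$ against an $nm \times 2n$ design
matrix $X$ with one row per matrix entry ($t_j$ at column $i$, $1$ at column
$n + i$). Solving $\hat\beta = (X^\top X)^{-1} X^\top y$ naively costs
$O(n^3 m)$ time and $O(n^2 m)$ space, which is what `buildDesignSystem()` /
`solveMCNaive()` implement (via a stable QR solve rather than a literal
inverse) — kept solely as a correctness oracle and gated to
$nm \le 10^6$ entries.

The structure of $X$ makes all of that unnecessary:

* $X^\top X$ consists of four $n \times n$ *diagonal* blocks built from
  three reductions of the age vector:
  $\mathrm{diag}(\Sigma t^2), \mathrm{diag}(\Sigma t);
  \mathrm{diag}(\Sigma t), \mathrm{diag}(m)$
  (`assembleNormalMatrix()`).
* Its inverse factors through the single scalar
  $\Lambda = 1 / ((\Sigma t)^2 - m\,\Sigma t^2)$, with blocks
  $\Lambda\,\mathrm{diag}(-m)$, $\Lambda\,\mathrm{diag}(\Sigma t)$,
  $\Lambda\,\mathrm{diag}(\Sigma t)$, $\Lambda\,\mathrm{diag}(-\Sigma t^2)$.
  By Cauchy–Schwarz $(\Sigma t)^2 < m\,\Sigma t^2$ strictly unless all ages
  are equal, so $\Lambda < 0$ exists exactly when the problem is solvable;
  all-equal ages are rejected as degenerate (`computeTimeMoments()`).
* The projector $(X^\top X)^{-1} X^\top$ is two stacked *banded* matrices:
  the row for site $k$ is non-zero only on that site's $m$-wide column band,
  and the band entries depend only on the position $j$ within the band:
  $u_j = -m t_j + \Sigma t$ (rate rows) and
  $l_j = t_j \Sigma t - \Sigma t^2$ (start-state rows), each scaled by
  $\Lambda$.

So the exact minimizer is two banded dot products per site:
$$r_k = \Lambda \sum_j u_j \hat s_{kj}, \qquad
  s_k^0 = \Lambda \sum_j l_j \hat s_{kj},$$
computed by `siteStep()` in $O(nm)$ time and space with no matrix formed.

**Operation counting.** `siteStep()` reports an instrumented count of scalar
multiplications in `metadata()$multiplications`. The counter covers the two
shared band-coefficient vectors ($m$ multiplications each — the
preprocessing) and the two $n \times m$ banded products ($nm$ each), i.e.
exactly $2nm + 2m$. Two boundary choices are deliberate: the moment sums
$\Sigma t, \Sigma t^2$ live in `computeTimeMoments()` and are outside the
counter, and $\Lambda$ is kept as one scalar applied *after* accumulation —
$2n$ trailing rescalings instead of $2m$ pre-scaled coefficients plus worse
conditioning — also outside the counter's scope. The per-site accumulation
runs in ascending column order, making results bit-reproducible across runs.

**Index convention.** The site-$k$ band occupies the half-open column range
$[(k-1)m, km)$ in 0-based terms — exactly $m$ entries. (An inclusive reading
of both endpoints would span $m + 1$ columns; the expanded-diagonal
structure forces the half-open one.)

# The closed-form time step

For fixed site parameters the RSS separates over individuals, and each
column's contribution is quadratic in its $t_j$, so the derivative is linear
and the unique minimizer is the rational closed form
$$t_j = \frac{\sum_i r_i (\hat s_{ij} - s_i^0)}{\sum_i r_i^2},$$
computed by `timeStep()` with $nm + n$ multiplications ($\Sigma r^2$ once,
then one product per entry). A vanishing $\Sigma r_i^2$ means no site caries
any time signal and the ages are unidentifiable; values below `1e-300`
(effective underflow) are treated as that error case. Estimates are returned
unbounded: negative or super-chronological epigenetic ages are meaningful
(deceleration / acceleration), and the model imposes no constraint.

# The CEM driver

`fitEPM()` alternates the two exact conditional minimizers, starting from
the chronological ages. Since the times are the initialized quantity, the
first conditional maximization must be over the site parameters, so each
iteration is: site step, then time step, recording the RSS after each
half-step. Both half-steps weakly decrease the RSS, so the trace is
non-increasing and the iteration converges to a critical point; and because
the clock solution is the pacemaker solution with ages pinned, the final
EPM RSS can never exceed the MC RSS (up to floating-point rounding).

Tunable parameters:

* `deltaCEM` (default `1e-6`, RSS units): stop once a full iteration
  improves the RSS by no more than this. With methylation levels of order 1
  and the RSS scaling like $nm\sigma^2$, this is far below any meaningful
  change at the problem sizes the package targets.
* `improvement` (`"absolute"` default, `"relative"` available): on data
  whose scale is far from 1, the absolute threshold is either too lax or
  too strict; relative mode divides the improvement by the current RSS.
* `maxIters` (default 100): a cap, reported via `converged = FALSE` when
  hit. In practice the alternation contracts geometrically and single-digit
  iteration counts are typical.

**Gauge degeneracy.** The fitted surface is invariant under
$(t, r, s^0) \to (a t + b,\; r/a,\; s^0 - (b/a) r)$ for any $a \ne 0$: the
likelihood cannot identify the affine frame of the time axis. No constraint
or penalty is imposed — determinism comes from the fixed initialization, and
the reported e-ages live in the frame anchored by the chronological ages.
Consequently, comparisons against external truth should use correlation or
an explicit affine alignment (`affineAlign()`); the package's own tests do
exactly that.

# Model comparison

`likelihoodRatioTest()` implements the nested comparison. Profiling the
Gaussian likelihood over $\sigma^2$ turns the log likelihood ratio into
$\log\Lambda_{LR} = -\frac{nm}{2}\log(RSS_{MC}/RSS_{EPM})$, so
$$\chi^2 = -2\log\Lambda_{LR} = nm \log\!\frac{RSS_{MC}}{RSS_{EPM}}$$
(natural logarithm), asymptotically $\chi^2_m$: the pacemaker frees exactly
the $m$ individual ages. `df` is exposed as an argument for sensitivity
analyses but defaults to $m$. The asymptotic null calibration is not
asserted at small sizes; the package only guarantees $\chi^2 \ge 0$.

Numerical boundaries: the nesting inequality is enforced with a `1e-9`
relative tolerance (smaller violations are clamped to ratio 1, larger ones
are errors); an exactly zero $RSS_{EPM}$ yields $\chi^2 = \infty$, $p = 0$
with a warning. `compareModels()` additionally knows the data scale, and
when *both* fits land below the rounding floor
$10^4 \varepsilon^2 \sum \hat s_{ij}^2$ — achievable only on data the clock
fits exactly, where both RSS are accumulated rounding error of order
$10^{-30}$ and their ratio is arbitrary — it reports $\chi^2 = 0$, $p = 1$
rather than a ratio of rounding noise.

# The simulator

`simulateMC()` / `simulateEPM()` generate data with exactly the model's
assumed structure, from a single seeded generator in a fixed draw order
(ages, rates, start states, dilations, noise row-major), so every fixture in
the test suite is reproducible from a seed and nothing is stored on disk.
Defaults, chosen once as a plausible human-blood-like regime:

* ages uniform on $[0, 100]$ years;
* rates uniform on $\pm[0.001, 0.01]$ level/year — the magnitude that takes
  a CpG a few percent to tens of percent of the beta scale across a
  lifetime; the dead zone below $|r| = 0.001$ keeps every site informative
  so simulated times stay identifiable;
* start states uniform on $[0.1, 0.9]$;
* dilation multipliers log-normal with median 1 and `sdlog = 0.25`
  (typical pacemakers within roughly ±25% of chronological rate — enough
  signal to separate the models without being caricature);
* noise $\sigma = 0.05$ by default; the recovery experiments use
  $\sigma = 0.03$, which against a median signal of
  $|r| \cdot \mathrm{sd}(t^*) \approx 0.0055 \times 29 \approx 0.16$ puts
  the typical per-site signal-to-noise ratio near 5.

What the simulator deliberately does **not** emulate: beta-value compression
near 0 and 1 (no clipping by default — `clip = TRUE` exists for demos but
breaks the linear-Gaussian model, so no correctness test uses it), array
batch effects, probe cross-hybridization, missingness, heteroscedastic
noise, or nonlinear trajectories. Passing tests therefore demonstrate
correctness of the estimators *under the model's own assumptions*, not
robustness to real-array artifacts; on real data the standard practice of
restricting to the top age-correlated CpGs (`selectSites()`) is the main
defense.

# Site selection

`selectSites()` ranks sites by Pearson correlation between methylation and
age and keeps the top $k$ (1000 is the customary panel size). Ranking uses
the *absolute* correlation by default — demethylating sites are as
informative as methylating ones and the model permits negative rates — with
`signed = TRUE` available. Zero-variance sites have undefined correlation
and are never eligible; ties break by original site order, so the selection
is deterministic.

# Numerical choices, degenerate inputs, and sizes

* Degenerate ages (all equal) are rejected wherever $\Lambda$ is needed;
  ages are otherwise arbitrary reals (zero and negative values, e.g.
  gestational ages, are valid).
* Missing matrix entries are rejected at read time with the offending cell
  named, never imputed: the closed forms assume a complete matrix.
* Delimited output serializes doubles with 17 significant digits, so
  write/read round trips are bit-stable.
* The naive oracle solves by QR, not inverse-then-multiply; the contract is
  the RSS minimizer, which is identical.
* Test and acceptance problem sizes: oracle equivalence on 200 random
  instances with $n \le 20$, $m \le 15$; time-step optimality on 100 cases;
  recovery under noise at $n = 1000$, $m = 200$. These sizes make the whole
  suite run in seconds while exercising every closed form well beyond its
  boundary cases.

# Known limitations

* The CEM converges to a critical point of a non-convex surface; no
  multi-start or global search is attempted. The chronological-age
  initialization is the standard, well-behaved choice.
* The $\chi^2_m$ null distribution of the test is asymptotic; small-sample
  calibration is out of scope.
* The per-individual pacemaker is a single net time dilation; change-point
  reconstruction within a lifetime is not modelled.
* No array preprocessing (IDAT parsing, normalization, batch correction)
  is provided; inputs are assumed to be cleaned methylation levels.
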