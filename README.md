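# EpiPacemaker

Fast, closed-form fitting of the **molecular clock (MC)** and **epigenetic
pacemaker (EPM)** models to CpG methylation data, with a likelihood-ratio
test between them, a seeded simulator for both generative models, and a
command-line interface.

## The problem and the models

DNA methylation at age-associated CpG sites changes slowly and roughly
linearly over life, which is the basis of "epigenetic clock" age predictors.
Given an n × m matrix of observed methylation levels ŝᵢⱼ (site i,
individual j) and each individual's chronological age tⱼ, the molecular
clock model assumes a constant per-site rate:

    ŝᵢⱼ = sᵢ⁰ + rᵢ tⱼ + εᵢⱼ ,   εᵢⱼ ~ N(0, σ²) i.i.d.

with per-site start state sᵢ⁰ and rate rᵢ. The epigenetic pacemaker relaxes
this: all of an individual's sites may speed up or slow down *in concert*,
which is equivalent to replacing the chronological age tⱼ by an
individual-specific **epigenetic age** (e-age) that is estimated from the
data. The difference e-age − chronological age is the individual's *age
acceleration*. Maximizing the Gaussian likelihood is equivalent to
minimizing the residual sum of squares

    RSS = Σᵢ Σⱼ (ŝᵢⱼ − (sᵢ⁰ + rᵢ tⱼ))² .

**What makes this package fast.** For fixed ages, the MC problem is ordinary
least squares against an nm × 2n design matrix — naively O(n³m) time and
O(n²m) space. But the normal matrix XᵀX consists of four diagonal n × n
blocks (diag Σt², diag Σt, diag Σt, diag m), its inverse factors through the
single scalar Λ = 1/((Σt)² − m Σt²), and the projector (XᵀX)⁻¹Xᵀ is a pair
of banded matrices whose entries depend only on the position within the
band. The whole solve therefore collapses to two banded dot products per
site,

    rᵢ = Λ Σⱼ (−m tⱼ + Σt) ŝᵢⱼ ,    sᵢ⁰ = Λ Σⱼ (tⱼ Σt − Σt²) ŝᵢⱼ ,

exactly 2nm + 2m scalar multiplications, with no matrix ever formed
(**site step**). Conversely, for fixed site parameters each e-age has the
closed form

    tⱼ = Σᵢ rᵢ (ŝᵢⱼ − sᵢ⁰) / Σᵢ rᵢ² ,

nm + n multiplications (**time step**). The EPM fit alternates these two
exact conditional minimizers (a conditional expectation–maximization, CEM)
from the chronological ages until the RSS improvement drops below a
threshold; every half-step weakly decreases the RSS, so convergence to a
critical point is guaranteed. Because the MC model is the EPM model with the
ages pinned, the two fits are nested and compared by the likelihood-ratio
statistic χ² = nm · log(RSS_MC / RSS_EPM) on m degrees of freedom.

## Worked example

```r
library(EpiPacemaker)

## simulate pacemaker data: 500 sites, 100 individuals, noise sd 0.03
sim <- simulateEPM(n = 500, m = 100, sigma = 0.03, seed = 42)
me  <- sim$experiment
me
#> MethylationExperiment: 500 sites x 100 individuals
#>   ages: range [0.02389, 98.89]
#>   methylation levels: range [-1.092, 2.109]

fit <- fitEPM(me)
fit
#> EPM fit: 500 sites, 100 individuals
#>   final RSS: 44.4592 after 3 iterations (converged)
#>   age acceleration: median -2.842, range [-45.14, 68.61]

cor(eAges(fit), sim$truth$epigeneticAges)
#> [1] 0.9999751

head(round(ageAcceleration(fit), 2), 5)
#> ind0001 ind0002 ind0003 ind0004 ind0005
#>   16.79   18.45   -1.73   -5.32  -20.72

compareModels(me)
#> Likelihood-ratio test: molecular clock (null) vs epigenetic pacemaker
#>   RSS_MC = 549.106, RSS_EPM = 44.4592 (n = 500 sites, m = 100 individuals)
#>   chi-squared = 125686 on 100 df, p = 0
```

The final RSS (44.46) sits close to its expected noise floor
nm·σ² = 500·100·0.0009 = 45, the estimated e-ages track the simulated
truth almost perfectly, and the test overwhelmingly rejects the pure clock —
as it should, since the data were generated with per-individual pacemakers.
Per-individual age acceleration (e-age − chronological age) recovers each
simulated dilation.

Real data enter through delimited text: `readMethylationExperiment(matrix,
ages)` reads a sites × individuals table plus a two-column age table, and
`selectSites(me, k = 1000)` restricts to the CpGs most Pearson-correlated
with age before fitting, as is customary for methylation clocks.

## Command line

```sh
exec/epm simulate --model epm --n 500 --m 100 --sigma 0.03 --seed 42 --out-prefix demo
exec/epm fit --model epm --matrix demo.matrix.tsv --ages demo.ages.tsv --out-prefix demo_fit
exec/epm compare --matrix demo.matrix.tsv --ages demo.ages.tsv --out demo_compare.json
exec/epm select-sites --k 100 --matrix demo.matrix.tsv --ages demo.ages.tsv --out-prefix demo_sel
```

Every command writes a `*.manifest.json` (parameters, seed, input checksums,
version) sufficient to re-run it bit-identically. After installation the
script lives in the package's `exec/` directory
(`system.file("..", "exec", "epm", package = "EpiPacemaker")` from R, or
simply call `epmCLI()`).

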