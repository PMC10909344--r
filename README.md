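# capturebias

Parasite infection changes host behaviour, and with it the chance that an
infected animal is captured.  Field estimates of parasite-driven selection
— comparisons of infected and uninfected hosts — are therefore computed
from samples whose composition is itself distorted by the thing being
measured.  `capturebias` is an individual-based simulation laboratory for
disease ecologists and population geneticists that quantifies how much this
capture bias, and plain sampling error, distort three standard metrics:

1. **Fitness cost of infection** — the difference in mean offspring number
   between uninfected and infected parents,
   `D = mean(k | uninfected) − mean(k | infected)`, and its corrected form
   `D / mean(k | uninfected)`;
2. **Relative risk** of infection for the susceptible genotype class,
   `RR = Pr(infected | high-risk genotype) / Pr(infected | low-risk genotype)`;
3. **Allele-frequency change** between generations,
   `Δq = q(offspring) − q(parents)` for the resistance allele.

A diploid host population (default 5,000 founders, one diallelic locus) is
infected through a genotype-plus-noise risk model
`Pr(infected) = clamp(w·g + (1−w)·r_i, 0, 1)` with genotype risks 0.8/0.2,
bred in 2,500 monogamous pairs with Poisson fecundity (base rate 10)
penalized per infected parent, and then sampled in five robust-design bouts
of 500 captures in which infected hosts can be over- or under-represented
by a bias multiplier `c`.  Each run evaluates every metric on the full
population (truth) and on paired control (`c = 1`), increased
(`c ~ U(1.1, 1.9)`) and decreased (`c ~ U(0.1, 0.9)`) samples, and fits a
from-scratch maximum-likelihood **Cormack–Jolly–Seber** model with
infection-group-specific detection probability; the group difference
`Δp = p̂_infected − p̂_uninfected` is the field-usable bias diagnostic.
Across 200-run experiments, sampled metrics are regressed on true values by
**standardized major axis** (slope `sign(r)·s_y/s_x`, one-sample slope test
against 1), with Fligner–Killeen variance tests, Welch t-tests on `Δp`, and
a residual-versus-`|Δp|` diagnostic regression.

See `vignettes/capture-bias-methods.Rmd` for the full model description,
parameter meanings, and design choices.

## Worked example

```r
library(capturebias)

cfg <- scenario_config(scheme = "heterozygote_advantage",
                       n_runs = 50L, seed = 7L)
tab <- run_experiment("relative_risk", cfg)   # ~6 s at full scale
sma_slope_test(tab$relative_risk_full, tab$relative_risk_decreased)
```

```
SMA slope = 2.4867 (2.2119, 2.7956), n = 50
  H0 slope = 1: F = 318.7468, r = 0.9323, p = 7.82e-23
```

Read: across 50 runs in which infected hosts were under-captured
(`c ~ U(0.1, 0.9)`), the relative risk measured from the captured sample
grows about two and a half times as fast as the true relative risk — under-sampling
infected hosts starves the low-risk-genotype-infected cell of the 2×2
table, inflating RR — and the 1:1 slope is firmly rejected.  The same run
table carries the CJS diagnostic that flags this distortion in the field:

```r
delta_p_group_test(tab$delta_p_control, tab$delta_p_decreased)[c("t", "df", "p_value")]
```

```
$t
[1] 15.58803

$df
[1] 68.84073

$p_value
[1] 2.82979e-24
```

`summarize_experiment(tab)` emits the whole battery (SMA, Fligner,
residual diagnostics, Welch t-tests) as a tidy table, and
`report_summary()` prints it.  A thin command-line front end is installed
at `inst/scripts/capturebias` (`simulate`, `experiment`, `summarize`).

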