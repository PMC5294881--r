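# adaptci

Exact one-sided confidence limits for the response rate after an adaptive
one-arm two-stage clinical trial with a binary endpoint.

## The problem

Adaptive two-stage phase II designs enrol `n1` patients, stop early for
futility (`X1 ≤ r1(f)`) or efficacy (`X1 ≥ r1(e)`), and otherwise continue
with `n2(X1)` further patients — where `n2(X1)` is **non-increasing** in the
stage-1 response count `X1` — declaring activity when `X1 + X2 ≥ r(X1)`.
Once such a trial has run, the reported confidence interval must match the
one-sided test and must keep its nominal coverage *exactly*, using binomial
probabilities rather than asymptotics. The Clopper–Pearson construction
does this, but only in combination with a *stochastic ordering* of the
terminal sample space `Ω = {G1, G2, G3}` (futility stops, completed
two-stage runs, efficacy stops): for an observed outcome with confidence
set `Ω_φ(X1, X2)` — the outcomes at least as extreme under ordering φ — the
`1 − α` one-sided interval is

    (L, 1],   pi ∈ (L, 1]  ⇔  P(Ω_φ(X1, X2) | pi) > α.

`adaptci` implements six orderings φ of the completed runs:

| φ | statistic | total order? | exact? |
|---|-----------|--------------|--------|
| RR | two-rate tail area (stage-1 and combined rate both ≥ observed) | no | no |
| PV | exact p-value `P(X1,X2) = Σ_Θ b(x1'; n1, π0) b(x2'; n2(x1'), π0)` | yes | yes |
| RR-A | the RR limits themselves, re-ranked (two-step) | yes | yes |
| RR-B | average response rate `(X1+X2)/(n1+n2(X1))` (MLE) | yes | yes |
| RR-LR | rate × `√n2(X1)` | yes | yes |
| RR-Score | rate × `n2(X1)` | yes | yes |

plus the evaluation machinery used to compare them: exact coverage curves
`P(L(X1,X2) < π | π)`, simple average length `AL = Σ_G2 [1 − L]/M`,
expected length `EL(π) = Σ_G2 [1 − L]·b(x1; n1, π) b(x2; n2(x1), π)`, EL
ratios, and the practical subsample space `G2(CI)` of outcomes whose
second-stage rate lies inside the exact two-sided CI of their first-stage
rate. It is aimed at trial statisticians analysing a completed adaptive
study and at methodologists comparing interval constructions.

## Worked example

A trial with design parameters (π0, π1, α, β) = (30%, 50%, 0.05, 0.1)
observes 11/22 responses in stage 1, continues with `n2(11) = 35` patients
and sees 13 more responses. (The shipped design file is a synthetic
stand-in with these parameters, built for documentation and testing.)

```r
library(adaptci)

design <- read_design(system.file("extdata", "synthetic_design_30_50.json",
                                  package = "adaptci"))
design
#> Adaptive two-stage design: n1 = 22, r1(f) = 6, r1(e) = 12
#>   pi0 = 0.3, pi1 = 0.5, alpha = 0.05, beta = 0.1
#>   continuation:
#> # A tibble: 5 × 3
#>      x1    n2     r
#>   <int> <int> <int>
#> 1     7    41    26
#> 2     8    39    25
#> 3     9    38    25
#> 4    10    36    24
#> 5    11    35    24

space <- sample_space(design)
glance(space)
#> # A tibble: 1 × 4
#>   n_points    g1    m2    g3
#>      <int> <int> <int> <int>
#> 1      212     7   194    11
```

The combined response rate is 24/57 = 42.1%. The 95% one-sided lower
limits of the six orderings at the observed outcome:

```r
sapply(c("PV", "RR-A", "RR-B", "RR-LR", "RR-Score", "RR"), function(o)
  limit_table(space, o)$lower_limit[which(space$x1 == 11 & space$x2 == 13)])
#>       PV     RR-A     RR-B    RR-LR RR-Score       RR
#>    0.322    0.324    0.312    0.302    0.286    0.333
```

So the study reports, e.g., the PV interval (0.322, 1]: response rates of
32.2% or less are excluded at one-sided level 0.05, consistent with
rejecting π ≤ 30%. The RR limit (0.333) is the largest — it always
dominates PV — but RR is only a partial order and its coverage is **not**
guaranteed; the five total orderings are exact:

```r
glance(coverage_curve(space, limit_table(space, "PV")))
#> # A tibble: 1 × 4
#>   ordering alpha min_coverage pi_min
#>   <chr>    <dbl>        <dbl>  <dbl>
#> 1 PV        0.05        0.950  0.251
```

`average_length()`, `expected_length()`, `el_ratio()` and `g2_ci_subset()`
compare orderings; `autoplot()` draws coverage curves and per-outcome
interval lengths; `generate_design()` synthesizes valid random designs for
simulation. A command-line wrapper ships as `exec/adaptci`
(`validate`, `enumerate`, `limits`, `evaluate`, `generate`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","adaptci",package="adaptci"))')" \
  limits --design design.json --out out/ --ordering all --observed 11,13
```

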