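---
title: "Exact one-sided limits after an adaptive two-stage trial: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact one-sided limits after an adaptive two-stage trial: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptci)
```

## The trial model

A single-arm phase II trial tests `H0: pi <= pi0` against `Ha: pi >= pi1`
for a binary response, rejecting for high response counts. Stage 1 enrols
`n1` patients. With `X1` responses the trial stops for futility when
`X1 <= r1(f)`, stops for efficacy when `X1 >= r1(e)`, and otherwise
continues with `n2(X1)` further patients, declaring the treatment promising
when `X1 + X2 >= r(X1)`. The defining feature of the adaptive family
handled here is that `n2(X1)` is a *non-increasing* function of `X1`: the
more responses already in hand, the fewer additional patients are needed.
Classical designs with a constant second stage are the special case of a
flat `n2`, and `adaptci` handles them too.

The terminal sample space partitions into three groups: futility stops
`G1` (identified by `X1` alone), completed two-stage runs `G2` (pairs
`(X1, X2)`), and efficacy stops `G3`. `G3` may be empty (`r1(e) = n1 + 1`);
a futility stop with `X2` "absent" is a different outcome from a completed
run with `X2 = 0`, which is why `x2` is `NA`, never `0`, for stage-1 stops.
All probabilities in the package are exact binomial sums —
`b(x1; n1, pi)` for stage-1 stops and `b(x1; n1, pi) * b(x2; n2(x1), pi)`
for completed runs — never normal approximations.

## Orderings and the Clopper–Pearson inversion

After the trial, a one-sided lower confidence limit `L` for `pi` must agree
with the one-sided test. The Clopper–Pearson construction carries over once
the sample space is *ordered* by evidence strength: for an outcome `p` with
confidence set `Omega(p)` (the outcomes at least as extreme as `p`), the
`1 - alpha` interval is `(L, 1]` where `pi` belongs to the interval exactly
when `P(Omega(p) | pi) > alpha`. Six orderings are implemented:

* **RR** — the tail-area partial order: `q` is at least as extreme as `p`
  when both its stage-1 rate and its combined rate are at least `p`'s. Two
  completed outcomes are comparable only when one lies in the other's tail,
  so RR is *not* a total order and its limits are not exact.
* **PV** — order by the exact p-value, the null probability of the RR tail
  area. A total order; exact.
* **RR-A** — the two-step ordering: compute the (non-exact) RR limits, then
  order the space by those limits. A total order; exact.
* **RR-B** — the average response rate `(X1+X2)/(n1+n2(X1))`, equivalent to
  the MLE ordering. Exact.
* **RR-LR** / **RR-Score** — the rate scaled by `sqrt(n2(X1))` and by
  `n2(X1)` respectively, the binary-outcome forms of the likelihood-ratio
  and score orderings. Implemented exactly as these scalings are usually
  printed, i.e. without centering the rate at `pi0`; `ordering_metric()`
  documents the formulas. With a constant `n2` all three rate-based
  orderings coincide.

Stage-1 stops order marginally by `X1` under every approach — futility
stops lowest, efficacy stops highest — so their limits always equal the
Clopper–Pearson binomial limits at `n1`, computed directly via the
`Beta(x, n - x + 1)` quantile identity.

The package's central theoretical property (verified as a test invariant)
is the tail-area inclusion: the RR tail of an outcome is contained in its
PV confidence set, hence `P(Omega_PV | pi) >= P(Omega_RR | pi)` everywhere
and the RR limit is always at least the PV limit. The RR limit's excess is
exactly what breaks its coverage: because RR cannot compare all pairs of
outcomes, its confidence sets are not nested and coverage can fall below
`1 - alpha` (on the shipped synthetic `pi0 = 20%` design it dips to about
92% at nominal 95%, while PV, RR-A and RR-B hold the level).

## Numerical choices

* **Rate comparisons are exact.** Tail-area membership compares rational
  numbers by integer cross-multiplication; ties (equal rates) are inside
  the tail, and tied ordering statistics always share a rank, so tied
  outcomes are always inside each other's confidence sets. This is what
  preserves the coverage guarantee at tie points.
* **Inversion.** `P(Omega | pi)` is profiled on a 512-point grid; the
  reported limit is the first upcrossing of `alpha`, refined by `uniroot`
  to better than 1e-8. For an upper-set `Omega` (RR, PV, RR-A, RR-B) the
  profile is non-decreasing and this is the unique root of
  `P(Omega | pi) = alpha`. The uncentered RR-LR/RR-Score statistics can
  produce confidence sets that are *not* upper sets, with non-monotone
  profiles; the set `{pi : P > alpha}` is then not an interval, and the
  package reports the left endpoint of its one-sided interval hull — the
  first upcrossing — which is the choice that keeps coverage at `1 - alpha`
  (taking the *last* upcrossing instead demonstrably loses coverage). A
  warning counts the affected outcomes. In the extreme case (seen for
  top-ranked RR-LR/RR-Score outcomes of designs without an efficacy stop)
  a confidence set's probability never reaches `alpha`; the inversion set
  is empty and the outcome receives the empty interval `L = 1`, again with
  a warning. Coverage is unaffected because such outcomes have probability
  below `alpha` at every `pi`.
* **RR-A ties.** RR limits are floating-point, so the two-step ordering
  treats limits within 1e-10 as tied.
* **Coverage curves.** Coverage `P(L(X1,X2) < pi | pi)` uses the strict
  inequality of the open interval `(L, 1]`. It jumps at the finitely many
  limit values, and its infimum is attained *at* a limit value (where the
  outcome with that limit is still uncovered), so the evaluation grid —
  0.001 to 0.999 in steps of 0.001 by default — is augmented with every
  limit value and the values ±1e-9 around it before the minimum is taken.
* **Degenerate inputs.** `x = 0` gives a zero lower limit (the interval is
  `(0, 1]`); a design with no futility bound uses `r1(f) = -1`; an empty
  `G3` uses `r1(e) = n1 + 1`. An empty `G2(CI)` subset (possible when
  second stages are very small and both attainable second-stage rates fall
  outside the stage-1 CI) makes the average length over that subset
  undefined, and the functions refuse rather than return a fabricated
  value.

## The synthetic design generator

`generate_design()` supplies the test battery. It emulates the structural
variety of adaptive two-stage designs rather than any optimality criterion:
stage-1 sizes 6–15 by default; no-efficacy-stop designs with probability
0.25; single-point continuation regions with probability 0.15; constant
second stages (the classical shape) with probability 0.2 and non-increasing
random step functions otherwise, with `n2` up to 10. Critical values are
drawn so the number of tolerated failures `x1 + n2(x1) + 1 - r(x1)` is
non-decreasing in `x1`, which makes the decision rule monotone — the
rejection probability is non-decreasing in `pi`, as any sensible design
should satisfy. What the generator does *not* emulate: calibrated
type I/II error rates (its `alpha`/`beta` fields are labels, not achieved
rates) and the sample sizes of real phase II trials (kept small so exact
enumeration over many designs stays fast). Passing tests therefore
demonstrate the *distribution-free* properties — exact coverage of the
five total orderings, the tail-area inclusion, CP equality for stage-1
stops — across design shapes, not the operating characteristics of any
published optimal design.

Two fixed designs ship under `inst/extdata/`, both with `synthetic` in the
name because they are this package's own constructions, not transcriptions
of published optimal designs: one with design parameters
`(30%, 50%, 0.05, 0.1)`, `n1 = 22` and `n2(11) = 35` so that the canonical
worked example — 11/22 responses then 13/35, combined rate 42.1% — runs
end to end, and one with `(20%, 40%, 0.05, 0.2)` on which the RR coverage
deficiency is clearly visible.

## Validation problem sizes

The shipped suite enumerates 50 generated designs (stage-1 size at most
15) for the coverage and ordering invariants, checks the inversion against
an independent dense-grid scan (step 1e-5, linear interpolation) on
designs small enough to brute-force (`n1 <= 6`, `n2 <= 3`), and runs a
32-configuration average-length sweep with `pi0` from 5% to 70% and
`pi1 - pi0` of 15 or 20 points. `scripts/acceptance.R` recomputes the same
quantities from scratch for any seed.

## Limitations

Lower limits only: exact upper limits are the mirror construction (order
reversal) and two-sided intervals would combine the two, but neither is
implemented. Designs are *inputs* — the package validates and analyses
them but does not search for optimal `(n1, n2(.), r(.))`. Point estimation
after an adaptive trial (the naive rate is biased) and exact p-value
inference are out of scope. Spaces with more than two stages or more than
one arm are not handled.
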