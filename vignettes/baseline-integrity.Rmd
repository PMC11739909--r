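---
title: "Screening baseline categorical data in randomized trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening baseline categorical data in randomized trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialscan)
```

## The statistical model

Randomization fixes the null model of a baseline table. Consider one
categorical baseline variable in a trial with arms of sizes
$N_1, \dots, N_G$ and level counts $n_{lg}$ (level $l$, arm $g$). If the
trial was run as described:

* **Arithmetic.** $\sum_l n_{lg} = N_g$ for every arm, and
  $\sum_{l,g} n_{lg} = N$. Any excess is impossible data; any shortfall
  is missing data or an error. Neither is a statistical question, which
  is why `check_sums()` is the first stage: it needs no model at all.
* **Allocation.** Conditional on the level totals $T_l$, the counts of a
  two-arm trial follow the multivariate hypergeometric law of drawing
  $N_1$ participants without replacement. For one level,
  $X \sim \mathrm{Hypergeom}(N, T, N_1)$ and the between-arm difference
  is $d = |2X - T|$. `freq_diff_distribution()` accumulates this law
  over every retained level and compares it with the observed histogram
  of $d$. Systematic excess at $d \in \{0, 1, 2\}$ means arms more alike
  than randomization can plausibly produce.
* **p-values.** A baseline p-value tests a hypothesis that is true by
  construction, so it follows its test's null distribution — uniform
  only asymptotically and only for the continuous-statistic tests.
  For small or sparse tables the attainable p-values are few and
  discrete, and exact-test p-values pile up near 1. Distributional
  screening therefore never assumes uniformity: the expected histogram
  is computed *empirically*, from datasets re-randomized under the
  binomial null (each participant's level drawn independently from the
  pooled level proportions, arm sizes fixed), with the same test applied
  to the same variables.
* **Studywise combination.** With $z_i = \Phi^{-1}(p_i)$, the studywise
  p-value is $\Phi(\sum_i z_i / \sqrt{k})$. Values near 1 mean the
  trial's baselines are collectively too similar; near 0, too
  dissimilar. Both tails are flagged (defaults 0.05 / 0.95, plus a 0.99
  stronger upper flag). The combination only has power against
  *collectively* extreme p-values — ten p-values all near 0.5 are a very
  unusual set, but combine to an unremarkable 0.5 — so it complements,
  never replaces, the distributional checks.

## The test battery and sparse data

Published tables rarely state which test produced a baseline p-value, so
`run_battery()` recomputes each one under all the common choices and
`match_reported()` asks whether *any* of them reproduces the printed
value. The battery:

| test | definition | applies to |
|---|---|---|
| `pearson` | $\sum (O-E)^2/E$, df $(L{-}1)(G{-}1)$ | any table with positive margins |
| `continuity` | Yates: $\sum \max(|O{-}E|{-}0.5, 0)^2/E$ | 2×2 |
| `fisher` | two-sided by probability ordering | 2×2 exact |
| `fisher_mc` | same ordering, Patefield-sampled null | r×c, Monte-Carlo |
| `midp` | tied tables (incl. observed) weighted ½ | 2×2 |
| `gtest` | $2\sum O \ln(O/E)$ | any table with positive margins |
| `oneway_*` | goodness-of-fit of per-arm totals | all-or-nothing variables |

Sparseness uses the conventional expected-cell rules: a 2×2 table is
sparse when any $E_{lg} < 5$; a larger table when any $E_{lg} < 1$ or
more than 20% of cells have $E_{lg} < 5$. Sparse tables make the
chi-square approximation unreliable; a reported p that matches a
chi-square computed on a sparse table is counted separately as test
misuse, not as vindication of the value.

Numerical conventions, fixed once:

* The two-sided Fisher p sums hypergeometric probabilities of all tables
  at most as probable as the observed one, with a *relative* tie
  tolerance of $10^{-7}$ — the convention of the dominant
  implementations. The mid-p test shares the enumeration and the same
  tie set, so mid-p ≤ Fisher holds on every table by construction (the
  suite verifies this exhaustively for all 2×2 tables up to $N = 30$).
* The Monte-Carlo r×c Fisher samples tables uniformly on the observed
  margins and reports $(1 + \#\{\text{tables} \le \text{observed}\}) /
  (B + 1)$, never 0; seed and $B$ are recorded in every result. Default
  $B = 10{,}000$.
* Matching uses the band $|p_{calc} - p_{rep}| \le 0.5 \cdot 10^{-d}$
  for a value printed with $d$ decimals, rather than literally
  re-rounding: the band is the union of all rounding conventions
  (half-up, half-even), so no convention mismatch can create a spurious
  non-match. It is a documented superset of any one convention.
  Threshold reports (">0.9999") match through the inequality, and the
  closest-distance is measured to the stated boundary.
* All-or-nothing variables (every count 0 or the full arm size) admit no
  two-way table. The one-way goodness-of-fit offers two expectation
  conventions: proportional to arm sizes (default; observed equals
  expected whenever the sums are clean, giving p = 1) and equal-split
  (informative under unequal arms). Which convention original analyses
  used is generally unrecoverable from a published value, so both are
  computed.
* Stouffer with $p_i = 1$ has no finite z; the conventional substitute
  $z = 3$ (≈ p of 0.998) is applied and flagged. $p_i = 0$ is handled
  symmetrically with $z = -3$ — a design choice here, since published
  practice documents only the p = 1 case — and every substitution is
  recorded so a sensitivity re-run can replace it.

## Distribution comparisons

The observed decile histogram of p-values is compared to the mean of the
simulated histograms with a chi-square-type statistic. Two details
matter. Bins whose expected count falls below 5 are merged with their
smaller adjacent neighbour until all expected counts reach 5 (the merge
map is reported). And because the reference histogram is itself
estimated from simulations, the statistic's null distribution is taken
from the simulations too: each simulated dataset's statistic is computed
against the mean of the *others* (leave-one-out), and the Monte-Carlo p
is the observed statistic's rank among them. The asymptotic
$\chi^2_{B-1}$ p is reported alongside for transparency, but the
Monte-Carlo p is the primary quantity — the asymptotic reference ignores
the estimation noise in the expected histogram.

For the frequency-difference distribution the default null is the exact
hypergeometric conditioning above (fixed-margins randomization); a
binomial Monte-Carlo alternative (independent per-arm draws at the
pooled proportion) is also shipped, since the two nulls answer slightly
different questions and the empirical p-value machinery uses the
binomial model. One level of every variable is dropped uniformly at
random before tallying, because with known arm sizes one level is an
exact linear function of the others — tallying all levels would
double-count every binary variable. The drop is seeded and recorded.

Test-selection policies (`p_policy()`) map each variable's table shape
and sparseness to a single test, covering the analysis variants of
interest: chi-square everywhere; exact tests on sparse 2×2 tables
(Fisher or mid-p); chi-square restricted to non-sparse tables; and the
mixed policies (mid-p for 2×2 with chi-square or Fisher for larger
tables). Fisher-based policies put visibly more mass in the top decile
than mid-p ones on the same sparse data — the property tests assert this
contrast rather than any particular histogram.

## The synthetic generator

`generate_trials()` is first-class, tested code, not a fixture: it
defines the study conditions under which the package's calibration
claims hold. Defaults emulate a typical published collection of small
parallel-arm RCTs: 170 trials; 80/15/5% two/three/four-arm; per-arm
sizes uniform on 20–80 with 70% of trials 1:1; `1 + Poisson(4.6)`
variables per trial (≈ 5.6 on average); 70/20/10% with 2/3/4 levels;
level probabilities from a symmetric Dirichlet(2); a reported p on 56%
of variables, produced by the Pearson test and printed with 2–4
decimals. Honest allocation is fixed-margins randomization (level
totals multinomial, arms filled by uniform allocation conditional on the
margins), with an independent-binomial option matching the simulation
null.

Anomalies are injected per variable at configured rates, each recorded
in a ground-truth ledger: `sum_error` perturbs one count by a nonzero
±1..5; `over_similar` redraws a two-arm variable's counts with
$|d| \le 1$ on every level (defined only for equal arms — arm-size
imbalance forces differences mechanically); `corrupt_p` replaces a
reported value with one rejection-sampled to match *no* battery test, so
its detection is deterministic and ledger-exact; `wrong_test` reports a
Fisher p where the chi-square was the convention; `threshold_p` turns a
numeric report into ">0.9999". Count-changing anomalies are applied
before p-corruptions so one injection cannot silently cancel another.

What the generator does *not* emulate — and what green calibration tests
therefore do not certify about real data: correlated baseline variables
(real characteristics co-vary; variables here are independent),
reporting idiosyncrasies beyond threshold strings (ranges, footnotes,
percent-only rows), non-1:1 randomization schemes such as blocked or
stratified allocation (which narrow the difference distribution
honestly), and any continuous-variable structure beyond per-row
summary-statistic t-tests.

## Calibration and recovery, as tested

The suite (and `scripts/acceptance.R`) verifies on the honest default
dataset: zero sum flags across all variables; a 100% reported-p match
rate (reported values are rounded test outputs, and the matching band is
exactly the rounding band); a studywise flag rate within 3σ of the
nominal 10% at 0.05/0.95 when restricted to non-sparse chi-square
p-values; and no frequency-difference excess beyond 3.5σ per support
point (3.5 rather than 3 because ~30 support points are tested
simultaneously; at 3σ a ~8% family-wise false alarm would make an exact
criterion flaky, at 3.5σ it is ~1%). On the injection dataset (20%
over-similar, 5% sum errors, 10% corrupted p): sum-error and corrupt-p
detections are ledger-exact — corrupt-p scored on variables whose
counts no other anomaly touched, mirroring the practice of analysing
sum-consistent variables separately — and the measured excess at
$d \le 1$ matches the ledger-predicted excess
$\sum_{\text{injected levels}} (1 - P_{null}(d \le 1))$ within 3σ.

Problem sizes are chosen to keep the default runs desk-scale while
leaving the estimates well-resolved: the calibration datasets use the
full 170-trial default; distribution comparisons in tests use 25–40
simulated null datasets; Monte-Carlo Fisher runs use 500–4000 samples in
tests and 10,000 at the pipeline default, matching the published
convention for r×c tables.

## Degenerate inputs and edge policy

Zero row/column margins make the chi-square family inapplicable
(reported as `applicable = FALSE`, never an exception); a 2×2 Fisher
with degenerate margins has a single attainable table and returns p = 1.
Variables whose level totals exceed the trial size are skipped from the
difference distribution with a warning — they are impossible data and
already flagged upstream. Missing reported p-values ("NS", blanks) are
parsed to an explicit `missing` kind with the verbatim string preserved
and are excluded from matching but counted. Excluded variables travel
through IO as flags, never as deletions, so analysed/excluded
bookkeeping is conserved end to end.

## Limitations

The package assesses *publication integrity* — internal consistency of
reported data with the stated design. A flag is a question, not a
verdict: extraction errors, typos, unreported analysis choices and
chance all produce flags, and distinguishing them requires
investigation, not statistics. Distributional findings (difference
excess, p-value histogram deviations) are properties of a collection
and support no inference about any individual trial. And where a
reported p matches several battery tests, matching identifies
consistency, not the test the authors actually ran.
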