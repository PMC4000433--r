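---
title: "Hierarchical hypothesis-set testing: model, procedures, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical hypothesis-set testing: model, procedures, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfdr)
```

## The testing problem

Ordered-category expression experiments — time courses, dose responses —
test several related hypotheses per gene. Gene $i$ carries individual
nulls $H_1(i), \dots, H_{n(i)}(i)$ (no change between successive time
points, or between each dose and baseline) plus a screening null
$H_0(i) = \bigcap_k H_k(i)$: the gene is not differentially expressed at
all. A gene (hypothesis set) is *rejected* when its screening null is
rejected, and *falsely rejected* when any true null inside it — screening
null included — is rejected. The package controls

$$\mathrm{OFDR} = E\!\left[\frac{V}{R \vee 1}\right], \qquad
  \mathrm{mdFDR} = E\!\left[\frac{V+S}{R \vee 1}\right],$$

where $R$ counts rejected sets, $V$ falsely rejected sets, and $S$
correctly rejected sets in which some true effect was declared with the
wrong sign (a directional, or type III, error). Since $S \ge 0$,
$\mathrm{OFDR} \le \mathrm{mdFDR}$ always, and the package asserts the
per-replication inequality, not just the aggregate.

## The two-step procedures

Step one screens: a per-set screening p-value is fed to the
Benjamini-Hochberg (BH) step-up procedure at level $\alpha$. Step two
tests individual hypotheses within each selected set with a family-wise
error rate (FWER) procedure at level $R\alpha/m$, and directions are
declared from the signs of the test statistics. The screening formula and
the second stage come in matched pairs:

| method       | screening $p_0(i)$                    | second stage      |
|--------------|----------------------------------------|-------------------|
| `bonferroni` | $n\,p_{(1)}(i)$                        | Bonferroni        |
| `holm`       | $n\,p_{(1)}(i)$                        | Holm step-down    |
| `hochberg`   | $\min_j\,(n+1-j)\,p_{(j)}(i)$          | Hochberg step-up  |

The screening p-value is exactly the smallest level at which the paired
FWER procedure would reject *something* in the set, so a selected set
always yields at least one individual rejection. Because the first two
share a screening formula they select identical sets on every input — a
property the test suite checks exactly — while Holm's step-down second
stage rejects a superset of Bonferroni's individual hypotheses, and the
Hochberg variant a superset of Holm's. OFDR control holds under
independence across sets; mdFDR control additionally uses the fact that
Bonferroni, Holm and Hochberg control directional errors for independent
two-sided t-statistics. Hochberg's second stage (and screening formula)
further requires independence or positive dependence *within* a set; with
successive-difference or common-baseline contrasts the within-gene
statistics are positively dependent, which is why `hochberg` is the
default in the expression front-end.

`simple_bh` is the deliberately naive comparator: BH on all pooled
individual p-values, a set counted as rejected when any member is. It
controls the individual-hypothesis FDR, rejects at least as many sets as
the Bonferroni-based procedure when all sets have equal size (the
guarantee does not extend to ragged collections, so the test asserting it
uses constant-size sets), and demonstrably fails to control the set-level
mdFDR.

### Numerical conventions

- Screening p-values are clipped to 1 for reporting; clipping never
  changes a BH decision because every BH threshold is below 1.
- Ties: all comparisons use $\le$, as in the formal step-up/step-down
  definitions, so tied p-values are rejected or retained together.
- $R = 0$ short-circuits step two entirely (the within-set level would be
  zero).
- A rejected hypothesis whose statistic is exactly zero gets direction 0
  and a warning — under continuous statistics this is a measure-zero
  event, but integer-valued or degenerate tests can produce it.
- Sets of unequal size are fully supported in `hset_test()`; the
  simulation and expression modules use a constant $q$.

## The simulation model

`simulate_timecourse()` / `run_experiment()` implement a standard
equicorrelated-normal time-course benchmark. With $m$ genes and $q+1$
time points, expression is $Z_{ji} \sim N(\mu_{ji}, 1)$, independent
across time points, with a common pairwise correlation $\rho$ across
genes within a time point. The successive-difference statistics and
p-values are

$$T_{ij} = \frac{Z_{j+1,i} - Z_{ji}}{\sqrt 2}, \qquad
  p_{ij} = 2\{1 - \Phi(|T_{ij}|)\},$$

so that $T_{ij} \sim N(\delta_{ij}, 1)$ with
$\delta_{ij} = (\mu_{j+1,i} - \mu_{ji})/\sqrt 2$. The $\sqrt 2$ in both
definitions is forced by internal consistency: two independent
unit-variance variables differ with variance 2, and only the
$\sqrt 2$-standardised statistic is standard normal under the null, as
the p-value formula requires.

Defaults are the reference study conditions: $m = 1000$ genes, 6 time
points ($q = 5$), $\alpha = 0.05$, $\rho \in \{0, 0.2, 0.5, 0.8\}$, 1000
replications, and $m - m_0$ false-null genes whose effect vectors are
drawn i.i.d. uniform from one of three intervals — $(-0.75, 0.75)$ with
probability 0.5 (weak, possibly sub-detectable effects),
$(-4.25, -2.75)$ and $(2.75, 4.25)$ with probability 0.25 each (strong
signed effects). Choices the model leaves open were fixed once:

- **Apportionment.** When $m - m_0$ is not divisible by the mixture,
  group sizes use largest-remainder apportionment with randomized ties.
- **Which genes are false-null** is uniform at random each replication;
  by exchangeability of the construction this is immaterial.
- **Baseline** $\mu_{1i} = 0$; only successive differences matter.
- **Equicorrelation sampling** uses the single-factor construction
  $Z_j = \mu_j + \sqrt\rho\,W_j + \sqrt{1-\rho}\,\varepsilon_j$, exact in
  distribution and $O(m)$ per draw instead of an $m \times m$ Cholesky.
- **Random numbers**: one seeded stream per experiment; every method sees
  the same data within a replication, so method contrasts are paired.
  Identical seed and configuration give bit-identical estimates.
- **$m_0$ grid**: `run_m0_sweep()` defaults to 11 evenly spaced points
  from 0 to $m$; the sweeps in the test suite use coarser 3–5 point grids
  with 200 replications, which keeps each sweep under a couple of minutes
  while leaving Monte-Carlo standard errors around $10^{-3}$ — small
  relative to every margin being tested.

What the generator does *not* emulate: autoregressive or block dependence
across time points, heavy-tailed or heteroscedastic noise, and
estimated-variance (t rather than z) statistics. Passing the simulation
checks therefore demonstrates control under exchangeable positive
dependence across genes with known unit variance, not under arbitrary
real-data dependence — which matches the scope of the available theory.

## Error and power accounting

`evaluate_decisions()` scores a decision report against the generating
truth. $V$ counts rejected sets containing any rejected true null, with a
rejected all-null set counting automatically (its screening null is
true); $S$ counts the remaining rejected sets with a wrong-signed
rejection of a real effect; the two are disjoint by construction.

Two notions of power are reported. *Power (I)* is the proportion of false
individual nulls correctly rejected; *power (II)* is the proportion of
false-null sets whose every internal decision is correct — each false
null rejected, no true null rejected. The one-line definitions leave a
choice: does a rejection with the wrong declared sign count as "correct"?
The package's default says no, for both metrics, consistent with the
directional-error framework that motivates the mdFDR; the alternative
reading is one flag away (`strict_direction = FALSE`). Both metrics error
on an empty denominator rather than silently returning 0.

Internally the Monte-Carlo runner uses vectorized matrix implementations
of the procedures and the accounting; property tests assert they agree
with the user-facing tibble interface on random instances, and both
routes are checked against `stats::p.adjust` and a literal brute-force
recount as independent oracles.

## The expression front-end

`analyze_expression()` applies the machinery to a genes-by-samples matrix
with an ordered category per sample (doses, time points). Per gene and
per contrast — `successive` (each category vs the previous) or `baseline`
(each vs the first) — it computes a two-sided two-sample t-test and the
sign of the mean difference, later minus earlier, so direction $+1$ means
induced. Welch's t is the default since expression variance is rarely
equal across groups; the pooled-variance t is available
(`test = "pooled_t"`). Genes are called `induced` when all significant
contrasts point up, `suppressed` when all point down, `mixed` otherwise,
and the report tabulates how many contrasts each significant gene
responds at — the dose-sensitivity distribution.

Degenerate inputs are handled conservatively: a contrast with zero
variance on both sides and equal means, or with fewer than two
non-missing replicates on either side, gets $p = 1$ and sign 0 with a
warning; zero variance with separated means gets $p = 0$. Categories with
fewer than two replicates are rejected at load time, as is an annotation
referencing samples absent from the matrix.

Values are assumed already normalized and log-scaled; normalization,
probe-to-gene mapping, fold-change filtering and enrichment analysis are
out of scope. The front-end is validated end to end on synthetic data
with known truth — repeated small datasets whose average observed false
discovery proportion must stay at the nominal level — because published
dose-response gene counts depend on preprocessing pipelines and on
per-gene test choices that are not part of this package's contract.

## Known limitations

- OFDR/mdFDR control across sets is proven under independence of each
  set's p-values from the other screening p-values; positive
  equicorrelation is covered empirically by the simulation study, but
  adversarial negative dependence is not.
- The Simes-based second stage is intentionally absent: it does not
  control the FWER, hence does not guarantee mdFDR control.
- Adaptive or weighted BH variants, dependence-adjusted
  (Benjamini-Yekutieli) screening, and moderated t-statistics for the
  expression front-end are out of scope.
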