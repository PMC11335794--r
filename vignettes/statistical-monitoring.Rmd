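---
title: "Statistical monitoring of key risk indicators: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical monitoring of key risk indicators: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statmon)
```

## The monitoring problem

Risk-based monitoring of a multi-site clinical trial asks a simple question
of every site, country, or other subset: is this group behaving differently
enough from the rest of the study to warrant follow-up? statmon answers it
with **key risk indicators** (KRIs): per-group metrics, each defined as a
numerator over a denominator, covering safety reporting (adverse and serious
adverse event rates, grade-3+ lab abnormalities), protocol compliance
(important and non-important deviation rates, study and treatment
discontinuation, screen failure), and data quality (query rate and age, form
entry lag, field change rate). `list_metrics()` enumerates the twelve
metrics in the registry. Rate-type metrics are denominated in exposure days;
percentage-type metrics in discrete opportunities (participants, samples,
queries, forms, data fields).

## The default analysis: an overdispersion-adjusted normal approximation

Let $y_i$ be the observed metric at group $i$ of $m$ evaluable groups, and
$\theta_0$ the pooled study-wide value (the overall proportion $\hat p$ for
percentages; the exposure-adjusted event rate $\hat\lambda$, total events
over total exposure, for rates). Under a binomial or Poisson model the
variance of $y_i$ is

$$V(Y \mid \theta_0) = \frac{\hat p (1 - \hat p)}{n_i}
\quad\text{or}\quad \frac{\hat\lambda}{T_i},$$

with $n_i$ the group's trial count and $T_i$ its total exposure days. Site
metrics in real trials are almost always more variable than these models
allow — sites differ in case mix, coding practice and operational habits —
so the unadjusted z-scores $z_i = (y_i - \theta_0)/\sqrt{V}$ are
overdispersed. statmon estimates the overdispersion factor as the mean
squared unadjusted z-score, $\varphi = \tfrac1m \sum_i z_i^2$, and reports
the **adjusted score**

$$z'_i = \frac{y_i - \theta_0}{\sqrt{\varphi^{*} \, V(Y \mid \theta_0)}},
\qquad \varphi^{*} = \max(\varphi, 1),$$

so that $z'_i = z_i / \sqrt{\varphi^{*}}$ and, whenever $\varphi > 1$, the
mean squared adjusted score is exactly 1. The method needs $m > 2$: with two
groups each one is always the mirror image of the other and the empirical
overdispersion has no degrees of freedom; such assessments are reported
"not evaluable" rather than scored.

**Why clamp $\varphi$ at 1.** The adjustment exists to keep the false-flag
rate honest when sites are heterogeneous. When the empirical $\varphi$ falls
below 1 (common with few groups and small counts, by chance), dividing by
$\sqrt{\varphi}$ would *inflate* every score and flag more aggressively than
the binomial/Poisson model itself — an anti-conservative move with no
substantive justification. The adjustment may therefore widen, never
shrink, the variance; the raw $\varphi$ is always reported alongside
(`glance()` on the analysis object) so under-dispersion remains visible.

**Degenerate inputs.** A pooled estimate at a boundary ($\hat p \in \{0,1\}$
or $\hat\lambda = 0$) leaves no variance to standardize against; the method
refuses with advice to use the exact test. Groups with a zero denominator
are excluded from $m$, $\theta_0$ and $\varphi$, and carried through as
"not evaluable" with flag 0. A subject with a zero denominator (no queries,
no exposure) contributes nothing to its group's totals — 0/0 carries no
information.

## Alternative methods

*Fisher's exact test* (percentages): each group is compared against all
other groups pooled in a 2×2 table; the two-sided p-value is the sum of the
probabilities of all tables, under the hypergeometric distribution with the
observed margins, that are no more probable than the observed one. A signed
$-\log_{10} p$ is reported as the score so all methods emit one orderable
column, but flagging uses the p-value and direction directly. The exact
test is the natural choice when events are rare or groups are few — exactly
where the normal approximation is weakest.

*Poisson regression* (rates): an intercept-only log-linear model of group
event counts with a log-exposure offset, scored by deviance residuals
$d_i = \mathrm{sign}(O_i - E_i)\sqrt{2[O_i \ln(O_i/E_i) - (O_i - E_i)]}$
with $E_i = \hat\lambda T_i$ (and the logarithmic term zero at $O_i = 0$,
so a zero-count group scores $-\sqrt{2E_i}$). The fit is delegated to
`stats::glm`; the closed form above serves as an independent cross-check in
the test suite. Deviance residuals approach the unadjusted normal z-scores
as counts grow, but behave better at small counts. Note the Poisson score
is *not* overdispersion-adjusted; with visibly heterogeneous sites the
default method is the more conservative choice.

No multiple-testing correction is applied by any method: flagging uses
fixed score thresholds per metric, and a study run evaluates twelve metrics
across all sites. Users who need family-wise control should tighten
thresholds accordingly; the per-group p-values are exported to make that
possible.

## Flags and thresholds

Scores become five-valued directional flags: sign = side of the study-wide
value, magnitude 2 (red) or 1 (amber) by threshold, 0 (green) otherwise.
Defaults mirror conventional monitoring practice — amber 2, red 3 on z-type
scores (2σ/3σ); amber 0.05, red 0.01 on Fisher p-values — and are
user-configurable per workflow. Boundaries are inclusive on the more
extreme side: a score sitting exactly on a threshold is flagged at that
level, a deterministic tie rule. Thresholds are symmetric in magnitude for
high and low deviations; asymmetric cutoffs are not supported and low-side
flags carry the same severity as high-side ones.

## Workflows, grouping, filters, snapshots

A workflow YAML names a metric and optionally a method, grouping level
(site, country, or a custom demographics column), subject filters, and
thresholds. Filters use a minimal grammar — domain, column, operator
(`eq`, `ne`, `in`), value — and keep the subjects satisfying *all* filters,
so application order can never matter; "randomized and treated" is two
`eq` filters on demographics flags. Assessments execute five stages —
build per-subject inputs, aggregate to groups, analyze, flag, summarize —
each replaceable by a user function honoring the same contract (stage
injection by named hook; the smallest API surface that supports
study-specific customization). Every intermediate artifact is retrievable
from the run log.

The analysis snapshot date is an explicit parameter, defaulting to the
latest date observed in the data — never the wall clock — so a re-run of
the same data is reproducible. It matters for the query-age metric: the
age of a query is (close date if closed, else snapshot date) minus open
date, and "aged" means strictly more than 30 days, so a query closed after
a long life still counts against the period in which it was open.
Boundary values (exactly 30 days; forms entered exactly 10 days after the
visit) are not flagged, a literal reading of the printed definitions.

The query-rate and field-change metrics are denominated in data fields,
which only an audit-style EDC export (`fd` domain) can supply; when that
domain is absent, those workflows are skipped with a warning rather than
failing the study run. Snapshot stores require strictly increasing dates
and feed the longitudinal views.

## The synthetic-trial generator

`simulate_trial()` emulates the operational texture of a mid-size
multi-site trial so the whole pipeline is testable without external data.
Per site $i$, an effect $b_i \sim N(0, \sigma^2)$ multiplies every rate and
probability by $e^{b_i}$ — a log-normal heterogeneity model chosen because
it keeps rates positive and because the $\varphi$ adjustment is agnostic to
the true mixing distribution. Event counts are Poisson in exposure days;
binary outcomes are Bernoulli with probabilities clamped to $[0, 0.99]$ so
large effects or injections keep draws valid; queries are drawn per data
field (binomially) so the percentage invariant numerator ≤ denominator
holds by construction. Risk injections multiply one site's rate or
probability for one metric. A single global seed drives a per-domain,
per-site stream-split RNG, so generating a subset of domains never
perturbs the draws of the rest.

Defaults describe the study conditions used throughout the package's own
checks: 20 sites of 25–35 subjects, 60–120 days on study, AE rate
0.10/subject-day, SAE rate 0.01, 5% grade-3+ samples, non-important /
important deviation rates 0.02 / 0.005 per day, 15% study and 20%
treatment discontinuation, 5% of fields queried, 25% of queries aged, 10%
late form entry, 10% changed fields, 15% screen failure, site effect
σ = 0.2. Structural choices the model leaves open are fixed at realistic
values: 4–12 lab samples and 6–12 forms per subject, 25 fields per form,
70% of queries closed by the snapshot, enrollment at the study start date.

What the generator does *not* emulate — and what passing tests therefore
cannot show about real data: staggered enrollment and time-varying rates,
correlated risk across metrics beyond the shared site effect, informative
discontinuation, visit-schedule structure, country-level effects beyond
site membership, or messy source formats (the mapping layer is exercised
with synthetic dialect files instead).

## Operating characteristics, as verified by the test suite

The acceptance tests (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) check, at these problem sizes:

* worked examples for all three methods on three-group studies, against
  hand/oracle arithmetic (to 1e-3, with 1e-10 oracle equivalence on 200
  random instances, and exact rational-arithmetic agreement for Fisher
  p-values at table totals up to 60);
* the algebraic identity $z' = z/\sqrt{\varphi^*}$ and renormalization of
  adjusted scores;
* null calibration: 500 replicates of 100 sites at σ = 0.5 — the red-flag
  rate at $|z'| \ge 3$ stays at or below 2% and the empirical variance of
  $z'$ within [0.7, 1.3];
* risk recovery: 200 replicates of 20 sites × 30 subjects × ~90 days at
  σ = 0.2 with one site's AE rate tripled — the injected site is
  red-flagged in at least 90% of replicates with false reds at or below 2%
  of site-replicates;
* end-to-end determinism: a seeded simulated study through all twelve
  default workflows, exports, and the HTML report, byte-identical on
  re-run, with every report number equal to the exported value.

## Known limitations

Beta-binomial and mixed-effect alternatives, exact Poisson tests, QTL
analyses and unsupervised monitoring are out of scope. The twelve KRIs
cover enrollment, safety, compliance and data quality, not study
endpoints. The heatmap's "status" column is derived from enrollment and
disposition (any enrolled, non-discontinued subject ⇒ "active"), a
convention rather than a CDISC-defined state. The HTML report is static by
design; interactive drill-down belongs to other tooling, and the report
embeds the underlying per-point data as tables so no information is lost.
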