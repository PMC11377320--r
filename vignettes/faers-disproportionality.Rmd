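---
title: "Disproportionality analysis of spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous-report databases such as the FDA Adverse Event Reporting
System (FAERS) collect safety reports — each linking one or more drugs to
one or more MedDRA-coded adverse events — without a denominator of exposed
patients. Signal detection therefore rests on *disproportionality*: is an
event reported together with the drug of interest more often than the rest
of the database would predict? `faersdpa` implements the full analysis
chain for this question, as applied in published pharmacovigilance studies
of single drugs (the bundled defaults are set up for temozolomide, an
alkylating chemotherapy agent used mainly in glioma):

1. ingestion of the quarterly `$`-delimited ASCII tables (DEMO, DRUG,
   REAC, THER, OUTC, INDI),
2. deduplication to one report per case,
3. selection of the primary-suspect (PS) cohort for the target drug,
4. 2×2 contingency tables per event at MedDRA PT and SOC level,
5. four signal-detection statistics — ROR, PRR with χ², BCPNN information
   component, and the MGPS empirical-Bayes geometric mean — with a
   configurable positivity rule,
6. descriptive surfaces: baseline characteristics, annual counts,
   time to onset, indication tallies.

Because the source database is a multi-gigabyte download, the package
ships a synthetic-report generator with known ground truth; every stage is
tested against it.

## The 2×2 table and the frequency statistics

For one drug–event pair, reports are cross-classified as

|                | event        | other events |
|----------------|--------------|--------------|
| **target PS drug** | $a$      | $b$          |
| **all other drugs**| $c$      | $d$          |

with $N = a+b+c+d$ and expected count under independence
$E = (a+b)(a+c)/N$. The frequency statistics are the standard forms:

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
  \mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
  \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big)$$

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}, \qquad
  \mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{PRR} \pm 1.96
  \sqrt{\tfrac1a-\tfrac1{a+b}+\tfrac1c-\tfrac1{c+d}}\Big)$$

$$\chi^2 = \frac{N\,(|ad-bc| - yN/2)^2}{(a+b)(c+d)(a+c)(b+d)},$$

where $y \in \{0,1\}$ toggles the Yates continuity correction. The
Yates-corrected form is the default (it is the common choice in FAERS
disproportionality practice); the uncorrected form is a flag, and both are
pinned by oracle tests against the cell-sum definition
$\sum (|O-E'|-y/2)^2/E'$ over the four cells.

**Zero cells.** A zero cell makes ROR/PRR undefined. The default policy
returns an undefined-statistic marker (`NA`), which classifies as
"not evaluable" rather than raising an error; the Haldane–Anscombe 0.5
correction is available by flag. Corrections change interval widths
materially, so neither is applied silently.

## BCPNN information component

The information component is
$\mathrm{IC} = \log_2 \frac{p(\text{drug},\text{event})}
{p(\text{drug})\,p(\text{event})}$. The package uses the closed-form
posterior approximation of the original BCPNN formulation, with
Dirichlet/Beta priors whose parameters are expectation-matched to
independence ($\gamma_{11}=1$, $\alpha_1=\beta_1=1$, $\alpha=\beta=2$,
and $\gamma$ matched so that $E[\mathrm{IC}]=0$ under independence):

$$\gamma = \gamma_{11}\frac{(N+\alpha)(N+\beta)}
  {(a+b+\alpha_1)(a+c+\beta_1)},\qquad
  \mathrm{IC} = \log_2\frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
  {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}$$

$$V(\mathrm{IC}) = \frac{1}{\ln^2 2}\left[
  \frac{N-a+\gamma-\gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
  \frac{N-a-b+\alpha-\alpha_1}{(a+b+\alpha_1)(1+N+\alpha)} +
  \frac{N-a-c+\beta-\beta_1}{(a+c+\beta_1)(1+N+\beta)}\right]$$

with $\mathrm{IC025} = \mathrm{IC} - 2\sqrt{V(\mathrm{IC})}$. These exact
expressions are locked by tests (an independent scalar transcription, plus
the behavioural properties: IC $<0$ at $a=0$, $|\mathrm{IC}|<0.05$ when
observed equals expected at large $N$, IC025 $<$ IC always). The posterior
is defined for zero cells, which is why BCPNN needs no zero-cell policy.

## MGPS: the two-gamma empirical-Bayes shrinker

The DuMouchel model treats the observed count as
$a \sim \mathrm{Poisson}(E\lambda)$ with the relative reporting rate
$\lambda$ drawn from a two-component gamma mixture prior
$w\,\Gamma(\alpha_1,\beta_1) + (1-w)\,\Gamma(\alpha_2,\beta_2)$
(shape/rate). Marginally $a$ is then a mixture of negative binomials with
$\mathrm{size}=\alpha_i$ and $\mathrm{prob}=\beta_i/(\beta_i+E)$, and the
five hyperparameters are fitted by maximizing the summed log marginal
likelihood over all drug–event tables at one level (single stratum; the
seed analysis describes no stratification).

Numerical choices:

* optimization is Nelder–Mead on $(\log\alpha_1,\log\beta_1,\log\alpha_2,
  \log\beta_2,\mathrm{logit}\,w)$, started from DuMouchel's conventional
  values $(0.2,\,0.1,\,2,\,4,\,1/3)$, restarted until a whole restart
  improves the log-likelihood by less than $10^{-8}$;
* the search is boxed to shapes and rates in $[10^{-6},10^{6}]$. With few
  tables the marginal likelihood can ridge toward a point-mass prior
  (both parameters of one component growing without bound at a fixed
  ratio); the box makes the optimum proper while leaving interior
  solutions untouched;
* non-convergence raises an error that carries the best-found parameters.

The posterior of $\lambda$ given $a$ is again a two-gamma mixture,
$\Gamma(\alpha_i+a,\ \beta_i+E)$ with weights proportional to the
component marginals, so

$$\mathrm{EBGM} = 2^{\,E[\log_2\lambda\mid a]}
 = 2^{\sum_i Q_i\,(\psi(\alpha_i+a)-\ln(\beta_i+E))/\ln 2},$$

with $\psi$ the digamma function, and EBGM05 is the posterior 5th
percentile, solved by root-finding on the mixture gamma CDF to an absolute
tolerance of $10^{-6}$ on the $\lambda$ scale. Published temozolomide
tables label EBGM05 a "confidence interval" limit; under the MGPS model it
is a posterior (credibility) quantile, and it is implemented as such. Both
quantities are verified against adaptive quadrature of the explicit
Poisson–gamma densities, which never touches the closed forms.

## The positivity rule

The default `signal_criteria()` requires, simultaneously,

* $a \ge 3$ (minimum case count),
* $\mathrm{ROR} \ge 3$,
* $\mathrm{PRR} \ge 2$,
* $\mathrm{EBGM05} > 2$ (strict, following the stated rule's wording), and
* $\mathrm{IC025} > 0$.

The seed analysis states three numeric thresholds but requires agreement
of four algorithms; the BCPNN criterion IC025 $>0$ completes the rule and
is individually overridable (set any threshold to `NA` to disable it), as
are all others. At exactly the thresholds a pair classifies negative on
the strict criteria — the boundary semantics are tested.

## Counting conventions

FAERS-style analyses are ambiguous about the counting unit, and published
case-report columns usually exceed the case total, implying event-level
counting. The package default is `counting_unit = "event"`: the unit is
the distinct (case, event-label) pair, a case reporting the same PT twice
counts once for that PT, and the margins $a+b$, $c+d$ are identical across
labels at a fixed level. Case-level counting is a flag. At SOC level each
PT maps to its single primary SOC; by default a case contributing two PTs
of one SOC counts twice, so SOC cells are exact sums of PT cells (the
conservation property is asserted in tests), with within-case SOC
deduplication available by flag.

The background is every case whose PS drugs do not include the target —
including cases where the target appears as secondary suspect or
concomitant. Drug names are uppercased, punctuation-stripped and mapped
through a user-supplied synonym list; a small temozolomide list ships with
the package. The PT→SOC map is likewise an input file — MedDRA is
licensed, so the bundled map is synthetic and only for tests and examples.

## Ingestion conventions

* **Deduplication** keeps, per `caseid`, the report with the latest
  receipt date, ties broken by the largest `primaryid` (the FAERS
  "latest case version" convention). The rule is prominent because it
  changes every downstream count; it never edits fields, only removes
  whole reports, and is idempotent.
* **Ages** arrive with a unit code and are converted to years
  (DEC×10, YR, MON/12, WK/52.14, DY/365.25; HR and ages over 120 are set
  missing).
* **Dates** are parsed from the 8/6/4-digit styles; partial dates resolve
  to the first day of the period, malformed dates become missing and are
  counted, never dropped rows.
* **Country** prefers the reporter-country field and falls back to the
  occurrence country.
* Reports with no reaction rows, and DRUG/REAC/OUTC rows whose key matches
  no DEMO row, are dropped with logged counts, so "records surviving each
  filter" is auditable in the run log.

## Descriptive surfaces

Percentages are rounded half-up to two decimals, matching how published
baseline tables behave. Each variable uses its own denominator: sex uses
known-sex reports; age buckets (`<20`, `[20,40)`, `[40,60)`, `>=60`,
unknown — left-closed, 60 in the oldest bucket) include unknown as a
category; outcome percentages divide by the outcome-code total because one
case can carry several outcome codes. Published route tables can imply a
denominator differing by a few reports from the sex total; the package
reproduces each variable's own printed total rather than forcing one.

Time to onset is the lag from the earliest target-drug therapy start to
event onset. Negative and missing lags are excluded from the median and
quartiles and counted; binned percentages divide by **all included
reports** — reporting practice for published onset tables divides by the
full cohort, so a report with unknown onset stays in the denominator
(`denominator = "known"` is available). Default bins: ≤30, 30–60, 60–90,
90–180, 180–365, 365–730, >730 days.

## The synthetic-report generator

`generate_faers()` emulates the multi-table case structure so the pipeline
can be exercised and calibrated without a download:

* one PS drug per case, 0–2 secondary/concomitant drugs;
* events arise per PT as independent Bernoulli draws at the
  `background_rate` (default 0.05 over 25 PTs, so cases carry ~1.3 events,
  a realistic handful); a planted pair $(g,e,\lambda)$ raises the
  probability to $\min(1, \lambda \cdot \text{background\_rate})$ when the
  case's PS drug is $g$; a case drawing no event receives one uniformly,
  preserving the "every report lists an event" invariant;
* case ids are sequential and report ids are `caseid × 100 + version`;
  duplicates (default 5% of cases) re-emit all of a case's rows under
  version 2 with a later receipt date and **no other change**, so the
  dedup rule's correctness is checkable by construction;
* therapy start precedes onset by an exponential lag with mean 60 days,
  matching the scale of observed oncology onset medians (~45 days), and
  missingness rates for age (21%) and onset (45%) match what the target
  drug's published cohort shows;
* receipt years 2004–2023 with a linearly increasing trend.

What it deliberately does **not** emulate: reporting-source biases (Weber
effect, notoriety bias), free-text drug-name noise beyond the synonym
list, correlated events within MedDRA hierarchies, or secular changes in
the background rates. Passing tests therefore demonstrate that the
*statistics and plumbing* are correct and that the four-criteria rule has
the claimed operating characteristics under independence-plus-planted-
signal data — not that real FAERS signals are causal.

Operating characteristics asserted in the test suite (fixed seeds,
simulated study conditions of 2,000 cases, 6 drugs, 25 PTs per
replicate): planted pairs with $\lambda = 10$ and expected counts well
above 20 are flagged in ≥95% of 200 replicates (observed: 100%), and with
$\lambda \equiv 1$ fewer than 1% of drug–event pairs are flagged over 200
replicates (observed: 0% — shrinkage makes the joint rule conservative
under the null). The MGPS fit on 5,000 cells simulated from a single
$\Gamma(2, 4)$ prior recovers both parameters within ±25%, with ≥0.9 of
the mixture weight on components in that band. These problem sizes were
chosen to give stable rates at interactive runtimes.

## A worked fixture

`fixture_small()` is a 20-row hand-written dataset (18 cases, two
duplicate reports, one missing age, one planted drug–event pair) whose
post-dedup counts, cohort membership, 2×2 cells and onset lags are all
documented in its help page and hand-verified in tests. It doubles as the
quick-start example and as the determinism fixture for the pipeline: two
runs from the same config produce byte-identical report bundles.

## Known limitations

* The MGPS fit is unstratified; age/sex/year stratification of expected
  counts is out of scope.
* Only the PT → primary-SOC level of MedDRA is modelled (no HLT/HLGT or
  SMQ groupings), and PT→SOC maps must be supplied by the user for real
  data.
* Wald intervals for ROR/PRR use 1.96 exactly; analyses built on other
  interval conventions will differ in the last digits.
* Duplicate detection is key-based (same case id). Probabilistic
  record-linkage dedup across different case ids is not attempted, so
  database-wide dedup totals from published analyses are not reproducible
  by construction.
* Multi-drug interaction signals and time-scan statistics are non-goals.
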