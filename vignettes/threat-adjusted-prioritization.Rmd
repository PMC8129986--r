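---
title: "Threat-adjusted cost-effectiveness prioritization of debt-conversion opportunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threat-adjusted cost-effectiveness prioritization of debt-conversion opportunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debtprior)
```

## The decision problem

Sovereign debt conversions (debt-for-nature swaps) restructure part of a
country's external debt in exchange for binding marine-conservation
commitments, typically the expansion of protected areas in the country's
Exclusive Economic Zone (EEZ). Negotiating one is expensive, so an
organization choosing among dozens of small island developing states and
coastal countries needs a transparent way to rank opportunities by expected
return on investment. `debtprior` implements a three-step framework for
that decision:

1. **Screening** — enabling conditions (economic, governance, political)
   filter the candidate list before any scoring happens.
2. **Scenario construction** — the analyst chooses benefit metrics and a
   threat classification, and varies them to build a matrix of scenarios.
3. **Prioritization** — each scenario produces a ranked list via a
   threat-adjusted cost-effectiveness score, and the top-k solution sets
   are compared across scenarios to see how robust the priorities are.

## The score

For each candidate the score is

$$\mathrm{CE} \;=\; \frac{B \, I_a \,(1 - \alpha I_u)\, P}{C},$$

where $B$ is the biodiversity benefit (EEZ area or coral-reef area, km²),
$I_a$ and $I_u$ are the country's additive burdens of *abatable* and
*unabatable* threats, $P$ the probability the action succeeds, and $C$ its
cost. The distinction between threat classes is the heart of the method:
marine protection can remove fishing pressure, benthic structures and
other direct human impacts ($I_a$ weights the benefit by how much threat
the action can actually abate), but it cannot touch climate-driven
stressors such as marine heat waves or acidification — those diminish the
expected payoff of acting at all, which the factor $(1-\alpha I_u)$
expresses as a counterfactual discount.

Burdens are sums of per-layer mean impact values (each layer normalized to
$[0,1]$ and averaged over the country's EEZ). Summing rather than
averaging means $I_u$ routinely exceeds 1, so a scaling parameter is
needed to keep the discount non-negative. The package sets
$\alpha = 1/\max(I_u)$ over the candidate pool: the most
unabatably-threatened country is discounted to exactly zero and everyone
else falls in $(0,1]$. When every country has $I_u = 0$ the convention
$\alpha = 0$ applies and the discount degenerates to 1.

Three consequences worth knowing:

* **Alpha is per scheme.** The pool maximum of $I_u$ depends on the threat
  classification (moving shipping into the unabatable class raises it), so
  one alpha per scheme is computed over the *full* candidate pool and
  shared across all filter/benefit scenarios using that scheme. Sharing a
  single alpha across schemes would either break the non-negativity
  guarantee or discount one scheme too weakly. A per-scenario
  recomputation switch exists (`alpha_scope = "scenario"` in
  `prioritize()`), at the cost of cross-scenario comparability of scores.
* **Exact zero at the boundary.** In floating point
  $\max(I_u)\times 1/\max(I_u)$ can miss 1 by one ulp, so discounts within
  $10^{-12}$ of zero are snapped to exactly 0. A discount below
  $-10^{-12}$ (possible only with a fixed alpha applied outside its pool)
  is a hard error, never clamped: silent clamping would hide a
  misconfigured alpha.
* **Zero abatable threat scores zero.** A country with $I_a = 0$ offers a
  protected area nothing to abate; the score is 0 regardless of $B$. The
  output keeps $B$, $I_a$ and the discount side by side so "no benefit"
  and "no abatable threat" remain distinguishable.

With no defensible estimates of $P$ and $C$ across candidates, both
default to 1 and the ranking is driven solely by threat-adjusted benefit;
column-sourced values are supported (`p_source = "column"`).

## Screening

Rules are inclusive threshold or flag tests (`debt_to_gdp >= 0.6`,
`sovereign is TRUE`) combined only conjunctively. The deliberate absence
of weighted scoring or disjunction follows the method's design stance:
enabling conditions form a decision tree, and ad-hoc weighting of
heterogeneous factors is exactly what screening should avoid. Alternative
conditions are explored as separate scenarios instead. A rule referencing
a missing field or a missing value fails loudly — screening must stay
auditable, so no candidate is ever dropped silently.

The shipped scenario design varies the debt-to-GDP threshold over
{none, ≥ 40%, ≥ 60%, ≥ 80%}, crosses it with two benefits (EEZ area,
coral-reef area) and two threat classifications (shipping abatable or
not), giving 16 scenarios. Debt ratios are stored as ratios (0.60), never
percent; loaders accept `percent = TRUE` to divide by 100 once at the
boundary.

## Ranking, ties and determinism

Candidates are ordered by descending score with ties broken by ascending
country id (radix order, locale-independent). Ranks run 1..n with no gaps.
The tie rule is arbitrary but fixed: reproducibility requires one, and an
all-tied pool (e.g. a coral scenario where no candidate has reef) simply
comes out in id order with zero scores. Scores are carried at full double
precision; rounding (2 decimals on benefit-scale columns, 4 on
dimensionless ones) happens only in the CSV writer, so repeated runs on
identical inputs are byte-identical.

## Comparing solution sets

Robustness across scenarios is measured on the *unordered* top-k sets
(default k = 10): pairwise Jaccard similarity
$J = |A \cap B| / |A \cup B|$, plus how many solution sets each country
appears in. Scenarios whose post-screening pool cannot fill a top-k set
are excluded and listed with the reason — the general form of dropping a
high-threshold scenario with too few candidates. Comparing two empty sets
is an error, not similarity 1: it signals a misconfigured run. For two
equal-size 10-sets the attainable similarities are exactly
$i/(20-i),\,i=0..10$, so the smallest non-zero overlap is
$1/19 \approx 0.053$ — one shared country out of ten. Rendered membership
percentages round half away from zero to whole percent; raw fractions are
preserved in `report.json`.

## The synthetic study

All tests and the acceptance script run on generated data, so the
generator is a first-class module. `generator_config()` defaults define
the study conditions:

* **53 candidates**, mirroring the scale of a global screen of small
  island developing states and coastal countries.
* **Debt ratios** uniform on 0.10–1.20, so every screening threshold
  (40/60/80%) separates the pool.
* **Areas** log-normal (EEZ: log-mean `log(2e5)`, log-sd 1.3; coral:
  log-mean `log(500)`, log-sd 1.8, with a 15% point mass at zero reef) —
  heavy-tailed, as real EEZ and reef inventories are.
* **19 threat layers**: 11 abatable (fishing fleets, benthic structures,
  shipping, direct human impacts, ocean-based pollution) drawn
  independently per country from Beta(mean 0.10–0.35, concentration 4–6),
  and 8 unabatable (heat stress, acidification, UV, sea-level rise,
  land-based inputs, invasives) with means 0.40–0.55. Unabatable layers
  share a latent per-country stress factor (Beta(mean 0.5,
  concentration 8)); each layer is then drawn tightly around
  $2\mu_\ell \times \mathrm{stress}$ (concentration 40). This gives the
  two class-level contrasts the analysis assumes: unabatable layers sit
  higher and vary less between countries (CV ≈ 0.37 vs ≈ 0.6–0.9), yet
  the *summed* unabatable burden still spreads enough between countries
  that the mean relative loss $\overline{\alpha I_u}$ lands near one half.
  Without the shared factor that combination is unreachable: a sum of 8
  independent bounded layers at low CV concentrates too hard for
  mean/max ≈ 0.54.

`calibrate_discount()` nudges the unabatable means by a common scale until
the mean relative loss hits a target (default 0.54 ± 0.10, evaluated at a
pool of 500 so the estimate is stable). A pure linear rescaling of $I_u$
cancels out of $\alpha I_u$; the scale works through the $[0,1]$
saturation of layer means, and the attainable range is floored by the
stress-factor spread — targets below it are reported as unattainable
together with the achieved value.

What the generator does *not* emulate: spatial structure, correlations
between debt and threat, real-country lookalikes, or the empirical layer
list of any particular impact database. Passing tests on this data show
the machinery is correct and the study regime reachable; they do not
reproduce any real-world ranking.

Determinism: generation is a pure function of the config (Mersenne-Twister
with inversion, fixed draw order), and the caller's RNG state is restored
afterwards.

## Problem sizes and numerical choices

The default study (53 countries, 16 scenarios, k = 10) runs in well under
a second; property tests use pools of 8–60 countries with up to 1,000
replicate pools, and calibration simulates 500 countries. Tolerances:
1e-12 on the alpha identity, threat-mass conservation and score
recomputations; 0.10 on the calibration target. Ties: lexicographic by
id, everywhere. Degenerate inputs: empty post-screening pools warn and
return empty rankings; an empty scenario list writes a manifest only;
all-zero unabatable pools take $\alpha = 0$.

## Known limitations

* Threats are treated as additive; antagonistic or synergistic
  interactions are out of scope, as is rescaling cumulative burdens into
  $[0,1]$ to avoid the alpha parameter altogether.
* The framework ranks; it does not optimize a portfolio under a budget.
* Whether a "before threats" benefit should be read as $B$ or
  $B \times I_a$ is a genuine ambiguity; outputs carry both so either
  comparison can be drawn (`plot(run, original = "b_ia")`).
* Governance and feasibility enter only as screening fields or as the
  $P$ column; the package constructs no indices of its own.
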